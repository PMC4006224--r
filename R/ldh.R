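# Local diffusion homogeneity: Kendall's coefficient of concordance (W) of
# the raw per-direction ADC series across each voxel's local neighbourhood.
# Each neighbourhood member is a "rater" ranking the gradient directions
# ("items") by diffusivity; W measures how much those rankings agree.

#' Kendall's coefficient of concordance (W)
#'
#' Each row is ranked independently (average ranks for ties); with
#' rank-sums `R_j` over the m rows,
#' `W = 12 sum_j (R_j - m(k+1)/2)^2 / (m^2 (k^3 - k))`. No tie-correction
#' term is applied: the ADC data this serves are continuous, so ties have
#' measure zero. A matrix whose rows are all constant yields W = 0 (there
#' is no rankable variation, and the rank-sum dispersion vanishes).
#'
#' @param series_matrix m x k numeric matrix, m >= 2 raters (voxels) by
#'   k >= 2 items (directions).
#' @return W in `[0, 1]`.
#' @export
kendalls_w <- function(series_matrix) {
  m <- nrow(series_matrix)
  k <- ncol(series_matrix)
  if (is.null(m) || m < 2) stop("need at least 2 rows (raters)")
  if (k < 2) stop("need at least 2 columns (items)")
  ranks <- t(apply(series_matrix, 1, rank))
  S <- sum((colSums(ranks) - m * (k + 1) / 2)^2)
  min(1, 12 * S / (m^2 * (k^3 - k)))
}

neighborhood_offsets <- function(size) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(size),
    "7" = ord <= 1,            # self + 6 face neighbours
    "19" = ord <= 2,           # + 12 edge neighbours
    "27" = ord <= 3,           # full 3x3x3 block
    stop("neighbourhood size must be 7, 19 or 27")
  )
  g[keep, , drop = FALSE]
}

#' Local diffusion homogeneity map
#'
#' For every in-mask voxel, the ADC series of its in-mask neighbourhood
#' members form the rater-by-item matrix of [kendalls_w()]. Each voxel's
#' series is ranked once and rank-sums are accumulated by shifted-array
#' addition, so the map costs O(neighbourhood) passes over the volume.
#' Voxels with fewer than `min_members` in-mask members (and all voxels
#' outside the mask) carry the sentinel 0.
#'
#' @param adc 4D ADC array from [adc_series()].
#' @param neighborhood 27 (default), 19 or 7.
#' @param mask logical 3D mask.
#' @param min_members minimum in-mask neighbourhood size (>= 4).
#' @return 3D LDH map in `[0, 1]`.
#' @export
ldh_map <- function(adc, neighborhood = 27, mask, min_members = 4) {
  stopifnot(length(dim(adc)) == 4, all(dim(adc)[1:3] == dim(mask)),
            min_members >= 4)
  shape <- dim(adc)[1:3]
  k <- dim(adc)[4]
  idx <- which(mask)
  series <- matrix(adc, ncol = k)[idx, , drop = FALSE]
  ranks <- t(apply(series, 1, rank))
  R4 <- array(0, dim(adc))
  for (j in seq_len(k)) {
    vol <- array(0, shape)
    vol[idx] <- ranks[, j]
    R4[, , , j] <- vol
  }
  offs <- neighborhood_offsets(neighborhood)
  Rsum <- array(0, dim(adc))
  m <- array(0, shape)
  maskd <- mask * 1
  for (r in seq_len(nrow(offs))) {
    Rsum <- Rsum + array_shift(R4, offs[r, ])
    m <- m + array_shift(maskd, offs[r, ])
  }
  Rsum_m <- matrix(Rsum, ncol = k)[idx, , drop = FALSE]
  mv <- m[idx]
  S <- rowSums((Rsum_m - mv * (k + 1) / 2)^2)
  W <- ifelse(mv >= pmax(min_members, 2),
              pmin(1, 12 * S / (mv^2 * (k^3 - k))), 0)
  out <- array(0, shape)
  out[idx] <- W
  out
}
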