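# Simplified tract-based spatial statistics on common-space cohorts: a
# mean-FA skeleton (ridge of the smoothed mean FA inside the FA > threshold
# mask) plus perpendicular maximum-FA projection of subject metric maps.
# The perpendicular ("across-tract") direction at each voxel is the
# dominant-curvature eigenvector of the smoothed mean-FA Hessian.

fa_hessian_dirs <- function(u, idx) {
  sh <- function(d) array_shift(u, d)
  dxx <- sh(c(1, 0, 0)) - 2 * u + sh(c(-1, 0, 0))
  dyy <- sh(c(0, 1, 0)) - 2 * u + sh(c(0, -1, 0))
  dzz <- sh(c(0, 0, 1)) - 2 * u + sh(c(0, 0, -1))
  dxy <- (sh(c(1, 1, 0)) + sh(c(-1, -1, 0)) -
            sh(c(1, -1, 0)) - sh(c(-1, 1, 0))) / 4
  dxz <- (sh(c(1, 0, 1)) + sh(c(-1, 0, -1)) -
            sh(c(1, 0, -1)) - sh(c(-1, 0, 1))) / 4
  dyz <- (sh(c(0, 1, 1)) + sh(c(0, -1, -1)) -
            sh(c(0, 1, -1)) - sh(c(0, -1, 1))) / 4
  H <- cbind(dxx[idx], dyy[idx], dzz[idx], dxy[idx], dxz[idx], dyz[idx])
  t(vapply(seq_len(nrow(H)), function(i) {
    h <- H[i, ]
    m <- matrix(c(h[1], h[4], h[5],
                  h[4], h[2], h[6],
                  h[5], h[6], h[3]), 3, 3)
    e <- eigen(m, symmetric = TRUE)
    e$vectors[, 3]                       # most negative curvature
  }, numeric(3)))
}

#' Build a mean-FA white-matter skeleton
#'
#' Averages the subject FA maps, keeps voxels with mean FA above the
#' threshold, and thins that mask to the FA ridge: a voxel stays on the
#' skeleton when the smoothed mean FA at the voxel is at least the values
#' one voxel away along +/- the across-tract direction (with at least one
#' strict inequality, so plateaus of zero curvature drop out). For a
#' straight slab this yields its mid-plane sheet.
#'
#' @param fa_maps list of 3D FA arrays on one (common-space) grid.
#' @param threshold FA threshold for the white-matter mask (default 0.2).
#' @param max_search_mm projection search half-length in mm (default 6).
#' @param voxdim voxel size in mm.
#' @param smooth_sigma Gaussian sd (voxels) for the ridge field.
#' @return Object of class `skeleton_model`: `skeleton` (logical 3D),
#'   `dirs` (n_skel x 3 across-tract unit directions, voxel space),
#'   `mean_fa`, `mask` (mean FA > threshold), `threshold`,
#'   `max_search_mm`, `voxdim`.
#' @export
make_skeleton <- function(fa_maps, threshold = 0.2, max_search_mm = 6,
                          voxdim = c(2, 2, 2), smooth_sigma = 1) {
  if (!is.list(fa_maps)) fa_maps <- list(fa_maps)
  mean_fa <- Reduce(`+`, fa_maps) / length(fa_maps)
  mask <- mean_fa > threshold
  if (!any(mask))
    stop("no voxel exceeds the FA threshold ", threshold,
         " (max mean FA ", format(max(mean_fa), digits = 3), ")")
  # normalised smoothing: dividing by the smoothed indicator removes the
  # artificial falloff at the array boundary, which would otherwise tilt
  # the ridge directions of edge columns
  u <- gaussian_smooth(mean_fa, smooth_sigma) /
    gaussian_smooth(array(1, dim(mean_fa)), smooth_sigma)
  idx <- which(mask)
  dirs <- fa_hessian_dirs(u, idx)
  coords <- cbind((idx - 1) %% dim(u)[1],
                  ((idx - 1) %/% dim(u)[1]) %% dim(u)[2],
                  (idx - 1) %/% (dim(u)[1] * dim(u)[2]))
  up <- trilinear_sample(u, coords + dirs)
  um <- trilinear_sample(u, coords - dirs)
  u0 <- u[idx]
  # both comparison points must sit inside the thresholded mask: rim
  # voxels whose across-tract direction points out of the white matter
  # are boundary artefacts, not ridge points
  maskd <- mask * 1
  inm <- trilinear_sample(maskd, coords + dirs) > 0.999 &
    trilinear_sample(maskd, coords - dirs) > 0.999
  on_ridge <- inm & u0 >= up & u0 >= um & (u0 > up | u0 > um)
  skeleton <- array(FALSE, dim(u))
  skeleton[idx[on_ridge]] <- TRUE
  structure(list(skeleton = skeleton,
                 dirs = dirs[on_ridge, , drop = FALSE],
                 mean_fa = mean_fa, mask = mask, threshold = threshold,
                 max_search_mm = max_search_mm, voxdim = voxdim),
            class = "skeleton_model")
}

#' @export
print.skeleton_model <- function(x, ...) {
  cat(sprintf(
    "<skeleton_model> %d skeleton / %d mask voxels (FA > %g)\n",
    sum(x$skeleton), sum(x$mask), x$threshold))
  invisible(x)
}

#' Project a subject metric map onto the skeleton
#'
#' For each skeleton voxel, the subject's FA is sampled along +/- the
#' across-tract direction up to `max_search_mm`; the location of the FA
#' maximum (the subject's local tract centre) supplies the metric value.
#' The search offsets include 0, so when the metric is FA itself the
#' projected value is never below the skeleton voxel's own FA. The same
#' FA-derived location is reused for MD and LDH maps.
#'
#' @param metric_map 3D metric array to project.
#' @param fa_map the same subject's 3D FA array (drives the search).
#' @param skeleton a [skeleton_model].
#' @return Numeric vector over skeleton voxels (order of
#'   `which(skeleton$skeleton)`), with attribute `offsets_mm` (signed
#'   search offset chosen per voxel).
#' @export
project_to_skeleton <- function(metric_map, fa_map, skeleton) {
  stopifnot(inherits(skeleton, "skeleton_model"),
            all(dim(metric_map) == dim(skeleton$skeleton)),
            all(dim(fa_map) == dim(skeleton$skeleton)))
  dm <- dim(fa_map)
  idx <- which(skeleton$skeleton)
  coords <- cbind((idx - 1) %% dm[1],
                  ((idx - 1) %/% dm[1]) %% dm[2],
                  (idx - 1) %/% (dm[1] * dm[2]))
  step <- min(skeleton$voxdim) / 2
  s <- seq(step, skeleton$max_search_mm, by = step)
  offsets <- c(-rev(s), 0, s)
  n <- length(idx)
  best_fa <- rep(-Inf, n)
  best_off <- numeric(n)
  dirs_vox <- skeleton$dirs / matrix(skeleton$voxdim, n, 3, byrow = TRUE)
  for (o in offsets) {
    pts <- coords + o * dirs_vox
    inside <- pts[, 1] >= 0 & pts[, 1] <= dm[1] - 1 &
      pts[, 2] >= 0 & pts[, 2] <= dm[2] - 1 &
      pts[, 3] >= 0 & pts[, 3] <= dm[3] - 1
    fa <- trilinear_sample(fa_map, pts)
    take <- inside & (fa > best_fa | (o == 0 & fa >= best_fa))
    best_fa[take] <- fa[take]
    best_off[take] <- o
  }
  pts <- coords + best_off * dirs_vox
  out <- trilinear_sample(metric_map, pts)
  attr(out, "offsets_mm") <- best_off
  out
}

#' Embed skeleton-voxel values back into a 3D array
#'
#' @param values vector over skeleton voxels.
#' @param skeleton a [skeleton_model].
#' @param fill background value.
#' @return 3D array.
#' @export
skeleton_to_volume <- function(values, skeleton, fill = 0) {
  out <- array(fill, dim(skeleton$skeleton))
  out[which(skeleton$skeleton)] <- values
  out
}
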