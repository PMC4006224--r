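# Diffusion tensor fitting and scalar metrics.
#
# The fit is ordinary least squares on the log-attenuation,
# ln(S0/S_g) = b g' D g, over the six unique tensor elements -- the
# standard log-linear fit. FA and MD come from the eigenvalues:
#   MD = mean(lambda);  FA = sqrt(3/2) ||lambda - MD|| / ||lambda||.

CLAMP_EPS <- 1e-6

#' Fit the diffusion tensor voxelwise by log-linear least squares
#'
#' `S0` is the mean of the b = 0 volumes; diffusion-weighted signals are
#' clamped to `1e-6 * S0` before the log so zero/negative noise
#' excursions stay finite. Voxels where any signal was clamped are flagged
#' in a QC mask but not excluded.
#'
#' @param dwi a [dwi_series] with >= 6 distinct directions and >= 1 b = 0
#'   volume.
#' @param mask logical 3D mask (default: voxels with `S0 > 0`).
#' @return A [tensor_field] with attributes `s0` (mean b = 0 volume) and
#'   `qc_clamped` (logical array: any clamped signal).
#' @export
fit_tensor_loglinear <- function(dwi, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_series"))
  X <- tensor_design(dwi$grad)
  dw <- attr(X, "dw")
  if (length(dw) < 6)
    stop("need >= 6 diffusion-weighted volumes, found ", length(dw))
  cond <- kappa(X, exact = TRUE)
  if (qr(X)$rank < 6)
    stop("gradient direction set is rank deficient (condition number ",
         format(cond, digits = 4), ")")
  shape <- dim(dwi$data)[1:3]
  b0 <- which(dwi$grad$bvals == 0)
  s0 <- apply(dwi$data[, , , b0, drop = FALSE], 1:3, mean)
  if (is.null(mask)) mask <- s0 > 0
  idx <- which(mask)
  s0v <- s0[idx]
  floor_v <- CLAMP_EPS * s0v
  S <- matrix(dwi$data[, , , dw], ncol = length(dw))[idx, , drop = FALSE]
  clamped <- S < floor_v                   # floor recycles down columns
  S <- pmax(S, floor_v)
  Y <- log(s0v / S)
  P <- X %*% solve(crossprod(X))           # (X'X)^-1 X' transposed
  Dfit <- Y %*% P
  D <- array(0, c(shape, 6))
  for (j in 1:6) {
    comp <- array(0, shape)
    comp[idx] <- Dfit[, j]
    D[, , , j] <- comp
  }
  qc <- array(FALSE, shape)
  qc[idx] <- rowSums(clamped) > 0
  out <- tensor_field(D, mask)
  attr(out, "s0") <- s0
  attr(out, "qc_clamped") <- qc
  out
}

#' Eigenvalues of packed symmetric tensors
#'
#' @param D6 m x 6 matrix (xx, yy, zz, xy, xz, yz).
#' @return m x 3 matrix of descending eigenvalues.
#' @export
tensor_eigenvalues <- function(D6) {
  D6 <- matrix(D6, ncol = 6)
  t(apply(D6, 1, function(d) {
    m <- matrix(c(d[1], d[4], d[5],
                  d[4], d[2], d[6],
                  d[5], d[6], d[3]), 3, 3)
    eigen(m, symmetric = TRUE, only.values = TRUE)$values
  }))
}

#' FA and MD maps from a tensor field
#'
#' MD is the eigenvalue mean (negative noisy eigenvalues are kept); FA is
#' the normalised eigenvalue dispersion, defined as 0 where all
#' eigenvalues vanish, and clipped to `[0, 1]`.
#'
#' @param tf a [tensor_field].
#' @return List with 3D arrays `fa` (dimensionless) and `md` (mm^2/s),
#'   0 outside the mask.
#' @export
tensor_scalars <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  shape <- dim(tf$D)[1:3]
  idx <- which(tf$mask)
  ev <- tensor_eigenvalues(matrix(tf$D, ncol = 6)[idx, , drop = FALSE])
  md_v <- rowMeans(ev)
  num <- rowSums((ev - md_v)^2)
  den <- rowSums(ev^2)
  fa_v <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  fa_v <- pmin(pmax(fa_v, 0), 1)
  fa <- array(0, shape); fa[idx] <- fa_v
  md <- array(0, shape); md[idx] <- md_v
  list(fa = fa, md = md)
}

#' Per-direction apparent diffusion coefficients
#'
#' `ADC_g = -(1/b) ln(S_g / S0)` for each b > 0 volume, with the same
#' signal clamping as the tensor fit (so the ADC ceiling is
#' `ln(1e6)/b`).
#'
#' @param dwi a [dwi_series].
#' @param mask logical 3D mask (default: `S0 > 0`).
#' @return 4D array (x, y, z, direction) of ADCs in mm^2/s, 0 outside the
#'   mask, with attribute `dw` (source volume indices).
#' @export
adc_series <- function(dwi, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_series"))
  shape <- dim(dwi$data)[1:3]
  dw <- which(dwi$grad$bvals > 0)
  b0 <- which(dwi$grad$bvals == 0)
  s0 <- apply(dwi$data[, , , b0, drop = FALSE], 1:3, mean)
  if (is.null(mask)) mask <- s0 > 0
  idx <- which(mask)
  s0v <- s0[idx]
  out <- array(0, c(shape, length(dw)))
  for (j in seq_along(dw)) {
    S <- dwi$data[, , , dw[j]][idx]
    S <- pmax(S, CLAMP_EPS * s0v)
    vol <- array(0, shape)
    vol[idx] <- log(s0v / S) / dwi$grad$bvals[dw[j]]
    out[, , , j] <- vol
  }
  attr(out, "dw") <- dw
  out
}
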