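# Rigid/affine transforms and the RMS-deviation head-motion score.
#
# All transforms are 4x4 homogeneous matrices acting on world coordinates in
# mm. A TransformChain stores one volume-to-reference transform per volume,
# the convention of FSL FLIRT .mat files. Head motion per transition is the
# RMS deviation of the difference transform over a sphere of radius R:
#
#   RMS = sqrt( R^2/5 * Trace(A'A) + t't ),   A = M - I
#
# with the rotation-centre correction t' = t + A %*% center, so that a pure
# rotation about `center` scores only its rotational displacement. The
# (1/5) R^2 factor is the average of x x' over a uniform ball of radius R.

#' Build a rigid transform from 6 parameters
#'
#' Rotations are applied in the order Rz Ry Rx about `center`, then the
#' translation is added, giving a world-mm homogeneous matrix.
#'
#' @param params numeric length 6: rotations (rad) about x, y, z then
#'   translations (mm) along x, y, z.
#' @param center rotation centre in world mm (default origin).
#' @return 4x4 rigid transform matrix.
#' @export
rigid_matrix <- function(params, center = c(0, 0, 0)) {
  stopifnot(length(params) == 6)
  cx <- cos(params[1]); sx <- sin(params[1])
  cy <- cos(params[2]); sy <- sin(params[2])
  cz <- cos(params[3]); sz <- sin(params[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  R <- Rz %*% Ry %*% Rx
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- params[4:6] + center - R %*% center
  M
}

check_transform <- function(m, what = "transform") {
  if (!is.matrix(m) || any(dim(m) != c(4, 4)) || !all(is.finite(m)))
    stop(what, " must be a finite 4x4 matrix")
  if (any(abs(m[4, ] - c(0, 0, 0, 1)) > 1e-6))
    stop(what, " bottom row must be (0, 0, 0, 1)")
  invisible(m)
}

is_rigid <- function(m, tol = 1e-6) {
  R <- m[1:3, 1:3]
  max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Construct a per-volume transform chain
#'
#' @param transforms list of 4x4 world-mm transforms, one per volume,
#'   mapping each volume to the reference.
#' @param reference index of the reference (non-diffusion-weighted) volume.
#' @return Object of class `transform_chain`.
#' @export
transform_chain <- function(transforms, reference = 1L) {
  stopifnot(is.list(transforms), length(transforms) >= 1)
  for (m in transforms) check_transform(m)
  structure(list(transforms = transforms, reference = as.integer(reference)),
            class = "transform_chain")
}

#' @export
length.transform_chain <- function(x) length(x$transforms)

#' @export
print.transform_chain <- function(x, ...) {
  cat(sprintf("<transform_chain> %d volumes, reference %d\n",
              length(x$transforms), x$reference))
  invisible(x)
}

#' RMS deviation between two transforms over a sphere of radius R
#'
#' Computes the difference transform `b a^-1`, splits it into the deviation
#' `A = M - I` from identity and the translation, corrects the translation
#' for the rotation centre, and returns
#' `sqrt(R^2/5 * Trace(A'A) + t't)` in mm. Identical transforms score 0;
#' a pure translation scores its Euclidean norm.
#'
#' @param a,b 4x4 world-mm transforms.
#' @param R sphere radius in mm (default 80, roughly cortex-to-head-centre).
#' @param center sphere/rotation centre in world mm; for data simulated by
#'   this package the field of view is centred on the origin, so the
#'   default `c(0, 0, 0)` is the geometric centre of the image.
#' @return RMS deviation in mm (non-negative scalar).
#' @export
rms_deviation <- function(a, b, R = 80, center = c(0, 0, 0)) {
  check_transform(a, "a"); check_transform(b, "b")
  stopifnot(R > 0, length(center) == 3)
  if (abs(det(a)) < 1e-12) stop("transform 'a' is singular")
  d <- b %*% solve(a)
  A <- d[1:3, 1:3] - diag(3)
  t <- d[1:3, 4] + A %*% center
  sqrt(R^2 / 5 * sum(A * A) + sum(t * t))
}

#' Per-transition head-motion trace of a transform chain
#'
#' The RMS deviation is computed for each consecutive pair of volume
#' transforms (volume i against volume i-1), i.e. motion relative to the
#' preceding volume, and summarised by the mean over all transitions.
#'
#' @param chain a [transform_chain] of length >= 2.
#' @inheritParams rms_deviation
#' @return Object of class `motion_trace`: list with `rms` (length
#'   n_volumes - 1, mm), `mean` (mm), `R` and `center`.
#' @export
motion_trace <- function(chain, R = 80, center = c(0, 0, 0)) {
  stopifnot(inherits(chain, "transform_chain"), length(chain) >= 2)
  tr <- chain$transforms
  rms <- vapply(seq_len(length(tr) - 1), function(i) {
    rms_deviation(tr[[i]], tr[[i + 1]], R = R, center = center)
  }, numeric(1))
  structure(list(rms = rms, mean = mean(rms), R = R, center = center),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d transitions, mean RMS %.4f mm (R = %g mm)\n",
              length(x$rms), x$mean, x$R))
  invisible(x)
}

#' Subject-level head-motion summary across sessions
#'
#' Arithmetic mean of the per-session mean RMS deviations.
#'
#' @param session_means numeric vector of per-session summary means (mm), or
#'   a list of [motion_trace] objects.
#' @return Scalar mean motion in mm.
#' @export
subject_motion_summary <- function(session_means) {
  if (is.list(session_means))
    session_means <- vapply(session_means, function(tr) tr$mean, numeric(1))
  stopifnot(length(session_means) >= 1, all(is.finite(session_means)))
  mean(session_means)
}

#' Read a 4x4 ascii transform file (FLIRT .mat dialect)
#'
#' @param path file with 4 whitespace-separated rows of 4 numbers.
#' @return 4x4 transform matrix.
#' @export
read_transform_mat <- function(path) {
  vals <- scan(path, what = numeric(), quiet = TRUE)
  if (length(vals) != 16)
    stop("expected 16 numbers (4x4) in ", path, ", found ", length(vals))
  m <- matrix(vals, 4, 4, byrow = TRUE)
  check_transform(m, paste0("transform in ", path))
  m
}

#' Write a 4x4 transform as ascii (FLIRT .mat dialect)
#'
#' @param m 4x4 transform.
#' @param path output file.
#' @export
write_transform_mat <- function(m, path) {
  check_transform(m)
  writeLines(apply(m, 1, function(r) {
    paste(formatC(r, format = "g", digits = 17), collapse = "  ")
  }), path)
  invisible(path)
}
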