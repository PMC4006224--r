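# Shared low-level array helpers: shifting, separable Gaussian smoothing,
# trilinear interpolation and mask adjacency used across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shift a 3D or 4D array along its spatial axes, zero-filling
#'
#' The fourth (volume/direction) axis, when present, is untouched.
#'
#' @param a 3D or 4D numeric array.
#' @param d integer shift `c(dx, dy, dz)` in voxels.
#' @return Array of the same shape with vacated entries set to 0.
#' @keywords internal
array_shift <- function(a, d) {
  dm <- dim(a)
  out <- array(0, dm)
  src <- vector("list", length(dm))
  dst <- vector("list", length(dm))
  for (i in 1:3) {
    n <- dm[i]
    s <- max(1L, 1L - d[i]):min(n, n - d[i])
    if (length(s) == 0 || s[1] > s[length(s)]) return(out)
    src[[i]] <- s
    dst[[i]] <- s + d[i]
  }
  if (length(dm) == 4L) src[[4]] <- dst[[4]] <- seq_len(dm[4])
  block <- do.call(`[`, c(list(a), src, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), dst, list(block)))
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k / sum(k)
}

smooth_along_dim <- function(a, dim_i, kern) {
  if (length(kern) == 1L) return(a)
  dm <- dim(a)
  n <- dm[dim_i]
  half <- (length(kern) - 1L) / 2L
  B <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - half):(j + half)
    ok <- idx >= 1 & idx <= n
    B[j, idx[ok]] <- kern[ok]
  }
  perm <- c(dim_i, setdiff(seq_along(dm), dim_i))
  ap <- aperm(a, perm)
  sm <- B %*% matrix(ap, nrow = n)
  aperm(array(sm, dm[perm]), order(perm))
}

#' Separable Gaussian smoothing of a 3D array (zero boundary)
#'
#' @param a 3D numeric array.
#' @param sigma kernel standard deviation in voxels (scalar or length 3).
#' @return Smoothed array of the same shape.
#' @keywords internal
gaussian_smooth <- function(a, sigma = 1) {
  sigma <- rep(sigma, length.out = 3)
  for (i in 1:3) a <- smooth_along_dim(a, i, gaussian_kernel_1d(sigma[i]))
  a
}

#' Trilinear interpolation at continuous voxel coordinates
#'
#' Coordinates are 0-based voxel indices; samples outside the array are 0
#' (constant padding), so an integer shift degenerates to a nearest lookup.
#'
#' @param vol 3D numeric array.
#' @param pts n x 3 matrix of 0-based voxel coordinates.
#' @return Numeric vector of n interpolated values.
#' @keywords internal
trilinear_sample <- function(vol, pts) {
  dm <- dim(vol)
  pts <- matrix(pts, ncol = 3)
  f0 <- floor(pts)
  w <- pts - f0
  acc <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- f0[, 1] + dx
    iy <- f0[, 2] + dy
    iz <- f0[, 3] + dz
    valid <- ix >= 0 & ix < dm[1] & iy >= 0 & iy < dm[2] & iz >= 0 & iz < dm[3]
    lin <- 1 + ix + dm[1] * (iy + dm[2] * iz)
    v <- numeric(nrow(pts))
    v[valid] <- vol[lin[valid]]
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
      (if (dy) w[, 2] else 1 - w[, 2]) *
      (if (dz) w[, 3] else 1 - w[, 3])
    acc <- acc + wt * v
  }
  acc
}

connectivity_offsets <- function(connectivity) {
  stopifnot(connectivity %in% c(6, 18, 26))
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
    "6" = ord == 1,
    "18" = ord >= 1 & ord <= 2,
    "26" = ord >= 1
  )
  g[keep, , drop = FALSE]
}

#' Adjacency of in-mask voxels in CSR form (0-based, for the TFCE kernel)
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return List with `ptr` (length n_mask + 1) and `idx`, both 0-based
#'   integer vectors over mask voxels ordered as `which(mask)`.
#' @keywords internal
build_adjacency <- function(mask, connectivity = 26) {
  dm <- dim(mask)
  ord <- array(0, dm)                     # 0 = outside mask (shift fill)
  ids <- which(mask)
  n <- length(ids)
  ord[ids] <- seq_len(n)
  offs <- connectivity_offsets(connectivity)
  from <- integer(0)
  to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    sh <- array_shift(ord, offs[r, ])
    nb <- sh[ids]
    ok <- nb >= 1
    from <- c(from, seq_len(n)[ok])
    to <- c(to, nb[ok])
  }
  o <- order(from)
  from <- from[o]
  to <- to[o]
  counts <- tabulate(from, nbins = n)
  list(ptr = c(0L, cumsum(counts)), idx = as.integer(to - 1L), n = n)
}

#' Generate all permutations of 1..n (n <= 9)
#' @keywords internal
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 9)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out[r + seq_len(nrow(sub)), ] <- cbind(i, matrix(rest[sub], nrow(sub)))
    r <- r + nrow(sub)
  }
  storage.mode(out) <- "integer"
  out
}

stage_log <- function(stage, t0, detail = "") {
  message(sprintf("[motiondiff] %-10s %6.2fs %s", stage,
                  as.numeric(Sys.time()) - t0, detail))
}
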