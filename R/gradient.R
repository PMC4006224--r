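# Gradient tables: construction, FSL bval/bvec I/O and the tensor design
# matrix shared by the simulator and the fitting code.

#' Construct a gradient table
#'
#' @param bvals numeric vector of b-values (s/mm^2), 0 for non-DW volumes.
#' @param bvecs 3 x n matrix of gradient directions (columns); non-zero-b
#'   columns are renormalised to unit length (with a warning when the stored
#'   norm differs from 1 by more than `norm_tol`).
#' @param norm_tol warn-and-renormalise tolerance on direction norms.
#' @return Object of class `gradient_table` with fields `bvals`, `bvecs`.
#' @export
gradient_table <- function(bvals, bvecs, norm_tol = 1e-6) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3) stop("bvecs must be a 3 x n matrix")
  if (ncol(bvecs) != length(bvals))
    stop("direction count (", ncol(bvecs), ") != b-value count (",
         length(bvals), ")")
  if (!any(bvals == 0)) stop("at least one b = 0 volume is required")
  dw <- which(bvals > 0)
  nrm <- sqrt(colSums(bvecs[, dw, drop = FALSE]^2))
  if (any(nrm == 0)) stop("zero direction vector at a non-zero b-value")
  if (any(abs(nrm - 1) > norm_tol))
    warning(sum(abs(nrm - 1) > norm_tol),
            " direction(s) renormalised to unit length")
  bvecs[, dw] <- sweep(bvecs[, dw, drop = FALSE], 2, nrm, "/")
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat(sprintf("<gradient_table> %d volumes (%d DW, b = %s; %d b=0)\n",
              length(x$bvals), sum(x$bvals > 0),
              paste(unique(x$bvals[x$bvals > 0]), collapse = "/"),
              sum(x$bvals == 0)))
  invisible(x)
}

#' Generate an approximately uniform gradient table
#'
#' Directions start from seeded random points on the sphere and are relaxed
#' by electrostatic repulsion between each point and all other points and
#' their antipodes, the standard construction for diffusion sampling
#' schemes. Deterministic for a fixed seed.
#'
#' @param n_directions number of diffusion-weighted directions (>= 6, the
#'   minimum for a determined tensor fit).
#' @param n_b0 number of leading b = 0 volumes.
#' @param b diffusion weighting (s/mm^2), > 0.
#' @param seed RNG seed.
#' @param n_iter repulsion iterations.
#' @return A [gradient_table] with `n_b0 + n_directions` volumes, b = 0
#'   volumes first.
#' @export
make_gradient_table <- function(n_directions, n_b0 = 1, b = 1500, seed = 0,
                                n_iter = 200) {
  if (n_directions < 6)
    stop("n_directions must be >= 6: the tensor fit is underdetermined")
  stopifnot(b > 0, n_b0 >= 1)
  set.seed(seed)
  p <- matrix(stats::rnorm(3 * n_directions), 3)
  p <- sweep(p, 2, sqrt(colSums(p^2)), "/")
  eta <- 0.05 / n_directions
  for (it in seq_len(n_iter)) {
    frc <- matrix(0, 3, n_directions)
    for (i in seq_len(n_directions)) {
      d1 <- p[, i] - p
      d2 <- p[, i] + p
      n1 <- colSums(d1^2)^1.5
      n2 <- colSums(d2^2)^1.5
      n1[i] <- Inf                       # no self-force
      frc[, i] <- rowSums(sweep(d1, 2, n1, "/")) +
        rowSums(sweep(d2, 2, n2, "/"))
    }
    p <- p + eta * frc
    p <- sweep(p, 2, sqrt(colSums(p^2)), "/")
  }
  flip <- p[3, ] < 0                     # canonical half-sphere
  p[, flip] <- -p[, flip]
  gradient_table(c(rep(0, n_b0), rep(b, n_directions)),
                 cbind(matrix(0, 3, n_b0), p))
}

#' Design matrix of the log-linear tensor model
#'
#' Row g of the design is `b * (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz,
#' 2 gy gz)` so that `X %*% d = b g' D g` for the tensor element vector
#' `d = (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`.
#'
#' @param grad a [gradient_table].
#' @return n_dw x 6 matrix with attribute `dw` (indices of b > 0 volumes).
#' @export
tensor_design <- function(grad) {
  dw <- which(grad$bvals > 0)
  g <- t(grad$bvecs[, dw, drop = FALSE])
  X <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  X <- X * grad$bvals[dw]
  colnames(X) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  attr(X, "dw") <- dw
  X
}

#' Read FSL-dialect bval/bvec files
#'
#' @param bval_path one whitespace-separated row of b-values.
#' @param bvec_path three whitespace-separated rows (x, y, z components).
#' @param b0_threshold b-values below this are treated as b = 0.
#' @return A [gradient_table].
#' @export
read_gradient_files <- function(bval_path, bvec_path, b0_threshold = 50) {
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  lines <- readLines(bvec_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 3)
    stop("expected 3 rows in ", bvec_path, ", found ", length(lines))
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(v)) stop("non-numeric token on line ", i, " of ", bvec_path)
    v
  })
  nc <- lengths(rows)
  if (length(unique(nc)) != 1 || nc[1] != length(bvals))
    stop("bvec column count (", paste(unique(nc), collapse = "/"),
         ") does not match bval count (", length(bvals), ")")
  bvals[bvals < b0_threshold] <- 0
  gradient_table(bvals, do.call(rbind, rows))
}

#' Write FSL-dialect bval/bvec files
#'
#' @param grad a [gradient_table].
#' @param bval_path,bvec_path output paths.
#' @export
write_gradient_files <- function(grad, bval_path, bvec_path) {
  fmt <- function(v) paste(formatC(v, format = "g", digits = 17),
                           collapse = " ")
  writeLines(fmt(grad$bvals), bval_path)
  writeLines(apply(grad$bvecs, 1, fmt), bvec_path)
  invisible(c(bval_path, bvec_path))
}
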