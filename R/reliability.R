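# Test-retest reliability: two-way ANOVA decomposition (random subjects,
# fixed sessions, one observation per cell) and the consistency intraclass
# correlation ICC = (BMS - EMS) / (BMS + (k-1) EMS). The session mean
# square (JMS) is computed and reported but never enters the ICC: fixed
# session effects are removed, not penalised.

#' Two-way ANOVA decomposition of an n x k test-retest table
#'
#' @param data numeric matrix, n >= 2 subjects (rows) by k >= 2 sessions
#'   (columns), no missing cells.
#' @return Object of class `anova_decomp` with mean squares `BMS`, `JMS`,
#'   `EMS`, sums of squares, `n` and `k`.
#' @export
anova_decompose <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 sessions")
  if (anyNA(data)) stop("missing cells are not supported (no imputation)")
  grand <- mean(data)
  ss_subject <- k * sum((rowMeans(data) - grand)^2)
  ss_session <- n * sum((colMeans(data) - grand)^2)
  ss_total <- sum((data - grand)^2)
  ss_error <- ss_total - ss_subject - ss_session
  structure(list(BMS = ss_subject / (n - 1),
                 JMS = ss_session / (k - 1),
                 EMS = ss_error / ((n - 1) * (k - 1)),
                 ss = c(subject = ss_subject, session = ss_session,
                        error = ss_error, total = ss_total),
                 n = n, k = k),
            class = "anova_decomp")
}

#' @export
print.anova_decomp <- function(x, ...) {
  cat(sprintf("<anova_decomp> n=%d k=%d  BMS=%.4g JMS=%.4g EMS=%.4g\n",
              x$n, x$k, x$BMS, x$JMS, x$EMS))
  invisible(x)
}

#' Consistency intraclass correlation coefficient
#'
#' `(BMS - EMS) / (BMS + (k - 1) EMS)`; not truncated, so sampling noise
#' can produce negative values. `BMS = EMS = 0` returns 0 by convention.
#'
#' @param decomp an [anova_decompose()] result, or a plain n x k matrix.
#' @param truncate clamp negative values to 0 (for comparison with tools
#'   that do; default `FALSE`).
#' @return Scalar ICC.
#' @export
icc <- function(decomp, truncate = FALSE) {
  if (is.matrix(decomp) || is.data.frame(decomp))
    decomp <- anova_decompose(decomp)
  stopifnot(inherits(decomp, "anova_decomp"))
  den <- decomp$BMS + (decomp$k - 1) * decomp$EMS
  val <- if (den <= 0) 0 else (decomp$BMS - decomp$EMS) / den
  if (truncate) max(0, val) else val
}

#' Voxelwise ICC map and its mask mean
#'
#' @param maps list over subjects, each a list over sessions of 3D arrays
#'   on one grid (every subject must have all k sessions).
#' @param mask logical 3D array restricting the computation (e.g. the
#'   skeleton); default everywhere.
#' @param truncate clamp negative voxel ICCs to 0 before averaging.
#' @return List with `icc` (3D array, 0 outside the mask), `mean_icc`
#'   (scalar mean over mask voxels), `bms`, `jms`, `ems` (3D arrays).
#' @export
icc_map <- function(maps, mask = NULL, truncate = FALSE) {
  n <- length(maps)
  k <- length(maps[[1]])
  stopifnot(n >= 2, k >= 2)
  dm <- dim(maps[[1]][[1]])
  for (s in maps) {
    if (length(s) != k) stop("every subject needs all ", k, " sessions")
    for (m in s) if (!all(dim(m) == dm)) stop("inconsistent map grids")
  }
  if (is.null(mask)) mask <- array(TRUE, dm)
  idx <- which(mask)
  Y <- array(0, c(length(idx), n, k))
  for (i in seq_len(n)) for (j in seq_len(k))
    Y[, i, j] <- maps[[i]][[j]][idx]
  grand <- apply(Y, 1, mean)
  subj <- apply(Y, c(1, 2), mean)
  sess <- apply(Y, c(1, 3), mean)
  ss_b <- k * rowSums((subj - grand)^2)
  ss_j <- n * rowSums((sess - grand)^2)
  ss_t <- apply((Y - array(grand, dim(Y)))^2, 1, sum)
  ss_e <- pmax(ss_t - ss_b - ss_j, 0)
  bms <- ss_b / (n - 1)
  jms <- ss_j / (k - 1)
  ems <- ss_e / ((n - 1) * (k - 1))
  den <- bms + (k - 1) * ems
  vals <- ifelse(den > 0, (bms - ems) / den, 0)
  if (truncate) vals <- pmax(vals, 0)
  to_vol <- function(v) { a <- array(0, dm); a[idx] <- v; a }
  list(icc = to_vol(vals), mean_icc = mean(vals),
       bms = to_vol(bms), jms = to_vol(jms), ems = to_vol(ems))
}

#' Simulate a two-way random-subject / fixed-session table
#'
#' `y_ij = mu + s_j + b_i + e_ij` with `b_i ~ N(0, sigma_b^2)` and
#' `e_ij ~ N(0, sigma_e^2)`; the analytic consistency ICC is
#' `sigma_b^2 / (sigma_b^2 + sigma_e^2)`.
#'
#' @param n subjects; @param k sessions.
#' @param sigma_b,sigma_e between-subject and residual sds.
#' @param session_shift fixed session effects (length k).
#' @param mu grand mean.
#' @param seed RNG seed.
#' @return n x k matrix.
#' @export
simulate_twoway <- function(n, k, sigma_b, sigma_e,
                            session_shift = rep(0, k), mu = 0, seed = 0) {
  stopifnot(sigma_b >= 0, sigma_e >= 0, length(session_shift) == k)
  set.seed(seed)
  b <- stats::rnorm(n, sd = sigma_b)
  mu + outer(b, session_shift, `+`) +
    matrix(stats::rnorm(n * k, sd = sigma_e), n, k)
}
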