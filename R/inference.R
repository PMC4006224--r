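# Voxelwise GLM of skeletonised metrics on head motion with nuisance
# covariates, TFCE enhancement and family-wise error control by the
# permutation distribution of the maximum TFCE statistic. Nuisance
# covariates are handled with the Freedman-Lane scheme: residuals of the
# reduced (nuisance-only) model are permuted, reduced-model fitted values
# are added back, and the full model is refit per permutation.

T_CAP <- 1e6

#' Build a GLM design matrix from a covariate table
#'
#' @param covars data frame with one row per subject; must contain the
#'   predictor columns.
#' @param predictors columns after the intercept (default motion, age,
#'   gender, handedness).
#' @param interest the variable the contrast selects (default "motion").
#' @param center mean-centre continuous predictors (motion, age); binary
#'   0/1 covariates are left as coded. Contrasts are unaffected.
#' @return Matrix n x p with attribute `contrast` (+1 on the column of
#'   interest).
#' @export
build_design <- function(covars, predictors = c("motion", "age", "gender",
                                                "handedness"),
                         interest = "motion", center = TRUE) {
  stopifnot(all(predictors %in% names(covars)), interest %in% predictors)
  X <- cbind(intercept = 1,
             as.matrix(covars[, predictors, drop = FALSE]))
  if (center) {
    for (col in intersect(c("motion", "age"), predictors))
      X[, col] <- X[, col] - mean(X[, col])
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)),
                               qrx$pivot[seq_len(qrx$rank)])]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  ctr <- as.numeric(colnames(X) == interest)
  attr(X, "contrast") <- ctr
  X
}

#' Voxelwise GLM t-statistics for a contrast
#'
#' Ordinary least squares per voxel:
#' `t = c'beta / sqrt(sigma^2 c'(X'X)^-1 c)` with
#' `sigma^2 = RSS / (n - p)`. Degenerate noiseless fits (RSS ~ 0) are
#' capped at +/- 1e6 instead of producing infinities.
#'
#' @param Y voxels x subjects matrix.
#' @param X subjects x predictors design (see [build_design()]).
#' @param contrast contrast vector (default: `attr(X, "contrast")`).
#' @return List with `t` (voxel vector), `beta` (contrast effect),
#'   `se`, `df`.
#' @export
glm_tstat <- function(Y, X, contrast = NULL) {
  contrast <- contrast %||% attr(X, "contrast")
  n <- ncol(Y); p <- ncol(X)
  stopifnot(nrow(X) == n, length(contrast) == p, n >= p + 2)
  XtXinv <- solve(crossprod(X))
  Bt <- XtXinv %*% t(X)                   # p x n
  B <- Bt %*% t(Y)                        # p x voxels
  fitted <- X %*% B
  rss <- colSums((t(Y) - fitted)^2)
  sigma2 <- rss / (n - p)
  cvc <- drop(t(contrast) %*% XtXinv %*% contrast)
  eff <- drop(t(contrast) %*% B)
  se <- sqrt(sigma2 * cvc)
  scale_ref <- sqrt(mean(rowSums(Y^2)) + 1e-300)
  tt <- ifelse(se > 1e-12 * scale_ref, eff / se,
               sign(eff) * T_CAP)
  tt <- pmin(pmax(tt, -T_CAP), T_CAP)
  list(t = tt, beta = eff, se = se, df = n - p)
}

#' TFCE parameter sets
#'
#' Presets follow common practice for the enhancement exponents: volumes
#' use H = 2, E = 0.5; skeletonised (sheet-like) data use H = 2, E = 1.
#' The integration step is `dh_frac * max(stat)`.
#'
#' @param preset "skeleton" or "volume".
#' @param H,E height and extent exponents (> 0); override the preset.
#' @param dh_frac integration step as a fraction of the map maximum
#'   (0 < dh_frac <= 0.1).
#' @param connectivity 6, 18 or 26.
#' @return List of class `tfce_params`.
#' @export
tfce_params <- function(preset = c("skeleton", "volume"), H = NULL,
                        E = NULL, dh_frac = 0.01, connectivity = 26) {
  preset <- match.arg(preset)
  H <- H %||% 2
  E <- E %||% if (preset == "skeleton") 1 else 0.5
  stopifnot(H > 0, E > 0, dh_frac > 0, dh_frac <= 0.1,
            connectivity %in% c(6, 18, 26))
  structure(list(H = H, E = E, dh_frac = dh_frac,
                 connectivity = connectivity, preset = preset),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' Only positive values are enhanced; evaluate a negative contrast by
#' flipping the sign of the map upstream.
#'
#' @param stat_map 3D statistic array (finite values).
#' @param mask logical 3D support mask.
#' @param params a [tfce_params()] list.
#' @param adjacency optional precomputed [build_adjacency()] result for
#'   `mask` (recomputed when `NULL`).
#' @return 3D TFCE array (0 outside the mask).
#' @export
tfce <- function(stat_map, mask, params = tfce_params(),
                 adjacency = NULL) {
  stopifnot(all(dim(stat_map) == dim(mask)))
  if (!all(is.finite(stat_map[mask])))
    stop("statistic map contains non-finite values inside the mask")
  adjacency <- adjacency %||% build_adjacency(mask, params$connectivity)
  sv <- pmax(stat_map[which(mask)], 0)
  mx <- max(sv)
  out <- array(0, dim(stat_map))
  if (mx <= 0) return(out)
  out[which(mask)] <- tfce_scores(sv, adjacency$ptr, adjacency$idx,
                                  params$dh_frac * mx, params$H, params$E)
  out
}

#' Permutation FWE-corrected inference with TFCE (Freedman-Lane)
#'
#' Per permutation, reduced-model (nuisance-only) residuals are permuted
#' over subjects, the full model is refit, and the maximum TFCE statistic
#' over the mask is recorded; `p_FWE(v) = (1 + #{max_perm >= TFCE(v)}) /
#' (1 + n_perm)`. When the requested `n_perm` reaches the number of
#' distinct permutations (n! for <= 8 subjects) the enumeration is
#' exhaustive and p-values are exact: `#{max >= obs} / n!` over all
#' permutations including the identity. Both contrast signs are evaluated
#' unless `alternative` restricts to one.
#'
#' @param Y voxels x subjects matrix (rows ordered as `which(mask)`).
#' @param mask logical 3D array locating the rows of `Y`.
#' @param X design matrix from [build_design()].
#' @param contrast contrast vector (default from `X`).
#' @param params a [tfce_params()] list.
#' @param n_perm requested permutations (>= 100 for production use;
#'   smaller values are allowed for exact/exhaustive runs and tests).
#' @param seed RNG seed (deterministic output).
#' @param alternative "both", "greater" (positive contrast) or "less".
#' @return List with 3D arrays `t`, `tfce_pos`, `tfce_neg`, `p_pos`,
#'   `p_neg` (NA outside the mask / unevaluated sign), the null maxima
#'   vectors, `n_perm_used` and `exhaustive`.
#' @export
permutation_fwe <- function(Y, mask, X, contrast = NULL,
                            params = tfce_params(), n_perm = 500,
                            seed = 0,
                            alternative = c("both", "greater", "less")) {
  alternative <- match.arg(alternative)
  contrast <- contrast %||% attr(X, "contrast")
  n <- ncol(Y)
  stopifnot(nrow(Y) == sum(mask), nrow(X) == n)
  adjacency <- build_adjacency(mask, params$connectivity)
  idx <- which(mask)

  # Freedman-Lane pieces: reduced model = columns not in the contrast
  Z <- X[, contrast == 0, drop = FALSE]
  Hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
  Yn <- t(Y)                              # subjects x voxels
  fitted_z <- Hz %*% Yn
  resid_z <- Yn - fitted_z

  exhaustive <- n <= 8 && factorial(n) <= n_perm
  if (exhaustive) {
    perms <- all_permutations(n)
  } else {
    set.seed(seed)
    perms <- t(replicate(n_perm, sample.int(n)))
  }
  n_used <- nrow(perms)

  do_sign <- c(pos = alternative %in% c("both", "greater"),
               neg = alternative %in% c("both", "less"))
  tfce_of <- function(tv, sgn) {
    sv <- pmax(sgn * tv, 0)
    mx <- max(sv)
    if (mx <= 0) return(numeric(length(tv)))
    tfce_scores(sv, adjacency$ptr, adjacency$idx,
                params$dh_frac * mx, params$H, params$E)
  }

  obs <- glm_tstat(Y, X, contrast)
  obs_pos <- if (do_sign["pos"]) tfce_of(obs$t, 1) else NULL
  obs_neg <- if (do_sign["neg"]) tfce_of(obs$t, -1) else NULL

  max_pos <- max_neg <- numeric(n_used)
  for (r in seq_len(n_used)) {
    Ystar <- fitted_z + resid_z[perms[r, ], , drop = FALSE]
    tv <- glm_tstat(t(Ystar), X, contrast)$t
    if (do_sign["pos"]) max_pos[r] <- max(tfce_of(tv, 1))
    if (do_sign["neg"]) max_neg[r] <- max(tfce_of(tv, -1))
  }

  pval <- function(obs_v, null_max) {
    if (exhaustive) {
      vapply(obs_v, function(o) mean(null_max >= o), numeric(1))
    } else {
      vapply(obs_v, function(o) (1 + sum(null_max >= o)) / (1 + n_used),
             numeric(1))
    }
  }
  to_vol <- function(v, fill = NA_real_) {
    a <- array(fill, dim(mask)); a[idx] <- v; a
  }
  list(
    t = to_vol(obs$t),
    tfce_pos = if (do_sign["pos"]) to_vol(obs_pos, 0),
    tfce_neg = if (do_sign["neg"]) to_vol(obs_neg, 0),
    p_pos = if (do_sign["pos"]) to_vol(pval(obs_pos, max_pos)),
    p_neg = if (do_sign["neg"]) to_vol(pval(obs_neg, max_neg)),
    null_max_pos = if (do_sign["pos"]) max_pos,
    null_max_neg = if (do_sign["neg"]) max_neg,
    n_perm_used = n_used, exhaustive = exhaustive
  )
}

#' Count and summarise significant skeleton voxels
#'
#' @param pmap 3D p-value array (NA outside the skeleton).
#' @param alpha significance level (default 0.05, FWE-corrected p).
#' @param skeleton_mask logical 3D skeleton.
#' @param sign label of the contrast direction that produced `pmap`
#'   ("+" or "-").
#' @return One-row data frame: `sign`, `n_voxels`, `percent` (of the
#'   skeleton), `min_p`.
#' @export
summarize_significant <- function(pmap, alpha = 0.05, skeleton_mask,
                                  sign = "+") {
  pv <- pmap[which(skeleton_mask)]
  total <- sum(skeleton_mask)
  nsig <- sum(pv < alpha, na.rm = TRUE)
  data.frame(sign = sign, n_voxels = nsig,
             percent = 100 * nsig / total,
             min_p = if (all(is.na(pv))) NA_real_ else min(pv, na.rm = TRUE),
             stringsAsFactors = FALSE)
}
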