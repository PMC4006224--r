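toy_covars <- function(n, seed = 0) {
  set.seed(seed)
  data.frame(motion = rnorm(n, 1.2, 0.3), age = runif(n, 18, 60),
             gender = rbinom(n, 1, 0.5), handedness = rbinom(n, 1, 0.5))
}

test_that("the GLM t-statistic matches hand OLS and caps degenerate fits", {
  # noiseless 4-point line: slope 1, RSS = 0 -> capped t
  Y <- matrix(c(1, 2, 3, 4), 1)
  X <- cbind(intercept = 1, x = c(0, 1, 2, 3))
  attr(X, "contrast") <- c(0, 1)
  r <- glm_tstat(Y, X)
  expect_equal(r$beta, 1)
  expect_equal(abs(r$t), 1e6)

  # compare against lm() on noisy data
  set.seed(40)
  n <- 14
  cv <- toy_covars(n)
  Xf <- build_design(cv)
  Y2 <- matrix(rnorm(5 * n), 5, n)
  r2 <- glm_tstat(Y2, Xf)
  for (v in 1:5) {
    fit <- summary(lm(Y2[v, ] ~ Xf[, -1]))
    expect_allclose(r2$t[v], fit$coefficients["Xf[, -1]motion", "t value"],
                    tol = 1e-8)
  }
})

test_that("under the null the t-map is centred on zero", {
  set.seed(41)
  n <- 20
  X <- build_design(toy_covars(n, seed = 41))
  Y <- matrix(rnorm(2000 * n), 2000, n)
  r <- glm_tstat(Y, X)
  se <- sd(r$t) / sqrt(length(r$t))
  expect_lt(abs(mean(r$t)), 3 * se)
})

test_that("collinear designs are rejected naming the columns", {
  cv <- toy_covars(8)
  cv$age <- 2 * cv$motion                # collinear after centring
  expect_error(build_design(cv), "age")
})

test_that("TFCE reproduces the analytic single-cluster integrals", {
  p <- tfce_params("volume", dh_frac = 0.001)
  m <- array(0, c(3, 1, 1)); m[2, 1, 1] <- 2
  v <- tfce(m, array(TRUE, c(3, 1, 1)), p)
  expect_lt(abs(v[2, 1, 1] - 8 / 3) / (8 / 3), 1e-4)

  m2 <- array(2, c(2, 1, 1))
  v2 <- tfce(m2, array(TRUE, c(2, 1, 1)), p)
  expect_lt(abs(v2[1, 1, 1] - sqrt(2) * 8 / 3) / (sqrt(2) * 8 / 3), 1e-4)

  expect_equal(tfce(array(0, c(3, 3, 1)), array(TRUE, c(3, 3, 1)), p),
               array(0, c(3, 3, 1)))
})

test_that("TFCE agrees with the dense-threshold igraph oracle", {
  set.seed(42)
  for (i in 1:5) {
    stat <- array(pmax(rnorm(16 * 16, 0.5), 0), c(16, 16, 1))
    mask <- array(TRUE, c(16, 16, 1))
    prm <- tfce_params("volume", dh_frac = 0.01)
    mine <- tfce(stat, mask, prm)
    orc <- oracle_tfce(stat, mask, H = prm$H, E = prm$E,
                       dh = 0.01 * max(stat), connectivity = 26)
    nz <- orc > 0
    expect_lt(max(abs(mine[nz] - orc[nz]) / orc[nz]), 0.01)
  }
})

test_that("scaling a stat map strictly increases every nonzero TFCE value", {
  set.seed(43)
  stat <- array(abs(rnorm(6^3)), c(6, 6, 6))
  mask <- array(TRUE, c(6, 6, 6))
  a <- tfce(stat, mask, tfce_params("skeleton"))
  b <- tfce(1.5 * stat, mask, tfce_params("skeleton"))
  expect_true(all(b[a > 0] > a[a > 0]))
})

test_that("five-subject inference enumerates all permutations exactly", {
  set.seed(44)
  n <- 5
  mask <- array(TRUE, c(4, 4, 1))
  Y <- matrix(rnorm(16 * n), 16, n)
  Y[1:4, ] <- Y[1:4, ] + outer(rep(1, 4), c(-1, 0, 0, 1, 2))
  cv <- toy_covars(n, seed = 44)
  X <- build_design(cv, predictors = c("motion", "age"))
  prm <- tfce_params("volume")
  res <- permutation_fwe(Y, mask, X, params = prm, n_perm = 1000,
                         seed = 1, alternative = "greater")
  expect_true(res$exhaustive)
  expect_equal(res$n_perm_used, 120)

  # independent enumeration with the same building blocks
  perms <- motiondiff:::all_permutations(n)
  Z <- X[, c(1, 3)]                      # intercept + age
  Hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
  Yn <- t(Y)
  fit <- Hz %*% Yn
  resd <- Yn - fit
  adjacency <- motiondiff:::build_adjacency(mask, prm$connectivity)
  tfce_vec <- function(tv) {
    sv <- pmax(tv, 0)
    if (max(sv) <= 0) return(numeric(length(tv)))
    motiondiff:::tfce_scores(sv, adjacency$ptr, adjacency$idx,
                             prm$dh_frac * max(sv), prm$H, prm$E)
  }
  maxima <- apply(perms, 1, function(pp) {
    max(tfce_vec(glm_tstat(t(fit + resd[pp, ]), X)$t))
  })
  obs <- tfce_vec(glm_tstat(Y, X)$t)
  p_oracle <- sapply(obs, function(o) mean(maxima >= o))
  expect_allclose(res$p_pos[mask], p_oracle, tol = 1e-12)
})

test_that("p-values are bounded below by the permutation resolution", {
  set.seed(45)
  n <- 12
  mask <- array(TRUE, c(3, 3, 1))
  Y <- matrix(rnorm(9 * n), 9, n)
  X <- build_design(toy_covars(n, seed = 45))
  res <- permutation_fwe(Y, mask, X, n_perm = 99, seed = 2,
                         alternative = "both")
  expect_true(all(res$p_pos[mask] >= 1 / 100))
  expect_true(all(res$p_pos[mask] <= 1))
  # determinism for a fixed seed
  res2 <- permutation_fwe(Y, mask, X, n_perm = 99, seed = 2,
                          alternative = "both")
  expect_identical(res$p_pos, res2$p_pos)
  expect_identical(res$p_neg, res2$p_neg)
})

test_that("a strong localized effect is detected while its absence is not", {
  set.seed(46)
  n <- 20
  mask <- array(TRUE, c(6, 6, 1))
  cv <- toy_covars(n, seed = 46)
  Y <- matrix(rnorm(36 * n, sd = 1), 36, n)
  region <- 1:8
  Y[region, ] <- Y[region, ] +
    outer(rep(3, length(region)), cv$motion - mean(cv$motion))
  X <- build_design(cv)
  res <- permutation_fwe(Y, mask, X, n_perm = 300, seed = 3,
                         alternative = "both")
  expect_true(any(res$p_pos[mask][region] < 0.05))
  expect_true(all(res$p_neg[mask] > 0.05))
})

test_that("significant-voxel summaries report count, percent and sign", {
  skel <- array(FALSE, c(10, 10, 10))
  skel[1:10, 1, 1] <- TRUE               # 10-voxel skeleton... enlarge
  skel[, , 1] <- TRUE                    # 100 voxels
  p <- array(NA_real_, dim(skel))
  p[skel] <- 1
  s <- summarize_significant(p, 0.05, skel, "+")
  expect_equal(s$n_voxels, 0)
  expect_equal(s$percent, 0)

  pv <- rep(1, 100); pv[1:10] <- 0.01
  p[skel] <- pv
  s2 <- summarize_significant(p, 0.05, skel, "-")
  expect_equal(s2$n_voxels, 10)
  expect_equal(s2$percent, 10)
  expect_equal(s2$sign, "-")
})
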