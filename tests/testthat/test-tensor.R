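random_spd6 <- function(n, seed = 0, scale = 1e-3) {
  set.seed(seed)
  t(sapply(seq_len(n), function(i) {
    A <- matrix(rnorm(9), 3)
    D <- crossprod(A) / 6 * scale + diag(3) * 0.05 * scale
    c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  }))
}

dwi_from_tensors <- function(D6, grad, s0 = 1000) {
  # lay n tensors out along x on a minimal grid
  n <- nrow(D6)
  shape <- c(n, 1, 1)
  D <- array(0, c(shape, 6))
  for (j in 1:6) D[, 1, 1, j] <- D6[, j]
  mask <- array(TRUE, shape)
  X <- tensor_design(grad)
  q <- D6 %*% t(X)
  nvol <- length(grad$bvals)
  data <- array(0, c(shape, nvol))
  dw <- attr(X, "dw")
  for (v in seq_len(nvol))
    data[, 1, 1, v] <- if (v %in% dw) s0 * exp(-q[, match(v, dw)]) else s0
  dwi_series(data, grad, diag(4))
}

test_that("log-linear fit recovers 100 random SPD tensors from 137 directions", {
  g <- make_gradient_table(137, 1, 1500, seed = 0)
  D6 <- random_spd6(100, seed = 1)
  dwi <- dwi_from_tensors(D6, g)
  tf <- fit_tensor_loglinear(dwi)
  fitted <- matrix(tf$D, ncol = 6)
  expect_lt(max(abs(fitted - D6)), 1e-10)
})

test_that("phantom -> noiseless DWI -> fit round-trips the tensor field", {
  ph <- default_phantom(c(16, 16, 16))
  g <- make_gradient_table(30, 1, 1500, seed = 2)
  dwi <- simulate_dwi(ph$tensor, g, ph$affine, s0 = 1000, noise_sigma = 0)
  tf <- fit_tensor_loglinear(dwi, ph$mask)
  expect_lt(max(abs(tf$D - ph$tensor$D)), 1e-10)
})

test_that("FA/MD follow their closed forms", {
  to6 <- function(ev) c(ev, 0, 0, 0)
  tfield <- function(ev) {
    D <- array(0, c(16, 16, 1, 6))
    for (j in 1:3) D[, , 1, j] <- ev[j]
    tensor_field(D, array(TRUE, c(16, 16, 1)))
  }
  iso <- tensor_scalars(tfield(c(2e-3, 2e-3, 2e-3)))
  expect_allclose(iso$fa, 0, tol = 1e-12)
  expect_allclose(iso$md, 2e-3, tol = 1e-15)

  stick <- tensor_scalars(tfield(c(1e-3, 0, 0)))
  expect_allclose(stick$fa, 1, tol = 1e-12)

  wm <- tensor_scalars(tfield(c(1.7e-3, 0.2e-3, 0.2e-3)))
  expect_allclose(wm$md, 0.7e-3, tol = 1e-15)
  expect_allclose(wm$fa, sqrt(1.5 * 1.5 / 2.97), tol = 1e-12)
  expect_allclose(wm$fa, 0.8704, tol = 5e-5)
})

test_that("FA is scale- and rotation-invariant, MD scales linearly", {
  D6 <- random_spd6(20, seed = 3)
  as_field <- function(M) {
    D <- array(0, c(20, 1, 1, 6))
    for (j in 1:6) D[, 1, 1, j] <- M[, j]
    tensor_field(D, array(TRUE, c(20, 1, 1)))
  }
  base <- tensor_scalars(as_field(D6))
  scaled <- tensor_scalars(as_field(3.7 * D6))
  expect_allclose(scaled$fa, base$fa, tol = 1e-12)
  expect_allclose(scaled$md, 3.7 * base$md, tol = 1e-15)

  R <- rigid_matrix(c(0.4, -0.7, 1.1, 0, 0, 0))[1:3, 1:3]
  rot <- t(apply(D6, 1, function(d) {
    m <- matrix(c(d[1], d[4], d[5], d[4], d[2], d[6], d[5], d[6], d[3]),
                3, 3)
    m2 <- R %*% m %*% t(R)
    c(m2[1, 1], m2[2, 2], m2[3, 3], m2[1, 2], m2[1, 3], m2[2, 3])
  }))
  rsc <- tensor_scalars(as_field(rot))
  expect_allclose(rsc$fa, base$fa, tol = 1e-12)
  expect_allclose(rsc$md, base$md, tol = 1e-15)
})

test_that("ADC series inverts the signal model and respects the clamp ceiling", {
  shape <- c(4, 4, 1)
  g <- gradient_table(c(0, 1500), cbind(c(0, 0, 0), c(1, 0, 0)))
  data <- array(0, c(shape, 2))
  data[, , , 1] <- 1000
  data[, , , 2] <- 1000 * exp(-1500 * 7e-4)
  adc <- adc_series(dwi_series(data, g, diag(4)))
  expect_allclose(adc[, , , 1], 7e-4, tol = 1e-15)

  data[, , , 2] <- 1000                  # no attenuation -> ADC 0
  adc0 <- adc_series(dwi_series(data, g, diag(4)))
  expect_allclose(adc0[, , , 1], 0, tol = 1e-15)

  data[, , , 2] <- 0                     # clamped -> ln(1e6)/b ceiling
  adcc <- adc_series(dwi_series(data, g, diag(4)))
  expect_allclose(adcc[, , , 1], log(1e6) / 1500, tol = 1e-12)
})

test_that("noiseless ADC equals g'Dg per direction", {
  g <- make_gradient_table(15, 1, 1500, seed = 4)
  D6 <- random_spd6(10, seed = 5)
  dwi <- dwi_from_tensors(D6, g)
  adc <- adc_series(dwi)
  X <- tensor_design(g) / 1500
  expected <- D6 %*% t(X)
  got <- matrix(adc, ncol = dim(adc)[4])
  expect_lt(max(abs(got - expected)), 1e-12)
})

test_that("rank-deficient direction sets are rejected with the condition number", {
  # 6 copies of only 3 distinct directions
  bv <- cbind(c(0, 0, 0), diag(3), diag(3))
  g <- gradient_table(c(0, rep(1000, 6)), bv)
  data <- array(1000, c(4, 4, 1, 7))
  expect_error(fit_tensor_loglinear(dwi_series(data, g, diag(4))),
               "rank deficient")
})

test_that("clamped voxels are flagged in the QC mask", {
  shape <- c(4, 4, 1)
  g <- make_gradient_table(6, 1, 1500, seed = 1)
  data <- array(1000, c(shape, 7))
  data[1, 1, 1, 3] <- 0
  tf <- fit_tensor_loglinear(dwi_series(data, g, diag(4)))
  qc <- attr(tf, "qc_clamped")
  expect_true(qc[1, 1, 1])
  expect_equal(sum(qc), 1)
})
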