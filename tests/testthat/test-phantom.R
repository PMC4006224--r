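test_that("cylindrical eigenvalues reproduce requested FA and MD", {
  # isotropic case
  expect_allclose(eigs_from_fa_md(0, 0.7e-3), rep(0.7e-3, 3), tol = 1e-15)

  # hand-solved case: FA for (1.7, 0.2, 0.2)e-3 is sqrt(1.5*1.5/2.97)
  fa_target <- sqrt(1.5 * 1.5 / 2.97)
  ev <- eigs_from_fa_md(fa_target, 0.7e-3)
  expect_allclose(ev, c(1.7e-3, 0.2e-3, 0.2e-3), tol = 1e-12)

  # inversion identity across the FA range
  for (fa in c(0.1, 0.5, 0.8, 0.95)) {
    ev <- eigs_from_fa_md(fa, 0.7e-3)
    md <- mean(ev)
    fa_back <- sqrt(1.5 * sum((ev - md)^2) / sum(ev^2))
    expect_allclose(md, 0.7e-3, tol = 1e-15)
    expect_allclose(fa_back, fa, tol = 1e-12)
  }
  expect_error(eigs_from_fa_md(1, 0.7e-3), "FA")
  expect_error(eigs_from_fa_md(0.5, 0), "MD")
})

test_that("phantom regions carry exactly the requested tensors", {
  ph <- default_phantom(c(16, 16, 16))
  iso <- ph$mask & !ph$slab
  # isotropic region: D = 0.7e-3 * I
  expect_allclose(ph$tensor$D[, , , 1][iso], 0.7e-3, tol = 1e-15)
  expect_allclose(ph$tensor$D[, , , 4][iso], 0, tol = 1e-15)
  # slab region: principal axis x
  sl <- which(ph$slab)
  ev <- eigs_from_fa_md(0.8, 0.7e-3)
  expect_allclose(ph$tensor$D[, , , 1][sl], ev[1], tol = 1e-12)
  expect_allclose(ph$tensor$D[, , , 2][sl], ev[2], tol = 1e-12)
})

test_that("noiseless signal follows the mono-exponential decay", {
  ph <- default_phantom(c(16, 16, 16))
  g <- make_gradient_table(12, 2, 1500, seed = 1)
  dwi <- simulate_dwi(ph$tensor, g, ph$affine, s0 = 1000, noise_sigma = 0)
  # b = 0 volumes equal S0 inside the mask
  expect_allclose(dwi$data[, , , 1][ph$mask], 1000, tol = 1e-9)
  # isotropic voxels: S/S0 = exp(-b MD) = exp(-1.05) in every direction
  iso <- ph$mask & !ph$slab
  for (v in 3:5)
    expect_allclose(dwi$data[, , , v][iso] / 1000, exp(-1.05), tol = 1e-12)
})

test_that("Rician corruption leaves the expected Rayleigh background floor", {
  ph <- default_phantom(c(16, 16, 16))
  g <- make_gradient_table(6, 1, 1500, seed = 1)
  dwi <- simulate_dwi(ph$tensor, g, ph$affine, s0 = 1000,
                      noise_sigma = 30, seed = 42)
  bg <- !ph$mask                         # S = 0 voxels
  vals <- as.vector(dwi$data[, , , 1][bg])
  expect_gt(length(vals), 1000)
  target <- 30 * sqrt(pi / 2)
  se <- 30 * sqrt((2 - pi / 2)) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - target), 4 * se)
})

test_that("motion injection is exact for identity and integer shifts", {
  ph <- default_phantom(c(16, 16, 16))
  g <- make_gradient_table(6, 1, 1500, seed = 1)
  dwi <- simulate_dwi(ph$tensor, g, ph$affine, s0 = ph$s0_map)
  n <- dim(dwi$data)[4]

  inj <- inject_motion(dwi, matrix(0, n, 6))
  expect_identical(inj$dwi$data, dwi$data)
  expect_true(all(sapply(inj$chain$transforms,
                         function(m) all(m == diag(4)))))

  # one-voxel (2 mm) x-translation: trilinear degenerates to a shift
  params <- matrix(0, n, 6)
  params[2, 4] <- 2
  inj2 <- inject_motion(dwi, params)
  shifted <- motiondiff:::array_shift(dwi$data[, , , 2], c(1, 0, 0))
  expect_allclose(inj2$dwi$data[, , , 2], shifted, tol = 1e-9)
  # ground-truth chain reproduces the rotation RMS closed form
  params[3, ] <- c(0, 0, 0.1, 0, 0, 0)
  inj3 <- inject_motion(dwi, params)
  r <- rms_deviation(diag(4), inj3$chain$transforms[[3]], R = 80)
  expect_allclose(r, 80 * sqrt(8 / 5) * sin(0.05))
})

test_that("translations beyond half the field of view are rejected", {
  ph <- default_phantom(c(16, 16, 16))
  g <- make_gradient_table(6, 1, 1500, seed = 1)
  dwi <- simulate_dwi(ph$tensor, g, ph$affine)
  params <- matrix(0, dim(dwi$data)[4], 6)
  params[2, 4] <- 100
  expect_error(inject_motion(dwi, params), "field of view")
})

test_that("drawn motion parameter sets hit their target mean RMS", {
  for (target in c(0.5, 1.5)) {
    p <- make_motion_params(20, target, seed = 1)
    ch <- lapply(seq_len(20), function(v) solve(rigid_matrix(p[v, ])))
    tr <- motion_trace(transform_chain(ch))
    expect_lt(abs(tr$mean - target) / target, 0.05)
  }
})

test_that("background volume is conserved up to the displaced shell", {
  ph <- default_phantom(c(16, 16, 16))
  g <- make_gradient_table(6, 1, 1500, seed = 1)
  dwi <- simulate_dwi(ph$tensor, g, ph$affine)
  params <- matrix(0, dim(dwi$data)[4], 6)
  params[2, ] <- c(0.02, 0, 0.03, 0.8, -0.5, 0.3)
  inj <- inject_motion(dwi, params)
  frac_before <- mean(dwi$data[, , , 2] == 0)
  frac_after <- mean(inj$dwi$data[, , , 2] < 1e-6)
  # displacement ~1 voxel: the background fraction moves by at most the
  # one-voxel boundary shell of the mask
  shell <- sum(ph$mask) - sum(motiondiff:::array_shift(ph$mask * 1, c(1, 0, 0)) *
                                ph$mask)
  expect_lt(abs(frac_after - frac_before),
            (6 * shell + 1) / length(ph$mask))
})
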