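small_spec <- function(seed = 7, ...) {
  cohort_spec(n_subjects = 6, shape = c(16, 16, 16), n_directions = 12,
              seed = seed, ...)
}

test_that("cohort simulation is bit-identical for a fixed seed", {
  a <- simulate_cohort(small_spec())
  b <- simulate_cohort(small_spec())
  expect_identical(a$maps, b$maps)
  expect_identical(a$motion, b$motion)
  expect_identical(a$covariates, b$covariates)
  c2 <- simulate_cohort(small_spec(seed = 8))
  expect_false(identical(a$maps$md, c2$maps$md))
})

test_that("zero within-subject terms make the two sessions identical", {
  sp <- small_spec(sigma_e = 0, motion_within_sd = 0)
  co <- simulate_cohort(sp)
  for (met in c("fa", "md", "ldh")) {
    for (i in seq_len(sp$n_subjects)) {
      expect_identical(co$maps[[met]][[i]][[1]], co$maps[[met]][[i]][[2]])
    }
  }
})

test_that("parametric couplings put the stated signs into the ground truth", {
  co <- simulate_cohort(small_spec())
  motion <- rowMeans(co$motion)
  reg <- which(co$region)
  cors <- sapply(c(fa = "fa", md = "md", ldh = "ldh"), function(met) {
    m <- sapply(seq_along(motion), function(i) {
      mean((co$maps[[met]][[i]][[1]] + co$maps[[met]][[i]][[2]])[reg] / 2)
    })
    cor(m, motion)
  })
  expect_gt(cors["md"], 0.5)
  expect_lt(cors["ldh"], -0.5)
  expect_lt(abs(cors["fa"]), 0.95)       # no systematic FA coupling forced
})

test_that("covariates follow their documented distributions and motion its scale", {
  sp <- cohort_spec(n_subjects = 200, shape = c(16, 16, 16),
                    n_directions = 8, seed = 3)
  co <- simulate_cohort(sp)
  expect_true(all(co$covariates$age >= 18 & co$covariates$age <= 60))
  expect_true(all(co$covariates$gender %in% 0:1))
  expect_true(all(co$covariates$handedness %in% 0:1))
  avg <- rowMeans(co$motion)
  expect_lt(abs(mean(avg) - 1.18), 0.08)
  expect_lt(abs(sd(avg) - 0.29), 0.08)
  # session-level spread is wider than the averaged spread
  expect_gt(sd(co$motion[, 1]), sd(avg))
})

test_that("the generated motion structure carries the intended reliability", {
  sp <- cohort_spec(n_subjects = 400, shape = c(16, 16, 16),
                    n_directions = 8, seed = 5)
  co <- simulate_cohort(sp)
  expect_lt(abs(icc(co$motion) - 0.54), 0.08)
})

test_that("an empty effect region with non-zero couplings is rejected", {
  sp <- small_spec(effect_region = array(FALSE, c(16, 16, 16)))
  expect_error(simulate_cohort(sp), "effect region")
})

test_that("mechanistic cohorts carry ground-truth transform chains", {
  sp <- cohort_spec(n_subjects = 3, n_sessions = 1, shape = c(16, 16, 16),
                    n_directions = 8, mode = "mechanistic", seed = 2,
                    noise_sigma = 0.01)
  co <- simulate_cohort(sp)
  expect_length(co$chains, 3)
  ch <- co$chains[[1]][[1]]
  expect_s3_class(ch, "transform_chain")
  tr <- motion_trace(ch)
  expect_lt(abs(tr$mean - co$motion[1, 1]) / co$motion[1, 1], 0.05)
  # metric maps exist and are in range
  expect_true(all(co$maps$fa[[1]][[1]] >= 0 & co$maps$fa[[1]][[1]] <= 1))
  expect_true(all(co$maps$ldh[[1]][[1]] >= 0 &
                    co$maps$ldh[[1]][[1]] <= 1))
})

test_that("injected motion degrades diffusion metrics in the physical mode", {
  ph <- default_phantom(c(16, 16, 16))
  g <- make_gradient_table(20, 1, 1500, seed = 1)
  dwi0 <- simulate_dwi(ph$tensor, g, ph$affine, s0 = ph$s0_map,
                       noise_sigma = 0)
  metric_at <- function(level) {
    p <- make_motion_params(21, level, seed = 9)
    inj <- inject_motion(dwi0, p)
    noisy <- inj$dwi
    set.seed(10)
    nd <- length(noisy$data)
    noisy$data <- sqrt((noisy$data + rnorm(nd, sd = 20))^2 +
                         rnorm(nd, sd = 20)^2)
    mm <- metric_maps_from_dwi(noisy, ph$mask)
    c(ldh = mean(mm$ldh[ph$slab]), md = mean(mm$md[ph$slab]))
  }
  lo <- metric_at(1)
  hi <- metric_at(5)
  # beyond the interpolation floor, more motion lowers slab LDH and
  # raises apparent MD -- the qualitative sign pattern of the couplings
  expect_lt(hi["ldh"], lo["ldh"])
  expect_gt(hi["md"], lo["md"])
})
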