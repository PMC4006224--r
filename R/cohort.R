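# Synthetic multi-subject, two-session DWI cohorts with known ground-truth
# motion/metric couplings.
#
# Two coupling modes:
#  * "parametric": per-subject FA/MD/LDH maps are the base phantom maps
#    plus additive structure -- a motion coupling beta * motion inside the
#    effect region, a per-subject random field (sd sigma_b * scale), and a
#    per-session random field (sd sigma_e * scale). Ground truth is exact,
#    which is what GLM/ICC recovery tests need.
#  * "mechanistic": per-volume rigid motion is injected into the DWI signal
#    itself and metrics are recomputed; associations emerge physically.
#
# Motion levels follow the two-session design: subject means are lognormal
# (location 1.18 mm), and between/within-subject sds (0.243 / 0.224 mm)
# were chosen so that session-averaged motion has sd 0.29 mm, session-level
# sd is about 0.33 mm, and the analytic motion ICC is about 0.54.

#' Specify a synthetic cohort
#'
#' @param n_subjects number of subjects (>= 3; default 20).
#' @param n_sessions sessions per subject (default 2).
#' @param shape,voxdim phantom grid (default 24 x 24 x 16 at 2 mm).
#' @param n_directions,n_b0,b gradient scheme (default 137 directions at
#'   b = 1500 s/mm^2 plus one b = 0).
#' @param motion_mean subject-level mean motion (mm, lognormal location).
#' @param motion_between_sd between-subject sd of mean motion (mm).
#' @param motion_within_sd within-subject (session) sd of motion (mm).
#' @param beta named coupling coefficients `c(fa=, md=, ldh=)` in metric
#'   units per mm of motion, applied inside the effect region.
#' @param effect_region logical 3D array; default: the central half
#'   (along x) of the phantom slab.
#' @param noise_sigma Rician noise sd as a fraction of S0.
#' @param sigma_b,sigma_e dimensionless between-subject and
#'   within-subject (session) map-noise multipliers of `metric_scales`.
#' @param metric_scales per-metric unit scales `c(fa=, md=, ldh=)`.
#' @param mode "parametric" or "mechanistic".
#' @param seed RNG seed, recorded in all outputs.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20, n_sessions = 2,
                        shape = c(24, 24, 16), voxdim = c(2, 2, 2),
                        n_directions = 137, n_b0 = 1, b = 1500,
                        motion_mean = 1.18, motion_between_sd = 0.243,
                        motion_within_sd = 0.224,
                        beta = c(fa = 0, md = 1.1e-4, ldh = -0.11),
                        effect_region = NULL,
                        noise_sigma = 0.02,
                        sigma_b = 1, sigma_e = 0.6,
                        metric_scales = c(fa = 0.02, md = 2e-5,
                                          ldh = 0.02),
                        mode = c("parametric", "mechanistic"),
                        seed = 0) {
  mode <- match.arg(mode)
  stopifnot(n_subjects >= 3, n_sessions >= 1, sigma_b >= 0, sigma_e >= 0,
            noise_sigma >= 0, motion_between_sd >= 0,
            motion_within_sd >= 0,
            all(c("fa", "md", "ldh") %in% names(beta)),
            all(c("fa", "md", "ldh") %in% names(metric_scales)))
  structure(list(n_subjects = n_subjects, n_sessions = n_sessions,
                 shape = shape, voxdim = voxdim,
                 n_directions = n_directions, n_b0 = n_b0, b = b,
                 motion_mean = motion_mean,
                 motion_between_sd = motion_between_sd,
                 motion_within_sd = motion_within_sd,
                 beta = beta, effect_region = effect_region,
                 noise_sigma = noise_sigma,
                 sigma_b = sigma_b, sigma_e = sigma_e,
                 metric_scales = metric_scales,
                 mode = mode, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d subjects x %d sessions, %s mode, seed %d\n",
    x$n_subjects, x$n_sessions, x$mode, x$seed))
  invisible(x)
}

draw_motion <- function(spec) {
  m <- spec$motion_mean
  if (spec$motion_between_sd > 0) {
    sdlog <- sqrt(log(1 + (spec$motion_between_sd / m)^2))
    mu <- stats::rlnorm(spec$n_subjects, meanlog = log(m) - sdlog^2 / 2,
                        sdlog = sdlog)
  } else {
    mu <- rep(m, spec$n_subjects)
  }
  sess <- matrix(stats::rnorm(spec$n_subjects * spec$n_sessions,
                              mean = rep(mu, spec$n_sessions),
                              sd = spec$motion_within_sd),
                 spec$n_subjects, spec$n_sessions)
  pmax(sess, 0.05)
}

base_metric_maps <- function(phantom, grad, spec) {
  dwi <- simulate_dwi(phantom$tensor, grad, phantom$affine,
                      s0 = phantom$s0_map,
                      noise_sigma = spec$noise_sigma * 1000,
                      seed = spec$seed)
  metric_maps_from_dwi(dwi, phantom$mask)
}

#' FA, MD and LDH maps from one DWI series
#'
#' Convenience wrapper: log-linear tensor fit, eigenvalue scalars, ADC
#' series and the n = 27 LDH map.
#'
#' @param dwi a [dwi_series].
#' @param mask logical 3D mask.
#' @param neighborhood LDH neighbourhood size.
#' @return List with 3D arrays `fa`, `md`, `ldh`.
#' @export
metric_maps_from_dwi <- function(dwi, mask, neighborhood = 27) {
  tf <- fit_tensor_loglinear(dwi, mask)
  sc <- tensor_scalars(tf)
  adc <- adc_series(dwi, mask)
  list(fa = sc$fa, md = sc$md,
       ldh = ldh_map(adc, neighborhood, mask))
}

#' Simulate a multi-subject two-session cohort
#'
#' See [cohort_spec()] for the generative model. Everything is seeded:
#' identical spec and seed give bit-identical output.
#'
#' @param spec a [cohort_spec()].
#' @return Object of class `dwi_cohort`: `spec`, `phantom`, `base`
#'   (noisy base metric maps), `maps` (`maps[[metric]][[subject]][[session]]`
#'   3D arrays), `motion` (n x k session motion matrix, mm), `covariates`
#'   (data frame: subject, motion, age, gender, handedness), `region`
#'   (effect mask), `chains` (mechanistic mode: per subject/session
#'   ground-truth [transform_chain]s).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  phantom <- default_phantom(spec$shape, spec$voxdim, seed = spec$seed)
  grad <- make_gradient_table(spec$n_directions, spec$n_b0, spec$b,
                              seed = spec$seed)
  region <- spec$effect_region
  if (is.null(region)) {
    ix <- slice.index(array(0, spec$shape), 1) - 1
    region <- phantom$slab & abs(ix - (spec$shape[1] - 1) / 2) <=
      spec$shape[1] / 4
  }
  if (!any(region) && any(spec$beta != 0))
    stop("effect region is empty while a coupling coefficient is non-zero")

  base <- base_metric_maps(phantom, grad, spec)

  set.seed(spec$seed + 1L)
  motion <- draw_motion(spec)
  covars <- data.frame(
    subject = sprintf("sub-%02d", seq_len(spec$n_subjects)),
    motion = rowMeans(motion),
    age = stats::runif(spec$n_subjects, 18, 60),
    gender = stats::rbinom(spec$n_subjects, 1, 0.5),
    handedness = stats::rbinom(spec$n_subjects, 1, 0.5)
  )

  metrics <- c("fa", "md", "ldh")
  maps <- stats::setNames(lapply(metrics, function(m) {
    lapply(seq_len(spec$n_subjects),
           function(i) vector("list", spec$n_sessions))
  }), metrics)
  chains <- NULL
  nvox <- prod(spec$shape)
  midx <- which(phantom$mask)

  if (spec$mode == "parametric") {
    for (met in metrics) {
      sc <- spec$metric_scales[[met]]
      bta <- spec$beta[[met]]
      for (i in seq_len(spec$n_subjects)) {
        subj_field <- array(stats::rnorm(nvox, sd = spec$sigma_b * sc),
                            spec$shape)
        for (j in seq_len(spec$n_sessions)) {
          sess_field <- array(stats::rnorm(nvox, sd = spec$sigma_e * sc),
                              spec$shape)
          m <- base[[met]] + subj_field + sess_field +
            bta * motion[i, j] * region
          m[-midx] <- 0
          maps[[met]][[i]][[j]] <- m
        }
      }
    }
  } else {
    dwi0 <- simulate_dwi(phantom$tensor, grad, phantom$affine,
                         s0 = phantom$s0_map, noise_sigma = 0)
    chains <- lapply(seq_len(spec$n_subjects),
                     function(i) vector("list", spec$n_sessions))
    for (i in seq_len(spec$n_subjects)) {
      for (j in seq_len(spec$n_sessions)) {
        sub_seed <- spec$seed + 1000L + i * spec$n_sessions + j
        params <- make_motion_params(length(grad$bvals), motion[i, j],
                                     seed = sub_seed)
        moved <- inject_motion(dwi0, params)
        noisy <- moved$dwi
        if (spec$noise_sigma > 0) {
          set.seed(sub_seed)
          nd <- length(noisy$data)
          sdn <- spec$noise_sigma * 1000
          noisy$data <- sqrt(
            (noisy$data + stats::rnorm(nd, sd = sdn))^2 +
              stats::rnorm(nd, sd = sdn)^2)
        }
        mm <- metric_maps_from_dwi(noisy, phantom$mask)
        for (met in metrics) maps[[met]][[i]][[j]] <- mm[[met]]
        chains[[i]][[j]] <- moved$chain
      }
    }
  }

  structure(list(spec = spec, phantom = phantom, grad = grad,
                 base = base, maps = maps, motion = motion,
                 covariates = covars, region = region, chains = chains),
            class = "dwi_cohort")
}

#' @export
print.dwi_cohort <- function(x, ...) {
  cat(sprintf(
    "<dwi_cohort> %d subjects x %d sessions (%s), mean motion %.2f mm\n",
    x$spec$n_subjects, x$spec$n_sessions, x$spec$mode, mean(x$motion)))
  invisible(x)
}

#' Session-averaged metric maps of a cohort
#'
#' @param cohort a [simulate_cohort()] result.
#' @param metric "fa", "md" or "ldh".
#' @return List over subjects of 3D arrays averaged across sessions.
#' @export
averaged_maps <- function(cohort, metric) {
  lapply(cohort$maps[[metric]], function(sess) {
    Reduce(`+`, sess) / length(sess)
  })
}
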