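# End-to-end orchestration: simulate (or accept) a cohort, score motion,
# build the skeleton, project metrics, compute test-retest ICC, and run
# the motion GLM with TFCE permutation correction -- per session or on
# session-averaged data, as in the study design this pipeline models.

#' Configure a pipeline run
#'
#' @param spec a [cohort_spec()] (the cohort to simulate), or an existing
#'   [simulate_cohort()] result.
#' @param out_dir output directory (`NULL`: nothing written).
#' @param radius RMS sphere radius in mm.
#' @param fa_threshold skeleton FA threshold.
#' @param neighborhood LDH neighbourhood size (27, 19 or 7).
#' @param max_search_mm skeleton projection search half-length.
#' @param tfce_preset "skeleton" or "volume".
#' @param alpha FWE-corrected significance level.
#' @param n_perm permutations for the GLM stage.
#' @param session_mode "averaged" (motion and metrics averaged across
#'   sessions before the GLM) or "per-session".
#' @param seed seed for the permutation stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = cohort_spec(), out_dir = NULL,
                            radius = 80, fa_threshold = 0.2,
                            neighborhood = 27, max_search_mm = 6,
                            tfce_preset = "skeleton", alpha = 0.05,
                            n_perm = 500,
                            session_mode = c("averaged", "per-session"),
                            seed = 0) {
  session_mode <- match.arg(session_mode)
  stopifnot(radius > 0, fa_threshold > 0, alpha > 0, alpha < 1,
            n_perm >= 1, neighborhood %in% c(7, 19, 27))
  structure(list(spec = spec, out_dir = out_dir, radius = radius,
                 fa_threshold = fa_threshold,
                 neighborhood = neighborhood,
                 max_search_mm = max_search_mm,
                 tfce_preset = tfce_preset, alpha = alpha,
                 n_perm = n_perm, session_mode = session_mode,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

glm_on_skeleton <- function(Y, skel, covars, config, motion_values) {
  covars$motion <- motion_values
  X <- build_design(covars)
  permutation_fwe(Y, skel$skeleton, X,
                  params = tfce_params(config$tfce_preset),
                  n_perm = config$n_perm, seed = config$seed,
                  alternative = "both")
}

#' Run the full motion/diffusion-metric pipeline
#'
#' Stages: simulate cohort -> motion summaries and motion ICC -> mean-FA
#' skeleton -> per-session and averaged skeleton projections of FA, MD and
#' LDH -> voxelwise metric ICC on the skeleton -> motion GLM with TFCE
#' permutation FWE correction for both contrast signs -> significant-voxel
#' summary in the sign/count/percent report format. When `out_dir` is set,
#' maps, tables and a YAML manifest sufficient to reproduce the run are
#' written there.
#'
#' @param config a [pipeline_config()].
#' @return List of class `pipeline_result` with elements `cohort`,
#'   `skeleton`, `motion` (summary data frame), `motion_icc`,
#'   `icc` (per-metric mean ICC and maps), `glm` (per-metric
#'   [permutation_fwe()] results; in per-session mode, nested per
#'   session), `summary` (data frame mirroring the sign-pattern report),
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- as.numeric(Sys.time())
  cohort <- if (inherits(config$spec, "dwi_cohort")) config$spec
  else simulate_cohort(config$spec)
  spec <- cohort$spec
  stage_log("simulate", t0, sprintf("%d subjects x %d sessions",
                                    spec$n_subjects, spec$n_sessions))

  # -- motion ---------------------------------------------------------
  motion_df <- data.frame(subject = cohort$covariates$subject,
                          cohort$motion)
  names(motion_df)[-1] <- sprintf("session%d", seq_len(spec$n_sessions))
  motion_df$averaged <- rowMeans(cohort$motion)
  motion_icc <- if (spec$n_sessions >= 2) icc(cohort$motion) else NA_real_
  stage_log("motion", t0, sprintf("mean %.2f mm, ICC %.2f",
                                  mean(motion_df$averaged), motion_icc))

  # -- skeleton -------------------------------------------------------
  fa_avg <- averaged_maps(cohort, "fa")
  skel <- make_skeleton(fa_avg, threshold = config$fa_threshold,
                        max_search_mm = config$max_search_mm,
                        voxdim = spec$voxdim)
  stage_log("skeleton", t0, sprintf("%d voxels", sum(skel$skeleton)))

  metrics <- c("fa", "md", "ldh")

  # per-session skeleton projections (FA search location reused per map)
  proj_sess <- lapply(metrics, function(met) {
    lapply(seq_len(spec$n_subjects), function(i) {
      lapply(seq_len(spec$n_sessions), function(j) {
        skeleton_to_volume(
          project_to_skeleton(cohort$maps[[met]][[i]][[j]],
                              cohort$maps$fa[[i]][[j]], skel),
          skel)
      })
    })
  })
  names(proj_sess) <- metrics

  # -- reliability ----------------------------------------------------
  icc_res <- if (spec$n_sessions >= 2) {
    lapply(proj_sess, function(mp) icc_map(mp, skel$skeleton))
  }
  if (!is.null(icc_res))
    stage_log("icc", t0, paste(sprintf("%s %.2f", metrics, vapply(
      icc_res, function(x) x$mean_icc, numeric(1))), collapse = " "))

  # -- GLM ------------------------------------------------------------
  skel_idx <- which(skel$skeleton)
  session_sets <- if (config$session_mode == "averaged") list(averaged = 0)
  else as.list(stats::setNames(seq_len(spec$n_sessions),
                               sprintf("session%d", seq_len(spec$n_sessions))))
  glm_res <- list()
  summary_rows <- list()
  for (set_name in names(session_sets)) {
    j <- session_sets[[set_name]]
    motion_values <- if (j == 0) motion_df$averaged else cohort$motion[, j]
    glm_res[[set_name]] <- list()
    for (met in metrics) {
      Y <- vapply(seq_len(spec$n_subjects), function(i) {
        vols <- proj_sess[[met]][[i]]
        v <- if (j == 0) Reduce(`+`, vols) / length(vols) else vols[[j]]
        v[skel_idx]
      }, numeric(length(skel_idx)))
      res <- glm_on_skeleton(Y, skel, cohort$covariates, config,
                             motion_values)
      glm_res[[set_name]][[met]] <- res
      pos <- summarize_significant(res$p_pos, config$alpha,
                                   skel$skeleton, "+")
      neg <- summarize_significant(res$p_neg, config$alpha,
                                   skel$skeleton, "-")
      assoc <- if (pos$n_voxels == 0 && neg$n_voxels == 0) "n.r."
      else paste(c("+", "-")[c(pos$n_voxels > 0, neg$n_voxels > 0)],
                 collapse = "/")
      summary_rows[[paste(set_name, met)]] <- data.frame(
        analysis = set_name, metric = toupper(met), association = assoc,
        n_pos = pos$n_voxels, pct_pos = pos$percent,
        n_neg = neg$n_voxels, pct_neg = neg$percent,
        skeleton_voxels = length(skel_idx))
      stage_log("glm", t0, sprintf("%s %s: %s", set_name, met, assoc))
    }
  }
  summary_df <- do.call(rbind, c(summary_rows,
                                 list(make.row.names = FALSE)))

  manifest <- list(
    package = "motiondiff",
    version = as.character(utils::packageVersion("motiondiff")),
    r_version = R.version.string,
    seed = config$seed,
    cohort = unclass(spec)[setdiff(names(unclass(spec)),
                                   "effect_region")],
    parameters = list(radius = config$radius,
                      fa_threshold = config$fa_threshold,
                      neighborhood = config$neighborhood,
                      max_search_mm = config$max_search_mm,
                      tfce_preset = config$tfce_preset,
                      alpha = config$alpha, n_perm = config$n_perm,
                      session_mode = config$session_mode)
  )

  result <- structure(list(cohort = cohort, skeleton = skel,
                           motion = motion_df, motion_icc = motion_icc,
                           icc = icc_res, glm = glm_res,
                           summary = summary_df, manifest = manifest),
                      class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    utils::write.table(motion_df, file.path(od, "motion.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_covariates_tsv(cohort, file.path(od, "covariates.tsv"))
    utils::write.table(summary_df, file.path(od, "glm_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_metric_nifti(skel$skeleton * 1, cohort$phantom$affine,
                       file.path(od, "skeleton.nii.gz"))
    write_metric_nifti(skel$mean_fa, cohort$phantom$affine,
                       file.path(od, "mean_fa.nii.gz"))
    if (!is.null(icc_res)) {
      icc_tab <- data.frame(metric = toupper(metrics),
                            mean_icc = vapply(icc_res, function(x)
                              x$mean_icc, numeric(1)))
      utils::write.table(icc_tab, file.path(od, "icc_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (met in metrics)
        write_metric_nifti(icc_res[[met]]$icc, cohort$phantom$affine,
                           file.path(od, sprintf("icc_%s.nii.gz", met)))
    }
    for (set_name in names(glm_res)) for (met in metrics) {
      res <- glm_res[[set_name]][[met]]
      for (fld in c("t", "p_pos", "p_neg")) {
        v <- res[[fld]]
        v[is.na(v)] <- if (fld == "t") 0 else 1
        write_metric_nifti(v, cohort$phantom$affine,
                           file.path(od, sprintf("%s_%s_%s.nii.gz",
                                                 set_name, met, fld)))
      }
    }
    write_manifest(manifest, file.path(od, "manifest.yaml"))
    stage_log("write", t0, od)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  motion: mean %.2f mm (sd %.2f), ICC %.2f\n",
              mean(x$motion$averaged), stats::sd(x$motion$averaged),
              x$motion_icc))
  if (!is.null(x$icc))
    cat(sprintf("  mean ICC: FA %.2f, MD %.2f, LDH %.2f\n",
                x$icc$fa$mean_icc, x$icc$md$mean_icc,
                x$icc$ldh$mean_icc))
  cat("  motion-brain association:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
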