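# On-disk formats: NIfTI-1 volumes (via RNifti), covariate / summary TSVs
# and the run manifest. Gradient and transform files live next to their
# modules (gradient.R, transforms.R).

#' Write a 3D/4D array as NIfTI-1 with its voxel-to-world affine
#'
#' @param data numeric array.
#' @param affine 4x4 voxel-to-world (RAS+ mm) matrix.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_metric_nifti <- function(data, affine, path) {
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume and its affine
#'
#' @param path NIfTI file.
#' @return List with `data` (array) and `affine` (4x4 matrix).
#' @export
read_metric_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  list(data = array(as.numeric(img), dim(img)),
       affine = matrix(as.numeric(aff), 4, 4))
}

#' Write a DWI series as NIfTI plus FSL bval/bvec
#'
#' @param dwi a [dwi_series].
#' @param prefix path prefix; writes `<prefix>.nii.gz`, `<prefix>.bval`,
#'   `<prefix>.bvec`.
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "dwi_series"))
  write_metric_nifti(dwi$data, dwi$affine, paste0(prefix, ".nii.gz"))
  write_gradient_files(dwi$grad, paste0(prefix, ".bval"),
                       paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' Read a DWI series from NIfTI plus FSL bval/bvec
#'
#' @param nii_path 4D NIfTI file.
#' @param bval_path,bvec_path gradient files.
#' @return A [dwi_series].
#' @export
read_dwi <- function(nii_path, bval_path, bvec_path) {
  vol <- read_metric_nifti(nii_path)
  dwi_series(vol$data, read_gradient_files(bval_path, bvec_path),
             vol$affine)
}

#' Write / read the cohort covariate table
#'
#' TSV with header `subject session motion age gender handedness` (one
#' row per subject-session).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param path output TSV.
#' @export
write_covariates_tsv <- function(cohort, path) {
  spec <- cohort$spec
  df <- do.call(rbind, lapply(seq_len(spec$n_sessions), function(j) {
    data.frame(subject = cohort$covariates$subject, session = j,
               motion = cohort$motion[, j],
               age = cohort$covariates$age,
               gender = cohort$covariates$gender,
               handedness = cohort$covariates$handedness)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates_tsv
#' @export
read_covariates_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a run manifest
#'
#' A structured-text (YAML) record of everything needed to reproduce a
#' run: package version, seed, cohort spec and stage parameters.
#'
#' @param manifest named list.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) yaml::read_yaml(path)
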