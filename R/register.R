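# Rigid registration of DW volumes to the non-DW reference: normalised
# cross-correlation, multi-resolution pyramid, derivative-free local
# optimisation from the identity. Registration is optional in the pipeline:
# ground-truth transform chains from the simulator run through the same
# downstream code.

block_downsample <- function(vol, f) {
  if (f == 1) return(vol)
  dm <- dim(vol)
  keep <- (dm %/% f) * f
  vol <- vol[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]),
             drop = FALSE]
  nd <- keep %/% f
  a <- array(vol, c(f, nd[1], f, nd[2], f, nd[3]))
  apply(a, c(2, 4, 6), mean)
}

# affine of the f-fold block-mean image: coarse voxel centre sits at fine
# index f*i + (f-1)/2
downsampled_affine <- function(affine, f) {
  A <- affine
  A[1:3, 1:3] <- affine[1:3, 1:3] * f
  A[1:3, 4] <- (affine %*% c(rep((f - 1) / 2, 3), 1))[1:3]
  A
}

ncc <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

#' Rigid registration of a moving volume to a reference
#'
#' Six-parameter rigid transform maximising the normalised
#' cross-correlation, optimised with Nelder-Mead over a x4 / x2 / x1
#' multi-resolution pyramid, starting from the identity. Both volumes are
#' lightly smoothed before matching. Deterministic.
#'
#' @param moving,reference 3D arrays on the same grid.
#' @param affine shared voxel-to-world matrix.
#' @param levels downsampling factors, coarse to fine.
#' @param smooth_sigma pre-smoothing sd in voxels.
#' @param maxit Nelder-Mead iteration cap per level.
#' @return 4x4 world-mm rigid transform mapping moving to reference, with
#'   attribute `params` (rx, ry, rz, tx, ty, tz) and `ncc`.
#' @export
rigid_register <- function(moving, reference, affine,
                           levels = c(4, 2, 1), smooth_sigma = 1,
                           maxit = 400) {
  stopifnot(all(dim(moving) == dim(reference)))
  if (all(moving == 0) || all(reference == 0))
    stop("cannot register an all-zero volume")
  mov_s <- gaussian_smooth(moving, smooth_sigma)
  ref_s <- gaussian_smooth(reference, smooth_sigma)
  par <- rep(0, 6)
  val <- NA_real_
  for (f in levels) {
    if (any(dim(moving) %/% f < 6)) next
    mv <- block_downsample(mov_s, f)
    rf <- block_downsample(ref_s, f)
    af <- downsampled_affine(affine, f)
    # Sample points sit on the moving image's grid and the *reference* is
    # interpolated at their transformed positions: the moving image (the
    # one already carrying the motion) is never re-interpolated, which
    # removes the interpolation-blur bias that otherwise shrinks rotation
    # estimates. Background is excluded; points are thinned for speed.
    sel <- which(mv > 0.05 * max(mv))
    if (length(sel) < 50) sel <- seq_along(mv)
    if (length(sel) > 4000) sel <- sel[seq(1, length(sel),
                                           length.out = 4000)]
    dm <- dim(mv)
    coords <- cbind((sel - 1) %% dm[1],
                    ((sel - 1) %/% dm[1]) %% dm[2],
                    (sel - 1) %/% (dm[1] * dm[2]))
    mvv <- mv[sel]
    iaf <- solve(af)
    obj <- function(p) {
      S <- iaf %*% rigid_matrix(p) %*% af   # moving voxel -> ref voxel
      src <- coords %*% t(S[1:3, 1:3]) +
        rep(1, nrow(coords)) %o% S[1:3, 4]
      -ncc(trilinear_sample(rf, src), mvv)
    }
    n_starts <- if (f == min(levels)) 2 else 1
    for (rep_i in seq_len(n_starts)) {
      opt <- stats::optim(par, obj, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-9,
                                         parscale = c(rep(0.02, 3),
                                                      rep(1, 3))))
      par <- opt$par
      val <- opt$value
    }
  }
  M <- rigid_matrix(par)
  attr(M, "params") <- par
  attr(M, "ncc") <- -val
  M
}

#' Estimate a motion transform chain by registering every volume
#'
#' Registers each volume of a DWI series to the reference (first b = 0)
#' volume; the reference volume itself gets the identity.
#'
#' @param dwi a [dwi_series].
#' @param reference reference volume index (default: first b = 0 volume).
#' @param ... passed to [rigid_register()].
#' @return A [transform_chain] of volume-to-reference transforms.
#' @export
estimate_motion <- function(dwi, reference = NULL, ...) {
  stopifnot(inherits(dwi, "dwi_series"))
  if (is.null(reference)) reference <- which(dwi$grad$bvals == 0)[1]
  nvol <- dim(dwi$data)[4]
  ref_vol <- dwi$data[, , , reference]
  chain <- vector("list", nvol)
  for (v in seq_len(nvol)) {
    chain[[v]] <- if (v == reference) diag(4)
    else rigid_register(dwi$data[, , , v], ref_vol, dwi$affine, ...)
  }
  transform_chain(chain, reference = as.integer(reference))
}
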