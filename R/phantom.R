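# Synthetic DWI phantoms: analytic tensor fields, the mono-exponential
# forward signal model with Rician noise, and rigid motion injection.
#
# Tensor fields are stored as nx x ny x nz x 6 arrays in the element order
# (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), the same order as tensor_design(). All
# phantom grids place the world origin at the centre of the field of view,
# so rotation about the origin is rotation about the head centre.

#' Eigenvalues of a cylindrically symmetric tensor with given FA and MD
#'
#' Solves `lambda1 >= lambda2 = lambda3` from the closed forms
#' `MD = (l1 + 2 l2) / 3` and the FA expression, via
#' `f = FA / sqrt(3 - 2 FA^2)`, `l1 = MD (1 + 2 f)`, `l2 = MD (1 - f)`.
#'
#' @param fa target fractional anisotropy in `[0, 1)`.
#' @param md target mean diffusivity (mm^2/s), > 0.
#' @return Numeric length 3, descending eigenvalues.
#' @export
eigs_from_fa_md <- function(fa, md) {
  if (fa < 0 || fa >= 1) stop("FA must be in [0, 1)")
  if (md <= 0) stop("MD must be > 0")
  f <- fa / sqrt(3 - 2 * fa^2)
  c(md * (1 + 2 * f), md * (1 - f), md * (1 - f))
}

tensor6_from_eigs <- function(eigs, axis = c(1, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal frame with `axis` first
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * axis) * axis
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(axis[2] * e2[3] - axis[3] * e2[2],
          axis[3] * e2[1] - axis[1] * e2[3],
          axis[1] * e2[2] - axis[2] * e2[1])
  V <- cbind(axis, e2, e3)
  D <- V %*% diag(eigs) %*% t(V)
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

#' Construct a tensor field
#'
#' @param D nx x ny x nz x 6 array of tensor elements
#'   (xx, yy, zz, xy, xz, yz) in mm^2/s.
#' @param mask logical 3D brain mask.
#' @return Object of class `tensor_field`.
#' @export
tensor_field <- function(D, mask) {
  stopifnot(length(dim(D)) == 4, dim(D)[4] == 6,
            all(dim(D)[1:3] == dim(mask)))
  structure(list(D = D, mask = mask), class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %s grid, %d mask voxels\n",
              paste(dim(x$D)[1:3], collapse = "x"), sum(x$mask)))
  invisible(x)
}

#' Build an analytic tensor phantom from region specifications
#'
#' Each region assigns cylindrically symmetric tensors that achieve the
#' requested FA and MD exactly (see [eigs_from_fa_md()]); later regions
#' overwrite earlier ones. Voxels outside every region (or outside `mask`)
#' hold zero tensors.
#'
#' @param shape integer length 3, each >= 16.
#' @param regions list of lists with fields `mask` (logical 3D array),
#'   `fa`, `md` and optional `axis` (principal direction, default x).
#' @param mask overall brain mask (default: union of region masks).
#' @return A [tensor_field].
#' @export
make_tensor_phantom <- function(shape, regions, mask = NULL) {
  stopifnot(length(shape) == 3)
  if (any(shape < 16)) stop("shape must be at least 16 along each axis")
  D <- array(0, c(shape, 6))
  covered <- array(FALSE, shape)
  for (rg in regions) {
    stopifnot(all(dim(rg$mask) == shape))
    d6 <- tensor6_from_eigs(eigs_from_fa_md(rg$fa, rg$md),
                            rg$axis %||% c(1, 0, 0))
    idx <- which(rg$mask)
    for (j in 1:6) {
      comp <- D[, , , j]
      comp[idx] <- d6[j]
      D[, , , j] <- comp
    }
    covered <- covered | rg$mask
  }
  if (is.null(mask)) mask <- covered
  for (j in 1:6) D[, , , j] <- D[, , , j] * mask
  tensor_field(D, mask)
}

#' Voxel-to-world affine of a centred grid
#'
#' RAS+ affine mapping 0-based voxel indices to world mm with the world
#' origin at the geometric centre of the field of view.
#'
#' @param shape grid dimensions.
#' @param voxdim voxel size in mm.
#' @return 4x4 affine.
#' @export
centered_affine <- function(shape, voxdim = c(2, 2, 2)) {
  A <- diag(4)
  diag(A)[1:3] <- voxdim
  A[1:3, 4] <- -(shape - 1) / 2 * voxdim
  A
}

#' Default slab-in-ellipsoid phantom
#'
#' An ellipsoidal "brain" of isotropic tissue (FA 0, MD 0.7e-3 mm^2/s)
#' crossed by a 5-voxel-thick high-FA slab (FA 0.8, principal axis x),
#' which thins to a single mid-plane sheet under skeletonisation. The
#' non-DW reference intensity map carries slab contrast, an off-centre
#' bright blob and a smooth seeded intensity field so that rigid
#' registration is well posed.
#'
#' @param shape grid dimensions (default 24 x 24 x 16).
#' @param voxdim voxel size in mm (default 2 mm isotropic).
#' @param slab_half half-thickness of the slab in voxels (default 2).
#' @param s0 reference non-DW signal level.
#' @param seed seed for the smooth intensity field.
#' @return List with `tensor` ([tensor_field]), `affine`, `voxdim`,
#'   `mask`, `slab` (logical slab mask), `s0_map`.
#' @export
default_phantom <- function(shape = c(24, 24, 16), voxdim = c(2, 2, 2),
                            slab_half = 2, s0 = 1000, seed = 0) {
  cx <- (shape - 1) / 2
  ix <- slice.index(array(0, shape), 1) - 1
  iy <- slice.index(array(0, shape), 2) - 1
  iz <- slice.index(array(0, shape), 3) - 1
  semi <- shape / 2 - 1.5
  mask <- ((ix - cx[1]) / semi[1])^2 + ((iy - cx[2]) / semi[2])^2 +
    ((iz - cx[3]) / semi[3])^2 <= 1
  slab <- mask & abs(iy - floor(shape[2] / 2)) <= slab_half
  tf <- make_tensor_phantom(
    shape,
    regions = list(
      list(mask = mask, fa = 0, md = 0.7e-3),
      list(mask = slab, fa = 0.8, md = 0.7e-3, axis = c(1, 0, 0))
    ),
    mask = mask
  )
  set.seed(seed)
  field <- gaussian_smooth(array(stats::rnorm(prod(shape)), shape), 1)
  field <- field / max(abs(field))
  blob <- ((ix - cx[1] - shape[1] / 5)^2 + (iy - cx[2] + shape[2] / 5)^2 +
             (iz - cx[3])^2) <= (min(shape) / 5)^2
  s0_map <- (s0 * (1 + 0.15 * field) - 200 * slab + 250 * blob) * mask
  list(tensor = tf, affine = centered_affine(shape, voxdim),
       voxdim = voxdim, mask = mask, slab = slab, s0_map = s0_map)
}

#' Construct a 4D DWI series
#'
#' @param data 4D array (x, y, z, volume), non-negative signal.
#' @param grad matching [gradient_table].
#' @param affine 4x4 voxel-to-world matrix.
#' @return Object of class `dwi_series`.
#' @export
dwi_series <- function(data, grad, affine) {
  stopifnot(length(dim(data)) == 4)
  if (dim(data)[4] != length(grad$bvals))
    stop("4th dimension (", dim(data)[4], ") != gradient table length (",
         length(grad$bvals), ")")
  if (min(data) < 0) stop("DWI signal must be non-negative")
  check_transform(affine, "affine")
  structure(list(data = data, grad = grad, affine = affine,
                 voxdim = sqrt(colSums(affine[1:3, 1:3]^2))),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  cat(sprintf("<dwi_series> %s grid, %d volumes, voxels %s mm\n",
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4],
              paste(signif(x$voxdim, 3), collapse = "x")))
  invisible(x)
}

#' Simulate a DWI series from a tensor field
#'
#' Mono-exponential model `S = S0 exp(-b g' D g)` per volume; optional
#' Rician corruption (magnitude of a complex Gaussian perturbation),
#' applied voxelwise in image space. Deterministic per seed.
#'
#' @param tf a [tensor_field].
#' @param grad a [gradient_table].
#' @param affine voxel-to-world matrix (default: centred 2 mm grid).
#' @param s0 non-DW signal: scalar (applied inside the mask) or 3D array.
#' @param noise_sigma Rician noise sd in signal units (>= 0).
#' @param seed RNG seed used when `noise_sigma > 0`.
#' @return A [dwi_series].
#' @export
simulate_dwi <- function(tf, grad, affine = NULL, s0 = 1000,
                         noise_sigma = 0, seed = 0) {
  stopifnot(inherits(tf, "tensor_field"), noise_sigma >= 0)
  shape <- dim(tf$D)[1:3]
  if (is.null(affine)) affine <- centered_affine(shape)
  s0_map <- if (length(s0) == 1) s0 * tf$mask else s0
  stopifnot(all(dim(s0_map) == shape))
  X <- tensor_design(grad)
  dw <- attr(X, "dw")
  nvol <- length(grad$bvals)
  Dm <- matrix(tf$D, ncol = 6)
  Q <- Dm %*% t(X)                        # b g' D g per voxel x DW volume
  data <- array(0, c(shape, nvol))
  for (v in seq_len(nvol)) {
    data[, , , v] <- if (v %in% dw) s0_map * exp(-array(Q[, match(v, dw)],
                                                        shape))
    else s0_map
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    n <- length(data)
    data <- sqrt((data + stats::rnorm(n, sd = noise_sigma))^2 +
                   stats::rnorm(n, sd = noise_sigma)^2)
  }
  dwi_series(data, grad, affine)
}

#' Resample a 3D volume through a world-space transform
#'
#' The object is moved by `M`: `out(x) = in(M^-1 x)` with trilinear
#' interpolation and constant-zero padding.
#'
#' @param vol 3D array.
#' @param M 4x4 world transform.
#' @param affine voxel-to-world matrix of `vol`.
#' @return Resampled 3D array.
#' @export
resample_affine <- function(vol, M, affine) {
  dm <- dim(vol)
  S <- solve(affine) %*% solve(M) %*% affine    # voxel-to-voxel pullback
  idx <- as.matrix(expand.grid(x = 0:(dm[1] - 1), y = 0:(dm[2] - 1),
                               z = 0:(dm[3] - 1)))
  src <- idx %*% t(S[1:3, 1:3]) + rep(1, nrow(idx)) %o% S[1:3, 4]
  array(trilinear_sample(vol, src), dm)
}

#' Inject per-volume rigid head motion into a DWI series
#'
#' Each volume is resampled through its own rigid transform (rotation about
#' the field-of-view centre plus translation). The returned chain holds the
#' exact volume-to-reference ground truth, i.e. the inverse of each applied
#' transform, directly comparable to registration output.
#'
#' @param dwi a [dwi_series].
#' @param params n_volumes x 6 matrix: rotations (rad) about x, y, z and
#'   translations (mm); the first row must be all zero (reference volume).
#' @return List with `dwi` (motion-corrupted series) and `chain`
#'   ([transform_chain] of ground-truth transforms).
#' @export
inject_motion <- function(dwi, params) {
  stopifnot(inherits(dwi, "dwi_series"))
  params <- as.matrix(params)
  nvol <- dim(dwi$data)[4]
  if (nrow(params) != nvol || ncol(params) != 6)
    stop("params must be ", nvol, " x 6")
  if (any(params[1, ] != 0)) stop("first volume must be the identity")
  fov <- dim(dwi$data)[1:3] * dwi$voxdim
  if (any(abs(params[, 4:6]) > rep(fov / 2, each = nvol)))
    stop("translation exceeds half the field of view")
  data <- dwi$data
  chain <- vector("list", nvol)
  chain[[1]] <- diag(4)
  for (v in 2:nvol) {
    if (all(params[v, ] == 0)) {
      chain[[v]] <- diag(4)
      next
    }
    A <- rigid_matrix(params[v, ])
    data[, , , v] <- resample_affine(dwi$data[, , , v], A, dwi$affine)
    chain[[v]] <- solve(A)
  }
  list(dwi = dwi_series(data, dwi$grad, dwi$affine),
       chain = transform_chain(chain, reference = 1L))
}

#' Draw per-volume rigid motion parameters with a target mean RMS
#'
#' Volumes receive independent small absolute poses (no cumulative drift,
#' as after coarse prospective correction); the pose scale is calibrated so
#' that the mean consecutive-transition RMS deviation matches
#' `target_mean_rms`. Deterministic per seed.
#'
#' @param n_vols number of volumes.
#' @param target_mean_rms desired mean per-transition RMS deviation (mm).
#' @param R,center RMS sphere radius (mm) and centre.
#' @param seed RNG seed.
#' @return n_vols x 6 parameter matrix (first row zero).
#' @export
make_motion_params <- function(n_vols, target_mean_rms, R = 80,
                               center = c(0, 0, 0), seed = 0) {
  stopifnot(n_vols >= 2, target_mean_rms >= 0)
  set.seed(seed)
  p <- cbind(matrix(stats::rnorm(3 * n_vols, sd = 0.02), n_vols),
             matrix(stats::rnorm(3 * n_vols), n_vols))
  p[1, ] <- 0
  if (target_mean_rms == 0) return(p * 0)
  mean_rms <- function(pp) {
    tr <- lapply(seq_len(n_vols), function(v) {
      solve(rigid_matrix(pp[v, ], center = center))
    })
    motion_trace(transform_chain(tr), R = R, center = center)$mean
  }
  for (i in 1:3) p <- p * (target_mean_rms / mean_rms(p))
  p
}
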