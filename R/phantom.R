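#' Deterministic diffusion gradient scheme for the phantom
#'
#' A fixed table of unit directions spread over the hemisphere by the
#' Fibonacci spiral (deterministic, roughly uniform), preceded by `n_b0`
#' b = 0 volumes. Emulates a clinical 20-direction single-shell scheme.
#'
#' @param n_dirs number of diffusion-weighted directions (default 20).
#' @param bvalue shell b-value in s/mm^2 (default 1000).
#' @param n_b0 number of b0 volumes (default 2).
#' @return A [gradient_table()].
#' @export
phantom_gradient_table <- function(n_dirs = 20L, bvalue = 1000, n_b0 = 2L) {
  i <- seq_len(n_dirs) - 1
  ga <- pi * (3 - sqrt(5))
  z <- (i + 0.5) / n_dirs
  r <- sqrt(1 - z^2)
  dirs <- cbind(r * cos(i * ga), r * sin(i * ga), z)
  bvecs <- rbind(matrix(0, n_b0, 3), dirs)
  bvals <- c(rep(0, n_b0), rep(bvalue, n_dirs))
  gradient_table(bvals, bvecs)
}

#' Configuration of the digital edema phantom
#'
#' A two-compartment (tissue + free water) digital DWI phantom: an
#' anisotropic white-matter bundle (straight tube or 90-degree elbow)
#' embedded in isotropic grey-matter-like background, with a spherical
#' lesion core, an edematous free-water shell around it whose ground-truth
#' fraction falls linearly from `f_edema_max` at the lesion border to
#' `f_edema_min` at the shell edge, and a CSF slab at one volume face.
#' Geometry is in 0-based voxel units on an isotropic grid.
#'
#' @param shape grid dimensions (default 40 x 40 x 20).
#' @param voxel_mm isotropic voxel size (default 2 mm, matching a clinical
#'   DTI acquisition).
#' @param bundle list: `type` ("straight" or "elbow"), `axis` (for straight;
#'   "x"), `center` (2 cross-axis voxel coordinates), `radius` (voxels),
#'   `evals` (tissue eigenvalues mm^2/s), optional `edema_evals` (tissue
#'   eigenvalues inside the edema shell; defaults to `evals`), and for the
#'   elbow a `corner` voxel where the tube turns from +x to +y.
#' @param lesion list: `center` (3 voxel coords), `radius` (voxels),
#'   `f` (default 0.9), `md` tissue diffusivity inside (default 1.0e-3).
#' @param edema list: `outer_radius` (voxels), `f_max` fraction at the lesion
#'   border (default 0.7), `f_min` at the shell edge (default 0.2).
#' @param background list: `md` (default 0.8e-3), `f` (default 0.05).
#' @param csf list: `axis`, `thickness` of the border slab in voxels
#'   (0 disables; f = 1 inside).
#' @param S0 non-diffusion-weighted signal level (default 1000).
#' @param snr Rician signal-to-noise ratio at b0 (default 30; 0 = noiseless).
#' @param seed RNG seed for the noise draw.
#' @param gtab gradient scheme (default [phantom_gradient_table()]).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(40L, 40L, 20L),
                           voxel_mm = 2,
                           bundle = list(type = "straight", axis = "x",
                                         center = c(20, 10), radius = 2.5,
                                         evals = c(1.7e-3, 0.3e-3, 0.3e-3)),
                           lesion = list(center = c(20, 28, 10), radius = 4,
                                         f = 0.9, md = 1.0e-3),
                           edema = list(outer_radius = 10, f_max = 0.7,
                                        f_min = 0.2),
                           background = list(md = 0.8e-3, f = 0.05),
                           csf = list(axis = "y", thickness = 2),
                           S0 = 1000, snr = 30, seed = 1L,
                           gtab = phantom_gradient_table()) {
  if (is.null(bundle$edema_evals)) bundle$edema_evals <- bundle$evals
  cfg <- structure(list(shape = as.integer(shape), voxel_mm = voxel_mm,
                        bundle = bundle, lesion = lesion, edema = edema,
                        background = background, csf = csf,
                        S0 = S0, snr = snr, seed = as.integer(seed),
                        gtab = gtab),
                   class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(length(cfg$shape) == 3L, all(cfg$shape > 0), cfg$voxel_mm > 0,
            cfg$S0 > 0, cfg$snr >= 0)
  fs <- c(cfg$lesion$f, cfg$edema$f_max, cfg$edema$f_min, cfg$background$f)
  if (any(fs < 0 | fs > 1)) stop("ground-truth fractions must lie in [0, 1]")
  if (cfg$lesion$radius >= cfg$edema$outer_radius) {
    stop("validation error: lesion must sit inside the edema shell")
  }
  ctr <- cfg$lesion$center
  if (any(ctr - cfg$lesion$radius < 0) ||
      any(ctr + cfg$lesion$radius > cfg$shape - 1)) {
    stop("validation error: lesion extends outside the grid")
  }
  invisible(cfg)
}

# distance of every voxel center to the bundle's axis (straight or elbow)
bundle_distance <- function(cfg, gx, gy, gz) {
  b <- cfg$bundle
  if (identical(b$type, "straight")) {
    ax <- match(b$axis, c("x", "y", "z"))
    cross <- list(c(2, 3), c(1, 3), c(1, 2))[[ax]]
    g <- list(gx, gy, gz)
    sqrt((g[[cross[1]]] - b$center[1])^2 + (g[[cross[2]]] - b$center[2])^2)
  } else if (identical(b$type, "elbow")) {
    # tube along +x up to the corner, then along +y; z fixed at center[2]
    cx <- b$corner[1]; cy <- b$corner[2]; cz <- b$center[2]
    # distance to the two half-lines meeting at the corner
    d1 <- sqrt(pmax(gx - cx, 0)^2 + (gy - cy)^2 + (gz - cz)^2)   # x-arm: x <= cx
    d2 <- sqrt((gx - cx)^2 + pmax(cy - gy, 0)^2 + (gz - cz)^2)   # y-arm: y >= cy
    pmin(d1, d2)
  } else stop("unknown bundle type: ", b$type)
}

# unit tangent of the bundle at each voxel (for the elbow, the nearer arm)
bundle_tangent <- function(cfg, gx, gy, gz) {
  b <- cfg$bundle
  n <- length(gx)
  if (identical(b$type, "straight")) {
    ax <- match(b$axis, c("x", "y", "z"))
    tang <- matrix(0, n, 3); tang[, ax] <- 1
    tang
  } else {
    cx <- b$corner[1]; cy <- b$corner[2]; cz <- b$center[2]
    d1 <- sqrt(pmax(gx - cx, 0)^2 + (gy - cy)^2 + (gz - cz)^2)
    d2 <- sqrt((gx - cx)^2 + pmax(cy - gy, 0)^2 + (gz - cz)^2)
    tang <- matrix(0, n, 3)
    xarm <- d1 <= d2
    tang[xarm, 1] <- 1
    tang[!xarm, 2] <- 1
    tang
  }
}

# tensor with given eigenvalues, principal axis rotated onto `tang`
oriented_tensor6 <- function(evals, tang) {
  n <- nrow(tang)
  out <- matrix(0, n, 6)
  for (i in seq_len(n)) {
    e1 <- tang[i, ]
    ref <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e2 <- ref - sum(ref * e1) * e1
    e2 <- e2 / sqrt(sum(e2^2))
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    M <- evals[1] * tcrossprod(e1) + evals[2] * tcrossprod(e2) +
      evals[3] * tcrossprod(e3)
    out[i, ] <- sym_to_6(M)
  }
  out
}

#' Generate a two-compartment digital DWI phantom
#'
#' Builds the ground-truth free-water fraction map, tissue tensor field and
#' region masks from a [phantom_config()], forward-simulates the two-
#' compartment signal `S_i = S0 ((1 - f) exp(-b_i g_i' D g_i) + f exp(-b_i
#' d_water))`, and adds Rician noise `sqrt((S + n1)^2 + n2^2)` with
#' `n1, n2 ~ N(0, S0/snr)` when `snr > 0`. Deterministic given the seed.
#'
#' @param cfg a [phantom_config()].
#' @param d_water free-water diffusivity used in the forward model
#'   (default 3.0e-3 mm^2/s).
#' @return A list: `dwi` (4D [image_volume()]), `gtab`, and `truth` with
#'   `f` ([freewater_map()]), `tensor` ([tensor_field()]) and masks
#'   (`bundle`, `lesion`, `edema`, `csf`, `brain` as [binary_mask()]).
#' @export
generate_phantom <- function(cfg = phantom_config(), d_water = 3.0e-3) {
  validate_phantom_config(cfg)
  dims <- cfg$shape
  affine <- diag(c(rep(cfg$voxel_mm, 3), 1))
  nvox <- prod(dims)
  idx <- arrayInd(seq_len(nvox), dims) - 1
  gx <- idx[, 1]; gy <- idx[, 2]; gz <- idx[, 3]

  rles <- sqrt((gx - cfg$lesion$center[1])^2 + (gy - cfg$lesion$center[2])^2 +
                 (gz - cfg$lesion$center[3])^2)
  lesion <- rles <= cfg$lesion$radius
  shell <- rles <= cfg$edema$outer_radius & !lesion
  dbun <- bundle_distance(cfg, gx, gy, gz)
  bundle <- dbun <= cfg$bundle$radius & !lesion
  csf <- rep(FALSE, nvox)
  if (!is.null(cfg$csf) && cfg$csf$thickness > 0) {
    ax <- match(cfg$csf$axis, c("x", "y", "z"))
    g <- list(gx, gy, gz)[[ax]]
    csf <- g < cfg$csf$thickness
  }
  shell <- shell & !csf
  bundle <- bundle & !csf
  edema <- shell  # perilesional mask: shell minus lesion (lesion already excluded)

  # ground-truth free-water fraction
  f <- rep(cfg$background$f, nvox)
  tshell <- (rles - cfg$lesion$radius) /
    (cfg$edema$outer_radius - cfg$lesion$radius)
  f[shell] <- cfg$edema$f_max +
    (cfg$edema$f_min - cfg$edema$f_max) * tshell[shell]
  f[bundle & !shell] <- 0   # dense white matter: no free-water compartment
  f[lesion] <- cfg$lesion$f
  f[csf] <- 1

  # ground-truth tissue tensor
  D6 <- matrix(0, nvox, 6)
  iso6 <- function(md) c(md, 0, 0, md, 0, md)
  D6[] <- matrix(iso6(cfg$background$md), nvox, 6, byrow = TRUE)
  bidx <- which(bundle)
  if (length(bidx)) {
    tang <- bundle_tangent(cfg, gx[bidx], gy[bidx], gz[bidx])
    inshell <- shell[bidx]
    D6[bidx[!inshell], ] <- oriented_tensor6(cfg$bundle$evals,
                                             tang[!inshell, , drop = FALSE])
    if (any(inshell)) {
      D6[bidx[inshell], ] <- oriented_tensor6(cfg$bundle$edema_evals,
                                              tang[inshell, , drop = FALSE])
    }
  }
  if (any(lesion)) {
    D6[lesion, ] <- matrix(iso6(cfg$lesion$md), sum(lesion), 6, byrow = TRUE)
  }
  if (any(csf)) {
    D6[csf, ] <- matrix(iso6(cfg$background$md), sum(csf), 6, byrow = TRUE)
  }

  # forward two-compartment signal
  g <- cfg$gtab$bvecs; b <- cfg$gtab$bvals
  N <- length(b)
  Xq <- cbind(b * g[, 1]^2, 2 * b * g[, 1] * g[, 2], 2 * b * g[, 1] * g[, 3],
              b * g[, 2]^2, 2 * b * g[, 2] * g[, 3], b * g[, 3]^2)
  att_t <- exp(-tcrossprod(Xq, D6))          # N x V tissue attenuation
  wat <- exp(-b * d_water)
  S <- cfg$S0 * (sweep(att_t, 2L, 1 - f, `*`) + outer(wat, f))

  if (cfg$snr > 0) {
    sigma <- cfg$S0 / cfg$snr
    S <- with_seed(cfg$seed, {
      n1 <- matrix(stats::rnorm(N * nvox, 0, sigma), N, nvox)
      n2 <- matrix(stats::rnorm(N * nvox, 0, sigma), N, nvox)
      sqrt((S + n1)^2 + n2^2)
    })
  }

  dwi <- array(t(S), dim = c(dims, N))
  to3d <- function(v) array(v, dim = dims)
  tensor <- array(0, dim = c(dims, 6L))
  for (k in 1:6) tensor[, , , k] <- to3d(D6[, k])
  brain <- array(TRUE, dims)

  truth <- list(
    f = freewater_map(to3d(f), brain, affine),
    tensor = tensor_field(tensor, array(cfg$S0, dims), brain, affine),
    bundle = binary_mask(to3d(bundle), affine),
    lesion = binary_mask(to3d(lesion), affine),
    edema = binary_mask(to3d(edema), affine),
    csf = binary_mask(to3d(csf), affine),
    brain = binary_mask(brain, affine))
  list(dwi = image_volume(dwi, affine), gtab = cfg$gtab, truth = truth)
}

#' The standard edema benchmark phantom
#'
#' Fixed recipe demonstrating the false-negative/recovery behaviour: a
#' straight bundle crosses an edematous shell around an off-axis lesion. The
#' free-water plateau inside the shell (f* from 0.88 at the lesion border to
#' 0.84 at the shell edge) and the mildly degraded tissue eigenvalues of the
#' edematous bundle section (1.3, 0.45, 0.45) x 10^-3 mm^2/s are chosen so
#' that the single-tensor FA of the contaminated section falls below the
#' 0.15 tracking threshold (standard tractography loses the bundle there)
#' while the tissue-compartment FA stays near 0.59 — trackable, and below
#' the 0.9 free-water display cutoff so the slider can recover the section.
#' The bundle is longer on one side of the shell so that standard tracking
#' still produces streamlines that survive the length filter.
#'
#' @param seed RNG seed for the noise draw (and downstream seeding).
#' @param snr Rician SNR (default 0 = noiseless, isolating the edema
#'   mechanism from noise effects).
#' @return As [generate_phantom()].
#' @export
standard_edema_phantom <- function(seed = 7L, snr = 0) {
  cfg <- phantom_config(
    shape = c(40L, 40L, 20L),
    voxel_mm = 2,
    bundle = list(type = "straight", axis = "x", center = c(14, 10),
                  radius = 2.0,
                  evals = c(1.7e-3, 0.3e-3, 0.3e-3),
                  edema_evals = c(1.3e-3, 0.45e-3, 0.45e-3)),
    lesion = list(center = c(25, 20.5, 10), radius = 3.5, f = 0.9, md = 1.0e-3),
    edema = list(outer_radius = 12, f_max = 0.88, f_min = 0.84),
    background = list(md = 0.8e-3, f = 0.05),
    csf = list(axis = "y", thickness = 2),
    S0 = 1000, snr = snr, seed = seed)
  generate_phantom(cfg)
}
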