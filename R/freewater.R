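#' Options for the bi-compartment free-water fit
#'
#' Tunable parameters of the single-shell free-water elimination fit. The
#' free-water compartment diffuses isotropically at `d_water` = 3.0e-3 mm^2/s
#' (free water at body temperature). The tissue-MD prior anchors the
#' interpolated initialization; the tissue-MD box keeps the ill-posed
#' single-shell problem identifiable; light spatial smoothing of f between
#' outer iterations regularizes the fraction map.
#'
#' @param md_tissue_prior expected tissue mean diffusivity, mm^2/s
#'   (default 0.6e-3).
#' @param md_box allowed tissue-MD interval, mm^2/s (default 0.1e-3..1.5e-3).
#' @param max_iter resolution of the fraction profile scan: the grid has
#'   `max_iter + 1` points across `f_bounds` (default 100, i.e. steps of
#'   about 0.01 before parabolic refinement).
#' @param tol relative curvature threshold below which the fraction profile
#'   is treated as flat and the best grid point kept (default 1e-6).
#' @param smooth_sigma Gaussian sigma for inter-pass smoothing of f, in
#'   voxels (default 1; 0 disables).
#' @param n_outer number of outer fit/smooth/refit passes (default 2).
#' @param d_water free-water diffusivity, mm^2/s (default 3.0e-3).
#' @param f_bounds fraction bounds, kept slightly inside (0, 1) so both
#'   compartments stay identifiable (default c(1e-4, 0.9999)).
#' @param md_penalty weight of the prior-anchoring term
#'   `((MD_t - md_tissue_prior) / (d_water - md_tissue_prior))^2` added to
#'   the fraction profile cost after scaling by `md_penalty` times the
#'   per-voxel minimum residual (default 30). A single shell leaves the
#'   fraction/tissue-diffusivity trade-off almost flat below the true
#'   fraction, so on noisy data the anchor keeps the estimate near the
#'   fraction consistent with the tissue prior; because it is scaled by the
#'   residual noise level it vanishes on noiseless data, which the data term
#'   alone identifies. 0 disables.
#' @return An object of class `fw_fit_options`.
#' @export
fw_fit_options <- function(md_tissue_prior = 0.6e-3,
                           md_box = c(0.1e-3, 1.5e-3),
                           max_iter = 100L,
                           tol = 1e-6,
                           smooth_sigma = 1,
                           n_outer = 2L,
                           d_water = 3.0e-3,
                           f_bounds = c(1e-4, 0.9999),
                           md_penalty = 30) {
  stopifnot(md_tissue_prior > 0, all(md_box > 0), md_box[1] < md_box[2],
            md_tissue_prior >= md_box[1], md_tissue_prior <= md_box[2],
            max_iter >= 1, tol > 0, smooth_sigma >= 0, n_outer >= 1,
            d_water > 0, f_bounds[1] > 0, f_bounds[2] < 1, md_penalty >= 0)
  structure(list(md_tissue_prior = md_tissue_prior, md_box = md_box,
                 max_iter = as.integer(max_iter), tol = tol,
                 smooth_sigma = smooth_sigma, n_outer = as.integer(n_outer),
                 d_water = d_water, f_bounds = f_bounds,
                 md_penalty = md_penalty),
            class = "fw_fit_options")
}

#' Per-voxel free-water volume fraction map
#'
#' @param f 3D array of fractions in \[0, 1\].
#' @param mask 3D logical fit mask.
#' @param affine 4 x 4 voxel-to-world transform.
#' @return An object of class `freewater_map`.
#' @export
freewater_map <- function(f, mask, affine = diag(4)) {
  stopifnot(all(dim(f) == dim(mask)))
  mode(mask) <- "logical"
  fin <- f[mask]
  if (length(fin) && (min(fin) < 0 || max(fin) > 1)) {
    stop("free-water fractions must lie in [0, 1]")
  }
  structure(list(f = f, mask = mask, affine = as.matrix(affine)),
            class = "freewater_map")
}

#' Interpolated initialization of the free-water fraction
#'
#' Places the initial fraction by linear interpolation of the single-tensor
#' mean diffusivity between a tissue prior and the free-water diffusivity:
#' `f_init = clamp((MD - MD_tissue_prior) / (d_water - MD_tissue_prior))`.
#' A voxel whose MD already equals the water diffusivity starts as (almost)
#' pure water; one at the tissue prior starts as (almost) pure tissue.
#'
#' @param md_maps a `scalar_maps` object from [tensor_metrics()] (its `md`,
#'   `mask` and `affine` are used).
#' @param opts an [fw_fit_options()].
#' @return A [freewater_map()] of initial fractions.
#' @export
initialize_fw <- function(md_maps, opts = fw_fit_options()) {
  md <- md_maps$md
  if (any(md[md_maps$mask] < 0)) {
    message("initialize_fw: clamping negative MD value(s) to 0")
    md[md < 0] <- 0
  }
  f <- (md - opts$md_tissue_prior) / (opts$d_water - opts$md_tissue_prior)
  f <- pmax(pmin(f, opts$f_bounds[2]), opts$f_bounds[1])
  f[!md_maps$mask] <- 0
  freewater_map(f, md_maps$mask, md_maps$affine)
}

# One tissue-tensor update: extract the tissue attenuation at fixed f,
# fit the log-linear tensor by OLS->WLS, and project eigenvalues/MD into
# their admissible ranges. A: Ndwi x V attenuations, f: length-V fractions.
fw_tensor_step <- function(A, f, w, Xd, opts) {
  At <- (A - outer(w, f)) / rep(1 - f, each = nrow(A))
  At[At < 1e-6] <- 1e-6
  Y <- log(At)
  b_ols <- wls_solve(Xd, Y)
  W <- exp(2 * (Xd %*% b_ols))
  beta <- wls_solve(Xd, Y, W)
  bad <- colSums(is.na(beta)) > 0
  if (any(bad)) beta[, bad] <- 0
  D6 <- t(beta)
  D6 <- clamp_tensor_eigenvalues(D6, lo = 1e-7, hi = opts$d_water)
  md <- (D6[, 1] + D6[, 4] + D6[, 6]) / 3
  scl <- rep(1, length(md))
  scl[md < opts$md_box[1]] <- opts$md_box[1] / md[md < opts$md_box[1]]
  scl[md > opts$md_box[2]] <- opts$md_box[2] / md[md > opts$md_box[2]]
  D6 * scl
}

# Profile cost of the fraction: for each candidate f, extract the tissue
# attenuation, fit the log-linear tensor by (fast, shared-design) OLS,
# project its MD into the box, and score the linear-domain residual. The
# MD box is what makes the scan identify pure water: explaining a water
# voxel with low f would need tissue MD near d_water, which the box forbids.
# Returns the data term and the prior-anchoring profile separately; the
# caller scales the latter by the per-voxel noise level.
fw_profile_costs <- function(A, w, Xd, P_ols, fgrid, opts) {
  V <- ncol(A)
  cost <- matrix(NA_real_, length(fgrid), V)
  pen <- matrix(NA_real_, length(fgrid), V)
  box <- opts$md_box
  for (j in seq_along(fgrid)) {
    f <- fgrid[j]
    At <- (A - f * w) / (1 - f)
    At[At < 1e-6] <- 1e-6
    beta <- P_ols %*% log(At)                       # 6 x V tensor components
    md <- (beta[1, ] + beta[4, ] + beta[6, ]) / 3
    scl <- rep(1, V)
    bad <- md <= 0
    scl[!bad & md < box[1]] <- box[1] / md[!bad & md < box[1]]
    scl[!bad & md > box[2]] <- box[2] / md[!bad & md > box[2]]
    if (any(bad)) {
      # non-physical extraction; replace by the isotropic prior
      beta[, bad] <- opts$md_tissue_prior * c(1, 0, 0, 1, 0, 1)
    }
    beta <- sweep(beta, 2L, scl, `*`)
    Tt <- exp(Xd %*% beta)
    R <- (1 - f) * Tt + f * w - A
    cost[j, ] <- colSums(R * R)
    pj <- ((md * scl - opts$md_tissue_prior) /
             (opts$d_water - opts$md_tissue_prior))^2
    pj[bad] <- 0   # the residual already punishes non-physical extraction
    pen[j, ] <- pj
  }
  list(data = cost, prior = pen)
}

# argmin of the profile cost with parabolic refinement on the grid
fw_select_f <- function(cost, fgrid, opts) {
  V <- ncol(cost)
  jmin <- max.col(-t(cost), ties.method = "first")
  f <- fgrid[jmin]
  h <- diff(fgrid[1:2])
  flagged <- rep(FALSE, V)
  inner <- jmin > 1L & jmin < length(fgrid)
  if (any(inner)) {
    iv <- which(inner)
    c1 <- cost[cbind(jmin[iv] - 1L, iv)]
    c2 <- cost[cbind(jmin[iv], iv)]
    c3 <- cost[cbind(jmin[iv] + 1L, iv)]
    den <- c1 - 2 * c2 + c3
    okc <- is.finite(den) & den > opts$tol * pmax(c2, 1e-12)
    shift <- ifelse(okc, 0.5 * h * (c1 - c3) / den, 0)
    shift <- pmin(h, pmax(-h, shift))
    f[iv] <- f[iv] + shift
    flagged[iv] <- !okc   # flat profile: keep the best grid iterate
  }
  list(f = pmin(opts$f_bounds[2], pmax(opts$f_bounds[1], f)),
       flagged = flagged)
}

#' Fit the bi-compartment free-water model to single-shell DWI
#'
#' Models each voxel's attenuation as a mixture of an anisotropic tissue
#' tensor and an isotropic free-water compartment:
#' `S_i = S0 * ((1-f) exp(-b_i g_i' D_t g_i) + f exp(-b_i d_water))`.
#' Because a single shell cannot separate the fraction from the tissue
#' diffusivity without constraints, the fraction is estimated by a profile
#' scan: for every candidate f on a grid the tissue attenuation is extracted,
#' the tissue tensor fitted (log-linear least squares with its mean
#' diffusivity projected into the box), and the residual of the full mixture
#' model scored; the per-voxel minimizer is refined parabolically. The
#' MD-interpolated initialization ([initialize_fw()]) and the tissue-MD box
#' resolve the remaining degeneracy. Each outer pass rescans (subsequent
#' passes within a window around the smoothed field), Gaussian-smooths f,
#' and refits the tensor with f fixed (eigenvalues kept in
#' \[1e-7, d_water\]). The procedure is fully deterministic.
#'
#' @param dwi 4D [image_volume()].
#' @param gtab single-shell [gradient_table()] (one non-zero b-value).
#' @param mask [binary_mask()] of voxels to fit.
#' @param opts an [fw_fit_options()].
#' @return A list with `fw` (a [freewater_map()]) and `tensor` (a
#'   [tensor_field()] holding the tissue compartment D_t; attribute
#'   `d_water` records the water diffusivity). Attribute `n_nonconverged`
#'   counts voxels that hit `max_iter` in the final pass.
#' @export
fit_freewater <- function(dwi, gtab, mask, opts = fw_fit_options()) {
  check_pairing(dwi, gtab)
  if (!same_grid(dwi, mask)) stop("mask and volume are not on the same grid")
  bshell <- unique(round(gtab$bvals[!gtab$b0s] / 25) * 25)
  if (length(bshell) != 1L) {
    stop("unsupported input: multi-shell acquisition (b = ",
         paste(bshell, collapse = ", "), "); the free-water fit is single-shell")
  }

  dims <- dim(dwi$data)[1:3]
  # single-tensor fit supplies the MD map for initialization
  st <- fit_tensor(dwi, gtab, mask)
  maps <- tensor_metrics(st)
  f_map <- initialize_fw(maps, opts)

  fit_mask <- st$mask
  vox <- which(fit_mask)
  N <- length(gtab$bvals)
  Sall <- matrix(aperm(dwi$data, c(4, 1, 2, 3)), nrow = N)[, vox, drop = FALSE]
  b0 <- gtab$b0s
  S0 <- colMeans(Sall[b0, , drop = FALSE])
  ok <- S0 > 0
  if (!all(ok)) {
    fit_mask[vox[!ok]] <- FALSE
    vox <- vox[ok]
    Sall <- Sall[, ok, drop = FALSE]
    S0 <- S0[ok]
  }
  A <- sweep(Sall[!b0, , drop = FALSE], 2L, S0, `/`)
  A[A < 1e-6] <- 1e-6
  w <- exp(-gtab$bvals[!b0] * opts$d_water)
  gd <- list(bvals = gtab$bvals[!b0], bvecs = gtab$bvecs[!b0, , drop = FALSE])
  Xd <- tensor_design(gd)[, -1, drop = FALSE]   # attenuation model: no intercept

  f_init <- pmin(opts$f_bounds[2], pmax(opts$f_bounds[1], f_map$f[vox]))
  P_ols <- solve(crossprod(Xd), t(Xd))
  n_grid <- opts$max_iter + 1L
  fgrid <- seq(opts$f_bounds[1], opts$f_bounds[2], length.out = n_grid)
  window <- 0.05

  f <- f_init
  D6 <- NULL
  n_nonconv <- 0L
  for (outer in seq_len(opts$n_outer)) {
    prof <- fw_profile_costs(A, w, Xd, P_ols, fgrid, opts)
    # prior weight scales with the per-voxel noise level (the minimum of the
    # data term): it vanishes on noiseless data, where the data term alone
    # identifies the fraction, and takes over where the profile is flat
    noise_lvl <- apply(prof$data, 2L, min)
    cost <- prof$data +
      prof$prior * rep(opts$md_penalty * noise_lvl, each = length(fgrid))
    if (outer > 1L) {
      # keep the rescan near the smoothed field from the previous pass
      out_of_window <- abs(outer(fgrid, f, `-`)) > window
      cost[out_of_window] <- Inf
    }
    sel <- fw_select_f(cost, fgrid, opts)
    f <- sel$f
    n_nonconv <- sum(sel$flagged)
    if (opts$smooth_sigma > 0) {
      fvol <- array(0, dims)
      fvol[vox] <- f
      fvol <- gaussian_smooth3d(fvol, opts$smooth_sigma, fit_mask)
      f <- pmin(opts$f_bounds[2], pmax(opts$f_bounds[1], fvol[vox]))
    }
    D6 <- fw_tensor_step(A, f, w, Xd, opts)   # refit tissue with f fixed
  }
  if (n_nonconv > 0L) {
    message("fit_freewater: flat fraction profile in ", n_nonconv,
            " voxel(s); keeping best grid iterate")
  }

  fvol <- array(0, dims)
  fvol[vox] <- f
  tensor <- array(0, dim = c(dims, 6L))
  for (k in 1:6) {
    comp <- array(0, dims)
    comp[vox] <- D6[, k]
    tensor[, , , k] <- comp
  }
  S0vol <- array(0, dims)
  S0vol[vox] <- S0
  ctf <- tensor_field(tensor, S0vol, fit_mask, dwi$affine)
  attr(ctf, "d_water") <- opts$d_water
  out <- list(fw = freewater_map(fvol, fit_mask, dwi$affine), tensor = ctf)
  attr(out, "n_nonconverged") <- n_nonconv
  out
}

#' Scalar maps of the free-water-corrected (tissue) compartment
#'
#' FA, MD and principal eigenvectors of the tissue tensor via
#' [tensor_metrics()]. When the fraction map is supplied, voxels with
#' f > 0.9 are flagged `unreliable`: almost no tissue signal remains there,
#' so the corrected eigenvectors carry no usable orientation and tracking
#' treats such voxels as non-tissue.
#'
#' @param ctf corrected [tensor_field()] from [fit_freewater()].
#' @param fw optional [freewater_map()] used to flag unreliable voxels.
#' @param reliability_cutoff fraction above which the tissue fit is flagged
#'   (default 0.9).
#' @return A `scalar_maps` object, with an `unreliable` logical array when
#'   `fw` is given.
#' @export
corrected_fa <- function(ctf, fw = NULL, reliability_cutoff = 0.9) {
  maps <- tensor_metrics(ctf)
  if (!is.null(fw)) {
    maps$unreliable <- fw$f > reliability_cutoff & fw$mask
  }
  maps
}

#' Free-water ratio of a lesion and its perilesional zone
#'
#' Volume of abnormal perilesional voxels divided by the volume of all
#' abnormal voxels (lesion plus perilesional edema). Volumes are voxel counts
#' times the voxel volume; with a shared grid the ratio reduces to the count
#' ratio. Used as the per-patient edema-severity covariate.
#'
#' @param lesion [binary_mask()] of the lesion core.
#' @param perilesional [binary_mask()] of the perilesional (edematous) zone;
#'   must be disjoint from the lesion and on the same grid.
#' @return The ratio in \[0, 1\].
#' @export
free_water_ratio <- function(lesion, perilesional) {
  if (!same_grid(lesion, perilesional)) {
    stop("validation error: masks are not on the same grid")
  }
  if (any(lesion$data & perilesional$data)) {
    stop("validation error: lesion and perilesional masks overlap")
  }
  vvol <- abs(det(lesion$affine[1:3, 1:3]))
  v_les <- sum(lesion$data) * vvol
  v_peri <- sum(perilesional$data) * vvol
  if (v_les + v_peri == 0) stop("undefined ratio: both masks are empty")
  v_peri / (v_les + v_peri)
}

# Separable Gaussian smoothing with mask renormalization (kernel truncated
# at 3 sigma). Voxels outside the mask do not contribute and stay zero.
gaussian_smooth3d <- function(arr, sigma, mask = NULL) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  if (is.null(mask)) mask <- array(TRUE, dim(arr))
  num <- arr * mask
  den <- array(as.numeric(mask), dim(mask))
  shift_axis <- function(a, off, axis) {
    d <- dim(a)
    out <- array(0, d)
    n <- d[axis]
    src <- seq_len(n) - off
    keep <- src >= 1 & src <= n
    if (!any(keep)) return(out)
    idx_to <- which(keep); idx_from <- src[keep]
    if (axis == 1L) out[idx_to, , ] <- a[idx_from, , ]
    else if (axis == 2L) out[, idx_to, ] <- a[, idx_from, ]
    else out[, , idx_to] <- a[, , idx_from]
    out
  }
  for (axis in 1:3) {
    num2 <- array(0, dim(arr)); den2 <- array(0, dim(arr))
    for (j in seq(-r, r)) {
      kj <- k[j + r + 1L]
      num2 <- num2 + kj * shift_axis(num, j, axis)
      den2 <- den2 + kj * shift_axis(den, j, axis)
    }
    num <- num2; den <- den2
  }
  out <- array(0, dim(arr))
  nz <- den > 1e-12 & mask
  out[nz] <- num[nz] / den[nz]
  out
}
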