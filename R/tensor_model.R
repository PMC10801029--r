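#' Per-voxel diffusion tensor field
#'
#' Stores the six unique tensor components (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz) in
#' mm^2/s, the non-diffusion-weighted signal S0, the fit mask and the grid
#' affine. Eigenvalues inside the mask are clamped to at least 1e-7 mm^2/s at
#' fit time.
#'
#' @param tensor 4D array (X, Y, Z, 6) of tensor components.
#' @param S0 3D array of S0 estimates.
#' @param mask 3D logical array of fitted voxels.
#' @param affine 4 x 4 voxel-to-world transform.
#' @return An object of class `tensor_field`.
#' @export
tensor_field <- function(tensor, S0, mask, affine = diag(4)) {
  stopifnot(length(dim(tensor)) == 4L, dim(tensor)[4] == 6L,
            all(dim(S0) == dim(tensor)[1:3]), all(dim(mask) == dim(S0)))
  mode(mask) <- "logical"
  structure(list(tensor = tensor, S0 = S0, mask = mask, affine = as.matrix(affine)),
            class = "tensor_field")
}

# N x 7 design matrix for the log-linear tensor model:
# ln S_i = ln S0 - b_i g_i' D g_i, parameters (ln S0, Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)
tensor_design <- function(gtab) {
  g <- gtab$bvecs; b <- gtab$bvals
  cbind(1,
        -b * g[, 1]^2,
        -2 * b * g[, 1] * g[, 2],
        -2 * b * g[, 1] * g[, 3],
        -b * g[, 2]^2,
        -2 * b * g[, 2] * g[, 3],
        -b * g[, 3]^2)
}

# Weighted least squares for many voxels at once. Y: N x V log-signals,
# W: N x V weights (or NULL for OLS). Returns 7 x V coefficients.
wls_solve <- function(X, Y, W = NULL) {
  if (is.null(W)) {
    XtX <- crossprod(X)
    return(solve(XtX, crossprod(X, Y)))
  }
  p <- ncol(X)
  V <- ncol(Y)
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  H <- X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]  # N x p(p+1)/2
  E <- crossprod(H, W)                                   # packed X'WX, per voxel
  R <- crossprod(X, W * Y)                               # p x V right-hand sides
  out <- matrix(0, p, V)
  A <- matrix(0, p, p)
  ut <- upper.tri(A, diag = TRUE)
  for (v in seq_len(V)) {
    A[ut] <- E[, v]
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    out[, v] <- tryCatch(solve(A, R[, v]), error = function(e) rep(NA_real_, p))
  }
  out
}

#' Fit the single-tensor model by two-pass weighted least squares
#'
#' Per voxel, solves the log-linearized Stejskal-Tanner model
#' `ln S_i = ln S0 - b_i g_i' D g_i` by ordinary least squares, then one
#' reweighted pass with weights equal to the squared predicted signals (the
#' standard WLS estimator). Non-positive signal samples are replaced by half
#' the smallest positive signal in that voxel before taking logs. Voxels
#' whose signal is zero in every frame are dropped from the mask; the count
#' is attached as attribute `n_dropped`. Eigenvalues below 1e-7 mm^2/s are
#' clamped.
#'
#' @param dwi 4D [image_volume()] paired with `gtab`.
#' @param gtab a [gradient_table()] with at least 6 diffusion-weighted
#'   directions.
#' @param mask a [binary_mask()] restricting the fit.
#' @return A [tensor_field()]. Attribute `n_floored` counts voxels where a
#'   non-positive sample was floored.
#' @export
fit_tensor <- function(dwi, gtab, mask) {
  check_pairing(dwi, gtab)
  if (sum(!gtab$b0s) < 6L) stop("need at least 6 diffusion-weighted directions")
  if (!same_grid(dwi, mask)) stop("mask and volume are not on the same grid")

  dims <- dim(dwi$data)[1:3]
  vox <- which(mask$data)
  N <- length(gtab$bvals)
  S <- matrix(aperm(dwi$data, c(4, 1, 2, 3)), nrow = N)[, vox, drop = FALSE]

  all_zero <- colSums(S > 0) == 0L
  n_dropped <- sum(all_zero)
  if (n_dropped > 0L) {
    message("fit_tensor: dropping ", n_dropped, " voxel(s) with all-zero signal")
  }

  n_floored <- 0L
  nonpos <- S <= 0
  if (any(nonpos & !rep(all_zero, each = N))) {
    flo <- which(colSums(nonpos) > 0L & !all_zero)
    n_floored <- length(flo)
    warning("fit_tensor: floored non-positive signal(s) in ", n_floored, " voxel(s)")
    for (v in flo) {
      s <- S[, v]
      s[s <= 0] <- min(s[s > 0]) / 2
      S[, v] <- s
    }
  }

  keep <- !all_zero
  X <- tensor_design(gtab)
  beta <- matrix(NA_real_, 7, ncol(S))
  if (any(keep)) {
    Y <- log(S[, keep, drop = FALSE])
    b_ols <- wls_solve(X, Y)
    W <- exp(2 * (X %*% b_ols))      # squared predicted signals (attenuation scale)
    beta[, keep] <- wls_solve(X, Y, W)
  }

  tensor <- array(0, dim = c(dims, 6L))
  S0 <- array(0, dim = dims)
  fitted_mask <- array(FALSE, dim = dims)
  ok <- keep & colSums(is.na(beta)) == 0L
  fitted_mask[vox[ok]] <- TRUE
  S0[vox[ok]] <- exp(beta[1, ok])
  D6 <- t(beta[2:7, ok, drop = FALSE])
  D6 <- clamp_tensor_eigenvalues(D6, lo = 1e-7)
  for (k in 1:6) {
    comp <- array(0, dim = dims)
    comp[vox[ok]] <- D6[, k]
    tensor[, , , k] <- comp
  }
  tf <- tensor_field(tensor, S0, fitted_mask, dwi$affine)
  attr(tf, "n_dropped") <- n_dropped
  attr(tf, "n_floored") <- n_floored
  tf
}

# Clamp eigenvalues of packed tensors into [lo, hi], reconstructing through
# the full eigenbasis only where clamping is actually needed.
clamp_tensor_eigenvalues <- function(D6, lo = 1e-7, hi = Inf) {
  D6 <- rbind(D6)
  if (!nrow(D6)) return(D6)
  ev <- eig3_sym(D6)$values
  bad <- which(ev[, 3] < lo | ev[, 1] > hi)
  for (i in bad) {
    e <- eigen(six_to_sym(D6[i, ]), symmetric = TRUE)
    lam <- pmin(pmax(e$values, lo), hi)
    M <- e$vectors %*% diag(lam) %*% t(e$vectors)
    D6[i, ] <- sym_to_6(M)
  }
  D6
}

#' Scalar maps from a tensor field
#'
#' Computes fractional anisotropy
#' `FA = sqrt(3/2) * sqrt(sum((lambda - MD)^2)) / sqrt(sum(lambda^2))`,
#' mean diffusivity `MD = (l1 + l2 + l3)/3` (synonymous with ADC here) and
#' the principal eigenvector (unit norm, sign-ambiguous). All-zero tensors
#' yield FA = 0, MD = 0 and a zero eigenvector, flagged in `degenerate`.
#'
#' @param tf a [tensor_field()] (or the tissue compartment of a free-water
#'   corrected field).
#' @return An object of class `scalar_maps`: list with 3D arrays `fa`, `md`,
#'   4D array `pev` (X, Y, Z, 3), logical `degenerate`, plus `mask`, `affine`.
#' @export
tensor_metrics <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  dims <- dim(tf$S0)
  vox <- which(tf$mask)
  D6 <- matrix(aperm(tf$tensor, c(4, 1, 2, 3)), nrow = 6)[, vox, drop = FALSE]
  e <- eig3_sym(t(D6))
  lam <- e$values
  md <- rowMeans(lam)
  den <- sqrt(rowSums(lam^2))
  num <- sqrt(1.5) * sqrt(rowSums((lam - md)^2))
  fa <- ifelse(den > 0, pmin(1, num / den), 0)

  fa_map <- array(0, dims); md_map <- array(0, dims)
  deg <- array(FALSE, dims)
  fa_map[vox] <- fa; md_map[vox] <- md
  deg[vox] <- e$degenerate
  pev <- array(0, dim = c(dims, 3L))
  for (k in 1:3) {
    comp <- array(0, dims)
    comp[vox] <- e$pev[, k]
    pev[, , , k] <- comp
  }
  structure(list(fa = fa_map, md = md_map, pev = pev, degenerate = deg,
                 mask = tf$mask, affine = tf$affine),
            class = "scalar_maps")
}

#' Forward-simulate diffusion-weighted signals from a tensor field
#'
#' `S_i = S0 * exp(-b_i g_i' D g_i)` per voxel and gradient direction.
#'
#' @param tf a [tensor_field()].
#' @param gtab a [gradient_table()].
#' @return A 4D [image_volume()] with one frame per gradient table entry.
#' @export
predict_signal <- function(tf, gtab) {
  stopifnot(inherits(tf, "tensor_field"))
  dims <- dim(tf$S0)
  N <- length(gtab$bvals)
  vox <- which(tf$mask)
  D6 <- matrix(aperm(tf$tensor, c(4, 1, 2, 3)), nrow = 6)[, vox, drop = FALSE]
  X <- tensor_design(gtab)[, -1, drop = FALSE]   # N x 6, the -b g'Dg part
  att <- exp(X %*% D6)                           # N x V
  sig <- sweep(att, 2L, tf$S0[vox], `*`)
  out <- array(0, dim = c(dims, N))
  flat <- matrix(0, nrow = prod(dims), ncol = N)
  flat[vox, ] <- t(sig)
  out[] <- flat
  image_volume(out, tf$affine)
}
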