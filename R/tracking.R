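#' Parameters for deterministic streamline tracking
#'
#' Conventional clinical deterministic-tractography settings: fixed-step
#' Euler integration along the principal eigenvector with an anisotropy
#' stopping threshold and a bend-angle limit.
#'
#' @param step integration step in mm (default 1).
#' @param max_angle maximum bend per step in degrees (default 45).
#' @param fa_threshold stop when interpolated FA falls below this
#'   (default 0.15). The threshold applies to whichever FA map is passed to
#'   [track()], so corrected tracking thresholds on tissue FA.
#' @param min_length,max_length streamline length bounds in mm
#'   (defaults 20 and 250); streamlines outside the range are discarded.
#' @param seeds_per_voxel seed points per mask voxel (default 1).
#' @param seed RNG seed for the uniform within-voxel seed jitter
#'   (default 42).
#' @return An object of class `tracking_params`.
#' @export
tracking_params <- function(step = 1, max_angle = 45, fa_threshold = 0.15,
                            min_length = 20, max_length = 250,
                            seeds_per_voxel = 1L, seed = 42L) {
  stopifnot(step > 0, max_angle > 0, max_angle <= 90,
            fa_threshold >= 0, fa_threshold < 1,
            min_length < max_length, seeds_per_voxel >= 1)
  structure(list(step = step, max_angle = max_angle,
                 fa_threshold = fa_threshold,
                 min_length = min_length, max_length = max_length,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 seed = as.integer(seed)),
            class = "tracking_params")
}

#' Seed points from a mask
#'
#' Places `seeds_per_voxel` points in every mask voxel, uniformly jittered
#' inside the voxel. Deterministic given `params$seed`.
#'
#' @param mask a [binary_mask()].
#' @param params a [tracking_params()].
#' @return An n x 3 matrix of world-mm points.
#' @export
seeds_from_mask <- function(mask, params = tracking_params()) {
  vox <- which(mask$data, arr.ind = TRUE) - 1  # 0-based centers
  if (nrow(vox) == 0L) stop("empty seed mask")
  spv <- params$seeds_per_voxel
  vox <- vox[rep(seq_len(nrow(vox)), each = spv), , drop = FALSE]
  jit <- with_seed(params$seed, matrix(stats::runif(length(vox), -0.5, 0.5),
                                       ncol = 3L))
  voxel_to_world(vox + jit, mask$affine)
}

# evaluate local direction + stopping scalars at world points
track_sample <- function(pts, env) {
  vox <- world_to_voxel(pts, env$affine)
  D6 <- trilinear4d(env$tensor, vox)
  e <- eig3_sym(ifelse(is.na(D6), 0, D6))
  fa <- trilinear3d(env$fa, vox)
  inmask <- nearest_lookup(env$mask, vox)
  ok <- !is.na(fa) & fa >= env$fa_threshold & !e$degenerate &
    !is.na(inmask) & inmask & rowSums(is.na(D6)) == 0
  if (!is.null(env$fw)) {
    fwv <- trilinear3d(env$fw, vox)
    ok <- ok & !is.na(fwv) & fwv <= env$fw_cutoff
  }
  list(dir = e$pev, ok = ok)
}

# propagate one half-streamline for a batch of seeds; returns points array
# [max_steps, n, 3] and per-seed step counts
track_half <- function(seeds, dir0, env, params) {
  n <- nrow(seeds)
  max_steps <- floor(params$max_length / params$step)
  pts <- array(NA_real_, c(max_steps, n, 3L))
  counts <- integer(n)
  cur <- seeds
  prev <- dir0
  active <- which(rowSums(dir0^2) > 0)
  cos_lim <- cos(params$max_angle * pi / 180)
  for (s in seq_len(max_steps)) {
    if (!length(active)) break
    if (s == 1L) {
      v <- prev[active, , drop = FALSE]   # direction at the seed, precomputed
    } else {
      smp <- track_sample(cur[active, , drop = FALSE], env)
      v <- smp$dir
      dots <- rowSums(v * prev[active, , drop = FALSE])
      v <- v * sign(ifelse(dots == 0, 1, dots))     # continue previous heading
      turn_ok <- abs(dots) >= cos_lim & smp$ok & rowSums(v^2) > 0
      active <- active[turn_ok]
      if (!length(active)) break
      v <- v[turn_ok, , drop = FALSE]
    }
    nxt <- cur[active, , drop = FALSE] + params$step * v
    smp2 <- track_sample(nxt, env)
    keep <- smp2$ok
    active <- active[keep]
    if (!length(active)) break
    nxt <- nxt[keep, , drop = FALSE]
    pts[s, active, ] <- nxt
    counts[active] <- s
    cur[active, ] <- nxt
    prev[active, ] <- v[keep, , drop = FALSE]
  }
  list(pts = pts, counts = counts)
}

#' Deterministic whole-volume streamline tractography
#'
#' Bidirectional Euler integration along the principal eigenvector of a
#' (possibly free-water-corrected) tensor field. Tensor components are
#' trilinearly interpolated and eigen-decomposed at each point, which avoids
#' eigenvector sign-flip artifacts; the step direction is the sign of the
#' local eigenvector that continues the previous heading (at the seed, both
#' signs are followed and the two half-tracks concatenated). A streamline
#' stops when the interpolated FA falls below the threshold, the bend per
#' step exceeds the angle limit, the point leaves the mask or volume, or —
#' when a free-water gate is supplied — the local free-water fraction
#' exceeds the gate cutoff (non-tissue, e.g. CSF). Streamlines outside the
#' length bounds are discarded.
#'
#' @param field a [tensor_field()] (uncorrected, or the tissue compartment
#'   from [fit_freewater()]).
#' @param fa 3D FA array or `scalar_maps` object used for the stopping rule
#'   (pass tissue FA for corrected tracking).
#' @param seeds n x 3 matrix of world-mm seed points
#'   (see [seeds_from_mask()]).
#' @param params a [tracking_params()].
#' @param fw_gate optional [freewater_map()]; voxels with fraction above
#'   `fw_cutoff` are treated as non-tissue and terminate streamlines.
#' @param fw_cutoff gate level (default 0.9).
#' @return A [tractogram()] in world mm.
#' @export
track <- function(field, fa, seeds, params = tracking_params(),
                  fw_gate = NULL, fw_cutoff = 0.9) {
  stopifnot(inherits(field, "tensor_field"))
  if (inherits(fa, "scalar_maps")) fa <- fa$fa
  stopifnot(all(dim(fa) == dim(field$S0)))
  seeds <- rbind(seeds)

  env <- list(tensor = field$tensor, fa = fa, mask = field$mask,
              affine = field$affine, fa_threshold = params$fa_threshold,
              fw = if (!is.null(fw_gate)) fw_gate$f else NULL,
              fw_cutoff = fw_cutoff)

  out <- list()
  chunk <- 4000L
  nseed <- nrow(seeds)
  for (start in seq(1L, nseed, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nseed)
    sd <- seeds[idx, , drop = FALSE]
    smp <- track_sample(sd, env)
    valid <- smp$ok
    if (!any(valid)) next
    sd <- sd[valid, , drop = FALSE]
    dir0 <- smp$dir[valid, , drop = FALSE]
    hp <- track_half(sd, dir0, env, params)
    hm <- track_half(sd, -dir0, env, params)
    for (i in seq_len(nrow(sd))) {
      np <- hp$counts[i]; nm <- hm$counts[i]
      n_total <- np + nm + 1L
      len <- (n_total - 1L) * params$step
      if (len < params$min_length || len > params$max_length) next
      fwd <- if (np > 0) hp$pts[seq_len(np), i, , drop = FALSE] else NULL
      bwd <- if (nm > 0) hm$pts[seq_len(nm), i, , drop = FALSE] else NULL
      sl <- rbind(
        if (!is.null(bwd)) matrix(bwd[rev(seq_len(nm)), 1, ], ncol = 3L),
        sd[i, , drop = FALSE],
        if (!is.null(fwd)) matrix(fwd[, 1, ], ncol = 3L))
      out[[length(out) + 1L]] <- sl
    }
  }
  tractogram(out)
}

# run expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
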