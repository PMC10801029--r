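#' Adaptive free-water correction slider configuration
#'
#' The slider maps a percentage `s` (0 = uncorrected appearance, 100 = fully
#' corrected) onto a free-water cutoff `tau` between `tau_min` and `tau_max`.
#' Points whose free-water value exceeds the cutoff are occluded, so moving
#' the slider up dynamically recovers sub-threshold tract segments.
#' `tau_max < 1` keeps pure CSF (f near 1) occluded even at 100%, which
#' constrains recovery to non-CSF areas; `tau_min` approximates the
#' uncorrected appearance by hiding every edematous point at 0%.
#'
#' @param tau_min cutoff at s = 0 (default 0.30).
#' @param tau_max cutoff at s = 100 (default 0.90).
#' @param min_points shortest surviving fragment, in points (default 5).
#' @return An object of class `slider_config`.
#' @export
slider_config <- function(tau_min = 0.30, tau_max = 0.90, min_points = 5L) {
  stopifnot(tau_min >= 0, tau_min < tau_max, tau_max <= 1, min_points >= 1)
  structure(list(tau_min = tau_min, tau_max = tau_max,
                 min_points = as.integer(min_points)),
            class = "slider_config")
}

#' Encode a tractogram by the free-water map
#'
#' Assigns every streamline point the trilinearly interpolated free-water
#' fraction at its location — the normalized "degree of free water" along
#' each segment. Points outside the map volume are scored 1.0 (maximally
#' occluded), so stray points are never recovered by the slider.
#' Re-parameterizing overwrites any existing channel.
#'
#' @param t a [tractogram()].
#' @param fw a [freewater_map()] sharing the tractogram's world frame.
#' @return A freewater-parameterized [tractogram()].
#' @export
parameterize_tractogram <- function(t, fw) {
  stopifnot(inherits(t, "tractogram"), inherits(fw, "freewater_map"))
  if (!length(t$streamlines)) return(tractogram(list(), NULL))
  npts <- vapply(t$streamlines, nrow, integer(1))
  allpts <- do.call(rbind, t$streamlines)
  vox <- world_to_voxel(allpts, fw$affine)
  vals <- trilinear3d(fw$f, vox)
  vals[is.na(vals)] <- 1.0
  vals <- pmin(1, pmax(0, vals))
  split_idx <- rep(seq_along(npts), npts)
  tractogram(t$streamlines, split(vals, split_idx))
}

#' Map a slider percentage to a free-water cutoff
#'
#' Linear: `tau = tau_min + (s/100) * (tau_max - tau_min)`.
#'
#' @param s slider position in percent, 0..100.
#' @param cfg a [slider_config()].
#' @return The cutoff tau.
#' @export
cutoff_from_slider <- function(s, cfg = slider_config()) {
  if (any(s < 0 | s > 100)) stop("validation error: slider must be in [0, 100]")
  cfg$tau_min + (s / 100) * (cfg$tau_max - cfg$tau_min)
}

#' Threshold a free-water-parameterized tractogram
#'
#' Splits each streamline into maximal runs of consecutive points whose
#' free-water value is at or below the cutoff; runs shorter than
#' `cfg$min_points` are discarded and the surviving runs become output
#' streamlines (scalars carried through, original order preserved). A link
#' between two points survives exactly when both endpoints survive, which is
#' the per-point reading of per-segment encoding. Raising tau recovers
#' previously occluded segments.
#'
#' @param fwt a freewater-parameterized [tractogram()].
#' @param tau cutoff in \[0, 1\] (see [cutoff_from_slider()]).
#' @param cfg a [slider_config()] (supplies `min_points`).
#' @return A [tractogram()] with the surviving fragments.
#' @export
apply_threshold <- function(fwt, tau, cfg = slider_config()) {
  stopifnot(inherits(fwt, "tractogram"))
  if (is.null(fwt$freewater)) {
    stop("validation error: tractogram has no freewater channel; run parameterize_tractogram() first")
  }
  min_pts <- max(2L, cfg$min_points)  # a streamline needs at least 2 points
  sl_out <- list(); fw_out <- list()
  for (i in seq_along(fwt$streamlines)) {
    keep <- fwt$freewater[[i]] <= tau
    if (!any(keep)) next
    runs <- rle(keep)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (j in which(runs$values & runs$lengths >= min_pts)) {
      rng <- starts[j]:ends[j]
      sl_out[[length(sl_out) + 1L]] <- fwt$streamlines[[i]][rng, , drop = FALSE]
      fw_out[[length(fw_out) + 1L]] <- fwt$freewater[[i]][rng]
    }
  }
  tractogram(sl_out, if (length(sl_out)) fw_out else NULL)
}

#' Streamline recovery statistics through a region of interest
#'
#' A streamline traverses the ROI if at least one of its points falls in an
#' ROI voxel (nearest-voxel lookup). Reports the traversal counts for two
#' tractograms (conventionally `a` = uncorrected/baseline, `b` =
#' corrected/recovered), total point counts, and the recovery ratio b/a.
#'
#' @param a,b [tractogram()]s in the ROI's world frame.
#' @param roi a [binary_mask()].
#' @return A list: `n_through_a`, `n_through_b`, `points_a`, `points_b`,
#'   `ratio` (NA with `undefined = TRUE` when `a` has no traversals).
#' @export
recovery_stats <- function(a, b, roi) {
  count_through <- function(t) {
    if (!length(t$streamlines)) return(0L)
    hits <- vapply(t$streamlines, function(pts) {
      vox <- world_to_voxel(pts, roi$affine)
      inr <- nearest_lookup(roi$data, vox)
      any(!is.na(inr) & inr)
    }, logical(1))
    sum(hits)
  }
  na <- count_through(a); nb <- count_through(b)
  pa <- sum(vapply(a$streamlines, nrow, integer(1)))
  pb <- sum(vapply(b$streamlines, nrow, integer(1)))
  undefined <- na == 0L
  list(n_through_a = na, n_through_b = nb,
       points_a = pa, points_b = pb,
       ratio = if (undefined) NA_real_ else nb / na,
       undefined = undefined)
}
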