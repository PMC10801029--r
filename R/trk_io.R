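#' Tractogram: streamlines in world millimetres
#'
#' A streamline is an ordered polyline of at least two 3D points in world
#' (RAS) mm. An optional per-point scalar channel named `"freewater"` holds a
#' normalized free-water value in \[0, 1\] for every point (see
#' [parameterize_tractogram()]).
#'
#' @param streamlines list of numeric n x 3 matrices (n >= 2).
#' @param freewater optional list of numeric vectors, one per streamline,
#'   with one value in \[0, 1\] per point.
#' @return An object of class `tractogram` with elements `streamlines` and
#'   `freewater` (possibly `NULL`).
#' @export
tractogram <- function(streamlines, freewater = NULL) {
  streamlines <- lapply(streamlines, function(s) {
    s <- rbind(s)
    storage.mode(s) <- "double"
    if (ncol(s) != 3L) stop("streamline points must be 3D")
    if (nrow(s) < 2L) stop("validation error: streamline with fewer than 2 points")
    s
  })
  if (!is.null(freewater)) {
    if (length(freewater) != length(streamlines)) {
      stop("validation error: scalar channel has ", length(freewater),
           " entries for ", length(streamlines), " streamlines")
    }
    npts <- vapply(streamlines, nrow, integer(1))
    nsc <- lengths(freewater)
    if (length(npts) && any(nsc != npts)) {
      stop("validation error: per-point scalar length mismatch at streamline(s) ",
           paste(utils::head(which(nsc != npts), 5), collapse = ", "))
    }
    fwv <- unlist(freewater, use.names = FALSE)
    if (length(fwv) && (min(fwv) < 0 || max(fwv) > 1)) {
      stop("validation error: freewater scalars must lie in [0, 1]")
    }
    freewater <- lapply(freewater, as.numeric)
  }
  structure(list(streamlines = streamlines, freewater = freewater),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  np <- sum(vapply(x$streamlines, nrow, integer(1)))
  cat("tractogram:", length(x$streamlines), "streamlines,", np, "points",
      if (!is.null(x$freewater)) "(freewater-parameterized)" else "", "\n")
  invisible(x)
}

#' Number of streamlines in a tractogram
#' @param t a [tractogram()].
#' @return Integer count.
#' @export
n_streamlines <- function(t) length(t$streamlines)

# ---------------------------------------------------------------------------
# TrackVis TRK codec. Binary little-endian, 1000-byte header (version 2).
# TRK stores points in "voxel-mm" with the origin at the *corner* of voxel
# (0,0,0): trk = (index + 0.5) * voxel_size. We convert to world mm through
# the vox_to_ras affine recorded in the version-2 header.
# ---------------------------------------------------------------------------

TRK_HDR_SIZE <- 1000L

pad_raw <- function(s, n) {
  r <- charToRaw(s)
  if (length(r) >= n) r[seq_len(n)] else c(r, raw(n - length(r)))
}

trk_voxel_order <- function(affine) {
  # dominant axis + sign per column, LPI/RAS-style code
  codes <- c("R", "A", "S"); neg <- c("L", "P", "I")
  out <- character(3)
  for (j in 1:3) {
    col <- affine[1:3, j]
    ax <- which.max(abs(col))
    out[j] <- if (col[ax] >= 0) codes[ax] else neg[ax]
  }
  paste(out, collapse = "")
}

#' Write a tractogram as TrackVis TRK
#'
#' Writes a version-2 TRK file. When the tractogram carries a `freewater`
#' channel it is stored as one per-point scalar named `"freewater"`. World-mm
#' points are converted to TRK's corner-origin voxel-mm convention using the
#' reference volume's affine and voxel sizes.
#'
#' @param t a [tractogram()].
#' @param path destination `.trk` path.
#' @param reference an [image_volume()] or [binary_mask()] supplying the grid
#'   dimensions and affine.
#' @return The path, invisibly.
#' @export
write_tractogram <- function(t, path, reference) {
  stopifnot(inherits(t, "tractogram"))
  affine <- reference$affine
  dims <- dim(reference$data)[1:3]
  vsz <- sqrt(colSums(affine[1:3, 1:3]^2))
  n_scalars <- if (is.null(t$freewater)) 0L else 1L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(pad_raw("TRACK", 6L), con)
  writeBin(as.integer(dims), con, size = 2L, endian = "little")
  writeBin(as.numeric(vsz), con, size = 4L, endian = "little")
  writeBin(numeric(3), con, size = 4L, endian = "little")          # origin
  writeBin(n_scalars, con, size = 2L, endian = "little")
  scal <- raw(200L)
  if (n_scalars == 1L) scal[1:20] <- pad_raw("freewater", 20L)
  writeBin(scal, con)
  writeBin(0L, con, size = 2L, endian = "little")                  # n_properties
  writeBin(raw(200L), con)                                         # property names
  writeBin(as.numeric(t(affine)), con, size = 4L, endian = "little")  # vox_to_ras, row-major
  writeBin(raw(444L), con)                                         # reserved
  writeBin(pad_raw(trk_voxel_order(affine), 4L), con)
  writeBin(raw(4L), con)                                           # pad2
  writeBin(numeric(6), con, size = 4L, endian = "little")          # image_orientation_patient
  writeBin(raw(2L), con)                                           # pad1
  writeBin(raw(6L), con)                                           # invert/swap flags
  writeBin(length(t$streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")                  # version
  writeBin(TRK_HDR_SIZE, con, size = 4L, endian = "little")

  for (i in seq_along(t$streamlines)) {
    pts <- t$streamlines[[i]]
    vox <- world_to_voxel(pts, affine)
    trkmm <- sweep(vox + 0.5, 2L, vsz, `*`)
    if (n_scalars == 1L) trkmm <- cbind(trkmm, t$freewater[[i]])
    writeBin(nrow(pts), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(trkmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a TrackVis TRK tractogram
#'
#' Points are converted from TRK's corner-origin voxel-mm convention to world
#' mm via the header's vox_to_ras affine (version 2). A per-point scalar
#' channel named `"freewater"` is restored when present; other scalar
#' channels are ignored with a warning.
#'
#' @param path a `.trk` file.
#' @return A [tractogram()]. The reference affine and grid dimensions are
#'   attached as attributes `affine` and `ref_dim`.
#' @export
read_tractogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(rawToChar(magic[1:5]), "TRACK")) {
    stop("format error: not a TRK file (bad magic)")
  }
  dims <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  vsz <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")        # origin
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  scal_names <- readBin(con, "raw", 200L)
  n_props <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  aff <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
                4L, 4L, byrow = TRUE)
  readBin(con, "raw", 444L)
  readBin(con, "raw", 4L); readBin(con, "raw", 4L)
  readBin(con, "numeric", 6L, size = 4L, endian = "little")
  readBin(con, "raw", 2L); readBin(con, "raw", 6L)
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(hdr_size, TRK_HDR_SIZE)) {
    stop("format error: corrupt TRK header (hdr_size = ", hdr_size, ")")
  }
  if (version < 2L || max(abs(aff)) == 0) {
    # pre-v2 files carry no affine; fall back to scaled identity
    aff <- diag(c(vsz, 1))
  }
  if (n_scalars > 0L) {
    nb <- scal_names[1:20]
    nm <- rawToChar(nb[cumsum(nb == as.raw(0)) == 0])  # up to first NUL
    has_fw <- identical(nm, "freewater")
    if (!has_fw || n_scalars > 1L) {
      warning("ignoring unrecognized TRK scalar channel(s)")
    }
  } else has_fw <- FALSE

  streamlines <- list(); scalars <- list(); i <- 0L
  repeat {
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(n) == 0L) break
    i <- i + 1L
    vals <- readBin(con, "numeric", n * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (length(vals) < n * (3L + n_scalars)) stop("format error: truncated TRK body")
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)
    if (n_props > 0L) readBin(con, "numeric", n_props, size = 4L, endian = "little")
    vox <- sweep(m[, 1:3, drop = FALSE], 2L, vsz, `/`) - 0.5
    streamlines[[i]] <- voxel_to_world(vox, aff)
    if (has_fw) scalars[[i]] <- pmin(1, pmax(0, m[, 4L]))
  }
  if (n_count > 0L && i != n_count) {
    warning("TRK header declared ", n_count, " streamlines but ", i, " were read")
  }
  out <- tractogram(streamlines, if (has_fw) scalars else NULL)
  attr(out, "affine") <- aff
  attr(out, "ref_dim") <- dims
  out
}
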