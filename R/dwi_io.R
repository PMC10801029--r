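#' Gradient table for a diffusion-weighted acquisition
#'
#' Bundles per-volume b-values (s/mm^2) and unit gradient directions. Volumes
#' with `bval <= b0_threshold` are treated as non-diffusion-weighted (b0) and
#' may carry zero gradient vectors. Directions of diffusion-weighted volumes
#' are renormalized to unit length when their norm deviates from 1 by less
#' than 1e-3; a larger deviation is treated as a corrupt file.
#'
#' @param bvals numeric vector of b-values in s/mm^2.
#' @param bvecs numeric N x 3 matrix of gradient directions (one row per
#'   volume, FSL convention).
#' @param b0_threshold b-values at or below this are considered b0
#'   (default 50 s/mm^2, typical scanner tolerance).
#' @return An object of class `gradient_table` with elements `bvals`,
#'   `bvecs` (N x 3, unit rows for b > threshold), `b0s` (logical) and
#'   `b0_threshold`.
#' @export
gradient_table <- function(bvals, bvecs, b0_threshold = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  storage.mode(bvecs) <- "double"
  if (ncol(bvecs) != 3L) stop("bvecs must have 3 components per direction")
  if (length(bvals) != nrow(bvecs)) {
    stop("format error: ", length(bvals), " b-values but ",
         nrow(bvecs), " gradient directions")
  }
  b0s <- bvals <= b0_threshold
  if (!any(b0s)) stop("validation error: no b0 volume present")
  nrm <- sqrt(rowSums(bvecs^2))
  dwi <- !b0s
  bad <- dwi & (nrm == 0 | abs(nrm - 1) >= 1e-3)
  if (any(bad)) {
    stop("format error: non-unit gradient direction(s) at volume(s) ",
         paste(which(bad), collapse = ", "))
  }
  renorm <- dwi & abs(nrm - 1) > 1e-9
  bvecs[renorm, ] <- bvecs[renorm, , drop = FALSE] / nrm[renorm]
  structure(list(bvals = bvals, bvecs = bvecs, b0s = b0s,
                 b0_threshold = b0_threshold),
            class = "gradient_table")
}

#' Read an FSL-dialect bval/bvec pair
#'
#' Whitespace-separated text files. The bvec file may be laid out as 3 rows
#' of N entries (FSL convention) or N rows of 3; orientation is auto-detected
#' from the shape, and an ambiguous 3 x 3 table is resolved as
#' rows-are-components (FSL).
#'
#' @param bval_path,bvec_path paths to the two text files.
#' @param b0_threshold see [gradient_table()].
#' @return A validated [gradient_table()].
#' @export
load_gradient_table <- function(bval_path, bvec_path, b0_threshold = 50) {
  if (!file.exists(bval_path)) stop("bval file not found: ", bval_path)
  if (!file.exists(bvec_path)) stop("bvec file not found: ", bvec_path)
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  lines <- readLines(bvec_path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric)
  nc <- lengths(rows)
  if (length(unique(nc)) != 1L) stop("format error: ragged bvec file")
  m <- do.call(rbind, rows)
  if (nrow(m) == 3L) {
    # 3 x N (FSL rows-are-components); covers the ambiguous 3 x 3 case too
    bvecs <- t(m)
  } else if (ncol(m) == 3L) {
    bvecs <- m
  } else {
    stop("format error: bvec file is neither 3 x N nor N x 3")
  }
  gradient_table(bvals, bvecs, b0_threshold = b0_threshold)
}

#' 3D/4D image volume with a voxel-to-world affine
#'
#' The affine maps 0-based voxel indices to world (RAS) millimetres, NIfTI
#' style. This is the single internal spatial frame; all tractography
#' coordinates are world mm.
#'
#' @param data 3D or 4D numeric array.
#' @param affine 4 x 4 invertible matrix.
#' @return An object of class `image_volume` with elements `data`, `affine`.
#' @export
image_volume <- function(data, affine = diag(4)) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop("data must be a 3D or 4D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps) {
    stop("affine must be an invertible 4 x 4 matrix")
  }
  structure(list(data = data, affine = affine), class = "image_volume")
}

#' Binary mask on an image grid
#'
#' @param data 3D array; nonzero/TRUE marks voxels inside the mask.
#' @param affine 4 x 4 voxel-to-world transform (must match the volume the
#'   mask is used with).
#' @return An object of class `binary_mask` with logical `data` and `affine`.
#' @export
binary_mask <- function(data, affine = diag(4)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("mask must be a 3D array")
  mode(data) <- "logical"
  data[is.na(data)] <- FALSE
  affine <- as.matrix(affine)
  structure(list(data = data, affine = affine), class = "binary_mask")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat("gradient_table:", length(x$bvals), "volumes,", sum(x$b0s), "b0,",
      sum(!x$b0s), "diffusion-weighted (b =",
      paste(unique(round(x$bvals[!x$b0s])), collapse = ", "), "s/mm^2)\n")
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-4) {
  all(dim(a$data)[1:3] == dim(b$data)[1:3]) &&
    max(abs(a$affine - b$affine)) < tol
}

#' Check that a 4D volume pairs with a gradient table
#'
#' @param vol an [image_volume()] with a 4th dimension.
#' @param gtab a [gradient_table()].
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
check_pairing <- function(vol, gtab) {
  d <- dim(vol$data)
  if (length(d) != 4L) stop("pairing error: volume is not 4D")
  if (d[4] != length(gtab$bvals)) {
    stop("pairing error: volume has ", d[4], " frames but gradient table has ",
         length(gtab$bvals), " entries")
  }
  invisible(TRUE)
}

#' Load a NIfTI-1 volume
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return An [image_volume()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("format error: not a readable NIfTI file: ",
                                           conditionMessage(e)))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  image_volume(as.array(img), aff)
}

#' Save a volume as NIfTI-1
#'
#' @param vol an [image_volume()].
#' @param path destination path (`.nii` or `.nii.gz`).
#' @param datatype on-disk datatype; `"float"` (32-bit, default) or
#'   `"double"`.
#' @return The path, invisibly.
#' @export
save_volume <- function(vol, path, datatype = "float") {
  stopifnot(inherits(vol, "image_volume"))
  arr <- vol$data
  attr(arr, "pixdim") <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Save a binary mask as NIfTI-1 (uint8)
#'
#' @param mask a [binary_mask()].
#' @param path destination path.
#' @return The path, invisibly.
#' @export
save_mask <- function(mask, path) {
  arr <- array(as.numeric(mask$data), dim = dim(mask$data))
  save_volume(image_volume(arr, mask$affine), path, datatype = "uint8")
}

#' Load a NIfTI volume as a binary mask
#'
#' @param path NIfTI file; nonzero voxels are inside the mask.
#' @return A [binary_mask()].
#' @export
load_mask <- function(path) {
  v <- load_volume(path)
  if (length(dim(v$data)) != 3L) stop("mask must be 3D")
  binary_mask(v$data != 0, v$affine)
}

# world <-> voxel coordinate helpers (points as n x 3 matrices)
world_to_voxel <- function(pts, affine) {
  pts <- rbind(pts)  # tolerate a single point as a vector
  ia <- solve(affine)
  t(ia[1:3, 1:3] %*% t(pts) + ia[1:3, 4])
}

voxel_to_world <- function(idx, affine) {
  idx <- rbind(idx)
  t(affine[1:3, 1:3] %*% t(idx) + affine[1:3, 4])
}
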