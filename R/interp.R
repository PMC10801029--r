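# Trilinear interpolation on 3D grids, vectorized over query points.
#
# Voxel coordinates are continuous and 0-based (voxel centers at integers).
# Queries beyond half a voxel outside the grid are flagged out-of-bounds;
# inside that margin the border value is extended (clamped corners).

trilinear_prepare <- function(dims, vox) {
  vox <- rbind(vox)
  oob <- vox[, 1] < -0.5 | vox[, 1] > dims[1] - 0.5 |
         vox[, 2] < -0.5 | vox[, 2] > dims[2] - 0.5 |
         vox[, 3] < -0.5 | vox[, 3] > dims[3] - 0.5 |
         rowSums(is.na(vox)) > 0
  i0 <- floor(vox)
  fr <- vox - i0
  dmax <- matrix(dims - 1, nrow(vox), 3, byrow = TRUE)
  lo <- pmin(pmax(i0, 0), dmax)
  hi <- pmin(lo + 1, dmax)
  # clamped fraction: where i0 < 0 the lower corner moved up, weight goes to it
  fr[i0 < 0] <- 0
  fr[i0 > matrix(dims - 2, nrow(vox), 3, byrow = TRUE)] <- 1
  fr[fr < 0] <- 0; fr[fr > 1] <- 1
  list(lo = lo, hi = hi, fr = fr, oob = oob, n = nrow(vox), dims = dims)
}

trilinear_apply <- function(arr, prep) {
  lo <- prep$lo; hi <- prep$hi; fr <- prep$fr; dims <- prep$dims
  nx <- dims[1]; nxy <- dims[1] * dims[2]
  idx <- function(ix, iy, iz) 1 + ix + iy * nx + iz * nxy
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  v000 <- arr[idx(lo[, 1], lo[, 2], lo[, 3])]
  v100 <- arr[idx(hi[, 1], lo[, 2], lo[, 3])]
  v010 <- arr[idx(lo[, 1], hi[, 2], lo[, 3])]
  v110 <- arr[idx(hi[, 1], hi[, 2], lo[, 3])]
  v001 <- arr[idx(lo[, 1], lo[, 2], hi[, 3])]
  v101 <- arr[idx(hi[, 1], lo[, 2], hi[, 3])]
  v011 <- arr[idx(lo[, 1], hi[, 2], hi[, 3])]
  v111 <- arr[idx(hi[, 1], hi[, 2], hi[, 3])]
  out <- (1 - fz) * ((1 - fy) * ((1 - fx) * v000 + fx * v100) +
                       fy * ((1 - fx) * v010 + fx * v110)) +
    fz * ((1 - fy) * ((1 - fx) * v001 + fx * v101) +
            fy * ((1 - fx) * v011 + fx * v111))
  out[prep$oob] <- NA_real_
  out
}

# interpolate a single 3D array at continuous voxel coordinates
trilinear3d <- function(arr, vox) {
  prep <- trilinear_prepare(dim(arr), vox)
  trilinear_apply(arr, prep)
}

# interpolate each channel of a 4D array (X,Y,Z,C) at the same points
trilinear4d <- function(arr4, vox) {
  dims <- dim(arr4)[1:3]
  C <- dim(arr4)[4]
  prep <- trilinear_prepare(dims, vox)
  out <- matrix(NA_real_, prep$n, C)
  nvol <- prod(dims)
  flat <- matrix(arr4, nrow = nvol, ncol = C)
  for (k in seq_len(C)) out[, k] <- trilinear_apply(flat[, k], prep)
  out
}

# nearest-voxel lookup (0-based rounding); FALSE outside the grid
nearest_lookup <- function(arr, vox) {
  vox <- rbind(vox)
  dims <- dim(arr)
  i <- round(vox)
  ok <- i[, 1] >= 0 & i[, 1] <= dims[1] - 1 &
        i[, 2] >= 0 & i[, 2] <= dims[2] - 1 &
        i[, 3] >= 0 & i[, 3] <= dims[3] - 1 &
        rowSums(is.na(i)) == 0
  out <- rep(NA, nrow(vox))
  if (any(ok)) {
    out[ok] <- arr[cbind(i[ok, 1, drop = FALSE] + 1,
                         i[ok, 2, drop = FALSE] + 1,
                         i[ok, 3, drop = FALSE] + 1)]
  }
  out
}
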