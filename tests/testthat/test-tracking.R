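# A minimal straight-bundle phantom for local tracking checks: tube along x
# with FA 0.87 inside, isotropic background.
straight_bundle_field <- function(dims = c(30, 11, 11), radius = 2,
                                  evals = c(1.7e-3, 0.3e-3, 0.3e-3),
                                  voxel_mm = 2) {
  affine <- diag(c(rep(voxel_mm, 3), 1))
  idx <- arrayInd(seq_len(prod(dims)), dims) - 1
  cy <- (dims[2] - 1) / 2; cz <- (dims[3] - 1) / 2
  inside <- sqrt((idx[, 2] - cy)^2 + (idx[, 3] - cz)^2) <= radius
  tensor <- array(0, c(dims, 6))
  bg <- fwtract:::sym_to_6(diag(rep(0.8e-3, 3)))
  tube <- fwtract:::sym_to_6(diag(evals))
  for (k in 1:6) {
    comp <- array(bg[k], dims)
    comp[inside] <- tube[k]
    tensor[, , , k] <- comp
  }
  tf <- tensor_field(tensor, array(1000, dims), array(TRUE, dims), affine)
  list(tf = tf, maps = tensor_metrics(tf),
       bundle = binary_mask(array(inside, dims), affine))
}

test_that("seeding places jittered points inside mask voxels, deterministically", {
  dims <- c(5, 5, 5)
  m <- array(FALSE, dims); m[2:3, 2, 2] <- TRUE; m[1, 5, 4] <- TRUE
  m[5, 1, 1] <- TRUE; m[4, 4, 4] <- TRUE
  m[2, 4, 1] <- TRUE; m[3, 3, 3] <- TRUE; m[1, 1, 5] <- TRUE
  m[5, 5, 5] <- TRUE; m[4, 2, 3] <- TRUE   # 10 voxels
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-5, -5, -5)
  mask <- binary_mask(m, aff)

  p1 <- tracking_params(seed = 3)
  s1 <- seeds_from_mask(mask, p1)
  expect_equal(nrow(s1), 10L)
  vox <- fwtract:::world_to_voxel(s1, aff)
  ctr <- which(m, arr.ind = TRUE) - 1
  expect_true(all(abs(vox - ctr[rep(seq_len(10), each = 1), ]) <= 0.5))

  expect_identical(seeds_from_mask(mask, p1), s1)  # same seed, same points

  p2 <- tracking_params(seed = 3, seeds_per_voxel = 2)
  expect_equal(nrow(seeds_from_mask(mask, p2)), 20L)

  expect_error(seeds_from_mask(binary_mask(array(FALSE, dims), aff), p1),
               "empty")
})

test_that("a straight bundle is tracked end to end and stays in the tube", {
  sb <- straight_bundle_field()
  params <- tracking_params(seed = 1, min_length = 20)
  seed <- matrix(c(29, 10, 10), 1, 3)   # world mm, tube centre
  t <- track(sb$tf, sb$maps, seed, params)
  expect_equal(n_streamlines(t), 1L)
  pts <- t$streamlines[[1]]
  # endpoints within one step of the two x-faces (x in [0, 58] world mm)
  expect_lt(min(pts[, 1]), 0 + params$step + 1)
  expect_gt(max(pts[, 1]), 58 - params$step - 1)
  # all points inside the tube (radius 2 voxels = 4 mm around y=z=10)
  expect_true(all(sqrt((pts[, 2] - 10)^2 + (pts[, 3] - 10)^2) <= 4 + params$step))
})

test_that("seeds in isotropic tissue emit no streamline", {
  sb <- straight_bundle_field()
  t <- track(sb$tf, sb$maps, matrix(c(29, 2, 2), 1, 3), tracking_params())
  expect_equal(n_streamlines(t), 0L)
})

test_that("a 90-degree elbow terminates tracking at the corner", {
  cfg <- phantom_config(
    shape = c(30L, 30L, 11L), voxel_mm = 2,
    bundle = list(type = "elbow", axis = "x", center = c(0, 5), radius = 2,
                  evals = c(1.7e-3, 0.3e-3, 0.3e-3), corner = c(20, 8)),
    lesion = list(center = c(5, 25, 5), radius = 2, f = 0.9, md = 1.0e-3),
    edema = list(outer_radius = 4, f_max = 0.7, f_min = 0.2),
    background = list(md = 0.8e-3, f = 0.05),
    csf = list(axis = "y", thickness = 0),
    snr = 0, seed = 1)
  ph <- generate_phantom(cfg)
  tf <- fit_tensor(ph$dwi, ph$gtab, ph$truth$brain)
  maps <- tensor_metrics(tf)
  # seed on the x-arm, away from the corner at voxel (20, 8, 5)
  seed <- matrix(c(10, 8, 5) * 2, 1, 3)
  t <- track(tf, maps, seed, tracking_params(seed = 2, max_angle = 45))
  expect_equal(n_streamlines(t), 1L)
  pts <- t$streamlines[[1]]
  # the streamline must not turn the corner onto the y-arm: it may run to the
  # end of the x-arm's rounded cap (corner + tube radius + interpolation
  # margin) but no further, and never up the y-arm
  expect_true(all(pts[, 1] <= (20 + 2 + 1) * 2 + 1))
  expect_true(all(pts[, 2] <= (8 + 2 + 1) * 2 + 1))
})

test_that("tracking is deterministic and indifferent to seed order", {
  sb <- straight_bundle_field()
  params <- tracking_params(seed = 5)
  seeds <- seeds_from_mask(sb$bundle, params)
  t1 <- track(sb$tf, sb$maps, seeds, params)
  t2 <- track(sb$tf, sb$maps, seeds, params)
  expect_identical(t1$streamlines, t2$streamlines)

  rev_idx <- rev(seq_len(nrow(seeds)))
  t3 <- track(sb$tf, sb$maps, seeds[rev_idx, ], params)
  expect_identical(t3$streamlines, rev(t1$streamlines))
})

test_that("emitted points stay within the mask dilated by one step", {
  bm <- standard_benchmark()
  pts <- do.call(rbind, bm$t_unc$streamlines)
  vox <- fwtract:::world_to_voxel(pts, bm$ph$dwi$affine)
  inmask <- fwtract:::nearest_lookup(bm$ph$truth$brain$data, vox)
  expect_true(all(!is.na(inmask) & inmask))
})

test_that("the free-water gate stops streamlines in water-dominated voxels", {
  sb <- straight_bundle_field()
  # water wall across the tube: f > 0.9 for x-voxels 14..16
  fw <- array(0, dim(sb$tf$S0)); fw[15:17, , ] <- 0.95
  gate <- freewater_map(fw, array(TRUE, dim(fw)), sb$tf$affine)
  params <- tracking_params(seed = 1, min_length = 10)
  seed <- matrix(c(10, 10, 10), 1, 3)
  t <- track(sb$tf, sb$maps, seed, params, fw_gate = gate)
  expect_equal(n_streamlines(t), 1L)
  # the wall starts at voxel 14 (world 28 mm); nothing tracked beyond it
  expect_true(all(t$streamlines[[1]][, 1] < 28))
})
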