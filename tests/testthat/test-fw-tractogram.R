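test_that("parameterization samples the free-water map per point", {
  dims <- c(10, 10, 10)
  aff <- diag(c(2, 2, 2, 1))

  # constant field: every point gets the constant
  fw_const <- freewater_map(array(0.5, dims), array(TRUE, dims), aff)
  t <- tractogram(list(cbind(seq(2, 10, 2), 6, 6)))
  fwt <- parameterize_tractogram(t, fw_const)
  expect_equal(fwt$freewater[[1]], rep(0.5, 5))

  # linear interpolation midway between voxel centres 0 and 1 along x
  f <- array(0, dims); f[2, , ] <- 1   # voxel x-index 1 (0-based)
  fw_lin <- freewater_map(f, array(TRUE, dims), aff)
  mid <- tractogram(list(rbind(c(1, 6, 6), c(1, 8, 8))))  # world x=1 = voxel 0.5
  expect_equal(parameterize_tractogram(mid, fw_lin)$freewater[[1]],
               c(0.5, 0.5))

  # points far outside the volume are maximally occluded
  out <- tractogram(list(rbind(c(-30, 6, 6), c(5, 6, 6))))
  expect_equal(parameterize_tractogram(out, fw_const)$freewater[[1]][1], 1.0)

  # idempotent: re-parameterizing overwrites
  twice <- parameterize_tractogram(parameterize_tractogram(t, fw_lin), fw_const)
  expect_equal(twice$freewater[[1]], rep(0.5, 5))

  # empty tractogram is valid
  expect_equal(n_streamlines(parameterize_tractogram(tractogram(list()),
                                                     fw_const)), 0L)
})

test_that("the slider maps linearly onto the cutoff", {
  cfg <- slider_config()
  expect_equal(cutoff_from_slider(0, cfg), 0.30)
  expect_equal(cutoff_from_slider(100, cfg), 0.90)
  expect_equal(cutoff_from_slider(50, cfg), 0.60)
  expect_error(cutoff_from_slider(101, cfg), "validation error")
  expect_error(cutoff_from_slider(-1, cfg), "validation error")
  expect_error(slider_config(tau_min = 0.9, tau_max = 0.3), ".")
})

test_that("thresholding splits streamlines into maximal sub-cutoff runs", {
  pts <- cbind(1:10, 0, 0)
  fw <- c(rep(0.2, 4), rep(0.95, 2), rep(0.2, 4))
  fwt <- tractogram(list(pts), list(fw))

  out <- apply_threshold(fwt, 0.9, slider_config(min_points = 2))
  expect_equal(n_streamlines(out), 2L)
  expect_equal(out$streamlines[[1]], pts[1:4, ])
  expect_equal(out$streamlines[[2]], pts[7:10, ])
  expect_equal(out$freewater[[2]], rep(0.2, 4))

  # min-fragment pruning drops the short middle run
  fw2 <- c(0.2, 0.2, 0.95, 0.2, 0.2, 0.2, 0.95, 0.2, 0.2, 0.2)
  out2 <- apply_threshold(tractogram(list(pts), list(fw2)), 0.9,
                          slider_config(min_points = 3))
  expect_equal(n_streamlines(out2), 2L)
  expect_true(all(vapply(out2$streamlines, nrow, integer(1)) >= 3))

  # all-clear input is returned unchanged; all-occluded input vanishes
  clear <- tractogram(list(pts), list(rep(0, 10)))
  expect_equal(apply_threshold(clear, 0.9)$streamlines[[1]], pts)
  occl <- tractogram(list(pts), list(rep(1, 10)))
  expect_equal(n_streamlines(apply_threshold(occl, 0.9)), 0L)

  # requires the scalar channel
  expect_error(apply_threshold(tractogram(list(pts)), 0.5), "freewater channel")
})

test_that("thresholding is idempotent and monotone in the cutoff", {
  set.seed(21)
  sls <- lapply(1:15, function(i) {
    n <- sample(5:40, 1)
    cbind(cumsum(runif(n)), runif(n, 0, 5), runif(n, 0, 5))
  })
  fws <- lapply(sls, function(s) round(runif(nrow(s)), 3))
  fwt <- tractogram(sls, fws)
  cfg1 <- slider_config(min_points = 1)

  counts <- vapply(seq(0, 100, 10), function(s) {
    out <- apply_threshold(fwt, cutoff_from_slider(s, cfg1), cfg1)
    sum(vapply(out$streamlines, nrow, integer(1)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))

  for (tau in c(0.3, 0.6, 0.9)) {
    once <- apply_threshold(fwt, tau, cfg1)
    twice <- apply_threshold(once, tau, cfg1)
    expect_identical(twice$streamlines, once$streamlines)
    expect_identical(twice$freewater, once$freewater)
  }

  # tau >= max scalar: identity; tau < min scalar: empty
  hi <- apply_threshold(fwt, 1.0, cfg1)
  expect_identical(hi$streamlines, fwt$streamlines)
  expect_equal(n_streamlines(apply_threshold(fwt, -0.1 + 0, cfg1)), 0L)
})

test_that("recovery statistics count ROI-traversing streamlines", {
  dims <- c(10, 10, 10)
  roi_arr <- array(FALSE, dims); roi_arr[5:6, 5:6, 5:6] <- TRUE
  roi <- binary_mask(roi_arr)   # identity affine, world = voxel

  through <- function(k) cbind(seq(4, 6, 0.5) + 0.01 * k, 5, 5)  # passes the ROI
  outside <- function(k) cbind(seq(0, 2, 0.5) + 0.01 * k, 1, 1)
  a <- tractogram(c(lapply(1:5, through), lapply(1:3, outside)))
  b <- tractogram(c(lapply(1:10, through), lapply(1:2, outside)))

  st <- recovery_stats(a, b, roi)
  expect_equal(st$n_through_a, 5L)
  expect_equal(st$n_through_b, 10L)
  expect_equal(st$ratio, 2.0)
  expect_false(st$undefined)
  expect_equal(st$points_a, 8 * 5)

  ident <- recovery_stats(a, a, roi)
  expect_equal(ident$ratio, 1.0)

  empty_roi <- binary_mask(array(FALSE, dims))
  st0 <- recovery_stats(a, b, empty_roi)
  expect_true(st0$undefined)
  expect_true(is.na(st0$ratio))
})

test_that("slider recovery on the edema benchmark grows with s and is monotone", {
  bm <- standard_benchmark()
  cfg <- slider_config()
  s0 <- apply_threshold(bm$fwt, cutoff_from_slider(0, cfg), cfg)
  s100 <- apply_threshold(bm$fwt, cutoff_from_slider(100, cfg), cfg)
  st <- recovery_stats(s0, s100, bm$ph$truth$edema)
  expect_gt(st$n_through_b, st$n_through_a)

  cfg1 <- slider_config(min_points = 1)
  counts <- vapply(seq(0, 100, 10), function(s) {
    out <- apply_threshold(bm$fwt, cutoff_from_slider(s, cfg1), cfg1)
    sum(vapply(out$streamlines, nrow, integer(1)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
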