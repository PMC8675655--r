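test_that("noise-free clones are recovered almost exactly", {
  d <- simulate_disc(small_cfg(seed = 2, noise_sd = 0))
  patches <- segment_patches(d$stack, d$truth$pouch_mask, min_volume = 30)
  truth <- d$truth$patch_mask$labels > 0L
  pred <- patches$labels > 0L
  jaccard <- sum(truth & pred) / sum(truth | pred)
  expect_gte(jaccard, 0.95)
  expect_identical(dim(patches$labels), dim(truth))
  expect_identical(patches$voxel_size, d$stack$voxel_size)
})

test_that("uniform clone channel segments to nothing", {
  a <- array(0, c(4L, 30L, 30L, 1L)); a[] <- 55
  st <- image_stack(a, c(1, 1, 1), c(gfp = 1L))
  roi <- label_mask(array(TRUE, dim(a)[1:3]), c(1, 1, 1))
  patches <- segment_patches(st, roi, min_volume = 5)
  expect_equal(max(patches$labels), 0L)
})

test_that("well-separated clones get separate contiguous labels", {
  a <- array(20, c(6L, 60L, 60L))
  a[2:5, 10:20, 10:20] <- 120
  a[2:5, 40:50, 40:50] <- 120
  st <- image_stack(array(a, c(dim(a), 1L)), c(1, 0.8, 0.8), c(gfp = 1L))
  roi <- label_mask(array(TRUE, dim(a)), c(1, 0.8, 0.8))
  patches <- segment_patches(st, roi, min_volume = 10, smooth_sigma = 1)
  labs <- sort(unique(as.vector(patches$labels)))
  expect_identical(labs, c(0L, 1L, 2L))
})

test_that("segmentation is invariant to a constant intensity offset", {
  d <- simulate_disc(small_cfg(seed = 6))
  p1 <- segment_patches(d$stack, d$truth$pouch_mask, min_volume = 30)
  st2 <- d$stack
  st2$data <- st2$data + 137
  p2 <- segment_patches(st2, d$truth$pouch_mask, min_volume = 30)
  expect_identical(p1$labels, p2$labels)
  d1 <- segment_death(d$stack, d$truth$pouch_mask)
  d2 <- segment_death(st2, d$truth$pouch_mask)
  expect_identical(d1$labels, d2$labels)
})

test_that("death segmentation respects the ROI and recovers volume", {
  d <- simulate_disc(small_cfg(seed = 4, noise_sd = 0))
  roi <- d$truth$pouch_mask
  death <- segment_death(d$stack, roi)
  truth_vol <- sum(d$truth$death_mask$labels > 0L)
  expect_lt(abs(sum(death$labels > 0L) - truth_vol) / truth_vol, 0.05)
  expect_true(all(death$labels[roi$labels == 0L] == 0L))
  # empty channel -> empty mask
  blank <- d$stack
  blank$data[, , , blank$channels[["death"]]] <- 20
  expect_equal(max(segment_death(blank, roi)$labels), 0L)
  # half-ROI restriction keeps the complement empty
  half <- roi$labels
  nx <- dim(half)[3]
  half[, , seq_len(floor(nx / 2))] <- 0L
  death_half <- segment_death(d$stack, label_mask(half, roi$voxel_size))
  expect_true(all(death_half$labels[, , seq_len(floor(nx / 2))] == 0L))
})

test_that("speckle counts recover the ground truth and respect thresholds", {
  cfg <- small_cfg(seed = 11, speckle_density = 1.2, noise_sd = 5,
                   channels = c("gfp", "stain2"))
  d <- simulate_disc(cfg)
  k <- nrow(d$truth$speckle_coords)
  expect_gt(k, 10)
  spots <- detect_speckles(d$stack, "stain2", c(0.6, 1.6), threshold = 40)
  expect_lte(abs(nrow(spots) - k), 2)
  # blank image
  blank <- d$stack
  blank$data[, , , blank$channels[["stain2"]]] <- 20
  expect_equal(nrow(detect_speckles(blank, "stain2", c(0.6, 1.6),
                                    threshold = 40)), 0)
  # count is non-increasing in the threshold, and zero at infinity
  lower <- detect_speckles(d$stack, "stain2", c(0.6, 1.6), threshold = 10)
  expect_gte(nrow(lower), nrow(spots))
  expect_equal(nrow(detect_speckles(d$stack, "stain2", c(0.6, 1.6),
                                    threshold = Inf)), 0)
  # detected positions sit close to true speckles
  tc <- d$truth$speckle_coords
  nn <- vapply(seq_len(nrow(spots)), function(i) {
    min(sqrt((tc[, 1] - spots$z[i])^2 + (tc[, 2] - spots$y[i])^2 +
               (tc[, 3] - spots$x[i])^2))
  }, numeric(1))
  expect_lt(stats::median(nn), 1.5)
})

test_that("cell diameter is estimated within 15% and falls back gracefully", {
  cfg <- small_cfg(seed = 3, channels = c("nuclei", "gfp"),
                   shape = c(14L, 90L, 90L), voxel_size = c(1, 0.6, 0.6))
  d <- simulate_disc(cfg)
  est <- estimate_cell_diameter(d$stack)
  expect_lt(abs(est - 4) / 4, 0.15)
  # resolution change leaves the physical estimate stable
  cfg2 <- small_cfg(seed = 3, channels = c("nuclei", "gfp"),
                    shape = c(14L, 135L, 135L), voxel_size = c(1, 0.4, 0.4))
  est2 <- estimate_cell_diameter(simulate_disc(cfg2)$stack)
  expect_lt(abs(est2 - est) / est, 0.2)
  # no nuclei -> warning and configured default
  blank <- d$stack
  blank$data[, , , blank$channels[["nuclei"]]] <- 20
  expect_warning(fb <- estimate_cell_diameter(blank, default = 4.5),
                 "default")
  expect_equal(fb, 4.5)
})

test_that("missing channels and empty ROIs are rejected", {
  a <- array(1, c(2L, 5L, 5L, 1L))
  st <- image_stack(a, c(1, 1, 1), c(stain = 1L))
  roi <- label_mask(array(TRUE, c(2L, 5L, 5L)), c(1, 1, 1))
  expect_error(segment_patches(st, roi), "no 'gfp' channel")
  expect_error(segment_death(st, roi), "no 'death' channel")
  st2 <- image_stack(a, c(1, 1, 1), c(gfp = 1L))
  empty <- label_mask(array(FALSE, c(2L, 5L, 5L)), c(1, 1, 1))
  expect_error(segment_patches(st2, empty), "empty")
})
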