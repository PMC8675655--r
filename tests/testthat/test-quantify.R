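make_stack <- function(values, vz = c(1, 1, 1), role = "stain") {
  image_stack(array(values, c(dim(values), 1L)), vz,
              stats::setNames(1L, role))
}

test_that("pouch coverage is a plain voxel-count percentage", {
  vz <- c(1, 1, 1)
  pouch <- label_mask(array(1L, c(2L, 10L, 10L)), vz)
  expect_equal(pouch_coverage(pouch, pouch), 100)
  none <- label_mask(array(0L, c(2L, 10L, 10L)), vz)
  expect_equal(pouch_coverage(none, pouch), 0)
  expect_error(pouch_coverage(pouch, none), "empty")
  half <- label_mask(array(rep(c(1L, 0L), each = 100), c(2L, 10L, 10L)), vz)
  expect_equal(pouch_coverage(half, pouch), 50)
})

test_that("death density handles full, empty and flagged territories", {
  terr <- array(0L, c(1L, 20L, 20L))
  terr[1, 1:10, ] <- 1L
  terr[1, 11:16, ] <- 2L
  tmap <- territory_map(terr, 4, c(1, 1, 1))
  none <- label_mask(array(0L, dim(terr)), c(1, 1, 1))
  expect_equal(unname(death_density(none, tmap)), c(0, 0, 0))
  # death covering exactly the border
  death <- label_mask(terr == 1L, c(1, 1, 1))
  dd <- death_density(death, tmap)
  expect_equal(dd[["border"]], 100)
  expect_equal(dd[["center"]], 0)
  # empty center is NA and flagged
  terr2 <- terr; terr2[terr2 == 2L] <- 1L
  dd2 <- death_density(death, territory_map(terr2, 4, c(1, 1, 1)))
  expect_true(is.na(dd2[["center"]]))
  expect_identical(attr(dd2, "empty"), "center")
  # exterior restricted to the ROI
  roi <- label_mask(terr >= 0L & array(rep(c(TRUE, FALSE), each = 200),
                                       dim(terr)), c(1, 1, 1))
  dd3 <- death_density(death, tmap, roi = roi)
  expect_false(is.na(dd3[["exterior_wt"]]))
})

test_that("mean intensity matches a brute-force loop on random stacks", {
  set.seed(9)
  for (i in 1:5) {
    a <- array(rnorm(4 * 8 * 8, 50, 10), c(4L, 8L, 8L))
    st <- make_stack(a)
    m <- array(runif(length(a)) < 0.3, dim(a))
    if (!any(m)) next
    mask <- label_mask(m, c(1, 1, 1))
    acc <- 0; cnt <- 0
    for (z in 1:4) for (y in 1:8) for (x in 1:8)
      if (m[z, y, x]) { acc <- acc + a[z, y, x]; cnt <- cnt + 1 }
    expect_equal(mean_intensity(st, "stain", mask), acc / cnt)
  }
  # constants and checkerboards
  st <- make_stack(array(7, c(1L, 4L, 4L)))
  all_mask <- label_mask(array(TRUE, c(1L, 4L, 4L)), c(1, 1, 1))
  expect_equal(mean_intensity(st, "stain", all_mask), 7)
  chk <- array(0, c(1L, 4L, 4L)); chk[1, , ] <- matrix(c(0, 10), 4, 4)
  expect_equal(mean_intensity(make_stack(chk), "stain", all_mask), 5)
  expect_error(mean_intensity(st, "stain",
                              label_mask(array(FALSE, c(1L, 4L, 4L)),
                                         c(1, 1, 1))), "empty")
})

test_that("P/A ratio: symmetry, reciprocity, scale invariance, offsets", {
  a <- array(0, c(2L, 10L, 10L))
  a[, , 1:5] <- 40; a[, , 6:10] <- 72
  st <- make_stack(a)
  ant <- array(FALSE, dim(a)); ant[, , 1:5] <- TRUE
  comps <- compartment_masks(ant, !ant, c(1, 1, 1))
  expect_equal(pa_ratio(st, "stain", comps), 1.8)
  # identical compartments -> 1
  b <- array(33, dim(a))
  expect_equal(pa_ratio(make_stack(b), "stain", comps), 1)
  # reciprocity under mask swap
  swapped <- compartment_masks(!ant, ant, c(1, 1, 1))
  expect_equal(pa_ratio(st, "stain", swapped),
               1 / pa_ratio(st, "stain", comps))
  # multiplicative invariance, additive sensitivity
  expect_equal(pa_ratio(make_stack(a * 3.7), "stain", comps), 1.8)
  expect_false(isTRUE(all.equal(
    pa_ratio(make_stack(a + 50), "stain", comps), 1.8)))
  # degenerate anterior
  z <- array(0, dim(a)); z[, , 6:10] <- 5
  expect_error(pa_ratio(make_stack(z), "stain", comps), "degenerate anterior")
})

test_that("patch-relative intensity compares clone to wild-type surround", {
  a <- array(10, c(1L, 10L, 10L))
  patch <- array(FALSE, dim(a)); patch[1, 3:6, 3:6] <- TRUE
  roi <- label_mask(array(TRUE, dim(a)), c(1, 1, 1))
  pm <- label_mask(patch, c(1, 1, 1))
  st <- make_stack(a)
  expect_equal(relative_patch_intensity(st, "stain", pm, roi), 1)
  a2 <- a; a2[patch] <- 20
  expect_equal(relative_patch_intensity(make_stack(a2), "stain", pm, roi), 2)
  # no wild-type voxels left
  expect_error(relative_patch_intensity(st, "stain",
                                        label_mask(array(TRUE, dim(a)),
                                                   c(1, 1, 1)), roi),
               "wild-type")
})

test_that("speckle density is count per 1000 um^3 inside the mask", {
  vz <- c(1, 1, 1)
  mask <- label_mask(array(TRUE, c(20L, 10L, 10L)), vz)  # 2000 um^3
  expect_equal(speckle_density(spot_set(matrix(numeric(0), 0, 3)), mask), 0)
  pts <- cbind(runif(10, 0, 20), runif(10, 0, 10), runif(10, 0, 10))
  expect_equal(speckle_density(spot_set(pts), mask), 5)
  # spots outside the mask are not counted
  half <- label_mask(array(rep(c(TRUE, FALSE), each = 1000),
                           c(20L, 10L, 10L)), vz)
  pts2 <- cbind(c(5, 15), c(5, 5), c(2.5, 7.5))  # one inside, one outside
  expect_equal(speckle_density(spot_set(pts2), half), 1)
  expect_error(speckle_density(spot_set(pts),
                               label_mask(array(FALSE, c(2L, 2L, 2L)), vz)),
               "empty")
})
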