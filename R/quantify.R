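#' Pouch coverage
#'
#' Percentage of the pouch volume occupied by clone (GFP-positive) voxels,
#' by voxel count.
#'
#' @param patches clone [label_mask].
#' @param pouch pouch ROI [label_mask]; must be non-empty and on the same grid.
#' @return percentage in `[0, 100]`.
#' @export
pouch_coverage <- function(patches, pouch) {
  p <- as_grid3d(patches) > 0L
  roi <- as_grid3d(pouch, dim(p), "pouch") > 0L
  if (!any(roi)) stop("pouch ROI is empty")
  100 * sum(p & roi) / sum(roi)
}

#' Death-marker density per territory
#'
#' Percentage of each territory's volume that is death-marker (dcp1)
#' positive: `100 * |death intersect territory| / |territory|`. The
#' wild-type exterior is evaluated over the ROI outside the patches when an
#' ROI is given (otherwise over the whole grid outside the patches). An
#' empty territory yields `NA` and is flagged via the `"empty"` attribute so
#' downstream pairing can exclude the disc.
#'
#' @param death binary [label_mask] of death-marker-positive voxels.
#' @param tmap [territory_map] from [decompose_border_center()].
#' @param roi optional pouch ROI [label_mask].
#' @return named numeric `c(border, center, exterior_wt)` in percent, with
#'   attribute `empty` naming territories of zero volume.
#' @export
death_density <- function(death, tmap, roi = NULL) {
  stopifnot(inherits(tmap, "territory_map"))
  dd <- as_grid3d(death, dim(tmap$territory), "death") > 0L
  terr <- tmap$territory
  regions <- list(border = terr == 1L, center = terr == 2L)
  ext <- terr == 0L
  if (!is.null(roi)) ext <- ext & (as_grid3d(roi, dim(terr), "roi") > 0L)
  regions$exterior_wt <- ext
  out <- vapply(regions, function(r) {
    v <- sum(r)
    if (v == 0L) NA_real_ else 100 * sum(dd & r) / v
  }, numeric(1))
  empty <- names(out)[is.na(out)]
  if (length(empty)) attr(out, "empty") <- empty
  out
}

#' Mean voxel intensity over a mask
#'
#' Arithmetic mean of voxel intensities across all z sections of the masked
#' region (volume mean, not a projection).
#'
#' @param stack an [image_stack].
#' @param role channel role.
#' @param mask [label_mask] (any positive label counts).
#' @return mean intensity in the channel's arbitrary units.
#' @export
mean_intensity <- function(stack, role, mask) {
  ch <- get_channel(stack, role)
  m <- as_grid3d(mask, dim(ch)) > 0L
  if (!any(m)) stop("mask is empty")
  mean(ch[m])
}

#' Posterior/anterior intensity ratio
#'
#' Ratio of the mean channel intensity over the posterior compartment to the
#' mean over the anterior compartment. Invariant to multiplying the channel
#' by a positive constant; sensitive to additive offsets (no background is
#' subtracted by default).
#'
#' @param stack an [image_stack].
#' @param role channel role.
#' @param comps a [compartment_masks] object.
#' @return positive ratio.
#' @export
pa_ratio <- function(stack, role, comps) {
  stopifnot(inherits(comps, "compartment_masks"))
  ch <- get_channel(stack, role)
  a <- mean(ch[as_grid3d(comps$anterior, dim(ch), "anterior") > 0])
  p <- mean(ch[as_grid3d(comps$posterior, dim(ch), "posterior") > 0])
  if (!is.finite(a) || a == 0) stop("degenerate anterior signal (mean is 0)")
  p / a
}

#' Patch-relative intensity
#'
#' Mean channel intensity over clone patches divided by the mean over the
#' wild-type remainder of the ROI.
#'
#' @param stack an [image_stack].
#' @param role channel role.
#' @param patches clone [label_mask].
#' @param roi analysis ROI [label_mask].
#' @return positive ratio.
#' @export
relative_patch_intensity <- function(stack, role, patches, roi) {
  ch <- get_channel(stack, role)
  p <- as_grid3d(patches, dim(ch), "patches") > 0L
  r <- as_grid3d(roi, dim(ch), "roi") > 0L
  if (!any(p & r)) stop("no patch voxels inside the ROI")
  wt <- r & !p
  if (!any(wt)) stop("no wild-type voxels in the ROI")
  mean(ch[p & r]) / mean(ch[wt])
}

#' Speckle density
#'
#' Number of detected spots falling inside the mask per 1000 cubic
#' micrometres of mask volume.
#'
#' @param spots a [spot_set] (coordinates in micrometres).
#' @param mask [label_mask] defining the reference volume.
#' @return spots per 1000 um^3.
#' @export
speckle_density <- function(spots, mask) {
  stopifnot(inherits(mask, "label_mask"))
  m <- mask$labels > 0L
  if (!any(m)) stop("mask is empty")
  vol <- sum(m) * voxel_volume(mask$voxel_size)
  if (nrow(spots) == 0L) return(0)
  idx <- um_to_voxel(as.matrix(spots[, c("z", "y", "x")]), mask$voxel_size,
                     dim(m))
  inside <- !is.na(idx[, 1]) &
    m[cbind(idx[, 1], idx[, 2], idx[, 3])]
  sum(inside) / vol * 1000
}

# physical um coordinates -> 1-based voxel indices (voxel i spans
# [(i-1)*h, i*h), half-open); rows outside the grid get NA
um_to_voxel <- function(coords, voxel_size, dims) {
  idx <- floor(sweep(coords, 2, voxel_size, "/")) + 1L
  storage.mode(idx) <- "integer"
  bad <- idx[, 1] < 1L | idx[, 1] > dims[1] |
         idx[, 2] < 1L | idx[, 2] > dims[2] |
         idx[, 3] < 1L | idx[, 3] > dims[3]
  idx[bad, ] <- NA_integer_
  idx
}
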