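#' Segment GFP-positive clone patches in 3D
#'
#' Anisotropy-aware Gaussian smoothing (sigma in micrometres, converted to
#' voxels per axis), Otsu thresholding computed over the ROI voxels only,
#' 3-D connected components with 26-connectivity, and removal of components
#' below `min_volume`. Voxels outside the ROI are background; surviving
#' components are relabeled contiguously from 1.
#'
#' @param stack an [image_stack] with a `gfp` channel.
#' @param roi analysis ROI (pouch) [label_mask] on the same grid.
#' @param min_volume smallest component volume retained, in cubic
#'   micrometres. Default `NULL`: one nuclear volume derived from
#'   [estimate_cell_diameter()] when a nuclei channel is present, else 0
#'   (keep everything).
#' @param smooth_sigma Gaussian sigma in micrometres.
#' @param threshold optional absolute threshold overriding Otsu.
#' @return clone patches as a [label_mask].
#' @export
segment_patches <- function(stack, roi, min_volume = NULL, smooth_sigma = 1,
                            threshold = NULL) {
  ch <- get_channel(stack, "gfp")
  roi_m <- as_grid3d(roi, dim(ch), "roi") > 0L
  if (!any(roi_m)) stop("ROI is empty")
  if (is.null(min_volume)) {
    min_volume <- if (has_channel(stack, "nuclei")) {
      d <- estimate_cell_diameter(stack)
      (4 / 3) * pi * (d / 2)^3
    } else 0
  }
  sm <- gauss_smooth(ch, smooth_sigma, stack$voxel_size)
  thr <- if (is.null(threshold)) otsu_threshold(sm[roi_m]) else threshold
  fg <- sm > thr & roi_m
  lab <- .cc_label_3d(fg, dim(fg))
  lab <- drop_small_components(lab, min_volume, stack$voxel_size)
  label_mask(lab, stack$voxel_size, relabel = TRUE)
}

drop_small_components <- function(lab, min_volume, voxel_size) {
  if (min_volume <= 0 || !any(lab > 0L)) return(lab)
  counts <- tabulate(lab[lab > 0L])
  vv <- voxel_volume(voxel_size)
  small <- which(counts * vv < min_volume)
  if (length(small)) lab[lab %in% small] <- 0L
  lab
}

#' Segment death-marker (dcp1) positive voxels
#'
#' Same smoothing-plus-Otsu-within-ROI scheme as [segment_patches()], but
#' returns a binary mask (all positive voxels labeled 1) since death regions
#' are accounted by territory overlap, not per object.
#'
#' @param stack an [image_stack] with a `death` channel.
#' @param roi analysis ROI [label_mask].
#' @param smooth_sigma Gaussian sigma in micrometres; the default is smaller
#'   than for clone segmentation because dcp1 puncta are near cell-sized.
#' @param threshold optional absolute threshold overriding Otsu.
#' @return binary [label_mask].
#' @export
segment_death <- function(stack, roi, smooth_sigma = 0.5, threshold = NULL) {
  ch <- get_channel(stack, "death")
  roi_m <- as_grid3d(roi, dim(ch), "roi") > 0L
  if (!any(roi_m)) stop("ROI is empty")
  sm <- gauss_smooth(ch, smooth_sigma, stack$voxel_size)
  thr <- if (is.null(threshold)) otsu_threshold(sm[roi_m]) else threshold
  label_mask(sm > thr & roi_m, stack$voxel_size)
}

#' Detect diffraction-limited speckles (puncta)
#'
#' Multiscale scale-normalized Laplacian-of-Gaussian blob detection over a
#' physical diameter range, run per z-section with 3-D de-duplication:
#' responses are computed at log-spaced sigmas spanning the range, in-plane
#' local maxima above `threshold` are collected across sections and scales,
#' and spots closer than the minimum diameter (3-D physical distance) are
#' merged keeping the strongest response.
#'
#' @param stack an [image_stack].
#' @param role channel role to detect in (default `stain2`).
#' @param diameter_range `(min, max)` spot diameter in micrometres.
#' @param threshold minimum detector response. Default `NULL` uses a robust
#'   noise floor, `8 * mad(response)` over the channel.
#' @param n_scales number of log-spaced sigmas.
#' @return a [spot_set].
#' @export
detect_speckles <- function(stack, role = "stain2",
                            diameter_range = c(0.4, 1.6),
                            threshold = NULL, n_scales = 4L) {
  stopifnot(length(diameter_range) == 2L, all(diameter_range > 0),
            diameter_range[1] < diameter_range[2])
  ch <- get_channel(stack, role)
  vz <- stack$voxel_size
  sigmas <- exp(seq(log(diameter_range[1] / (2 * sqrt(2))),
                    log(diameter_range[2] / (2 * sqrt(2))),
                    length.out = n_scales))
  nz <- dim(ch)[1]
  resp_all <- vector("list", nz * length(sigmas))
  k <- 0L
  for (si in seq_along(sigmas)) {
    s <- sigmas[si]
    sm <- gauss_smooth(ch, s, vz)
    resp <- -s^2 * laplacian_inplane(sm, vz)
    for (z in seq_len(nz)) {
      m <- resp[z, , ]
      pk <- local_maxima_2d(m)
      if (!nrow(pk)) next
      v <- m[pk]
      keep <- v > 0
      if (!any(keep)) next
      k <- k + 1L
      resp_all[[k]] <- cbind(z = z, y = pk[keep, 1], x = pk[keep, 2],
                             response = v[keep], sigma = s)
    }
  }
  if (k == 0L) return(spot_set(matrix(numeric(0), 0, 3)))
  pk <- do.call(rbind, resp_all[seq_len(k)])
  if (is.null(threshold)) threshold <- 8 * stats::mad(as.vector(ch))
  pk <- pk[pk[, "response"] >= threshold, , drop = FALSE]
  if (!nrow(pk)) return(spot_set(matrix(numeric(0), 0, 3)))
  # voxel indices -> physical coordinates (voxel centres)
  um <- cbind((pk[, "z"] - 0.5) * vz[1],
              (pk[, "y"] - 0.5) * vz[2],
              (pk[, "x"] - 0.5) * vz[3])
  # the same physical spot is detected on neighbouring z sections; merge
  # within the larger of the minimum diameter and 1.5 axial steps
  dedupe_spots(um, pk[, "response"],
               min_dist = max(diameter_range[1], 1.5 * vz[1]))
}

# greedy non-maximum suppression: keep strongest spot, drop everything
# within min_dist (um, 3-D), repeat
dedupe_spots <- function(um, response, min_dist) {
  ord <- order(response, decreasing = TRUE)
  um <- um[ord, , drop = FALSE]
  response <- response[ord]
  keep <- logical(length(response))
  alive <- rep(TRUE, length(response))
  for (i in seq_along(response)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    d2 <- (um[, 1] - um[i, 1])^2 + (um[, 2] - um[i, 2])^2 +
      (um[, 3] - um[i, 3])^2
    alive <- alive & d2 > min_dist^2
  }
  spot_set(um[keep, , drop = FALSE], response[keep])
}

# discrete in-plane Laplacian with physical spacing (per z-section)
laplacian_inplane <- function(a, voxel_size) {
  d <- dim(a)
  lap <- array(0, d)
  if (d[2] > 2L) {
    lap[, 2:(d[2] - 1L), ] <- lap[, 2:(d[2] - 1L), ] +
      (a[, 1:(d[2] - 2L), ] - 2 * a[, 2:(d[2] - 1L), ] + a[, 3:d[2], ]) /
      voxel_size[2]^2
  }
  if (d[3] > 2L) {
    lap[, , 2:(d[3] - 1L)] <- lap[, , 2:(d[3] - 1L)] +
      (a[, , 1:(d[3] - 2L)] - 2 * a[, , 2:(d[3] - 1L)] + a[, , 3:d[3]]) /
      voxel_size[3]^2
  }
  lap
}

#' Estimate the cell diameter from the nuclei channel
#'
#' Segments nuclear cross-sections on a central band of z-sections (Gaussian
#' smoothing, Otsu threshold, distance-map watershed to split touching
#' nuclei) and returns the median equivalent-circle diameter. Supplies the
#' physical unit for the "2 cell diameters" border definition. Falls back to
#' `default` with a warning when fewer than 20 nuclei are found.
#'
#' @param stack an [image_stack] with a `nuclei` channel.
#' @param default fallback diameter in micrometres.
#' @param n_sections how many central z-sections to pool.
#' @param smooth_sigma Gaussian sigma in micrometres.
#' @param min_nuclei minimum cross-sections required before falling back.
#' @return estimated cell diameter in micrometres.
#' @export
estimate_cell_diameter <- function(stack, default = 5, n_sections = 3L,
                                   smooth_sigma = 0.7, min_nuclei = 20L) {
  ch <- get_channel(stack, "nuclei")
  nz <- dim(ch)[1]
  mid <- ceiling(nz / 2)
  zs <- unique(pmin(pmax(mid + seq_len(n_sections) - ceiling(n_sections / 2), 1L), nz))
  px_area <- stack$voxel_size[2] * stack$voxel_size[3]
  diams <- c()
  for (z in zs) {
    sl <- ch[z, , ]
    sm <- gauss_smooth(array(sl, c(1L, dim(sl))), smooth_sigma,
                       stack$voxel_size)[1, , ]
    thr <- otsu_threshold(as.vector(sm))
    bin <- sm > thr
    if (!any(bin)) next
    dm <- EBImage::distmap(bin * 1)
    ws <- EBImage::watershed(dm, tolerance = 0.5)
    areas <- tabulate(ws[ws > 0])
    areas <- areas[areas * px_area > 1]  # discard debris < 1 um^2
    diams <- c(diams, 2 * sqrt(areas * px_area / pi))
  }
  # a section through a sphere at uniform random height has median chord
  # diameter sqrt(3)/2 of the true diameter; undo that stereological bias
  diams <- diams * 2 / sqrt(3)
  if (length(diams) < min_nuclei) {
    warning("fewer than ", min_nuclei, " nuclei found; using default ",
            default, " um")
    return(default)
  }
  stats::median(diams)
}
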