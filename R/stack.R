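#' Multichannel 3D image stack
#'
#' Container for a confocal z-stack: a 4-D intensity array indexed
#' `(z, y, x, channel)` with physical voxel spacing in micrometres and a map
#' from channel roles to channel indices. Recognised roles are `nuclei`,
#' `gfp` (clone marker), `stain` / `stain2` (immunostain or reporter
#' channels) and `death` (apoptosis marker, e.g. cleaved dcp1).
#'
#' @param data numeric array, `(z, y, x)` for a single channel or
#'   `(z, y, x, channel)`.
#' @param voxel_size numeric length 3, `(dz, dy, dx)` in micrometres; all > 0.
#' @param channels named integer vector mapping roles to channel indices,
#'   e.g. `c(gfp = 1, death = 2)`.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_size, channels) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) stop("data must be a 3-D or 4-D array")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be three strictly positive values (dz, dy, dx) in um")
  channels <- check_channel_map(channels, dim(data)[4L])
  structure(list(data = data, voxel_size = voxel_size, channels = channels),
            class = "image_stack")
}

check_channel_map <- function(channels, n_channels) {
  roles <- c("nuclei", "gfp", "stain", "stain2", "death")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channel map must be a named vector (role = index)")
  bad <- setdiff(names(channels), roles)
  if (length(bad))
    stop("unknown channel role(s): ", paste(bad, collapse = ", "),
         "; expected roles among ", paste(roles, collapse = ", "))
  channels <- stats::setNames(as.integer(channels), names(channels))
  if (anyDuplicated(channels)) stop("channel indices must be unique")
  if (any(channels < 1L) || any(channels > n_channels))
    stop("channel index out of range: stack has ", n_channels,
         " channel(s); fix the channel map or supply the missing channel")
  channels
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d x %d voxels (z,y,x), %d channel(s)\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size (dz,dy,dx): %s um\n",
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  cat("  channels:", paste(sprintf("%s=%d", names(x$channels), x$channels),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel of an image stack
#'
#' @param stack an [image_stack].
#' @param role channel role to extract.
#' @return 3-D numeric array `(z, y, x)`.
#' @export
get_channel <- function(stack, role) {
  stopifnot(inherits(stack, "image_stack"))
  if (!role %in% names(stack$channels))
    stop("stack has no '", role, "' channel (available: ",
         paste(names(stack$channels), collapse = ", "), ")")
  ch <- stack$data[, , , stack$channels[[role]], drop = FALSE]
  dim(ch) <- dim(ch)[1:3]  # keep singleton spatial axes
  ch
}

has_channel <- function(stack, role) role %in% names(stack$channels)

#' Labeled voxel mask
#'
#' Non-negative integer labels on a `(z, y, x)` grid; 0 is background and
#' labels are contiguous from 1. A binary mask is a label mask whose only
#' label is 1.
#'
#' @param labels integer (or logical) array; a 2-D matrix is treated as a
#'   single-section stack.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param relabel if `TRUE`, relabel positive values contiguously from 1
#'   (order of first occurrence).
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(labels, voxel_size, relabel = FALSE) {
  if (is.logical(labels)) {
    l <- array(0L, dim(labels)); l[labels] <- 1L
    dim(l) <- dim(labels); labels <- l
  }
  if (length(dim(labels)) == 2L) dim(labels) <- c(1L, dim(labels))
  if (length(dim(labels)) != 3L) stop("labels must be a 2-D or 3-D array")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be non-negative")
  if (relabel) labels <- relabel_contiguous(labels)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three strictly positive values")
  structure(list(labels = labels, voxel_size = voxel_size),
            class = "label_mask")
}

relabel_contiguous <- function(labels) {
  u <- unique(as.vector(labels)); u <- u[u > 0L]
  if (!length(u)) return(labels)
  map <- integer(max(u)); map[u] <- seq_along(u)
  out <- labels
  pos <- labels > 0L
  out[pos] <- map[labels[pos]]
  out
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$labels)
  k <- n_labels(x)
  cat(sprintf("<label_mask> %d x %d x %d voxels, %d label(s), %d fg voxels\n",
              d[1], d[2], d[3], k, sum(x$labels > 0L)))
  invisible(x)
}

n_labels <- function(mask) {
  m <- max(mask$labels)
  if (m == 0L) 0L else length(unique(as.vector(mask$labels[mask$labels > 0L])))
}

#' Physical volume of one voxel
#' @param voxel_size `(dz, dy, dx)` in micrometres, or an object carrying one.
#' @return volume in cubic micrometres.
#' @export
voxel_volume <- function(voxel_size) {
  if (is.list(voxel_size)) voxel_size <- voxel_size$voxel_size
  prod(voxel_size)
}

# coerce label_mask / array input to a 3-D array, checking grid compatibility
as_grid3d <- function(x, ref_dim = NULL, what = "mask") {
  a <- if (inherits(x, "label_mask")) x$labels else x
  if (is.null(dim(a)) || length(dim(a)) == 2L) dim(a) <- c(1L, dim(a))
  if (!is.null(ref_dim) && !identical(dim(a), as.integer(ref_dim)))
    stop(what, " grid (", paste(dim(a), collapse = "x"),
         ") does not match stack grid (", paste(ref_dim, collapse = "x"), ")")
  a
}

#' Border/center territory decomposition of clone patches
#'
#' Categorical voxel grid produced by [decompose_border_center()]:
#' 0 = exterior (wild-type / non-patch), 1 = border band, 2 = center.
#'
#' @param territory integer array with values in `{0, 1, 2}`.
#' @param band_width border band width in micrometres.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @return an object of class `territory_map`.
#' @export
territory_map <- function(territory, band_width, voxel_size) {
  if (length(dim(territory)) == 2L) dim(territory) <- c(1L, dim(territory))
  storage.mode(territory) <- "integer"
  if (!all(territory %in% 0:2)) stop("territory codes must be 0, 1 or 2")
  structure(list(territory = territory, band_width = band_width,
                 voxel_size = as.numeric(voxel_size)),
            class = "territory_map")
}

#' @export
print.territory_map <- function(x, ...) {
  vv <- voxel_volume(x$voxel_size)
  cat(sprintf("<territory_map> band width %.3g um; border %.4g um^3, center %.4g um^3\n",
              x$band_width, sum(x$territory == 1L) * vv,
              sum(x$territory == 2L) * vv))
  invisible(x)
}

#' Detected diffraction-limited spots
#'
#' @param coords numeric matrix with columns `(z, y, x)` in micrometres.
#' @param response per-spot detector response (scale-normalized
#'   Laplacian-of-Gaussian magnitude).
#' @return an object of class `spot_set` (a data frame with columns
#'   `z`, `y`, `x`, `response`).
#' @export
spot_set <- function(coords, response = numeric(nrow(coords))) {
  coords <- matrix(as.numeric(coords), ncol = 3,
                   dimnames = list(NULL, c("z", "y", "x")))
  out <- data.frame(coords, response = as.numeric(response))
  class(out) <- c("spot_set", "data.frame")
  out
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set> %d spot(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(head(x, 10))
  invisible(x)
}

#' Anterior/posterior compartment masks
#'
#' @param anterior,posterior binary/logical voxel grids on the stack grid;
#'   must be disjoint and each non-empty.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @return an object of class `compartment_masks`.
#' @export
compartment_masks <- function(anterior, posterior, voxel_size) {
  a <- as_grid3d(anterior) > 0
  p <- as_grid3d(posterior, dim(a), "posterior") > 0
  if (!any(a)) stop("anterior compartment mask is empty")
  if (!any(p)) stop("posterior compartment mask is empty")
  if (any(a & p)) stop("compartment masks must be disjoint")
  structure(list(anterior = a, posterior = p,
                 voxel_size = as.numeric(voxel_size)),
            class = "compartment_masks")
}

#' Split a pouch ROI into anterior and posterior halves
#'
#' Convention used by the synthetic generator and available for real data
#' lacking a drawn boundary: the compartment boundary is the vertical
#' midline plane of the ROI bounding box along x, with posterior on the
#' right (higher x), matching the usual mounting orientation.
#'
#' @param roi a [label_mask] for the pouch.
#' @return a [compartment_masks] object.
#' @export
split_compartments <- function(roi) {
  m <- roi$labels > 0L
  if (!any(m)) stop("ROI is empty")
  xs <- which(apply(m, 3, any))
  mid <- (min(xs) + max(xs)) / 2
  nx <- dim(m)[3]
  xidx <- rep(seq_len(nx), each = dim(m)[1] * dim(m)[2])
  ant <- m & array(xidx <= mid, dim(m))
  pos <- m & array(xidx > mid, dim(m))
  compartment_masks(ant, pos, roi$voxel_size)
}
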