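# Internal image primitives shared by segmentation and the generator.

# 1-D Gaussian kernel, sigma in voxels; returns NULL when smoothing is a no-op
gauss_kernel <- function(sigma_vox) {
  if (sigma_vox < 0.25) return(NULL)
  r <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# convolve a 3-D array along one axis with nearest (replicate) padding
conv_axis <- function(a, k, axis) {
  if (is.null(k)) return(a)
  .conv_axis_cpp(a, as.integer(dim(a)), as.numeric(k), as.integer(axis))
}

# separable anisotropy-aware Gaussian smoothing; sigma is physical (um)
# and converted per axis via the voxel spacing
gauss_smooth <- function(a, sigma, voxel_size) {
  if (sigma <= 0) return(a)
  for (axis in 1:3) {
    if (dim(a)[axis] > 1L)
      a <- conv_axis(a, gauss_kernel(sigma / voxel_size[axis]), axis)
  }
  a
}

# Otsu threshold of an intensity sample (typically ROI-restricted voxels).
# Wraps EBImage::otsu, which operates on images; the sample is passed as a
# one-column image with its own range.
otsu_threshold <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) return(Inf)  # constant input: nothing is foreground
  EBImage::otsu(EBImage::Image(matrix(values, ncol = 1L)),
                range = rng, levels = levels)
}

# Euclidean distance (um) from foreground voxels to nearest background voxel.
# per_slice = TRUE computes the in-plane (per z section) transform.
distance_to_background <- function(mask, voxel_size, per_slice = TRUE) {
  d2 <- .edt_sq(as.logical(mask), as.integer(dim(mask)),
                as.numeric(voxel_size), isTRUE(per_slice))
  sqrt(d2)
}

# 8-neighbour local maxima of a 2-D matrix; plateaus are broken
# lexicographically (>= against earlier neighbours, > against later ones)
# so a flat-topped peak yields exactly one maximum
local_maxima_2d <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  if (ny < 3L || nx < 3L) return(matrix(numeric(0), 0, 2))
  pad <- matrix(-Inf, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- m
  ok <- matrix(TRUE, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2:(ny + 1L)) + dy, (2:(nx + 1L)) + dx]
    later <- dx > 0 || (dx == 0 && dy > 0)
    ok <- ok & (if (later) m > nb else m >= nb)
  }
  which(ok, arr.ind = TRUE)
}
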