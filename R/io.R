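#' Write an image stack to multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered z within channel, channels in index order (axis order
#' Z within C). Intensities are stored as 16-bit samples; values are divided
#' by the scale recorded in the sidecar (`<path>.json`, which also carries
#' voxel size, grid shape and the channel map), so integer-valued stacks
#' round-trip exactly up to the 16-bit range.
#'
#' @param stack an [image_stack].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (any(stack$data < 0)) stop("negative intensities cannot be stored")
  # integer-valued stacks up to 65535 (the native case: quantized counts)
  # are stored losslessly with scale 65535; anything else is scaled to the
  # 16-bit range and quantized
  int_ok <- max(stack$data) <= 65535 && all(stack$data == round(stack$data))
  scale <- if (int_ok) 65535 else max(stack$data, 1)
  pages <- list()
  for (ci in seq_len(d[4])) for (z in seq_len(d[1]))
    pages[[length(pages) + 1L]] <- stack$data[z, , , ci] / scale
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                        compression = "LZW", reduce = FALSE)
  sidecar <- sub("\\.tiff?$", "", path)
  jsonlite::write_json(
    list(shape = d[1:3], n_channels = d[4],
         voxel_size_um = stack$voxel_size,
         channels = as.list(stack$channels),
         intensity_scale = scale,
         axis_order = "pages are z within channel; in-page axes (y, x)"),
    paste0(sidecar, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()] (or a plain TIFF)
#'
#' With the JSON sidecar present, geometry, channel map and intensity scale
#' are restored from it (explicit arguments override the sidecar). Without a
#' sidecar, `channel_map` and `voxel_size` are required and pages are
#' interpreted as z within channel.
#'
#' @param path `.tif` path.
#' @param channel_map named integer vector role -> channel index.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param n_channels channel count (sidecar-free files only; default: length
#'   of the channel map's index range).
#' @return an [image_stack].
#' @export
read_stack <- function(path, channel_map = NULL, voxel_size = NULL,
                       n_channels = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sc_path <- paste0(sub("\\.tiff?$", "", path), ".json")
  scale <- 1
  if (file.exists(sc_path)) {
    sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
    if (is.null(voxel_size)) voxel_size <- sc$voxel_size_um
    if (is.null(channel_map)) channel_map <- unlist(sc$channels)
    if (is.null(n_channels)) n_channels <- sc$n_channels
    scale <- sc$intensity_scale
  }
  if (is.null(voxel_size))
    stop("no voxel size available: supply voxel_size = c(dz, dy, dx) in um ",
         "or provide the JSON sidecar written by write_stack()")
  if (is.null(channel_map))
    stop("no channel map available: supply channel_map = c(role = index, ...)")
  if (is.null(n_channels)) n_channels <- max(channel_map)
  n_pages <- length(pages)
  if (n_pages %% n_channels != 0L)
    stop("page count ", n_pages, " is not a multiple of n_channels ",
         n_channels)
  nz <- n_pages %/% n_channels
  dyx <- dim(pages[[1]])
  data <- array(0, c(nz, dyx[1], dyx[2], n_channels))
  k <- 0L
  for (ci in seq_len(n_channels)) for (z in seq_len(nz)) {
    k <- k + 1L
    data[z, , , ci] <- pages[[k]]
  }
  data <- round(data * 65535) * (scale / 65535)  # undo 16-bit quantization
  image_stack(data, voxel_size, channel_map)
}

#' Write a label mask as 16-bit TIFF plus sidecar
#' @param mask a [label_mask].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535L) stop("labels exceed 16-bit range")
  d <- dim(mask$labels)
  pages <- lapply(seq_len(d[1]), function(z) mask$labels[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW",
                  reduce = FALSE)
  jsonlite::write_json(list(shape = d, voxel_size_um = mask$voxel_size,
                            kind = "label_mask"),
                       paste0(sub("\\.tiff?$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a region of interest: label-mask TIFF or per-section polygon JSON
#'
#' Polygon JSON format: `{"shape": [nz, ny, nx], "voxel_size_um": [dz,dy,dx],
#' "polygons": [{"z": [1, 20], "y": [...], "x": [...]}, ...]}` with polygon
#' vertices in micrometres applied to the inclusive z-section range `z`;
#' sections are rasterized with even-odd fill at voxel centres.
#'
#' @param path `.tif`/`.tiff` or `.json` path.
#' @param voxel_size,shape overrides/requirements when metadata is absent.
#' @return a [label_mask].
#' @export
read_roi <- function(path, voxel_size = NULL, shape = NULL) {
  if (grepl("\\.json$", path)) {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    shape <- if (is.null(shape)) as.integer(spec$shape) else as.integer(shape)
    voxel_size <- if (is.null(voxel_size)) spec$voxel_size_um else voxel_size
    if (is.null(shape) || is.null(voxel_size))
      stop("polygon ROI needs 'shape' and 'voxel_size_um'")
    m <- array(FALSE, shape)
    polys <- spec$polygons
    if (is.data.frame(polys)) polys <- split(polys, seq_len(nrow(polys)))
    yc <- (seq_len(shape[2]) - 0.5) * voxel_size[2]
    xc <- (seq_len(shape[3]) - 0.5) * voxel_size[3]
    grid <- cbind(rep(xc, each = shape[2]), rep(yc, shape[3]))
    for (pg in polys) {
      zr <- unlist(pg$z)
      bnd <- cbind(unlist(pg$x), unlist(pg$y))
      inside <- mgcv::in.out(rbind(bnd, bnd[1, ]), grid)
      sect <- matrix(inside, shape[2], shape[3])
      for (z in zr[1]:zr[2]) m[z, , ] <- m[z, , ] | sect
    }
    return(label_mask(m, voxel_size))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  sc_path <- paste0(sub("\\.tiff?$", "", path), ".json")
  if (file.exists(sc_path)) {
    sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
    if (is.null(voxel_size)) voxel_size <- sc$voxel_size_um
  }
  if (is.null(voxel_size))
    stop("no voxel size available for ROI: supply voxel_size = c(dz, dy, dx)")
  nz <- length(pages)
  lab <- array(0L, c(nz, dim(pages[[1]])))
  for (z in seq_len(nz)) lab[z, , ] <- as.integer(round(pages[[z]] * 65535))
  label_mask(lab, voxel_size)
}

#' Write ground truth (masks + parameters) for a simulated disc
#' @param truth a `ground_truth` from [simulate_disc()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir, prefix = "disc") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mask(truth$pouch_mask, file.path(dir, paste0(prefix, "_pouch.tif")))
  write_mask(truth$patch_mask, file.path(dir, paste0(prefix, "_patches.tif")))
  write_mask(truth$death_mask, file.path(dir, paste0(prefix, "_death.tif")))
  vz <- truth$patch_mask$voxel_size
  write_mask(label_mask(truth$territory_map$territory, vz),
             file.path(dir, paste0(prefix, "_territory.tif")))
  jsonlite::write_json(
    list(realized_coverage_pct = truth$realized_coverage,
         realized_death_density_pct = as.list(truth$realized_death_density),
         true_pa_ratio = truth$true_pa_ratio,
         speckle_coords_um = truth$speckle_coords,
         band_width_um = truth$territory_map$band_width,
         seed = truth$seed),
    file.path(dir, paste0(prefix, "_truth.json")), auto_unbox = TRUE,
    digits = NA, na = "null")
  invisible(dir)
}
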