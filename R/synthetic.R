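#' Configuration for the synthetic wing-disc generator
#'
#' Defines the study conditions for one simulated disc: grid geometry, an
#' ellipsoidal pouch, GFP-positive clone patches grown to a target coverage
#' fraction, death-marker-positive blobs occupying configured fractions of
#' the border/center/wild-type territories, a reporter channel with a
#' posterior/anterior fold change, diffraction-limited speckles, and
#' Gaussian noise on a flat background. Intensities are quantized to integer
#' counts, as in real detector data.
#'
#' @param shape grid size `(n_z, n_y, n_x)` in voxels.
#' @param voxel_size `(dz, dy, dx)` in micrometres; the axial step defaults
#'   to 1 um as in typical confocal acquisition, the in-plane pixel size is a
#'   free parameter.
#' @param pouch_center,pouch_semiaxes ellipsoid centre and semi-axes
#'   `(z, y, x)` in micrometres; defaults centre the pouch and give it 42%
#'   of each physical extent.
#' @param n_patches number of clone seed points.
#' @param target_coverage fraction of pouch volume occupied by clones, in
#'   `[0, 1]`.
#' @param cell_diameter cell (and nuclear) diameter in micrometres.
#' @param death_rate_border,death_rate_center,death_rate_wt fraction of each
#'   territory's volume that is death-marker positive, each in `[0, 1]`.
#' @param pa_fold_change posterior/anterior intensity factor (> 0) of the
#'   `stain` channel.
#' @param speckle_density speckles per 1000 cubic micrometres of pouch
#'   (rendered into the `stain2` channel).
#' @param background_level,signal_level,noise_sd intensity model parameters
#'   (arbitrary units): voxel value = background + signal * mask + Gaussian
#'   noise, clipped at 0 and rounded.
#' @param seed integer RNG seed.
#' @param channels which channels to render (subset of `nuclei`, `gfp`,
#'   `stain`, `stain2`, `death`).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(shape = c(20L, 160L, 160L),
                       voxel_size = c(1, 0.5, 0.5),
                       pouch_center = NULL,
                       pouch_semiaxes = NULL,
                       n_patches = 2L,
                       target_coverage = 0.3,
                       cell_diameter = 4,
                       death_rate_border = 0.10,
                       death_rate_center = 0.05,
                       death_rate_wt = 0.02,
                       pa_fold_change = 1,
                       speckle_density = 0,
                       background_level = 20,
                       signal_level = 100,
                       noise_sd = 10,
                       seed = 1L,
                       channels = c("nuclei", "gfp", "stain", "stain2",
                                    "death")) {
  extent <- shape * voxel_size
  if (is.null(pouch_center)) pouch_center <- extent / 2
  if (is.null(pouch_semiaxes)) pouch_semiaxes <- 0.42 * extent
  cfg <- list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
              pouch_center = as.numeric(pouch_center),
              pouch_semiaxes = as.numeric(pouch_semiaxes),
              n_patches = as.integer(n_patches),
              target_coverage = target_coverage,
              cell_diameter = cell_diameter,
              death_rate_border = death_rate_border,
              death_rate_center = death_rate_center,
              death_rate_wt = death_rate_wt,
              pa_fold_change = pa_fold_change,
              speckle_density = speckle_density,
              background_level = background_level,
              signal_level = signal_level,
              noise_sd = noise_sd, seed = as.integer(seed),
              channels = match.arg(channels,
                                   c("nuclei", "gfp", "stain", "stain2",
                                     "death"), several.ok = TRUE))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$shape) == 3L, all(cfg$shape >= 1L))
  if (any(cfg$voxel_size <= 0)) stop("voxel_size entries must be > 0")
  rates <- c(cfg$death_rate_border, cfg$death_rate_center, cfg$death_rate_wt)
  if (any(rates < 0 | rates > 1)) stop("death rates must lie in [0, 1]")
  if (cfg$target_coverage < 0 || cfg$target_coverage > 1)
    stop("target_coverage must lie in [0, 1]")
  if (cfg$pa_fold_change <= 0) stop("pa_fold_change must be > 0")
  if (cfg$speckle_density < 0) stop("speckle_density must be >= 0")
  if (cfg$cell_diameter <= 0) stop("cell_diameter must be > 0")
  if (cfg$n_patches < 0L) stop("n_patches must be >= 0")
  invisible(cfg)
}

# evaluate code under a fixed RNG seed, restoring the caller's RNG state
with_rng_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

# integer voxel offsets (n x 3) covering a sphere of physical radius r_um;
# always contains the centre voxel
sphere_offsets <- function(r_um, voxel_size) {
  r <- pmax(0L, floor(r_um / voxel_size))
  g <- expand.grid(z = -r[1]:r[1], y = -r[2]:r[2], x = -r[3]:r[3])
  keep <- (g$z * voxel_size[1])^2 + (g$y * voxel_size[2])^2 +
    (g$x * voxel_size[3])^2 <= r_um^2
  m <- as.matrix(g[keep, , drop = FALSE])
  if (!nrow(m)) m <- matrix(0L, 1, 3, dimnames = list(NULL, c("z", "y", "x")))
  storage.mode(m) <- "integer"
  m
}

# absolute linear indices of `offsets` centred at voxel (z,y,x), clipped to grid
offsets_at <- function(offsets, center, dims) {
  z <- offsets[, 1] + center[1]
  y <- offsets[, 2] + center[2]
  x <- offsets[, 3] + center[3]
  ok <- z >= 1L & z <= dims[1] & y >= 1L & y <= dims[2] & x >= 1L & x <= dims[3]
  (z + dims[1] * (y - 1L) + dims[1] * dims[2] * (x - 1L))[ok]
}

lin_to_zyx <- function(lin, dims) {
  lin0 <- lin - 1L
  cbind(z = lin0 %% dims[1] + 1L,
        y = (lin0 %/% dims[1]) %% dims[2] + 1L,
        x = lin0 %/% (dims[1] * dims[2]) + 1L)
}

#' Simulate one synthetic wing disc with ground truth
#'
#' Deterministic given the config (identical seed, identical output). Clone
#' patches are unions of overlapping spheres grown from random seed points
#' until the target pouch coverage is met (the final sphere shrinks to land
#' on the target); death-positive voxels are small blobs of roughly one
#' nuclear volume placed within each territory until the configured volume
#' fraction is reached. The `stain` channel mean over the posterior pouch
#' half equals `pa_fold_change` times the anterior mean before noise.
#'
#' @param config a [sim_config].
#' @return `list(stack, truth)`: an [image_stack] and a `ground_truth`
#'   holding the true masks, territory map, speckle coordinates and realized
#'   (voxel-count-derived) coverage and death densities.
#' @export
simulate_disc <- function(config) {
  validate_sim_config(config)
  with_rng_seed(config$seed, simulate_disc_impl(config))
}

simulate_disc_impl <- function(cfg) {
  dims <- cfg$shape
  vz <- cfg$voxel_size
  pouch <- ellipsoid_mask(dims, vz, cfg$pouch_center, cfg$pouch_semiaxes)
  pouch_idx <- which(pouch)
  if (!length(pouch_idx)) stop("pouch ellipsoid contains no voxels")

  patch_lab <- grow_patches(pouch, pouch_idx, cfg)
  patch_cc <- .cc_label_3d(patch_lab > 0L, dims)
  patches <- label_mask(patch_cc, vz)

  tmap <- if (any(patch_cc > 0L))
    decompose_border_center(patches, cfg$cell_diameter, 2)
  else territory_map(array(0L, dims), 2 * cfg$cell_diameter, vz)

  death <- place_death(tmap, pouch, cfg)

  speckles <- if ("stain2" %in% cfg$channels && cfg$speckle_density > 0)
    place_speckles(pouch_idx, dims, vz, cfg)
  else matrix(numeric(0), 0, 3, dimnames = list(NULL, c("z", "y", "x")))

  stack <- render_channels(pouch, patch_cc, death, speckles, cfg)

  n_pouch <- length(pouch_idx)
  terr <- tmap$territory
  realized_death <- c(
    border = region_pct(death, terr == 1L),
    center = region_pct(death, terr == 2L),
    exterior_wt = region_pct(death, pouch & terr == 0L))
  truth <- structure(list(
    pouch_mask = label_mask(pouch, vz),
    patch_mask = patches,
    territory_map = tmap,
    death_mask = label_mask(death, vz),
    speckle_coords = speckles,
    realized_coverage = 100 * sum(patch_cc > 0L) / n_pouch,
    realized_death_density = realized_death,
    true_pa_ratio = cfg$pa_fold_change,
    config = cfg, seed = cfg$seed), class = "ground_truth")
  list(stack = stack, truth = truth)
}

region_pct <- function(mask, region) {
  v <- sum(region)
  if (v == 0L) NA_real_ else 100 * sum(mask & region) / v
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> coverage %.2f%%; death density b/c/wt = %s%%; P/A = %.3g\n",
              x$realized_coverage,
              paste(signif(x$realized_death_density, 3), collapse = "/"),
              x$true_pa_ratio))
  invisible(x)
}

ellipsoid_mask <- function(dims, vz, center, semiaxes) {
  zc <- ((seq_len(dims[1]) - 0.5) * vz[1] - center[1]) / semiaxes[1]
  yc <- ((seq_len(dims[2]) - 0.5) * vz[2] - center[2]) / semiaxes[2]
  xc <- ((seq_len(dims[3]) - 0.5) * vz[3] - center[3]) / semiaxes[3]
  a <- array(zc^2, dims) +
    array(rep(yc^2, each = dims[1]), dims) +
    array(rep(xc^2, each = dims[1] * dims[2]), dims)
  a <= 1
}

grow_patches <- function(pouch, pouch_idx, cfg) {
  dims <- dim(pouch)
  lab <- array(0L, dims)
  target_vox <- round(cfg$target_coverage * length(pouch_idx))
  if (target_vox == 0L || cfg$n_patches == 0L) {
    if (target_vox > 0L)
      stop("target_coverage ", cfg$target_coverage,
           " unreachable with n_patches = 0 inside pouch")
    return(lab)
  }
  # seed points, kept >= 2 cell diameters apart where possible
  seeds <- integer(0)
  min_d2 <- (2 * cfg$cell_diameter)^2
  coords_of <- function(lin) {
    zyx <- lin_to_zyx(lin, dims)
    sweep(zyx - 0.5, 2, cfg$voxel_size, "*")
  }
  tries <- 0L
  while (length(seeds) < cfg$n_patches && tries < 500L) {
    tries <- tries + 1L
    cand <- pouch_idx[sample.int(length(pouch_idx), 1L)]
    if (length(seeds)) {
      d2 <- rowSums(sweep(coords_of(seeds), 2, coords_of(cand)[1, ], "-")^2)
      if (any(d2 < min_d2) && tries < 400L) next
    }
    seeds <- c(seeds, cand)
  }
  off_full <- sphere_offsets(cfg$cell_diameter, cfg$voxel_size)
  patch_vox <- vector("list", length(seeds))
  covered <- 0L
  # add a sphere; if it overshoots the target, trim the outermost of the
  # voxels it just added so realized coverage lands on the target exactly
  add_sphere <- function(p, center_lin) {
    ctr_zyx <- lin_to_zyx(center_lin, dims)[1, ]
    idx <- offsets_at(off_full, ctr_zyx, dims)
    idx <- idx[pouch[idx] & lab[idx] == 0L]
    if (!length(idx)) return(0L)
    overshoot <- covered + length(idx) - target_vox
    if (overshoot > 0L) {
      zyx <- lin_to_zyx(idx, dims)
      d2 <- rowSums(sweep(sweep(zyx, 2, ctr_zyx, "-"), 2,
                          cfg$voxel_size, "*")^2)
      idx <- idx[order(d2)][seq_len(length(idx) - overshoot)]
    }
    if (length(idx)) {
      lab[idx] <<- p
      patch_vox[[p]] <<- c(patch_vox[[p]], idx)
      covered <<- covered + length(idx)
    }
    length(idx)
  }
  for (p in seq_along(seeds)) add_sphere(p, seeds[p])
  stall <- 0L
  it <- 0L
  while (covered < target_vox) {
    it <- it + 1L
    p <- (it - 1L) %% length(seeds) + 1L
    if (!length(patch_vox[[p]])) { stall <- stall + 1L } else {
      ctr <- patch_vox[[p]][sample.int(length(patch_vox[[p]]), 1L)]
      added <- add_sphere(p, ctr)
      stall <- if (added == 0L) stall + 1L else 0L
    }
    if (stall >= 500L)
      stop("target_coverage ", cfg$target_coverage, " unreachable with ",
           "n_patches = ", cfg$n_patches, " inside pouch (growth stalled at ",
           signif(100 * covered / length(pouch_idx), 3), "% coverage)")
  }
  lab
}

# Death blobs respect the clone (genotype) boundary but straddle the
# border/center line freely -- that line is an analysis construct, not a
# barrier to apoptosis. Each territory is filled to its volume-fraction
# target counting every death voxel that lands in it (own blobs plus spill
# from the neighbouring territory); the final blob of a territory is trimmed
# (outermost voxels first) so the realized fraction lands on the target.
place_death <- function(tmap, pouch, cfg) {
  dims <- dim(pouch)
  terr <- tmap$territory
  death <- array(FALSE, dims)
  blob <- sphere_offsets(cfg$cell_diameter / 2, cfg$voxel_size)
  patch_scope <- terr > 0L
  wt_scope <- pouch & terr == 0L
  regions <- list(
    border = list(mask = terr == 1L, rate = cfg$death_rate_border,
                  scope = patch_scope),
    center = list(mask = terr == 2L, rate = cfg$death_rate_center,
                  scope = patch_scope),
    wt = list(mask = wt_scope, rate = cfg$death_rate_wt, scope = wt_scope))
  ridx <- lapply(regions, function(r) which(r$mask))
  size <- lengths(ridx)
  # Candidate centres are the region plus its dilation by one blob radius
  # across the clipping (scope) boundary only: blobs are clipped at the
  # genotype boundary, which would otherwise deplete coverage in a shell
  # along it (centres beyond it can never be drawn) and enrich the region
  # interior in compensation. Letting centres sit just outside the scope --
  # their blobs are rendered clipped -- makes expected coverage uniform.
  # The border/center line is not a clipping boundary, so no dilation there.
  r_blob <- cfg$cell_diameter / 2
  cand <- lapply(regions, function(r) {
    if (!any(r$mask)) return(integer(0))
    d2 <- .edt_sq(!r$mask, as.integer(dims), as.numeric(cfg$voxel_size),
                  FALSE)
    which(r$mask | (d2 <= r_blob^2 & !r$scope))
  })
  target <- vapply(seq_along(regions), function(k)
    if (size[k] == 0L) 0L else as.integer(round(regions[[k]]$rate * size[k])),
    integer(1))
  # interleaved fill: always advance the territory with the largest voxel
  # deficit, counting spill received from neighbours toward each territory's
  # own target. Keeps the residual overshoot from late cross-territory spill
  # balanced between border and center rather than piling onto one of them.
  placed <- integer(length(regions))
  stall <- 0L
  while (any(placed < target)) {
    k <- which.max(target - placed)
    region <- regions[[k]]
    free <- ridx[[k]][!death[ridx[[k]]]]
    remaining <- target[k] - placed[k]
    if (!length(free)) break  # region saturated below target: give up
    if (stall >= 200L) {  # near-saturation: fill single voxels directly
      take <- free[sample.int(length(free), min(remaining, length(free)))]
      death[take] <- TRUE
      placed[k] <- placed[k] + length(take)
      stall <- 0L
      next
    }
    ctr_lin <- cand[[k]][sample.int(length(cand[[k]]), 1L)]
    ctr_zyx <- lin_to_zyx(ctr_lin, dims)[1, ]
    idx <- offsets_at(blob, ctr_zyx, dims)
    idx <- idx[region$scope[idx] & !death[idx]]
    in_k <- idx[region$mask[idx]]
    spill <- setdiff(idx, in_k)
    if (length(in_k) > remaining) {
      zyx <- lin_to_zyx(in_k, dims)
      d2 <- rowSums(sweep(sweep(zyx, 2, ctr_zyx, "-"), 2,
                          cfg$voxel_size, "*")^2)
      in_k <- in_k[order(d2)][seq_len(remaining)]
    }
    new_vox <- c(in_k, spill)
    stall <- if (length(in_k)) 0L else stall + 1L
    if (length(new_vox)) {
      death[new_vox] <- TRUE
      for (m in seq_along(regions))
        placed[m] <- placed[m] + sum(regions[[m]]$mask[new_vox])
    }
  }
  death
}

place_speckles <- function(pouch_idx, dims, vz, cfg, min_sep = 2) {
  pouch_vol <- length(pouch_idx) * prod(vz)
  n_spk <- round(cfg$speckle_density * pouch_vol / 1000)
  if (n_spk == 0L) return(matrix(numeric(0), 0, 3,
                                 dimnames = list(NULL, c("z", "y", "x"))))
  acc <- matrix(numeric(0), 0, 3)
  tries <- 0L
  while (nrow(acc) < n_spk && tries < 100L * n_spk) {
    tries <- tries + 1L
    lin <- pouch_idx[sample.int(length(pouch_idx), 1L)]
    um <- (lin_to_zyx(lin, dims)[1, ] - 0.5) * vz
    if (nrow(acc)) {
      d2 <- rowSums(sweep(acc, 2, um, "-")^2)
      if (min(d2) < min_sep^2 && tries < 90L * n_spk) next
    }
    acc <- rbind(acc, um)
  }
  dimnames(acc) <- list(NULL, c("z", "y", "x"))
  acc
}

render_channels <- function(pouch, patch_cc, death, speckles, cfg) {
  dims <- dim(pouch)
  vz <- cfg$voxel_size
  bg <- cfg$background_level
  sig <- cfg$signal_level
  ch_list <- list()
  for (role in cfg$channels) {
    v <- switch(role,
      nuclei = bg + sig * render_nuclei(pouch, cfg),
      gfp = bg + sig * (patch_cc > 0L),
      stain = render_stain(pouch, cfg),
      stain2 = bg + render_spots(speckles, dims, vz, amplitude = 2 * sig,
                                 sigma = 0.5),
      death = bg + sig * death)
    if (cfg$noise_sd > 0) v <- v + rnorm(length(v), 0, cfg$noise_sd)
    v <- round(pmax(v, 0))
    ch_list[[role]] <- v
  }
  data <- array(unlist(ch_list, use.names = FALSE), dim = c(dims,
                                                            length(ch_list)))
  image_stack(data, vz, stats::setNames(seq_along(ch_list), names(ch_list)))
}

# nuclei as non-overlapping spheres on a jittered grid inside the pouch
render_nuclei <- function(pouch, cfg) {
  dims <- dim(pouch)
  vz <- cfg$voxel_size
  d <- cfg$cell_diameter
  sp <- 1.3 * d
  nuc <- array(FALSE, dims)
  offs <- sphere_offsets(d / 2 * 0.95, vz)
  centers <- expand.grid(
    z = seq(d / 2, dims[1] * vz[1] - d / 2, by = sp),
    y = seq(d / 2, dims[2] * vz[2] - d / 2, by = sp),
    x = seq(d / 2, dims[3] * vz[3] - d / 2, by = sp))
  if (!nrow(centers)) return(nuc)
  jit <- matrix(runif(3 * nrow(centers), -0.15 * d, 0.15 * d),
                ncol = 3)
  centers <- as.matrix(centers) + jit
  for (i in seq_len(nrow(centers))) {
    ctr <- pmin(pmax(floor(centers[i, ] / vz) + 1L, 1L), dims)
    lin <- ctr[1] + dims[1] * (ctr[2] - 1L) + dims[1] * dims[2] * (ctr[3] - 1L)
    if (!pouch[lin]) next
    nuc[offsets_at(offs, ctr, dims)] <- TRUE
  }
  nuc
}

# anterior pouch half at background+signal, posterior at fold change times
# that (so the posterior/anterior mean ratio equals the fold change exactly
# before noise); background outside the pouch
render_stain <- function(pouch, cfg) {
  dims <- dim(pouch)
  v <- array(cfg$background_level, dims)
  base <- cfg$background_level + cfg$signal_level
  xs <- which(apply(pouch, 3, any))
  mid <- if (length(xs)) (min(xs) + max(xs)) / 2 else dims[3] / 2
  xidx <- array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dims)
  v[pouch & xidx <= mid] <- base
  v[pouch & xidx > mid] <- base * cfg$pa_fold_change
  v
}

render_spots <- function(coords, dims, vz, amplitude, sigma) {
  v <- array(0, dims)
  if (!nrow(coords)) return(v)
  r <- 3 * sigma
  offs <- sphere_offsets(r, vz)
  off_um <- sweep(offs, 2, vz, "*")
  g <- amplitude * exp(-rowSums(off_um^2) / (2 * sigma^2))
  for (i in seq_len(nrow(coords))) {
    ctr <- pmin(pmax(as.integer(floor(coords[i, ] / vz)) + 1L, 1L), dims)
    z <- offs[, 1] + ctr[1]; y <- offs[, 2] + ctr[2]; x <- offs[, 3] + ctr[3]
    ok <- z >= 1L & z <= dims[1] & y >= 1L & y <= dims[2] &
      x >= 1L & x <= dims[3]
    lin <- (z + dims[1] * (y - 1L) + dims[1] * dims[2] * (x - 1L))[ok]
    v[lin] <- v[lin] + g[ok]
  }
  v
}

#' Simulate a cohort of wing discs
#'
#' Per-disc seeds are derived deterministically from the cohort seed
#' (`seed * 1009 + disc index`). `per_disc_jitter` is the relative standard
#' deviation of a lognormal factor applied independently to each effect
#' parameter (death rates, P/A fold change, speckle density) of each disc;
#' jittered rates are clamped to `[0, 1]`.
#'
#' @param config a [sim_config]; its `seed` is the cohort seed.
#' @param n_discs number of discs (>= 1).
#' @param per_disc_jitter relative sd of the per-disc effect jitter.
#' @return list of `list(stack, truth)`, one per disc.
#' @export
simulate_cohort <- function(config, n_discs, per_disc_jitter = 0) {
  validate_sim_config(config)
  stopifnot(n_discs >= 1L)
  eff <- c("death_rate_border", "death_rate_center", "death_rate_wt",
           "pa_fold_change", "speckle_density")
  factors <- with_rng_seed(config$seed, {
    if (per_disc_jitter > 0)
      matrix(rlnorm(n_discs * length(eff), 0, per_disc_jitter),
             nrow = n_discs, dimnames = list(NULL, eff))
    else matrix(1, n_discs, length(eff), dimnames = list(NULL, eff))
  })
  lapply(seq_len(n_discs), function(i) {
    cfg <- config
    cfg$seed <- as.integer((as.double(config$seed) * 1009 + i) %%
                             .Machine$integer.max)
    for (e in eff) cfg[[e]] <- cfg[[e]] * factors[i, e]
    for (e in c("death_rate_border", "death_rate_center", "death_rate_wt"))
      cfg[[e]] <- min(cfg[[e]], 1)
    simulate_disc(cfg)
  })
}

#' Simulate a ribosomal-protein log-fold-change table
#'
#' Gaussian log2 fold changes with class-specific means for `n_ssu`
#' small-subunit and `n_lsu` large-subunit proteins (defaults match the
#' detected counts of the motivating proteomics experiment: 29 SSU, 49 LSU).
#'
#' @param n_ssu,n_lsu number of proteins per class (>= 1).
#' @param mean_ssu,mean_lsu true class means (log2 units).
#' @param sd common within-class sd (log2 units, >= 0).
#' @param seed RNG seed.
#' @param comparison comparison label.
#' @return `list(table, truth)`: a [protein_table] and the true parameters.
#' @export
simulate_proteome <- function(n_ssu = 29L, n_lsu = 49L, mean_ssu = -0.35,
                              mean_lsu = 0.15, sd = 0.2, seed = 1L,
                              comparison = "mutant_vs_wt") {
  stopifnot(n_ssu >= 1L, n_lsu >= 1L, sd >= 0)
  tab <- with_rng_seed(seed, {
    data.frame(
      protein_id = c(sprintf("P_SSU_%02d", seq_len(n_ssu)),
                     sprintf("P_LSU_%02d", seq_len(n_lsu))),
      gene_symbol = c(sprintf("RpS%d", seq_len(n_ssu)),
                      sprintf("RpL%d", seq_len(n_lsu))),
      lfc = c(rnorm(n_ssu, mean_ssu, sd), rnorm(n_lsu, mean_lsu, sd)))
  })
  list(table = protein_table(tab, comparison = comparison),
       truth = list(mean_ssu = mean_ssu, mean_lsu = mean_lsu, sd = sd,
                    n_ssu = n_ssu, n_lsu = n_lsu, seed = seed))
}
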