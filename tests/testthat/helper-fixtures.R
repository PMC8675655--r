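# Shared fixtures and independent brute-force oracles.

# small, fast disc configuration used across tests (one clone large enough
# to own a center territory at band width 8 um)
small_cfg <- function(seed = 1, ...) {
  args <- list(shape = c(10L, 80L, 80L), voxel_size = c(1, 0.9, 0.9),
               n_patches = 1L, target_coverage = 0.4, cell_diameter = 4,
               death_rate_border = 0.10, death_rate_center = 0.05,
               death_rate_wt = 0.02, noise_sd = 10,
               channels = c("gfp", "death"), seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# brute-force two-sided exact p for the signed-rank test: enumerate every
# sign assignment and recompute the statistic from first principles
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# brute-force two-sided exact p for the U test: enumerate every split of the
# pooled values and count x > y pairs directly
oracle_mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(xi) sum(outer(pooled[xi], pooled[-xi], ">")) +
    0.5 * sum(outer(pooled[xi], pooled[-xi], "=="))
  u_obs <- u_of(seq_len(n1))
  splits <- combn(n1 + n2, n1)
  u_all <- apply(splits, 2, u_of)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# render binary spheres (physical radius um) into a fresh array
render_sphere_array <- function(dims, voxel_size, centers_um, radius_um) {
  a <- array(0, dims)
  zc <- (seq_len(dims[1]) - 0.5) * voxel_size[1]
  yc <- (seq_len(dims[2]) - 0.5) * voxel_size[2]
  xc <- (seq_len(dims[3]) - 0.5) * voxel_size[3]
  for (i in seq_len(nrow(centers_um))) {
    d2 <- outer(outer((zc - centers_um[i, 1])^2, (yc - centers_um[i, 2])^2,
                      "+"), (xc - centers_um[i, 3])^2, "+")
    a[d2 <= radius_um^2] <- 1
  }
  a
}

# in-plane disk mask (single- or multi-section)
disk_mask <- function(n = 120L, radius = 50, nz = 1L, voxel_size = c(1, 1, 1)) {
  yc <- (seq_len(n) - 0.5) * voxel_size[2]
  xc <- (seq_len(n) - 0.5) * voxel_size[3]
  ctr <- n * voxel_size[2] / 2
  sect <- outer((yc - ctr)^2, (xc - ctr)^2, "+") <= radius^2
  lab <- array(0L, c(nz, n, n))
  for (z in seq_len(nz)) lab[z, , ] <- sect * 1L
  label_mask(lab, voxel_size)
}
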