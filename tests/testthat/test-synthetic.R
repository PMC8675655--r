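test_that("identical config and seed give bit-identical output", {
  cfg <- small_cfg(seed = 42, speckle_density = 1,
                   channels = c("gfp", "stain", "stain2", "death"))
  a <- simulate_disc(cfg)
  b <- simulate_disc(cfg)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$patch_mask$labels, b$truth$patch_mask$labels)
  expect_identical(a$truth$speckle_coords, b$truth$speckle_coords)
  d <- simulate_disc(small_cfg(seed = 43))
  expect_false(identical(a$stack$data, d$stack$data))
})

test_that("zero target coverage yields an empty clone compartment", {
  d <- simulate_disc(small_cfg(seed = 1, target_coverage = 0, noise_sd = 0))
  expect_equal(d$truth$realized_coverage, 0)
  expect_equal(sum(d$truth$patch_mask$labels), 0L)
})

test_that("ground truth is self-consistent with its own masks", {
  d <- simulate_disc(small_cfg(seed = 3))
  tr <- d$truth
  pouch <- tr$pouch_mask$labels > 0L
  expect_equal(tr$realized_coverage,
               100 * sum(tr$patch_mask$labels > 0L) / sum(pouch))
  terr <- tr$territory_map$territory
  dm <- tr$death_mask$labels > 0L
  expect_equal(tr$realized_death_density[["border"]],
               100 * sum(dm & terr == 1L) / sum(terr == 1L))
  expect_equal(tr$realized_death_density[["center"]],
               100 * sum(dm & terr == 2L) / sum(terr == 2L))
  # territories live exactly on the patch
  expect_true(all((terr > 0L) == (tr$patch_mask$labels > 0L)))
})

test_that("realized death densities honor the configured rates", {
  # equal rates: no net spill across the border/center line, every
  # territory fills to its target almost exactly
  for (s in 1:2) {
    d <- simulate_disc(small_cfg(seed = s, death_rate_border = 0.05))
    rd <- d$truth$realized_death_density
    expect_lt(abs(rd[["border"]] - 5), 0.6)
    expect_lt(abs(rd[["center"]] - 5), 0.6)
    expect_lt(abs(rd[["exterior_wt"]] - 2), 0.6)
  }
  # doubled border rate: border and wild-type stay on target; the center
  # receives genuine spill from border blobs straddling the analysis line,
  # so it can only sit at or above its own target, below the border
  for (s in 1:3) {
    d <- simulate_disc(small_cfg(seed = s))
    rd <- d$truth$realized_death_density
    expect_lt(abs(rd[["border"]] - 10), 1)
    expect_gte(rd[["center"]], 4.5)
    expect_lt(rd[["center"]], rd[["border"]])
    expect_lt(abs(rd[["exterior_wt"]] - 2), 0.6)
  }
})

test_that("raising the border death rate strictly raises realized density", {
  lo <- simulate_disc(small_cfg(seed = 9, death_rate_border = 0.05))
  hi <- simulate_disc(small_cfg(seed = 9, death_rate_border = 0.15))
  expect_gt(hi$truth$realized_death_density[["border"]],
            lo$truth$realized_death_density[["border"]])
})

test_that("posterior stain mean is the configured multiple of the anterior", {
  cfg <- small_cfg(seed = 2, pa_fold_change = 1.8, noise_sd = 0,
                   channels = "stain")
  d <- simulate_disc(cfg)
  comps <- split_compartments(d$truth$pouch_mask)
  expect_equal(pa_ratio(d$stack, "stain", comps), 1.8, tolerance = 0.01)
})

test_that("unreachable coverage and invalid configs are rejected", {
  expect_error(simulate_disc(small_cfg(n_patches = 0L, target_coverage = 0.3)),
               "unreachable")
  expect_error(sim_config(death_rate_border = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(target_coverage = -0.1), "\\[0, 1\\]")
  expect_error(sim_config(pa_fold_change = 0), "> 0")
  expect_error(sim_config(voxel_size = c(1, 0, 0.5)), "> 0")
})

test_that("cohorts derive seeds deterministically and jitter effects", {
  cfg <- small_cfg(seed = 5)
  cohort <- simulate_cohort(cfg, 3, per_disc_jitter = 0)
  # without jitter every disc carries the same effect parameters
  rates <- vapply(cohort, function(d) d$truth$config$death_rate_border,
                  numeric(1))
  expect_true(all(rates == 0.10))
  # a singleton cohort equals simulate_disc at the derived seed
  single <- simulate_cohort(cfg, 1)
  cfg1 <- cfg
  cfg1$seed <- as.integer((5 * 1009 + 1) %% .Machine$integer.max)
  expect_identical(single[[1]]$stack$data, simulate_disc(cfg1)$stack$data)
  # jitter varies parameters but reproducibly
  j1 <- simulate_cohort(cfg, 3, per_disc_jitter = 0.2)
  j2 <- simulate_cohort(cfg, 3, per_disc_jitter = 0.2)
  rj <- vapply(j1, function(d) d$truth$config$death_rate_border, numeric(1))
  expect_gt(stats::sd(rj), 0)
  expect_identical(rj, vapply(j2, function(d) d$truth$config$death_rate_border,
                              numeric(1)))
})

test_that("a doubled border/center rate ratio orders every disc correctly", {
  cfg <- small_cfg(seed = 17, death_rate_border = 0.10,
                   death_rate_center = 0.05)
  cohort <- simulate_cohort(cfg, 13, per_disc_jitter = 0)
  for (d in cohort) {
    rd <- d$truth$realized_death_density
    expect_gt(rd[["border"]], rd[["center"]])
  }
})

test_that("proteome tables have the requested size and exact sd-zero means", {
  p <- simulate_proteome(n_ssu = 29, n_lsu = 49, seed = 1)
  expect_equal(nrow(p$table), 78)
  expect_equal(sum(p$table$subunit_class == "SSU"), 29)
  expect_equal(sum(p$table$subunit_class == "LSU"), 49)
  p0 <- simulate_proteome(n_ssu = 5, n_lsu = 5, mean_ssu = -0.4,
                          mean_lsu = 0.2, sd = 0, seed = 2)
  expect_true(all(p0$table$lfc[p0$table$subunit_class == "SSU"] == -0.4))
  expect_true(all(p0$table$lfc[p0$table$subunit_class == "LSU"] == 0.2))
})

test_that("proteome sample means obey the CLT bound across seeds", {
  sd <- 0.2; n <- 29; mu <- -0.35
  for (s in 1:100) {
    p <- simulate_proteome(n_ssu = n, n_lsu = 2, mean_ssu = mu, sd = sd,
                           seed = s)
    m <- mean(p$table$lfc[p$table$subunit_class == "SSU"])
    expect_lt(abs(m - mu), 4 * sd / sqrt(n))
  }
})
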