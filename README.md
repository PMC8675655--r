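# discquant

Volume-based quantification of cell-competition readouts in *Drosophila*
wing imaginal disc confocal z-stacks.

## The problem

In mosaic wing discs, "loser" cells (e.g. ribosomal-protein heterozygotes or
cells under proteotoxic stress) are eliminated by their wild-type
neighbours. Because the killing is contact-dependent, apoptosis concentrates
at the **border** of a marked clone rather than its **center**. Detecting
that signature requires segmenting clones in 3-D, splitting each clone into
a border band and a center territory, and normalizing apoptosis-marker
volume to each territory's volume — per disc, across a cohort, with
small-sample nonparametric statistics. `discquant` provides that pipeline,
plus the companion readouts used in such studies: pouch coverage,
posterior/anterior (P/A) compartment intensity ratios, clone-relative
intensity, puncta (speckle) density, and a ribosomal SSU/LSU
stoichiometry summary for proteomics tables.

For a disc `i` with death mask `D`, territory `T ∈ {border, center}`:

    death density(i, T) = 100 · |D ∩ T| / |T|        (percent of volume)

with the border defined as clone tissue within 2 cell diameters of the
clone perimeter (per z-section Euclidean distance transform, physical
spacing). Border and center densities of a disc form one pair; cohorts are
compared with the **exact** two-sided Wilcoxon matched-pairs signed-rank
test (enumeration for n ≤ 15), unpaired designs with the exact
Mann–Whitney U test (enumeration for n₁+n₂ ≤ 12). No multiplicity
correction is applied.

A synthetic wing-disc generator with voxel-level ground truth
(`simulate_disc` / `simulate_cohort` / `simulate_proteome`) makes every
stage testable without microscope data.

## Worked example

```r
library(discquant)

cfg <- sim_config(shape = c(10L, 80L, 80L), voxel_size = c(1, 0.9, 0.9),
                  n_patches = 1L, target_coverage = 0.4, cell_diameter = 4,
                  death_rate_border = 0.10, death_rate_center = 0.05,
                  death_rate_wt = 0.02, noise_sd = 10,
                  channels = c("gfp", "death"), seed = 1)
cohort <- simulate_cohort(cfg, 8, per_disc_jitter = 0.2)
rt <- run_mosaic_pipeline(cohort, list(cell_diameter = 4, min_volume = 33))
rt
#> <results_table> 32 quantification row(s), 1 test row(s)
#>             test_name            metric scope_a scope_b statistic  p_value n
#>  wilcoxon_signed_rank death_density_pct  border  center        36 0.007812 8
#>  method
#>   exact
head(rt$quant, 4)
#>   disc_id            metric       scope     value   units flag
#> 1 disc_01      coverage_pct       pouch 39.980954 percent
#> 2 disc_01 death_density_pct      border  8.793517 percent
#> 3 disc_01 death_density_pct      center  6.473724 percent
#> 4 disc_01 death_density_pct exterior_wt  2.045929 percent
```

Eight discs were simulated with a border death rate twice the center rate
(10% vs 5% of territory volume) and 20% per-disc jitter. The pipeline
segments each clone, recovers ~40% pouch coverage and border/center death
densities close to the generating rates, and the paired exact Wilcoxon
rejects at p = 0.0078: border exceeded center in all eight discs
(statistic 36 = 8·9/2, the maximum), giving the smallest two-sided p the
enumeration over 2^8 sign patterns allows. `write_results(rt, "out/run")` writes the long-format CSV,
the test rows and a JSON summary (plus an optional scatter plot with a
median line per group).

The proteomics stage summarizes a log2 fold-change table:

```r
p <- simulate_proteome(seed = 1)   # 29 SSU / 49 LSU, means -0.35 / +0.15
summarize_imbalance(p$table)
#> Ribosomal subunit imbalance summary (mutant_vs_wt; t CI)
#>  subunit_class  n mean_lfc ci_lower ci_upper p_vs_zero
#>            SSU 29  -0.3358  -0.4072  -0.2644 2.702e-06
#>            LSU 49   0.1784   0.1267   0.2301 1.424e-07
#> SSU vs LSU (two-sided Mann-Whitney): p = 8.391e-13
```

A thin command-line front end over the same functions lives at
`inst/cli/discquant.R` (`simulate`, `mosaic`, `compartment`, `proteome`
subcommands with a YAML config).

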