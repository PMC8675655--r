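---
title: "Quantifying clone competition readouts in wing disc stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying clone competition readouts in wing disc stacks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discquant)
```

## What the package measures

Cell competition in mosaic *Drosophila* wing imaginal discs eliminates viable
"loser" cells preferentially where they touch fitter neighbours. The
quantitative signature is spatial: apoptosis (cleaved dcp1) concentrates at
the *border* of a genetically marked clone rather than at its *center*.
`discquant` reimplements, as tested R code, the volume-based quantification
scheme used in such studies:

1. **Clone segmentation.** The GFP clone channel is smoothed with an
   anisotropy-aware Gaussian (sigma given in micrometres and converted to
   voxels per axis, because confocal stacks have dz typically 1 um but much
   finer in-plane sampling), thresholded by Otsu's method *within the pouch
   ROI*, labeled by 3-D connected components (26-connectivity), and filtered
   by a minimum component volume (default: one nuclear volume, so
   single-cell clones survive while debris does not).
2. **Border/center decomposition.** The border is the band of clone tissue
   within `n_cell_diameters` (default 2) cell diameters of the clone
   perimeter. Distances are computed per z-section with an exact Euclidean
   distance transform on the physical in-plane spacing; everything deeper is
   the center. Border and center partition the clone voxels exactly, by
   construction, and each labeled clone is decomposed independently. A 3-D
   distance mode is available behind the `mode` flag; the per-section
   convention is the default because the border definition is a perimeter
   notion and because a 1-um z-step makes 3-D distances strongly
   anisotropic.
3. **Death density.** `100 * |death mask ∩ territory| / |territory|`, i.e.
   the percentage of each territory's volume that is death-marker positive.
   The border and center values of one disc form a natural pair, analysed
   cohort-wide with the exact Wilcoxon matched-pairs signed-rank test.
4. **Compartment ratios.** For half-disc (posterior-driver) experiments,
   readouts are posterior/anterior ratios of mean voxel intensity over the
   pouch halves. Means are taken over the full masked volume, not over a
   projection, consistent with the volume normalization used for death
   densities. No background is subtracted by default — ratios of raw
   intensities are reported, and the documentation notes that a P/A ratio
   is invariant to multiplicative rescaling but *not* to additive offsets.
5. **Speckle density.** Ubiquitin-conjugate (FK2-type) puncta are detected
   by multiscale scale-normalized Laplacian-of-Gaussian filtering over a
   physical diameter range, per section, followed by 3-D non-maximum
   suppression; density is spots per 1000 um^3 of the reference mask.
6. **Ribosomal subunit stoichiometry.** From a per-protein log2
   fold-change table, proteins are classified as cytoplasmic SSU (RpS*,
   RpSA) or LSU (RpL*) — mitochondrial mRpS*/mRpL* are excluded — and each
   class is summarized by its mean, a Student-t 95% confidence interval, a
   two-sided one-sample Wilcoxon signed-rank test against 0, plus a
   two-sided Mann-Whitney U test between the classes.

All per-disc metrics carry the convention that one wing disc (or one disc
compartment) is one statistical observation; no multiple-comparison
correction is applied anywhere, matching the univariate analysis style of
the experiments this tooling supports.

## The statistical toolkit

The three tests are implemented with exact small-sample null distributions:
the signed-rank statistic by enumeration of all `2^n` sign assignments for
`n <= 15`, and the U statistic by enumeration of all `choose(n1+n2, n1)`
rank splits for `n1 + n2 <= 12`. Those bounds keep enumeration well under a
second; beyond them — or in the presence of ties, which exact enumeration
refuses — a tie-corrected normal approximation with continuity correction
is used, and the `method` field of the result records which path was taken.
Pairs with zero difference are dropped (the standard Wilcoxon convention)
and the dropped count is reported. The exact paths reproduce
`stats::wilcox.test` p-values to machine precision in the test suite, and a
brute-force enumeration oracle written independently in the tests checks
every sign pattern exhaustively for `n <= 8`.

## The synthetic wing disc

Because the package's claims are about recovering known quantities, it
ships a generator (`simulate_disc`, `simulate_cohort`, `simulate_proteome`)
whose ground truth is the recovery oracle for every stage:

* **Pouch**: an ellipsoid, by default spanning 42% of each physical extent
  of a 20 x 80 x 80 um field (z-step 1 um, in-plane 0.5 um — the axial step
  matches common confocal acquisition; the in-plane pixel size is a free
  parameter since objectives and zoom vary).
* **Clones**: unions of overlapping spheres grown from random seed points
  until a target fraction of the pouch volume is covered; the last sphere
  is trimmed voxel-by-voxel so realized coverage lands on the target
  exactly. Merged patches are relabeled as connected components, mimicking
  irregular clone outlines without simulating growth dynamics.
* **Death**: blobs of roughly one nuclear volume placed until each
  territory's configured volume fraction is reached (the final blob is
  trimmed so the realized fraction lands on the target). Blobs respect the
  clone (genotype) boundary but straddle the border/center line freely —
  that line is an analysis construct, not a barrier to apoptosis — which
  keeps death density spatially uniform across the line. Because blobs are
  clipped at the genotype boundary, centres are drawn from each territory
  *dilated by one blob radius across that boundary* (an edge-corrected
  sampling scheme): otherwise voxels along the boundary would see only a
  half-sphere of candidate centres, producing a depleted shell there and a
  compensating enrichment in the territory interior. Earlier designs that
  clipped blobs at the territory line, or sampled centres from the bare
  territory, produced exactly such shells and a measurable artefactual
  shift in the border-minus-center null.
* **Intensity model**: `background + signal * mask + Gaussian noise`,
  clipped at zero and quantized to integer counts as a detector would. The
  reporter channel is rendered so the posterior pouch half's mean is
  exactly `pa_fold_change` times the anterior mean before noise. No
  point-spread-function optics and no autofluorescence gradients are
  modelled: the generator validates mask recovery, volume bookkeeping and
  ratio arithmetic, not deconvolution. Passing tests therefore demonstrate
  correctness of the measurement pipeline, not robustness to every optical
  artefact of real microscopy.
* **Speckles**: diffraction-limited Gaussian spots (sigma 0.5 um) at a
  controllable density per 1000 um^3 of pouch, placed at least 2 um apart.
* **Cohorts**: per-disc seeds are derived as `seed * 1009 + disc_index`,
  so a cohort is reproducible from one integer; `per_disc_jitter` is the
  relative standard deviation of a lognormal factor applied independently
  to each disc's effect parameters, emulating disc-to-disc biological
  variability.
* **Proteome**: Gaussian log2 fold changes with class-specific means; the
  default class sizes (29 SSU, 49 LSU) match the detected-protein counts of
  the motivating mass-spectrometry comparison.

## Numerical choices and degenerate inputs

* Otsu thresholding operates on ROI-restricted intensities with 256
  histogram levels; a constant channel yields an infinite threshold, i.e.
  an empty segmentation rather than arbitrary foreground. Thresholds can
  be overridden per call for channels where Otsu's bimodality assumption
  fails.
* The Euclidean distance transform is the exact lower-envelope algorithm
  with per-axis physical spacing, so anisotropic grids need no resampling.
  It is cross-checked against an independent isotropic 2-D implementation
  (`EBImage::distmap`) in the tests.
* Spots detected on neighbouring z-sections are the same physical speckle;
  non-maximum suppression merges detections within
  `max(min_diameter, 1.5 * dz)`.
* Nuclear cross-sections sampled at random heights underestimate the true
  diameter (median chord is `sqrt(3)/2` of it); `estimate_cell_diameter`
  applies the inverse factor and falls back to a configured default, with
  a warning, when fewer than 20 nuclei are found.
* A disc whose clone is all border (thinner than the band) has an empty
  center: its death density is `NA`, flagged, excluded from the paired
  cohort test, and noted in the run log.
* An empty clone mask, an empty ROI, an all-zero difference vector and a
  degenerate (zero-mean) anterior compartment all raise errors naming the
  problem rather than propagating NaNs.

## Problem sizes used by the test suite

Simulation-heavy checks (detection power and size of the paired
border-vs-center test; the unit-fold-change null of the compartment
pipeline) run on 10 x 80 x 80-voxel discs at (1, 0.9, 0.9) um spacing with
a single large clone at 40% coverage, 200 seeded cohorts of 13 (mosaic) or
10 (compartment) discs per condition. These sizes were chosen so that a
clone comfortably contains a center territory at the default two-cell
border band and the whole suite runs on a laptop-class single core;
geometry recovery itself is validated on full-size default discs. The
compartment-mode simulations set coverage and death rates to zero, since in
those experiments the posterior compartment itself is the genotype region
and no clones exist.

## Known limitations

* Compartment masks are user-supplied (or the generator's midline split);
  inferring the anterior/posterior boundary from a marker channel is out of
  scope.
* Whether intensity readouts of the original macros were volume means or
  projections is not recorded in the protocols this package follows; the
  volume-mean convention is used consistently and stated here as a choice.
* Otsu-within-ROI assumes a bimodal intensity histogram inside the ROI;
  discs with no positive signal at all require the fixed-threshold
  override (a uniform channel is handled, but a pure-noise channel is
  Otsu's pathological case).
* TIFF I/O stores 16-bit samples; integer-valued stacks up to 65535 counts
  round-trip exactly, higher-precision data are scaled and quantized.
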