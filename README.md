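# wmhperf

Perfusion analysis of white matter hyperintensities (WMH) and their
penumbra.

## The problem

White matter hyperintensities — bright lesions on FLAIR MRI — are a core
imaging marker of cerebral small-vessel disease and brain aging. The tissue
immediately surrounding a lesion (its *penumbra*) is at elevated risk of
converting to WMH, and reduced cerebral blood flow (CBF) is a candidate
mechanism and biomarker for that conversion. Testing this requires a chain
of image-analysis steps that are easy to get subtly wrong: distance
transforms in physical units on anisotropic voxel grids, compartment
boundaries measured from the ventricular surface, morphological shells
around hundreds of individual lesions, longitudinal lesion tracking, and
repeated-measures statistics.

`wmhperf` implements that chain as a tested R package, for neuroimaging
researchers who have co-registered anatomical masks (ventricles, GM, WM,
WMH) and ASL perfusion data — or who want to validate such a pipeline
before trusting it on real data.

## What it computes

For each subject and session:

- **Ventricular distance bands.** An exact Euclidean distance transform in
  millimetres (anisotropy-aware, voxel-center semantics) from the
  ventricular mask partitions white matter into juxtaventricular
  (d ≤ 3 mm), periventricular (3 < d ≤ 10 mm) and deep (d > 10 mm)
  compartments.
- **Penumbra shells and NAWM.** WM voxels within 4 mm and 8 mm of any WMH
  voxel form the P4/P8 penumbra masks (cumulative by default, annular
  optional); normal-appearing white matter is WM minus WMH minus P8.
- **CBF quantification and normalization.** Control/label ASL series are
  reduced by (surround) subtraction and quantified with the consensus
  single-compartment pulsed-ASL closed form,
  CBF = 6000·λ·ΔM·exp(TI/T1b) / (2·α·TI1·M0), then divided by the
  subject's total-brain mean to give relative CBF (rCBF); precomputed CBF
  volumes can be supplied instead.
- **Lesion tracking.** Individual lesions are 26-connected components
  (≥ 10 mm³); follow-up lesions are matched to baseline by voxel overlap
  and classified *growing* (> 10 % volume increase), *stagnant* (< 10 %
  change) or *new* (follow-up only), with baseline perfusion back-projected
  under new lesions' footprints.
- **Statistics.** Tidy ROI tables feed linear mixed-effects models
  (subject random intercepts): rCBF on tissue and location; rCBF on
  lesion volume × location; and lesion-level category × session models per
  location and tissue, with Benjamini–Hochberg-corrected contrast tables.

A seeded synthetic cohort generator (`cohort_spec()`, `simulate_subject()`,
`emit_cohort()`) builds fully labeled two-session phantoms — ellipsoidal
anatomy, planted lesions with known trajectories, perfusion painted from
known tissue factors — so every stage is testable against ground truth
without any MRI download. The anti-circularity rule throughout: the
generator paints using its own labels, while the pipeline re-derives every
mask from the raw volumes.

## Worked example

```r
library(wmhperf)

spec <- cohort_spec(n_subjects = 4, n_longitudinal = 2, seed = 42)
res  <- run_cohort(spec)          # simulate + analyze, in memory
sm   <- summarize_cohort(res$roi)
sm[sm$region == "whole", ]
#> # A tibble: 6 × 5
#>   tissue region     n mean_rcbf       sem
#>   <chr>  <chr>  <int>     <dbl>     <dbl>
#> 1 GM     whole      4     1.31  0.0000214
#> 2 NAWM   whole      4     1.07  0.0000364
#> 3 P4     whole      4     0.845 0.000357
#> 4 P8     whole      4     0.880 0.000156
#> 5 WM     whole      4     1.04  0.00130
#> 6 WMH    whole      4     0.815 0.00118
```

Each row is the cohort mean (± SEM) of per-subject mean rCBF in that
compartment: gray matter is the best-perfused tissue (≈ 1.31 × the brain
mean), lesions the worst (≈ 0.81), and the 4- and 8-mm penumbra shells sit
in between, recovering the generator's painted factors through
independently reconstructed geometry. Note `WM` (the full white-matter
mask, diluted by lesions and penumbra, ≈ 1.04) is reported separately from
`NAWM` (≈ 1.07).

Mixed-model layer, on a simulated volume-by-location table:

```r
tbl <- simulate_volume_location_table(n_subjects = 300, seed = 42)
fit <- fit_volume_location_model(tbl)   # deep region as reference
fit[, c("term", "estimate", "se", "t", "p")]
#> # A tibble: 6 × 5
#>   term                         estimate      se      t        p
#> 1 (Intercept)                   -0.116  0.00807 -14.4  1.28e-40
#> 2 log_rvol_centered             -0.0536 0.00671  -8.00 4.97e-15
#> 3 locationJV                    -0.110  0.00813 -13.6  8.87e-37
#> 4 locationPV                    -0.108  0.00811 -13.3  2.35e-35
#> 5 log_rvol_centered:locationJV  -0.233  0.00969 -24.0  8.61e-95
#> 6 log_rvol_centered:locationPV  -0.182  0.00917 -19.9  1.25e-70
```

The interaction terms are the location-specific differences in the slope
of log rCBF on centered log relative lesion volume, relative to the deep
region — here recovering the planted simulation values (−0.2369 and
−0.1897) within sampling error.

A thin command-line wrapper (`inst/cli/wmhperf.R`) exposes
`simulate` / `analyze` / `report` / `run_all` subcommands over a YAML
config for running the same stages against a cohort directory on disk.

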