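---
title: "Methods: distance-banded WMH perfusion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-banded WMH perfusion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`wmhperf`: the quantities the pipeline computes, the assumptions under
which they are valid, the defaults and why they were chosen, and what the
synthetic-cohort tests do and do not demonstrate about real data.

## The measurement model

The pipeline quantifies cerebral perfusion inside white matter
hyperintensities (WMH), in their surrounding penumbra, and in
normal-appearing white matter (NAWM), stratified by distance from the
ventricular surface. Its primitive quantities are:

**Ventricular distance.** For every voxel, the Euclidean distance in
millimetres from its center to the center of the nearest ventricular
voxel, computed by a separable lower-envelope distance transform
(`src/kernels.cpp`) that weights each axis by its voxel dimension. We use
voxel-center-to-voxel-center semantics rather than distance to an
interpolated sub-voxel surface: this is the standard discrete EDT, it is
exactly testable against a brute-force all-pairs oracle, and it makes the
3/10 mm thresholds interpretable (a voxel whose center is within 3 mm of
some ventricle-voxel center is juxtaventricular). No resampling is
performed; anisotropy (the default grid is 1 × 1 × 2 mm) is handled in
physical units everywhere.

**Bands.** White matter (plus WMH) is partitioned as juxtaventricular
(JV, d ≤ 3 mm), periventricular (PV, 3 < d ≤ 10 mm) and deep
(D, d > 10 mm). The band edges are closed on the inner side, so at
exactly 3 mm a voxel is JV and at exactly 10 mm it is PV. Descriptions of
these compartments conflict at the boundaries ("within 3 mm", "10 mm or
further"); closing inner edges is the unique convention that keeps the
three bands an exact partition, and it is asserted as an invariant in the
test suite.

**Penumbra shells.** P4 and P8 are the WM voxels whose distance to the
nearest WMH voxel is in (0, 4] and (0, 8] mm respectively, with all WMH
voxels excluded. The default is therefore *cumulative* (P4 ⊆ P8), reading
"within 8 mm" literally; an *annular* mode (4–8 mm only) is provided
because published penumbra statistics are sometimes reported that way.
Lesion-specific shells additionally exclude the voxels of every other
lesion, so adjacent lesions never contaminate each other's penumbra.

**NAWM.** WM minus WMH minus the 8-mm (cumulative) penumbra. Banded NAWM
is the intersection with the band partition.

**CBF and rCBF.** When a raw pulsed-ASL series is supplied, the
perfusion-weighted signal ΔM is formed by control–label subtraction
(pairwise by default; a surround variant subtracts the mean of the two
temporally adjacent label volumes from each control, cancelling linear
drift to first order — the exact subtraction scheme used by scanners and
published pipelines varies, so both are provided and the choice is a
flag). CBF in ml/100g/min follows the consensus single-compartment
QUIPSS II closed form

$$\mathrm{CBF} = \frac{6000\,\lambda\,\Delta M\,e^{TI/T_{1b}}}{2\,\alpha\,TI_1\,M_0}$$

with defaults λ = 0.9 ml/g, α = 0.98, T1b = 1650 ms, TI = 1800 ms,
TI1 = 1650 ms. A deterministic closed form (rather than variational-Bayes
inference) is used deliberately: the listed constants fully determine it,
it is linear in ΔM and 1/M0 (property-tested), and it is checkable on a
desk calculator (ΔM/M0 = 0.01 gives ≈ 49.7 ml/100g/min). Voxels with M0
at or below 10 % of its robust (99th-percentile) maximum are masked to
guard against division blow-ups.

Relative CBF divides by the mean CBF over the **whole brain mask,
including CSF and ventricles**. This choice matters and is deliberate:
empirical rCBF values for both GM (≈ 1.3) and white matter (≈ 1.07) above
1 are only arithmetically possible if the normalizer includes a
low-perfusion compartment. The rCBF brain-mask mean is exactly 1 for
every subject, which the suite asserts to 1e-12.

**A note on "WM" vs "NAWM".** Cross-sectional white-matter perfusion is
conventionally reported for normal-appearing WM. The ROI table therefore
exposes both a `WM` tissue (the full WM mask, diluted by lesions and
penumbra) and a `NAWM` tissue; the ≈ 1.067 figure corresponds to NAWM.
Consumers should be explicit about which they mean.

## Lesion tracking

A lesion is a maximal set of WMH voxels connected under 26-connectivity
("three-dimensional voxel neighborhood" is ambiguous between 6, 18 and
26; the most inclusive reading is the default and the others are
selectable — the suite verifies both against a flood-fill oracle).
Clusters below 10 mm³ are excluded, strictly: exactly 10 mm³ is kept.

Matching across sessions is by voxel overlap (≥ 1 shared voxel by
default; a minimum-overlap option exists). When one follow-up cluster
overlaps several baseline clusters (a merge), the largest overlap wins
and ties go to the lower baseline id — a deterministic rule verified
against an exhaustive pairwise-overlap table. The growth fraction
(V_fu − V_bl)/V_bl classifies trajectories: strictly greater than +10 %
is *growing*, at or below −10 % is *shrinking*, everything between
(including exactly +10 %) is *stagnant*; follow-up-only clusters are
*new* and baseline-only clusters *vanished*. Shrinking and vanished
lesions are first-class outputs but excluded from the three-category
longitudinal models, matching the convention that analyses cover
stagnant/growing/new only. A follow-up cluster whose baseline partner
fell below the volume floor surfaces as *new* (the floor is applied per
session, before matching).

Lesion bands use the **centroid rule** by default — the band of the
ventricular distance at the cluster centroid — with a majority-vote
alternative; both labels, the centroid distance (kept as a continuous
covariate for the distance-gradient model) and a disagreement flag are
always recorded, because elongated lesions can span bands.

For new lesions, baseline perfusion is *back-projected*: the baseline
rCBF volume is sampled under the follow-up lesion footprint (and its
penumbra), measuring the pre-lesional tissue. Footprint voxels outside
the baseline brain mask are excluded and counted; a fully masked
footprint yields a missing-value record, not an error.

## Statistical models

All models are linear mixed-effects fits (lme4, REML) with per-subject
random intercepts, on natural-log-transformed rCBF; confidence intervals
are Wald (estimate ± 1.96 SE) and p-values use Satterthwaite degrees of
freedom (lmerTest). Natural log is a convention choice (the base is
configurable and recorded); centering of log relative lesion volume
subtracts the mean log WMH rVol over the analysis set, computed once and
stored with the output.

- *Tissue–location model*: `log rCBF ~ tissue + location + (1 | subject)`
  with NAWM and JV as default references, so the `locationD` coefficient
  is the deep-vs-JV contrast.
- *Volume–location model*:
  `log rCBF ~ centered log rVol × location + (1 | subject)` with deep as
  reference, so the JV/PV interaction terms are slope differences
  relative to deep, and per-location slopes are base + interaction. The
  printed "interaction" coefficients in the literature this mirrors are
  interpreted as D-referenced interactions, not region-specific slopes;
  both are returned (`attr(fit, "slopes")`).
- *Lesion longitudinal models*: per location × tissue,
  `log rCBF ~ category × session + (1 | subject)` with stagnant/baseline
  references, so `categorygrowing` and `categorynew` are baseline mean
  differences vs stagnant. Categories with fewer than two lesions are
  reported non-estimable rather than silently absorbed.
- *Multiplicity*: Benjamini–Hochberg within each category's family of 9
  location × tissue contrasts (the family definition is configurable and
  logged; Holm and Bonferroni are selectable) — the correction method
  behind published corrected p-values is typically unstated, so the
  default is the least conservative standard choice.

On balanced noiseless designs the mixed-model estimates coincide with
ordinary least squares (asserted to 1e-6), and singular random-effect
fits are flagged in the result's diagnostics rather than hidden.

## The synthetic cohort generator

The generator exists so that every stage above can be tested against
known truth. It emulates: FLAIR-space grids (default 96 × 96 × 48 voxels
at 1 × 1 × 2 mm), a connected central ventricular system inside a WM
core, a GM shell and an outer sulcal-CSF shell (nested ellipsoids with
per-subject jitter); WMH lesions planted as connected blobs grown by
geodesic accretion inside WM, cycling through the three bands; two
sessions with planted stagnant/growing/new trajectories (growing lesions
dilate geodesically inside WM to a sampled volume ratio, achieved within
2 %); and perfusion volumes painted as
nominal brain CBF × tissue factor × (1 + Gaussian noise).

Key calibrations:

- CSF/ventricle voxels are painted at the single value that makes the
  noise-free brain-mask mean equal the nominal brain CBF *exactly* (one
  linear equation; a negative solution raises an error telling the user
  the tissue factors are inconsistent with a unit normalizer).
- The penumbra is painted as a two-step radial profile: the P4 factor on
  0–4 mm and a 4–8 mm annulus value solved per volume so the cumulative
  0–8 mm mean equals the requested P8 factor — making both cumulative
  and annular read-outs testable.
- Default demographics (age 77 ± 7.9, MMSE 28 ± 2.4, 199/300 female,
  inter-scan interval 1.9 ± 0.7 y) and cohort sizes (300 subjects, 90
  longitudinal) reflect a typical elderly aging cohort; tissue factors
  default to the whole-tissue set (GM 1.315, NAWM 1.067, WMH 0.814,
  P4 0.845, P8 0.880) with a banded alternative (WMH 0.495/0.592/0.892,
  NAWM 0.816/0.973/1.156 across JV/PV/D).
- No WMH load distribution was available to copy, so the generator uses
  one fixed realistic choice: 3 + Poisson(5) lesions per subject, radii
  log-normal (median 3.2 mm, log-SD 0.3) clamped to 2.3–6 mm, growth
  ratios log-normal (median 1.35) truncated at 1.15 so planted ratios
  stay clear of the 10 % classification boundary, and a 25-voxel minimum
  lesion so that voxel-count granularity keeps achieved growth ratios
  within 2 % of target. The nominal brain CBF (40 ml/100g/min) is a free
  scale parameter; all reported quantities are relative.

What the generator does **not** emulate — and therefore what passing
tests do not show: realistic lesion shapes (blobs, not confluent caps),
spatially correlated noise (noise is voxelwise independent Gaussian, so
ROI means converge faster than on real ASL), registration error, motion,
atrophy, partial-volume effects, or FLAIR/T1 intensities and
segmentation error (masks are consumed as given). Recovery of painted
factors demonstrates the *geometry and bookkeeping* are right, not that
segmentation or registration upstream of this package would be.

The anti-circularity guarantee: the generator paints perfusion using its
own labels, while the pipeline re-derives every mask — distance maps,
bands, shells, NAWM, lesion components — from the raw ventricle/WM/WMH
volumes. A round-trip test writes a cohort to NIfTI, reads it back, and
checks the re-derived geometry voxel-for-voxel against the in-memory
truth.

## Problem sizes and determinism

The test suite runs its end-to-end checks on reduced 64 × 64 × 32 grids
(with a proportionally smaller ventricle) and 2–40-subject cohorts; the
acceptance script uses two 40-subject cohorts on the full default grid
and mixed-model recovery experiments at 300 subjects (or ≈ 300 lesions),
sizes at which Monte-Carlo error is comfortably below the ± 0.02–0.03
recovery tolerances. Everything is seeded: identical (spec, seed) pairs
give bit-identical cohorts, and per-subject, per-stage RNG streams keep
subjects independent of cohort size and iteration order.

## Known limitations

- Lesion merges and splits across sessions are resolved by a maximal-
  overlap rule; biologically a "merge" may deserve joint modeling.
- The centroid band rule assigns one band per lesion even when voxels
  span bands (flagged, but models use the single label).
- Back-projected baseline measurements for new lesions assume perfect
  cross-session registration.
- The ASL module covers single-delay pulsed ASL only: no multi-delay,
  no arterial-transit-time mapping, no partial-volume correction.
- Mixed models use Wald intervals; profile or bootstrap intervals may be
  preferable near variance boundaries.
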