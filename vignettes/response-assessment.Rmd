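---
title: "Lesion-level response assessment for brain metastases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-level response assessment for brain metastases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ranobm)
```

## The problem

Brain metastases treated with stereotactic radiosurgery are followed with
serial MRI, and per-lesion treatment response is graded with the RANO-BM
categories: complete response (CR, disappearance), partial response (PR,
at least a 30% decrease of the longest axial diameter relative to
baseline), progressive disease (PD, at least a 20% increase relative to
the nadir — the smallest size recorded up to the assessment, baseline
included), and stable disease (SD) otherwise. The longest axial diameter
is operator- and slice-dependent; lesion volume, computable from a 3D
contour, is a natural competitor. This package implements the whole
comparison machinery at the lesion level: size measurement from binary
contour masks, unidimensional and volumetric classification, stability of
measurements and assessments under contour rotation and across time,
inter-method agreement statistics, and how early each method detects the
one-year response.

Because real follow-up cohorts of this kind are not publicly available,
the package ships a seeded synthetic cohort generator with the statistical
structure the analyses assume, so that every pipeline stage can be
exercised, tested and benchmarked end to end.

## Size measurement

A lesion contour is a binary occupancy array with physical voxel spacing
(`mask3d`); the canonical grid is 1 mm isotropic, with the third array
axis the inferior–superior (z) direction so axial slices are fixed-z
planes. Two measures are defined:

* **Volume** (`volume_mm3`): occupied-voxel count times voxel volume. At
  1 mm spacing this is simply the voxel count.
* **Longest axial diameter** (`longest_axial_diameter`): for each axial
  slice, the maximum center-to-center distance between occupied voxels
  (in-plane Feret maximum); the maximum over slices. The axial restriction
  is deliberate — it mirrors clinical practice, so a lesion elongated
  along z is measured by its largest axial cross-section, not its 3D
  extent. A single-voxel slice contributes 0 mm; an alternative "+1 voxel
  extent" convention was considered and rejected because center-to-center
  distances are unambiguous and directly checkable against an exhaustive
  pairwise-distance oracle (which the test suite does). Masks with several
  connected components are measured as one object: a labeled lesion is one
  unit.
* **Cube-root size** (`cube_root_size`): volumes are mapped to
  `V^(1/3)` whenever they are compared or pooled with diameters, so both
  live on a linear (mm) scale.

When comparing the two classification families, the unidimensional
thresholds are extrapolated to volumes through a sphere: a 30% diameter
decrease corresponds to a `1 - 0.7^3 = 65.7%` volume decrease and a 20%
increase to `1.2^3 - 1 = 72.8%` volume increase
(`volumetric_thresholds_from_diameter`). The defining property — on
exactly spherical lesions the diameter-based and volume-based
classifications coincide — is asserted in the tests over random
trajectories.

## Response classification

`classify_rano` applies, per follow-up: CR if the size is exactly 0; else
PD if the size is at least `(1 + pd)` times the nadir; else PR if at most
`(1 - pr)` times baseline; else SD. Three decisions were genuinely open
and are fixed here:

* **PD precedence over PR.** Both rules can fire at once (e.g. diameters
  `20, 5, 10`: 50% below baseline but 100% above the nadir). Progression
  relative to nadir is the clinically alarming signal and takes
  precedence, consistent with how RECIST-family criteria are applied.
* **Regrowth after CR is PD.** Once a lesion has disappeared the nadir is
  0 and any positive size is progression; this rule (not an epsilon)
  avoids division by zero.
* **The nadir window is causal**: the minimum over time points up to and
  including the assessed one. A category therefore never depends on later
  values, which the tests assert by truncation.

`classify_clinician_style` emulates radiologist assessment: the reference
is the *previous* time point (not baseline/nadir), and growth is
interpreted through a gadolinium-T1/T2 match flag — any diameter increase
with a T1/T2 mismatch is read as radio-necrosis (RN) rather than PD. The
threshold at which a mismatch is consulted is configurable
(`rn_growth_threshold`, default 0 = any increase, the clinical reading).
Radio-necrosis is not a RANO category, so lesions ever labeled RN are
removed wholesale from cross-method comparisons
(`exclude_radionecrosis`), and the exclusion fraction is reported.

Keeping the two reference policies (baseline/nadir vs previous visit)
explicit lets the confusion-matrix analysis attribute disagreement between
automated RANO and clinician-style assessment to the policy itself rather
than to measurement noise.

## Stability analyses

**Rotation.** A rigid rotation of the head leaves a lesion intrinsically
unchanged, so any variation of a measurement across rotated versions of
its contour is method noise. Contours are rotated about the x-axis from
-20° to +20° in 2° steps (21 versions including the unrotated one;
`rotation_set`, `rotate_mask`), with an "extreme" mode composing x-, y-
and z-rotations of the same magnitude in that fixed order (composition is
non-commutative; the order is part of the contract). Rotation uses
inverse-mapping nearest-neighbor resampling at native spacing about the
voxel center nearest the occupancy centroid — snapping the center to the
lattice makes axis-aligned 90° rotations exact permutations, a property
the tests pin. If a rotation would carry occupied voxels off the grid the
operation errors rather than silently cropping; `pad_mask` provides
headroom. Per lesion and measurement method the coefficient of variation
(sample sd / mean; volumes as cube roots) summarizes the spread
(`rotation_cov`), and `rotation_response_change` asks whether re-measuring
only the last time point under rotation flips the final RANO category
(baseline and nadir stay unrotated). Lesions in CR at the last follow-up
are excluded (an empty mask cannot be rotated), as are lesions whose
axial diameter is 0 (sub-measurable). Paired CoVs are compared with a
two-sided Wilcoxon signed-rank test and paired change indicators with a
two-sided McNemar test.

**Time.** Under the working hypothesis that true post-treatment size
evolution is monotone, the absolute Spearman correlation between time and
size (`temporal_monotonicity`, lesions with at least 3 time points)
measures repeatability across visits; alternating growth and shrinkage
depresses it. An exactly constant series carries no evidence of a
monotone trend and is defined as 0 with a warning. Response-sequence
churn is summarized by `consecutive_change_count` (adjacent unequal
categories over assessed follow-ups; `[PR, CR, CR]` is 1 change of 2
pairs) and pooled across lesions as total changes over total pairs
(`pooled_change_rate`) — a pooled rate, deliberately not a mean of
per-lesion rates.

Both tests switch from exact to approximate forms at fixed desk-scale
constants: the signed-rank test uses the exact distribution up to 25
informative pairs (validated in the tests against full sign-pattern
enumeration), and McNemar uses the doubled-binomial exact form below 25
discordant pairs (validated against the binomial oracle).

## Agreement statistics

Continuous agreement uses Pearson correlation and Lin's concordance
correlation coefficient with population (1/n) moments (Lin's original
definition; a sample-moment variant sits behind a flag). The CCC
penalizes location and scale shift, so CCC ≤ |r| always — asserted as a
property test.

To compare the diameter-to-cube-root-volume correlation between the two
contour sources — two *dependent, non-overlapping* correlations measured
on the same lesions — the package implements the Pearson–Filon z-test
with the classical covariance term assembled from the six pairwise
correlations. Because textbook presentations of that term differ in
arrangement, the implementation is validated two independent ways in the
test suite: a 2000-replicate null simulation (empirical type-I error must
fall in [0.03, 0.07] at α = 0.05) and agreement with a 10⁴-resample
bootstrap-standard-error oracle on a fixed dataset. No multiple-testing
correction is applied anywhere; raw two-sided p-values are reported, and
the output metadata says so.

Categorical agreement between assessment methods uses confusion matrices
over the intersection of (lesion, time) keys — only follow-ups assessed
by both methods enter — with percent agreement, Cohen's kappa, and the
prevalence- and bias-adjusted kappa `(k·p₀ − 1)/(k − 1)` for k
categories, which equals Cohen's kappa exactly when marginals are
uniform (also a property test).

## One-year outcome

The final outcome of a lesion is the category of the first follow-up
strictly beyond 365 days ("12 months" is fixed as 365 days, strict
inequality). `time_to_outcome` is the day of the earliest follow-up whose
category equals that final category, with no persistence requirement —
the stated minimum (first follow-up) and maximum (the defining follow-up
itself) force this reading. Lesions without a follow-up beyond one year
are excluded via a typed condition so the filtering is visible to
callers. `cohort_outcome_summary` reports per-method detection-day
statistics and pairwise paired Wilcoxon p-values.

## The synthetic cohort generator

`generate_cohort` emulates, at configurable scale, the structure of a
~49-patient melanoma brain-metastasis cohort: ~9 lesions per patient
(Poisson), per-patient imaging schedules of 1–8 follow-ups at ~75 ± 25
day intervals (follow-up spans averaging ~225 days), log-normal baseline
diameters around 10 mm, a trajectory mix of shrinking (35%), stable
(20%), growing (15%), pseudo-progressive (15%) and complete-response
(15%) lesions, 10.9% of labeled lesions marked radio-necrosis, and
manual diameter readings for 76% of lesions carrying a multiplicative
bias of 0.75 (the observed ~8.0 vs ~10.6 mm contrast between manually
measured and contour-derived diameters). Only the cohort's means are
public knowledge; the distributions around them are order-of-magnitude
choices made once and documented here.

Lesions are plain ellipsoids with random orientation and a low-order
spherical-harmonic radial perturbation (amplitude 5% of the radius) to
vary sphericity; this is sufficient to create the diameter-vs-volume
instability the analyses probe while keeping analytic volumes available
for oracle tests. Growth is capped at 3× baseline volume (growing
lesions are retreated in practice, and the cap bounds rendering grids).
Complete response is an exactly empty mask from the sampled
disappearance time onward — no partial-voxel fade — which makes CR (size
0) well defined without a minimum-measurable-size band.

Each observation carries a "manual" and an "automatic" contour perturbed
from the *same* rendered truth, matching the near-identical volumes of
the two contour sources in practice. The manual style applies an
independent in-plane dilation/erosion offset per axial slice — the
coarse, sawtooth-like surface along z characteristic of slice-by-slice
human contouring — while the automatic style smooths the same per-slice
offsets along z (Gaussian kernel, sd 1.5 slices), emulating a 3D
segmentation model's smoother surface. Both keep every changed voxel
within the configured amplitude of the original boundary (default 0.8 mm
manual, 0.4 mm automatic), implemented with per-slice Euclidean distance
transforms.

All randomness flows from one master seed through a documented
stream-splitting scheme (`derive_seed` hashes the seed with
patient/lesion/time labels), so any module can be exercised in isolation
and the same `(config, seed)` reproduces a cohort bit for bit.

### What the generator does and does not emulate

It reproduces the *relationships* the analyses rest on — paired contours
of one truth, slice-wise manual roughness, biased manual diameters,
monotone-plus-pseudo-progression trajectories, radio-necrosis labels. It
does not simulate MRI intensities (the pipeline never consumes gray
values), inter-time-point registration error (the cohort is generated
aligned), observer-specific systematic styles, or true segmentation
failures (false positives/negatives of a real model). Passing tests
therefore demonstrate that the measurement and assessment machinery
behaves correctly and that the stability orderings follow from the
modeled noise structure — not that a particular clinical effect size
would be observed on real data.

One consequence worth stating: because both contour styles perturb the
same truth, the rotational CoV of *volumes* is dominated by
nearest-neighbor interpolation noise and is statistically
indistinguishable between contour sources in this synthetic setting,
whereas on real data automatic contours were the more stable. The
source ordering is reproduced for diameters (where surface roughness
matters); tests assert the structural orderings only.

## Numerical choices

* Rendering grids are sized from the lesion's maximal extent over its
  trajectory plus noise amplitudes and a ≥3-voxel margin; rendering into
  a too-small explicit extent is an error naming the lesion.
* Digitized-sphere regression bounds, characterized empirically before
  being pinned: volume within 2% of `4/3·π·r³` at 1 mm spacing (0.5% at
  0.25 mm), axial diameter within 3% of the true value at 0.5 mm,
  cube-root-volume CoV under the ±20° rotation set below 0.01, diameter
  CoV below 0.02.
* `rotation_cov` errors on empty or mean-zero inputs rather than
  returning NaN; CoV uses the sample (n−1) sd.
* Spearman ties use average ranks (R's default), matching the rank
  arithmetic in the test oracle.

## Problem sizes

The shipped analyses run at deliberately desk-friendly sizes chosen as
the package's own defaults: the study-scale synthetic cohort used by the
stability and agreement suites has 22 patients (~190 lesions, ~700
observations), the null simulation for the Pearson–Filon calibration uses
2000 replicates at n = 100, and bootstrap oracles use 10⁴ resamples.
These reproduce all qualitative orderings with comfortable significance
margins.

## A worked example

```{r, eval = FALSE}
library(ranobm)

co <- generate_cohort(cohort_config(n_patients = 5, seed = 31))
meas <- measure_cohort(co)
rs <- rotation_stability(co, measurements = meas)

mean(rs$cov_diam)  # pooled diameter CoV across rotations
mean(rs$cov_vol)   # pooled cube-root-volume CoV (smaller)
paired_difference_test(rs$cov_diam, rs$cov_vol)

ts <- temporal_stability(co, meas)
sapply(split(ts$monotonicity$abs_spearman, ts$monotonicity$method), mean)
```

Or, staged with artifacts on disk:

```{r, eval = FALSE}
run_pipeline("all", cohort_config(n_patients = 5, seed = 31),
             outdir = "bm-run")
```

## Known limitations

* The clinician-style assessment is driven by simulated manual diameters
  and an all-match T1/T2 pattern except at injected radio-necrosis
  events; real radiologist behavior (use of context beyond the diameter)
  is not modeled.
* Diameter quantization on a 1 mm grid can tie consecutive measurements
  of a slowly changing lesion; the monotonicity statistic treats ties by
  average ranks, so measured-series monotonicity can fall below 1 even
  for a truly monotone lesion. Invariants about perfect monotonicity are
  therefore stated on true (simulated) series.
* Non-axis-aligned NIfTI affines are rejected on read rather than
  resampled into the canonical frame.
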