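---
title: "Automated hemorrhage volumetry and expansion detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated hemorrhage volumetry and expansion detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemovol)
```

## The problem

Spontaneous intracerebral hemorrhage (ICH) appears on non-contrast head CT
(NCCT) as a hyperdense region — acute blood attenuates around 50–90
Hounsfield units (HU) against brain parenchyma near 25–45 HU. Two
quantities drive management: the hematoma volume at presentation, and
hematoma expansion (HE) on follow-up imaging within the first day. Manual
planimetric volumetry (slice-by-slice outlining) is accurate but slow;
`hemovol` implements an automated pipeline for both volumetry and serial HE
classification, plus the diagnostic-accuracy machinery to evaluate such a
detector against reader calls, and a synthetic head phantom so everything is
testable without patient data.

## The detection model

Detection is threshold-based, relative to the patient's own brain tissue:

1. **Resampling.** Axial acquisitions of 1–5 mm slices are merged and
   averaged to a uniform 5 mm analysis thickness
   (`resample_thickness()`). Each output slice is the thickness-weighted
   mean of the input slices it spans; fractional edge weights conserve HU
   mass for non-divisor ratios. Thicker-than-target data are refused —
   merging is well-defined, interpolation to thinner slices is not.
   Gantry tilt is recorded, never corrected.
2. **Intracranial masking.** Skull is voxels above `bone_hu` (default
   300 HU). Each slice's skull-enclosed cavity is filled, the largest 3D
   connected cavity is kept, and voxels in `[0, bone_hu)` HU are retained —
   the upper bound is deliberately generous so hyperdense blood is never
   excluded from the "brain" over which the reference median is taken.
3. **Slice-range restriction.** Slices below the brain stem and above the
   vertex are dropped. "Below the brain stem" has no crisp geometric
   definition, so the package uses a reproducible proxy: the lowest
   analysed slice is the first whose cavity cross-section reaches 25% of
   the maximum cross-section.
4. **Thresholding.** The brain median HU is computed over the intracranial
   mask and a voxel is hyperdense when its HU is *strictly greater* than
   `median + 15`. The median includes any lesion voxels (no iterative
   re-estimation): for very large ICH this biases the threshold upward by a
   fraction of an HU per tens of cc, a documented conservatism. The offset
   is global, not per-slice.
5. **Component analysis and false-positive correction.** Hyperdense voxels
   are grouped by 26-connectivity (configurable to 6/18). A component is
   rejected if its volume is below 1 cc (the detection floor, applied per
   component) or if more than 50% of its voxels fall inside the anatomical
   exclusion zone.
6. **Volumetry.** Volume is voxel count × in-plane pixel area × slice
   thickness, reported in cc.

### The anatomical exclusion zone

Normal dense structures — the dural venous sinuses (torcular Herophili,
straight, inferior/superior sagittal and transverse sinuses) and the falx
cerebri — exceed any parenchyma-relative threshold and must be rejected.
Clinical products solve this with undisclosed machinery; this package
realises the rejection *geometrically*, as a deliberate, documented
surrogate: the sinuses hug the inner skull table, so a peripheral shell
(the mask minus its 3D erosion by `dural_margin_mm = 3`) covers them, and
the falx runs in the posterior interhemispheric fissure, covered by a
posterior mid-sagittal band of half-width `midline_band_mm = 2` around the
per-slice cavity centre-of-mass column. The surrogate is functionally
analogous to, not equivalent to, atlas- or learning-based rejection; its
per-slice midline estimate assumes an untilted, roughly symmetric head and
is a known limitation on rotated real scans. Both margins, the 50% overlap
rule, and the component floor are exposed as parameters and logged per
component in the `lesion_report`.

## Serial comparison and the conjunction rule

`compare_serial()` reports `followup − baseline` (growth positive; the
signed "negative expansion" of shrinking measurements is preserved) and the
percent change relative to baseline. HE is called when **both** criteria
hold: absolute increase ≥ 6 cc **and** relative increase ≥ 33%. The
conjunction is the stricter, specificity-oriented reading used in the HE
literature; both thresholds are parameters, and comparisons are non-strict
(`≥`), so the exact boundary pair (12 → 18 cc: +6 cc, +50%) is positive.
Baselines under 1 cc are refused — percent change below the detection floor
is not meaningful. Percent change is always computed within one
measurement modality (automated against automated, manual against manual).

## Diagnostic accuracy

`summarize_diagnostics()` evaluates automated HE calls against reference
(reader) calls treated as ground truth: sensitivity, specificity, PPV, NPV
and accuracy with exact Clopper–Pearson 95% intervals (beta-quantile form;
conservative by construction), and likelihood ratios with log-method
intervals, `exp(ln LR ± 1.96·SE)`,
`SE(ln LR+) = √(1/tp − 1/(tp+fn) + 1/fp − 1/(fp+tn))`. The exact interval
was chosen over Wald/Wilson because reference implementations of reported
CIs for small positive counts (e.g. 16/17) are reproduced by it to the
printed decimals; rounding happens only at display. Zero cells making an
LR undefined raise an error rather than a silent continuity correction;
the summary surfaces the error per metric and still reports the
proportions.

## The phantom

`generate_phantom()` builds an ellipsoidal skull shell (default outer
semi-axes 85 × 70 × 46 mm, 6 mm thick, 1200 HU) around a brain cavity at
35 HU, with air at −1000 HU, on a 192 × 192 × 40 grid of 1 × 1 × 2.5 mm
voxels — a thin-slice acquisition the pipeline must merge to 5 mm.
Ellipsoidal lesions (default 70 HU) carry analytic volumes
(`4/3·π·abc`) and voxelised truth masks; spec validation rejects lesions
protruding from the cavity or overlapping each other. The distractors are
the point of the HU palette: falx plate and sinus blob sit at 60 HU —
*above* any realistic median-plus-15 threshold, like lesions — so only the
anatomical rejection path can remove them. Noise is i.i.d. Gaussian
(default σ = 4 HU) inside the head; CT streaks, beam hardening and partial
volume at the skull base are deliberately not modelled. Passing tests on
phantoms therefore demonstrate the pipeline's internal correctness
(thresholding, labelling, rejection, volumetry, classification), not
performance on real scans.

Serial pairs (`generate_serial_pair()`) share geometry and rescale the
lesion isotropically to the target follow-up volume; truth HE labels come
from the analytic volumes. `simulate_cohort()` draws baselines log-uniform
in 2–60 cc and separates classes with margin: growth cases gain ≥ 8 cc and
≥ 50%, stable cases change by ≤ 2 cc and ≤ 10%. The margins exist because
the evaluation asks whether the *pipeline* preserves well-separated truth,
not where its decision boundary wobbles.

## Numerical choices and degenerate inputs

* Strict `>` at the detection threshold (ties excluded), `≥` at both HE
  criteria; both documented rather than load-bearing — measure-zero events
  on noisy data.
* Medians over even counts use the midpoint convention of `stats::median`.
* Volumes are held as `float64` end to end; report rounding is
  display-only.
* Degenerate inputs have defined behaviour: single-slice series read fine;
  an empty detection mask yields a zero-volume report; an all-air volume
  is "not a head CT"; an empty exclusion zone is valid; `k = 0`/`k = n`
  binomials take the conventional 0/100 bounds.
* Components are labelled by a compiled flood fill; labels are assigned in
  first-voxel scan order, so reports are deterministic.

### Measured partial-volume behaviour

Merging 2.5 mm acquisitions to 5 mm averages boundary voxels of a 70 HU
lesion in 35 HU brain to 52.5 HU — above threshold — so thin-slice
acquisitions over-measure by construction; for a 25 cc sphere this is
~6–7%, and the test suite bounds it at +10% rather than hiding it. On
5 mm-native data the noiseless pipeline recovers truth masks voxelwise
exactly, and noisy recovery of a 25 cc lesion is within 5%. Serial
comparison is largely immune: the inflation is common mode between
baseline and follow-up of the same geometry and mostly cancels in the
difference.

## Problem sizes

The shipped tests and the acceptance script run phantoms at
192 × 192 × 20 × (1 × 1 × 5 mm) and 192 × 192 × 40 × (1 × 1 × 2.5 mm), a
40-pair serial cohort, 2000-replicate coverage simulations, and 50
random-mask labelling comparisons — sizes chosen to exercise every path at
full in-plane resolution while keeping a complete run in the order of a
minute or two.

## Known limitations

* The exclusion-zone surrogate is geometric; real falx calcification,
  head rotation, or sinus anatomy far from the skull table can defeat it.
* Peripheral lesions (subdural/epidural collections abutting the inner
  table) overlap the dural shell by construction and risk rejection; the
  package targets intraparenchymal hemorrhage.
* The brain median includes lesion voxels; extreme lesion burdens shift
  the threshold upward.
* DICOM support covers uncompressed Explicit VR Little Endian CT series —
  the common scanner export; compressed transfer syntaxes are rejected
  explicitly.
* No registration between serial scans: comparison is of scalar volumes,
  as in serial HE practice.
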