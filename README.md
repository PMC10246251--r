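# hemovol

Automated intracerebral hemorrhage (ICH) volumetry and hematoma-expansion
(HE) detection on non-contrast head CT, in R.

Acute blood is hyperdense on CT (≈50–90 HU) against brain parenchyma
(≈25–45 HU). `hemovol` measures hemorrhage volume by thresholding relative
to the patient's own brain: after merging the acquisition to 5 mm axial
slices and segmenting the intracranial cavity, a voxel is hyperdense when
its HU exceeds the **brain-tissue median + 15 HU**. Hyperdense voxels are
grouped into 3D connected components; components below the 1 cc detection
floor, or lying mostly within an anatomical exclusion zone covering the
dural venous sinuses and falx cerebri (normal, physiologically hyperdense
structures), are rejected as false positives. Volume is pixel area × slice
thickness, in cc.

For serial imaging, expansion is classified by the conjunction rule used in
the HE literature:

> HE positive ⇔ (V_followup − V_baseline ≥ 6 cc) **and**
> (100 · (V_followup − V_baseline)/V_baseline ≥ 33%)

and automated calls are scored against reader calls with a 2×2 table,
exact Clopper–Pearson 95% CIs for sensitivity/specificity/PPV/NPV/accuracy,
and log-method CIs for the likelihood ratios.

Because clinical CT archives cannot ship with a package, `hemovol` includes
a synthetic head phantom — ellipsoidal skull, noisy brain, ground-truthed
lesions, and falx/sinus distractors engineered to be separable only by the
anatomical rejection step — used throughout the test suite.

## Worked example

```r
library(hemovol)

# a noisy head phantom with a 25 cc lesion and both distractors
ph <- generate_phantom(phantom_spec(
  shape = c(192L, 192L, 20L), spacing_mm = c(1, 1, 5),
  noise_sigma = 4, seed = 42,
  falx_plate = TRUE, sinus_blob = TRUE,
  lesions = list(phantom_lesion(volume_cc = 25))))

detect_ich(ph$volume)
#> Automated hyperdensity detection
#>   brain median: 35.2 HU   threshold: > 50.2 HU
#>   components: 1 kept, 7 rejected
#>     - rejected #1 (0.01 cc): below_detection_floor
#>     - rejected #2 (0.01 cc): below_detection_floor
#>     - rejected #4 (6.62 cc): dural_structure
#>     - rejected #5 (0.01 cc): below_detection_floor
#>     - rejected #6 (0.01 cc): below_detection_floor
#>     - rejected #7 (0.01 cc): below_detection_floor
#>     - rejected #8 (0.01 cc): below_detection_floor
#>   total ICH volume: 25.00 cc

compare_serial(10, 16.5)
#> Serial comparison: 10.00 cc -> 16.50 cc
#>   absolute change: +6.50 cc   relative change: +65.00%
#>   hematoma expansion (>= 6 cc AND >= 33%): POSITIVE

summarize_diagnostics(confusion_table(tp = 16, fp = 3, fn = 1, tn = 107))
#> Diagnostic accuracy (reference = reader calls)
#>             Reference
#> Automated    Growth Non-growth
#>   Growth         16          3
#>   Non-growth      1        107
#>   sensitivity  94.12% (95% CI: 71.31-99.85)
#>   specificity  97.27% (95% CI: 92.24-99.43)
#>   PPV          84.21% (95% CI: 60.42-96.62)
#>   NPV          99.07% (95% CI: 94.95-99.98)
#>   accuracy     96.85% (95% CI: 92.13-99.14)
#>   LR+          34.51 (95% CI: 11.23-106.02)
#>   LR-          0.06 (95% CI: 0.01-0.41)
```

The detection report shows the 6.6 cc falx/sinus distractor rejected
anatomically, isolated noise specks rejected by the 1 cc detection floor,
and the 25 cc lesion recovered; the diagnostic block
turns a confusion table of serial HE calls into the standard
test-performance metrics with 95% intervals.

A command-line interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/hemovol.R", package="hemovol"))') \
  evaluate --table 16 3 1 107 --out metrics.json
```

with subcommands `detect`, `compare`, `classify`, `evaluate`, `simulate`.

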