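# phantomQA

In-silico phantom framework for quality assurance of auto-generated **body
contours** and **adapted dose** in online adaptive radiotherapy.

In adaptive workflows the treatment system segments the patient outline on
each session CBCT and calculates dose inside it — and the body contour is
not editable during the session. Two head-and-neck scenarios stress it:
*weight loss* (the outline shrinks; contours anchored to the planning
anatomy lag behind) and *bolus application* (air gaps between skin and bolus
can make an AI segmenter reject the bolus from the body). `phantomQA`
rebuilds the whole measurement chain synthetically, with known ground
truth at every step:

1. **Synthetic neck phantom** (`phantom_spec()`, `make_phantom()`,
   `make_weight_loss_series()`) — elliptical-cylinder tissue slab, bone
   insert, hemispherical 23 cm³ surface target, uniform-thickness bolus
   shells (0–2 cm) with per-sector air-gap profiles, CBCT-like noise and
   PSF blur; every session comes with truth masks.
2. **HU homogenization** (`homogenize()`) — converts a bolus-plus-airgap
   image into a simulated weight-loss image: air below −200 HU flagged,
   adjacent-pixel jumps above 45 HU flagged, bolus-window (100–600 HU)
   voxels replaced with background-matched random values, per-row linear
   interpolation across the gaps, exterior restored.
3. **Body contouring** (`threshold_body()`, `baseline_contour()`) — HU
   thresholding with largest-component and hole-fill post-processing; the
   baseline contours each image at −300/−450/−600 HU and reports mean
   volume ± sample SD, the study's uncertainty ceiling.
4. **Contour statistics** (`mean_abs_deviation()`, `r_squared()`,
   `summarize_sessions()`) — signed volume deviations from baseline, MAD,
   and the thickness–volume fit
   `R²% = 100% − var(y − y_fit)/var(y)·100%` with population (1/N)
   variances.
5. **Auto-contour failure-mode emulator** (`emulate_autocontour()`) —
   `accurate`, `reference_anchored` (partial adaptation + registration
   jitter) and `bolus_excluding` (drops bolus above 2.5 mm gaps, unstable
   below 0.4 mm).
6. **Dose evaluation** (`toy_dose_model()`, `dvh_metric()`,
   `gamma_pass_rate()`) — exponential depth dose along radiological paths
   with Gaussian penumbra, rescaled to prescription (adapted) or replaying
   the reference scale (scheduled); D95%/D99% from voxel-dose order
   statistics; 3%/3 mm global-normalization gamma index with a 10% cutoff.

`run_study()` chains everything from one seeded `study_config()`; the
numbered scripts under `analysis/` run the same stages through on-disk
artifacts (MetaImage/NIfTI images, CSV/JSON tables under `results/`).

## Worked example

```r
library(phantomQA)
res <- run_study(study_config(seed = 20))

res$contour$mad_cm3
#>           accurate reference_anchored              truth
#>           2.319867         233.550267           2.319867
res$contour$r2_percent
#>           accurate reference_anchored              truth
#>        99.88733292         0.06090191        99.88733292
res$contour$max_baseline_sd_cm3
#> [1] 4.47848
unlist(res$dose_summary)
#>                planned_d95_gy max_abs_scheduled_dev_percent
#>                     66.913783                     14.903517
#>   max_abs_adapted_dev_percent        min_gamma_pass_percent
#>                      1.602572                     96.723885
res$bolus$mad_cm3
#> bolus_excluding           truth
#>        83.77267        25.43233
```

Reading: the direct-segmentation workflow tracks the shrinking body
(MAD 2.3 cm³, inside the 4.5 cm³ baseline-uncertainty ceiling) with an
almost perfectly linear volume-vs-thickness trend (R² 99.9%); the
reference-anchored workflow overestimates massively (MAD 234 cm³) with no
usable linear trend. Replaying the reference plan on the shrinking anatomy
drifts the target D95% by up to 14.9%, while re-normalizing per session
(plan adaptation) keeps it within 1.6%. In the bolus cases the emulated AI
contour rejects the bolus over the wide-gap sectors, deviating 84 cm³ from
baseline — far outside uncertainty — mirroring the clinical need for
tight-fitted, air-gap-free bolus.

The same pipeline, stage by stage with on-disk intermediates:

```sh
Rscript analysis/01_simulate_phantoms.R   # phantom series + truth masks
Rscript analysis/02_homogenize.R          # simulated weight-loss images
Rscript analysis/03_contour_volumes.R     # baselines, emulation, MAD, R^2
Rscript analysis/04_dose_evaluation.R     # D95% tracking + gamma checks
Rscript analysis/05_report.R              # results/summary.json
```

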