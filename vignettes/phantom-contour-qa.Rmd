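---
title: "Phantom-based QA of auto-generated body contours and adapted dose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based QA of auto-generated body contours and adapted dose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomQA)
```

## The problem

In online adaptive radiotherapy the treatment system segments the patient's
body outline on each session's cone-beam CT (CBCT) and calculates dose inside
it. The body contour is typically not editable during the session, so
systematic contouring failures propagate silently into the delivered dose.
Two clinically important head-and-neck scenarios stress this machinery:

* **weight loss** — the outline shrinks session by session, and a contour
  anchored to the planning anatomy (via deformable registration) lags behind
  the true surface;
* **bolus application** — tissue-equivalent material on the skin should be
  part of the dose-carrying volume, but air gaps between skin and bolus can
  make an AI segmenter reject the bolus as an external device.

`phantomQA` reproduces this measurement problem fully in silico: a
parametric neck phantom with known ground truth stands in for the physical
phantom, a seeded failure-mode emulator stands in for the commercial
auto-segmentation systems, and an analytic toy dose model stands in for the
treatment planning system. Every downstream statistic — volume deviations,
their mean absolute deviation (MAD), the thickness–volume linear-fit R², DVH
metrics and the 3-D gamma index — is computed by the package itself and is
exercised end to end by the test suite.

## The synthetic phantom

The phantom is an elliptical cylinder of tissue (default semi-axes 60 × 50
mm, slab 74 mm along z) with an optional bone insert and a hemispherical
surface target whose default radius, 22.23 mm, solves
$\tfrac{2}{3}\pi r^3 = 23\ \mathrm{cm}^3$ — a realistic nodal-level target
volume. A uniform-thickness surface layer ("bolus", thickness 0–2 cm in the
study schedule) wraps the tissue, separated from it by a piecewise-constant
per-sector air-gap profile. Geometry is voxelized at 1 mm isotropic spacing
on a voxel-center lattice; all unit conversions go through one cm↔mm
helper pair.

Image formation adds, in order: per-material Gaussian HU noise (tissue
0 ± 20 HU, bolus 300 ± 30 HU, air −1000 HU, bone 700 HU — plausible CBCT
magnitudes consistent with the classification windows used by the
preprocessing algorithm), an in-plane Gaussian point-spread blur
(σ = 0.7 mm ≈ 1.6 mm FWHM, a plausible CBCT in-plane resolution), and
rounding to integer HU. The PSF blur matters scientifically: it creates the
partial-volume surface ramp on which the three contouring thresholds
disagree. With a perfectly sharp synthetic edge all thresholds would return
identical masks, the baseline SD would be identically zero, and the study's
uncertainty ceiling would be degenerate. Conversely the noise-SD contract of
the generator (sample SD within 5% of the nominal value) holds for the
*pre-blur* noise, so it is verified on unblurred phantoms.

What the generator deliberately does **not** emulate: anatomical texture,
scatter and beam-hardening artifacts, HU calibration error, couch and
immobilization hardware. Passing tests therefore show that the *algorithms*
behave correctly on geometry with known truth, not that the commercial
systems behave identically on clinical images.

Each weight-loss session is emitted twice from one seed stream: the raw
image (bolus HU plus air gaps) and a homogenized-ground-truth twin in which
gap and bolus already carry tissue HU. The twin is the oracle against which
the homogenization stage is validated; its body mask (tissue ∪ former gap ∪
former bolus) is also the truth outline a contour on the homogenized image
should recover.

## HU homogenization (simulated weight loss)

The preprocessing that turns a bolus-plus-airgap image into a simulated
weight-loss image works per slice, per row along the left–right axis:

1. voxels below −200 HU are classified as air and provisionally flagged;
2. adjacent-pixel differences above 45 HU flag the pixel on the low-HU side
   of the jump (these spikes otherwise anchor the interpolation badly);
3. voxels inside the bolus window (100–600 HU) are replaced by random values
   drawn uniformly over the sampled background range, so their mean and
   range match the phantom background by construction;
4. flagged runs lying strictly inside the row's unflagged extent are filled
   by linear interpolation (this closes the air gaps);
5. flagged voxels outside the outer edge — the outermost unflagged content
   of the row — are restored to their original values, preserving exterior
   air.

Several choices here were genuinely open and are fixed as follows. The scan
direction is left–right (configurable to anterior–posterior): gaps in a
neck-like cross-section are roughly normal to that axis over most of the
circumference. Interpolation is linear between the bounding unflagged
pixels — the simplest scheme consistent with "fill the gap". The replacement
distribution is uniform over the sampled background range, matching the
stated mean-and-range contract. The spike rule runs before the bolus
replacement, and replacement wins on pixels caught by both; a switch
(`spike_before_replacement`) swaps the order, since the original processing
order is ambiguous. The background sampling region is an explicit required
parameter (`background_box()` provides a sensible default inside tissue).

Two boundary behaviors are worth knowing. First, the exterior is preserved
*bit-identically* on phantoms whose bolus outer surface is smooth (uniform
gap widths); where the gap profile has angular steps, a handful of exterior
voxels in rows tangent to the surface step lie between two bolus crossings
and are legitimately interpolated — the same thing happens to a real image
processed row-wise. Second, the 0 cm session carries no bolus, so nothing is
replaced and the native partial-volume surface ramp remains; the ≥99%
above-air guarantee applies to the bolus-carrying sessions.

## Body contouring and the baseline

`threshold_body()` keeps voxels at or above a HU threshold, selects the
largest 26-connected 3-D component (robust to thin noisy bridges at 1 mm
spacing) and fills fully enclosed cavities, mirroring the solid body
structures of a planning system; both post-processing steps are
configurable off. The baseline protocol contours the body three times at
−300, −450 and −600 HU, crops every member to a common superior–inferior
slab (voxel-center inclusion, closed interval), and reports the mean volume
with the sample SD (n − 1: three observations treated as a sample of
thresholding choices). The maximum baseline SD across sessions is the
study's uncertainty ceiling: an emulated workflow whose MAD exceeds it is
flagged. The z crop is always explicit configuration — the machine
coordinates of a clinical crop do not transfer to a synthetic lattice, so
the phantom's z = 0 landmark (superior slab face) is recorded in the
manifest.

## Contour statistics

Volume deviations are signed (source minus baseline mean); MAD is their
absolute mean across sessions, including the reference session
(configurable). The linear-fit quality statistic is
$$R^2\% = 100\% - \frac{\mathrm{var}(y - y_{\mathrm{fitted}})}{\mathrm{var}(y)} \times 100\%, \qquad \mathrm{var}\,x = \frac{1}{N}\sum_{i=1}^{N}(x_i - \mu)^2,$$
with an ordinary least squares line of volume on surface-layer thickness as
the fitted model and the population (1/N) variance throughout — even though
the baseline SD uses n − 1; the two quantities follow different conventions
on purpose. The tests verify `r_squared()` against both hand computations
and a brute-force grid-search fit oracle.

## The auto-contour emulator

Three modes reproduce the observed failure modes of the commercial systems:

* `accurate` — returns the true outline, bolus included when present: the
  behavior of a well-functioning direct segmentation.
* `reference_anchored` — a contour anchored to the reference session.
  A pure copy of the reference body would make every session's volume
  identical, leaving R² undefined (var y = 0), so the mode models partial
  adaptation: per-slice signed-distance fields of reference and truth are
  blended (`anchor_adaptation`, default 0.15, the fraction of surface motion
  the registration recovers) plus a per-session random surface offset
  (`anchor_jitter_mm`, default 1.5 mm, the scale of deformable-registration
  surface errors reported for bolus regions). Setting both to zero recovers
  the pure copy.
* `bolus_excluding` — drops bolus (and enclosed gap) from the body wherever
  the local gap width exceeds 2.5 mm, and behaves randomly (seeded, per
  sector and slice) where the gap is below 0.4 mm, reproducing the
  documented thresholds of AI bolus rejection.

The physical gap widths of the original bolus sessions are not public; the
default profiles are therefore free parameters chosen once: small gaps
(1.5 / 0.8 mm sectors) for the weight-loss series, where homogenization
removes them, and a mixed profile for the bolus cases — two 3 mm pocket
sectors (triggering exclusion), a 0.3 mm sliver (triggering instability) and
contact elsewhere, so that the bolus stays attached to the body for the
baseline but is partially rejected by the emulator.

## Dose evaluation

`dvh_metric()` computes Dq% as the (1 − q/100) quantile of the voxel dose
multiset with linear interpolation between order statistics (masks are
binary; no sub-voxel partial volumes). Dose grids live at 2.5 mm (the
clinical 0.25 cm resolution) and are resampled nearest-neighbor onto the
image lattice before DVH evaluation (trilinear available). For the 0 cm
session the target is evaluated after a 3 mm skin-sparing crop back from the
surface.

The gamma index uses a 3%/3 mm criterion with global normalization to the
reference maximum and a 10% low-dose cutoff — common clinical defaults, made
explicit because the original comparison software's settings are not
published — searching a cubic neighborhood of radius 2×DTA with trilinear
interpolation at steps ≤ DTA/3. The tests pin the implementation to an
exhaustive no-interpolation oracle on random grids, verify the identity and
global-scaling closed forms, and document that gamma is not symmetric in
its arguments.

The toy dose model is artifact plumbing, not a physics engine: each beam
enters along a lattice axis, dose falls exponentially with water-equivalent
depth (radiological path through ρ = max(0, 1 + HU/1000)) at an effective
attenuation of 0.05 cm⁻¹ — typical of a 6 MV photon beam past build-up —
and falls off laterally as a Gaussian (σ = 3 mm) of the distance to the
target's beam's-eye-view footprint. "Adapted" plans rescale the summed beam
dose so the target mean equals the prescription on the *current* anatomy;
"scheduled" plans replay the reference session's scale factor unchanged.
This captures the adaptation contrast without an optimizer: removing
surface material shortens the radiological path, so a replayed plan
overdoses a surface target by roughly $e^{\mu \Delta t}$, while the adapted
plan re-normalizes it away. The emulator-vs-forward-calculation gamma check
compares the fine-lattice plan downsampled to the dose grid against the same
plan recomputed on a coarsened anatomy — a genuine discretization
consistency test, which is why its pass rates sit in the high 90s rather
than at exactly 100%.

## Orchestration, seeding, problem sizes

`run_study()` chains the stages from one `study_config()`; the master seed
spawns per-stage sub-seeds (generator, fill, emulator) so any stage can be
re-run in isolation, and two runs from the same config are byte-identical.
The numbered scripts under `analysis/` run the same stages through on-disk
artifacts (MetaImage volumes plus CSV/JSON tables) so every intermediate can
re-enter the pipeline.

The default study runs the full paper-scale geometry — five weight-loss
sessions at 2.0/1.5/1.0/0.5/0 cm plus two bolus cases on ~190 × 170 × 81
lattices at 1 mm — in under a minute on one core; the module tests use
smaller phantoms (24–40 mm semi-axes) chosen to keep each property check
well-resolved at 1 mm spacing.

## Known limitations

* The emulator's failure modes are *models* of the commercial systems'
  observed behavior, with free parameters; absolute MAD/R²/D95 values from
  clinical systems on a physical phantom are not reproducible here, and the
  package claims only the orderings (direct segmentation within baseline
  uncertainty with a strong linear thickness trend; reference-anchored
  contours outside it with a weak trend; adapted dose deviations smaller
  than scheduled ones; bolus rejection above millimetre-scale gaps).
* The toy dose model has no scatter, build-up, beam divergence or
  heterogeneity corrections beyond the radiological path; it supports
  axis-aligned beams only.
* In-plane voxel spacing must be isotropic (distance transforms and the PSF
  blur assume it); DICOM series reading is not implemented — MetaImage and
  NIfTI cover import/export.
* Surface-distance metrics (Hausdorff, DSC) are not computed; the study
  quantifies volume agreement only.
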