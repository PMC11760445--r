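---
title: "Methods: CT densitometry and baseplate micromotion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT densitometry and baseplate micromotion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glenostab)
```

`glenostab` quantifies glenoid bone density from clinical CT and relates it
to the primary (time-zero) fixation stability of reverse shoulder
arthroplasty (RSA) baseplates measured on a rocking-horse bench. This
vignette describes the models and procedures the package implements, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the numerical choices behind the implementation.

## Patient-specific CT densitometry

Clinical CT grayscale is scanner- and protocol-dependent, so the package
uses an internal (phantomless) calibration: mean grayscales sampled in
three reference tissues — air, subcutaneous fat and muscle — are pinned to
fixed bone-mineral-density equivalents of −840, −80 and +30 mgHA/cm³, and
grayscale maps to BMD by linear interpolation between adjacent anchors.
Outside the anchors the terminal segment slopes are continued; bone lies
well above the muscle grayscale and is therefore extrapolated on the
fat–muscle slope. Two properties follow directly from this construction
and are enforced by tests:

* **Monotonicity.** With reference grayscales ordered air < fat < muscle,
  the fitted map is non-decreasing everywhere.
* **Scanner-affine invariance.** Any gain/offset distortion of the scanner
  transforms the reference samples the same way it transforms the tissue
  of interest, so recalibrating with the distorted samples reproduces the
  identical BMD volume. This is the property that makes the method usable
  across scanners and protocols.

The bone volume fraction BV/TV of a region is computed by pixel counting:
the fraction of voxels at or above a global segmentation threshold. The
threshold value is not standardized; the package default is
**100 mgHA/cm³**, it is a configuration key, and every report records the
value used. With trabecular bone around 300–450 mgHA/cm³ and marrow near
the fat anchor, classification is insensitive to moderate changes of this
threshold.

## Anatomical volumes of interest

Density is extracted in three regions: a global glenoid mask (supplied as
a label map — automatic segmentation is out of scope) and two coaxial
cylinders constructed from landmarks:

* The **scapular axis** runs through the glenoid centre and the root of
  the scapular spine, oriented laterally → medially.
* The **cylinder diameter** is 50 % of the 3-to-9 o'clock glenoid width at
  the articular surface.
* The **glenoid vault cylinder** starts at the articular surface and ends
  where it reaches the medial cortex (depth = medial − articular cortex
  level).
* The **subchondral cylinder** shares axis and diameter, has exactly
  one-third of the vault depth, and starts medial to the articulating
  cortex, skipping a configurable necrosis offset (default **2 mm**). The
  thickness convention of the articular-cortex boundary is not
  standardized; the fixed offset is deliberately simple, is applied
  identically to every specimen, and is validated in tests by showing
  that a necrotic pocket placed lateral to the offset leaves subchondral
  metrics untouched.

Cylinders rasterize to voxel masks with a voxel-centre-in-solid rule (no
partial volumes), matching the pixel-counting convention. At 0.6 mm
spacing the mask volume is within a surface-voxel layer of the analytic
πr²h (≈1–3 % depending on grid alignment, converging as spacing shrinks);
density means are insensitive to this boundary layer.

## Augment planning geometry

A circular baseplate (default diameter **24 mm**) is positioned 3 mm
superior to the inferior glenoid rim, targeting 0° inclination (RSA angle)
and 5° retroversion. An inclination correction θ delivered as a full wedge
raises the baseplate's far rim by

$$\Delta = \frac{D}{2}\,\tan\theta,$$

which is the additional lateral offset of the centre of rotation: 2.1 mm
at 10° and 4.4 mm at 20° for D = 24 mm. Delivering the same correction by
reaming removes the equivalent bone wedge, medializing the joint line by
the same magnitude — the package reports it as a negative lateral offset.
Whether clinically printed offsets include graft compression is unknowable
from geometry alone; the package treats them as pure wedge trigonometry,
which reproduces the published implant values exactly.

Wedge seating is checked by a contact fraction: the wedge underside is
lowered rigidly onto the prepared surface until first contact, and the
fraction of footprint sample points with a residual gap ≤ 0.1 mm (config
key) is reported. `optimize_wedge_rotation()` searches whole-degree
rotations of the wedge's high side for the smallest-magnitude rotation
reaching an 80 % contact threshold, flagging the plan when none does. The
1° grid and 0.1 mm tolerance are pragmatic defaults for a check whose
commercial implementations are unpublished; both are configuration keys.

## Micromotion from optical marker tracking

The bench protocol: constant 430 N compression with a sinusoidal ±350 N
superior–inferior shear at 1/6 Hz for 25 cycles, sampled optically at
5 Hz (750 frames), before and after 10,000 abduction fatigue cycles
(45°–93° at 0.5 Hz). Six labelled markers sit on each tracked body
(glenosphere, glenoid rim, and the graft in bone-graft constructs).

Processing steps:

1. **Cycle segmentation.** Windows run between successive positive-going
   mean crossings of the shear channel, detected with hysteresis (arm at
   5 % of amplitude below the mean) and refined to the nearest frame by a
   local least-squares line, so channel noise at the crossing sample
   cannot shift a boundary. A constant channel falls back to fixed-length
   windows of `sample_hz / frequency` frames.
2. **Rigid-body fitting.** Each body's markers in each frame are aligned
   to its first frame by the least-squares orthogonal (Kabsch) transform
   with a proper rotation; collinear marker sets are rejected.
3. **Relative displacement.** The glenosphere motion is composed with the
   inverse glenoid-rim motion and evaluated at a reference point. Because
   a rigid body's translation is point-dependent under rotation, the point
   matters; the package uses the centroid of the glenosphere markers in
   the first frame (standing in for the baseplate centre) and makes it
   configurable. The series is reported in µm as a 3-D magnitude by
   default, with a switch for the shear-direction component, since optical
   systems differ in whether they resolve out-of-plane motion.
4. **Rotation.** The angle between the first-to-last marker lines of the
   two bodies, as change from the first frame, in degrees. The 3-D angle
   is used rather than a camera-plane projection.
5. **Outcome reduction.** Micromotion and rotation are the mean per-cycle
   min-to-max range over the 25 windows, computed for the pre and post
   phases; the pre-to-post difference quantifies loosening, and post-cyclic
   micromotion is compared against the **150 µm** osseointegration limit.
   For bone-graft constructs the graft is tracked separately and the total
   motion is partitioned into implant–graft and graft–glenoid percentages.

Both relative measures are invariant to any common rigid motion of all
bodies, which removes rig compliance and camera-frame drift by
construction.

**Noise floor.** With 2.8 µm per-coordinate optical noise and no injected
motion, the pipeline reports a small nonzero micromotion because the
per-cycle range of a noisy series is positive. Monte-Carlo simulation (60
independent recordings of the standard protocol) bounds this floor at
7.0 µm and 0.085°; the package documents the rounded constants
`MICROMOTION_NOISE_FLOOR_UM = 9` and `ROTATION_NOISE_FLOOR_DEG = 0.09`.
Injected amplitudes of 10–200 µm and 0.05–0.5° are recovered exactly
(noiseless) or within these floors (noisy) in the test suite.

## Statistical pipeline

Group comparisons follow a gated design at α = 0.05 (inclusive, p ≤ 0.05):

* Shapiro–Wilk per group and a Brown–Forsythe (median-centred Levene)
  equal-variance test decide between a one-way ANOVA with
  Holm–Šidák-adjusted pairwise pooled-variance t tests and a
  Kruskal–Wallis test with Bonferroni-adjusted Dunn rank post hoc tests.
  Groups too small for Shapiro–Wilk (n < 3) do not fail the gate on their
  own; a zero-spread group forces the non-parametric branch.
* **Variability** (spread rather than location) is compared with the
  Brown–Forsythe construction — an ANOVA on absolute deviations from
  group medians — with Holm-adjusted pairwise tests. This choice is a
  package decision: spread-difference testing has no single standard, and
  Brown–Forsythe is the natural companion of the variance gate already in
  the pipeline. All-constant groups return p = 1 with a warning.
* **Correlations** between density metrics and micromotion are Pearson's
  r per group with two-sided tests; zero-variance inputs raise an error
  rather than returning NA.
* **Observed power** of the parametric branch is the noncentral-F power
  at α = 0.05 with noncentrality SS_between / MS_within from the sample —
  the usual post hoc ("observed") power definition. It describes the
  sample at hand and is reported, not used for gating.

Under 2000 null simulations the gated omnibus test and Pearson's test hold
their nominal 5 % level within the binomial confidence band (verified in
the acceptance tests). Report footnotes flag small subgroups (n ≤ 5),
whose comparisons are inevitably low-powered.

## What the synthetic generators emulate — and what they do not

The generators exist so every pipeline stage has exact, countable ground
truth; they are study-condition definitions, not fitted models.

**Phantoms** (`generate_phantom_ct()`): a capped elliptical cylinder
(default 28 mm wide, 24 mm vault depth, 0.6 mm isotropic voxels) with a
1–2-voxel cortical shell (800 mgHA/cm³), a trabecular interior whose
bone/marrow texture comes from thresholding a smooth random field so the
bone-voxel count matches the target BV/TV exactly (default 0.66), marrow
near the fat anchor, reference-tissue blobs for calibration, affine
scanner distortion and Gaussian grayscale noise (default SD 10).
Landmarks are emitted analytically — landmark *detection* is out of scope,
and downstream geometry needs exact truth. Not emulated: realistic
scapular anatomy, DICOM metadata, beam hardening, scatter, or
partial-volume blur. Passing tests therefore demonstrate correctness of
calibration, geometry and counting — not robustness to clinical
segmentation or artefact handling.

**Bench recordings** (`generate_marker_recording()`): marker rings on the
glenosphere equator, glenoid rim and graft (the placement is configurable;
real marker positions are rig-specific). The relative motion follows the
shear channel with a within-cycle envelope rising 0 → amplitude → 0, so
the per-cycle range equals the injected amplitude exactly at the 5 Hz
sampling grid; rotation oscillates about the implant axis through the
reference point. The post-fatigue phase adds a constant (permanent
migration) offset plus an enlarged elastic amplitude — both components of
real loosening are representable, and the per-cycle range isolates the
elastic part while the pre/post difference captures the added motion.
Default amplitudes (pre 60 µm elastic, +20 µm and +10 µm permanent offset
post, 0.2° rotation) were chosen once as plausible magnitudes for a
well-fixed baseplate comfortably below the 150 µm limit. Optical noise is
white per coordinate at 2.8 µm; real optical systems have correlated and
anisotropic errors (2.8 µm holds only in the focus plane).

**Cohorts** (`generate_cohort()`): the five-cell design (Reference n = 10;
MA and BIO at 10° and 20°, n = 5 each) with per-group subchondral BMD
levels of 238 ± 37, 217 ± 34 and 211 ± 16 mgHA/cm³ (Reference/MA/BIO).
BIO specimens draw density and micromotion from a bivariate normal with
correlation −0.63 (the generator default); MA and Reference draw them
independently. Micromotion levels (60–95 µm means, with larger spread in
the BIO and 20° cells) encode the qualitative study findings — greater
BIO variability and a density–micromotion coupling unique to bone-graft
fixation — as generator truth. Each specimen uses a fixed-increment
substream of the master seed, so cohort reproducibility is independent of
iteration order. Micromotion draws are truncated below at 1 µm; at the
default means this affects ~3 in 10⁴ draws and does not measurably bias
the imposed correlation.

## Numerical choices and degenerate inputs

* Coordinates: world mm; 0-based voxel indices; voxel centre of index
  (i, j, k) at `origin + (i, j, k) · spacing`; cylinder depth intervals
  are half-open `[start, start + depth)`.
* Rigid fits reject collinear marker sets (second singular value below
  10⁻⁹ of the first) and fewer than 3 markers.
* Cycle windows require at least two detected cycles; leading partial
  windows are kept only when the recording starts at a crossing, trailing
  windows only when at least half a period remains.
* Wedge rotation search ties (equal |rotation|) resolve to the positive
  rotation.
* The BV/TV threshold comparison is inclusive (`BMD ≥ threshold`).
* Empty masks, empty cohorts, non-monotone calibration samples, mismatched
  pre/post bench configurations and out-of-range thresholds raise errors
  with stage-tagged messages in the pipeline.

## Problem sizes

The test suite and reproduction script favour sizes that exercise every
code path while staying quick: phantoms of 32³–64³ voxels (the 64³ default
matches a 38 mm cube at clinical 0.6 mm resolution), 100-phantom counting
sweeps, full-length 750-frame recordings, a 5000-specimen cohort for
correlation recovery, and 2000-replicate null calibrations. The full
default pipeline (30 specimens, 64³ phantoms, pre/post recordings each)
runs in about a minute on one core.

## Known limitations

* Ground-truth landmarks sidestep the (out-of-scope) segmentation and
  landmark-detection problem; results on clinical scans inherit whatever
  landmark error the upstream planning tool makes.
* The fixed 2 mm necrosis offset is a convention, not a detection of
  necrotic tissue.
* The global segmentation threshold's published value is unknown; 100
  mgHA/cm³ is a documented, overridable default.
* The micromotion magnitude is 3-D; systems reporting in-plane components
  will read systematically lower (a config switch provides that variant).
* The exact spread-difference test behind published variability p values
  is not standardized; Brown–Forsythe is this package's documented choice.
* Synthetic phantoms and benches validate the computational pipeline, not
  biological or tribological realism: no bone ingrowth, no contact
  mechanics, no finite-element load transfer.
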