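---
title: "Simulating and scoring dental mirror-technique skills"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring dental mirror-technique skills}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirrorsim)
```

## The measurement problem

When a dentist examines an anterior tooth by indirect vision, the
clinical question "is the mirror held well?" can be made quantitative by
looking at the mirror image itself: a well-positioned mirror shows the
lesion centred on the mirror surface, large, and nearly circular, and the
operator reaches that state quickly. A VR evaluation system operationalises
this by capturing a screenshot of the head-mounted display view at the
moment the operator declares the position appropriate, and measuring four
quantities on it:

* **distance between centres** (mm) — lesion image centre to mirror
  surface centre; an index of centring;
* **relative ratio** (%) — area of the lesion image over the area of the
  mirror surface; an index of magnification/approach;
* **ellipticity** — minor/major axis ratio of the lesion image; 1 means
  the lesion is seen face-on as a perfect circle;
* **manipulation time** (s) — how long the operator took.

`mirrorsim` reproduces this chain headlessly. Every stage is ordinary
geometry and image analysis, so each has an exact oracle against which it
is tested.

## Mirror optics

The virtual image behind a planar mirror is the reflection of the object
through the mirror plane; the viewer camera then sees that virtual image
directly. `reflect_point()` implements the reflection (an involution and
an isometry — both tested to 1e-9), `virtual_image_of_disc()` maps an
oriented circular disc to its mirror image, and `project_disc()`
perspective-projects a disc by sampling 256 boundary points and fitting
the exact conic through them. For a disc at distance $d$, radius $r$,
face-on, the projected radius is $f r / d$ with $f$ the focal length in
pixels; tilted by $\theta$, the image axis ratio tends to $\cos\theta$ in
the orthographic limit ($d/r \ge 50$, within 1%). Both closed forms are
asserted in the tests.

Following the rendering rule this emulates, `mirror_view()` applies no
occlusion between the mirror surface and the virtual image: the mirror
shows its content regardless of what lies behind it. Whether the *mirror
itself* is visible to the viewer is a separate scene-level validity
criterion.

Two conventions matter downstream: image coordinates are pixels with y
down and the origin at the top-left; ellipse orientations are reported in
[0°, 180°) from the +x image axis, the convention of common
image-analysis tools.

## The scene and the validity criteria

The dentition is modelled with parameterised primitives — capsules for
the eight anterior teeth (FDI 12, 11, 21, 22 and 42, 41, 31, 32) on a
parabolic arch, an ellipsoid tongue, and an axis-aligned frame box that
stands in for the lips/cheek mucosa bounding the working space. Scanned
anatomy is intentionally not used: the metrics depend only on
mirror/lesion/viewer geometry, and primitives admit exact distance tests.
The occlusal plane is vertical (perpendicular to the ground plane), with
the viewer working from the 12 o'clock position behind the head; the
mandibular arch is dropped 15 mm along the arch axis to model the open
mouth.

A task is valid when (trial 1) the entire mirror is visible — all
projected boundary points inside the viewport and 32 eye-to-boundary rays
unobstructed by teeth or tongue, with tangency conservatively counted as
occluded — and the mirror penetrates nothing (exact disc-to-capsule
distances; 64 boundary samples against the tongue ellipsoid and the box
walls). Trial 2 adds: handpiece tip inside the frame box, and tip not
overlapping the lesion's mirror image (point-in-ellipse in image space).
The lesion sits on the tooth surface facing the mirror in this posture —
lingual for the maxillary teeth, labial for the mandibular ones; the
anchor and its normal are fields of the scene object and can be changed
if a different placement is wanted.

Arch dimensions (50 mm wide, 25 mm deep), tooth radii and the frame box
are plausible for an adult anterior dentition but are conventions, not
measurements; all are configurable through `build_default_scene()`.

## Screenshot rasterisation and moment measurement

`render_screenshot()` rasterises the analytic mirror and lesion ellipses
into a labelled image (background 0, mirror 1, lesion 2) by pixel-centre
sampling; the lesion is clipped to the mirror, as a mirror clips its
content. `fit_ellipse_moments()` recovers an ellipse from a pixel set via
its centroid and second-order central moments, adding 1/12 per pixel (the
variance of a unit square) so a filled region's moments match the
continuous region, and rescaling the axes so the ellipse area equals the
pixel count — the same-area convention of standard "fit ellipse" tools,
which is also how the screenshots this pipeline emulates were measured.

Pixel-to-millimetre conversion must be per-image, because the
magnification differs between screenshots. The calibration reference is
the mirror's known 20 mm diameter against the *major* axis of the fitted
mirror ellipse: a tilted circle keeps its true diameter along the tilt
axis, so the major axis is the tilt-robust scale. The mirror inclination
is then $\theta = \arccos(b/a)$.

With mirror ellipses ≳ 100 px and lesion ellipses ≳ 20 px in semi-axis,
the raster round trip recovers centres within 0.5 px and axes within 2%
(tested on 100 random poses), and the measured metrics carry no
detectable systematic bias relative to the analytic values (≲ 0.2% on
the centre distance, ≲ 0.03% on ellipticity and area ratio) — which is
what makes the calibration-recovery checks below meaningful. Axes much
below ~15 px leave this regime; `fit_ellipse_moments()` refuses fewer
than 16 pixels outright.

## The synthetic cohort generator

The generator's purpose is to make the whole pipeline testable without
human data, with group-level targets that are *exactly encodable*. It
therefore parameterises the **apparent** quantities directly rather than
simulating hand kinematics:

* radial offset of the lesion image from the mirror centre ~
  Gamma(shape 4), mean = the group's target distance;
* lesion-image ellipticity target ~ Beta with mean = the group target and
  SD 0.075;
* lesion/mirror area-ratio target ~ Gamma, SD 0.43 percentage points;
* manipulation time ~ log-normal, sdlog 0.55, mean = the group target;
* mirror inclination ~ Gamma(shape 4), mean 8°, capped at 35°.

The distributional forms are support-driven choices (non-negative,
(0, 1)-bounded, positively skewed); the dispersions are derived from the
published effect sizes connecting the reported group means (e.g. a 0.03
ellipticity difference at *d* = 0.40 implies SD ≈ 0.075). They were fixed
once, before any acceptance measurement, and define the simulated study
conditions.

For each record a full 3-D pose is constructed: the mirror is placed near
the target tooth, tilted about the camera-right axis (so its projected
major axis — the calibration reference — stays unforeshortened), and the
lesion's *virtual image* is placed coplanar with the mirror surface with
its centre offset along the tilt axis, where perspective projection
preserves lengths exactly. The lesion tilt and radius are then solved by
a short secant/fixed-point iteration against the package's own analytic
projection so that the analytic image ellipticity and area ratio equal
the sampled targets to ~1e-6. The initial guess is the orthographic
closed form (tilt = arccos of the target); the iteration removes the
small perspective deviation from it, which a 3-standard-error recovery
check cannot absorb. The physical lesion disc returned is the reflection
of the virtual image through the mirror plane — its stop-state apparent
position, not a position on tooth anatomy.

Mirror and viewer placements per tooth were chosen once so that the
validity criteria pass across the whole sampled tilt range (a geometric
feasibility requirement, not a tuning target): in the default scene,
every sampled pose is a valid task.

Printed area ratios (up to 3.46%) exceed the 2.25% bound implied by
coplanar 3 mm / 20 mm discs at equal magnification, so the generator
treats the ratio as a free apparent quantity and lets the lesion-image
radius exceed 1.5 mm; the scale or convention that produced those values
in the source system is not recoverable.

What the generator does **not** emulate: hand kinematics and tremor,
learning dynamics across tasks (a per-task warm-up multiplier
`task1_time_factor` is available but defaults to 1), segmentation noise
in the screenshots (a label-flip rate is available, default 0),
between-participant skill heterogeneity (all variance is within-group),
and any correlation between metrics within a record. Passing
calibration-recovery tests therefore shows the *measurement chain* is
unbiased end-to-end; it says nothing about whether real operators behave
like the sampling model.

### Calibration tables

`inst/extdata/calibrated_cohort.yaml` encodes the per-group target means
per tooth and trial where reported (group sizes 25/24/17/21). Two source
paragraphs describing between-teeth contrasts carry trial labels
inconsistent with the between-group paragraphs; the tables follow the
between-group values, whose cross-checks agree. Cells never reported
(e.g. ST trial-2 tooth-21, GS ellipticity) are interpolated consistently
with the reported group ordering and are marked `synthetic fill` in the
file. Ellipticity was reported per trial only and is encoded as a scalar
per group.

### Determinism

Every record draws from an RNG stream keyed by (seed, group, participant,
task), so cohorts are reproducible under reordering and subsetting; the
run manifest (seed, sizes, config hash) reproduces a run bit-for-bit.
Seeds passed through the public interfaces stay below 2^31.

## Statistics

The analysis battery mirrors the comparison families of the study design,
per metric:

* Kolmogorov–Smirnov normality screen per group × trial, with the
  Lilliefors construction: parameters estimated from the sample, p-value
  by seeded Monte-Carlo simulation of the null (default 10⁴ replicates;
  the analysis wrapper uses 2000).
* Friedman tests for **within-participant** factors: across the four
  tooth conditions per group × trial, and across the four trial-1 task
  positions for manipulation time. Ranks are averaged on ties and the
  statistic tie-corrected; for small, tie-free layouts (up to 10⁵
  permutation configurations) the p-value is computed by exact
  enumeration of all within-block rank permutations, otherwise by the
  χ²(k−1) approximation. The χ² approximation is coarse below ~10 blocks
  (deviations of ~0.05–0.18 from the exact null at n = 3–6 are normal and
  reproduce the published exact tables), which is why the exact path
  exists.
* **Between-group** contrasts use pairwise Wilcoxon rank-sum tests with
  Bonferroni adjustment (m = 6 for four groups, per tooth × trial family;
  families are not pooled across teeth), and the paired trial-1 vs
  trial-2 contrast per group uses the signed-rank test (m = 1). The
  source analysis nominally applied the Friedman test *between* unequal
  independent groups, which its blocked design does not support; this
  package deliberately assigns Friedman to within-participant factors and
  rank tests to between-group contrasts, reproducing the same comparison
  families.
* Cohen's *d* accompanies every comparison: pooled-SD form for
  independent samples, mean difference over SD of differences for paired
  ones. The raw-value pooled-SD form is a choice; a rank-based effect
  size would be equally defensible.

Significance markers follow the `*` (p < 0.05) / `**` (p < 0.001)
convention. Bonferroni's family-wise guarantee is verified by simulation:
under identical profiles the family-wise error at 10³ replicates stays
below 0.05.

## Numerical choices and degenerate inputs

* Conic fitting normalises coordinates (centroid shift, mean-radius
  scale) before the SVD; non-elliptical fits raise errors rather than
  returning garbage.
* Rasterisation uses half-open pixel boxes and `≤ 1` on the ellipse
  quadratic form, so boundary pixels resolve deterministically.
* `fit_ellipse_moments()` rejects < 16 pixels and collinear pixel sets
  (degeneracy judged on the raw point moments, before the 1/12 term).
* `measure()` names the missing label class in its error; `arccos` is
  clamped at 1 so face-on mirrors give θ = 0 rather than NaN. Because
  arccos is steep near 1, θ near zero inflates by a degree or two under
  raster noise — harmless for the metrics, which never invert it.
* Tangency counts as occlusion (visibility) and as contact (penetration):
  both criteria fail conservatively at ties.
* Beta parameterisation by mean/SD degenerates to a point mass at SD 0;
  an SD too large for (0, 1) support falls back to a near-flat Beta.
* The problem sizes in the test-suite recovery checks (cohorts of one
  group × trial 1, a few seed replicates; 100-pose raster agreement;
  10³-replicate type-I simulation) keep each check's Monte-Carlo error
  well inside the tolerance it asserts.

## Known limitations

* The capture camera defaults (600×600 px, 12° vertical FOV, 250 mm
  viewing distance — a capture zoomed on the mirror region) are
  conventions; the source system's HMD optics and capture resolution are
  not public. All are configurable, and the mm-scale metrics are
  resolution-invariant by construction.
* Soft tissue, collision response and molar targets are out of scope, as
  in the system this emulates.
* The generator's independence assumptions (no between-participant
  heterogeneity, independent metrics) make its p-values optimistic
  relative to real cohorts; it is a pipeline-validation tool, not a power
  calculator for human studies.
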