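---
title: "Measuring Certas Plus valve settings from CT marker segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring Certas Plus valve settings from CT marker segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(certasdial)
```

## The measurement problem

The Codman Certas Plus is an adjustable cerebrospinal-fluid shunt valve with
eight opening-pressure settings selected by rotating an internal magnet pair.
On CT the valve appears as a handful of very bright metal components at an
arbitrary rigid pose, surrounded by artefact. Reading the setting amounts to
measuring one angle: the orientation of the rotor's magnet axis relative to
the valve's own reference axis. `certasdial` performs that measurement from a
label map of the five radiopaque markers and converts it to a setting.

The method assumes:

* the five markers are labelled 1–5 (ball magnet, plain magnet, rotating
  construct, right-hand-side marker, distal tip) on a grid whose NIfTI affine
  is correct — all geometry is done in physical millimetres, so anisotropic
  spacing and oblique acquisitions are handled by construction;
* the segmentation errors are roughly balanced around each marker, so the
  binary (unweighted) centroid is a good estimate of the marker center. Large
  one-sided errors move centroids and hence the angle; small boundary noise
  mostly cancels;
* the three plane-defining markers (rotating construct, RHS, tip) are not
  collinear — true for the physical valve, where the tip lies well off the
  RC–RHS axis.

## From centroids to a setting

With RC, RHS and TIP the centroids of labels 3–5, the valve frame is

* reference axis `r = unit(RHS − RC)`,
* plane normal `n = unit((RHS − RC) × (TIP − RC))`,
* flow axis `unit(TIP − RC)` (reporting only).

The indicator direction `d` runs from the plain magnet to the ball magnet:
the sub-millimetre tantalum ball marks the pointer end of an otherwise nearly
symmetric rotor, and orienting `d` by it is what prevents confusion between
opposing settings (e.g. 2 vs 6). `d` is projected into the valve plane and
the angle measured as

```
theta = atan2((r x d) . (-n), r . d)      # degrees, clockwise positive
```

**Sign convention.** Settings increase clockwise when looking at the valve
face, but "clockwise" in 3-D needs an orientation. Here the normal's sign
comes from the RHS/TIP cross product, and the angle is measured clockwise
about that normal. Mirroring the patient (scanning the valve from the other
side) flips both the apparent rotation sense and the constructed normal, so
the reported angle is unchanged — the property tests exercise exactly this
reflection invariance, along with invariance under 100 random rigid motions
at 1e-6 degree tolerance. Any consistent flip of both conventions would be
equivalent; this pair is fixed jointly with the phantom generator and
validated by round-trip tests.

**Zones.** The eight settings tile the dial in 45° zones increasing
clockwise; 0° (indicator superimposed on the RC–RHS axis) is the cutoff
between settings 2 and 3. Angles are reported in `[−90, 270)` so that the
zone centers run −67.5°, −22.5°, …, 247.5° for settings 1–8. Zone boundaries
are measure-zero events, but a deterministic rule is still needed: zones are
half-open and lower-inclusive, so an exact 0° reads as setting 3.

**Degenerate inputs.** Missing markers raise typed conditions naming the
markers (`certasdial_missing_marker`), which the pipeline converts into an
`undeterminable` row — a data outcome, not a failure, mirroring the clinical
workflow where such scans are read manually. Two genuinely degenerate
geometries are errors: a collinear RC/RHS/TIP triple (minimum triangle
altitude below 0.1 mm, under voxel scale, where the normal is noise) and an
indicator axis perpendicular to the valve plane (projected norm below 1e-6 of
the original), which cannot happen for a physical rotor.

## The synthetic phantom

No public CT dataset with Certas Plus ground truth exists, so the package
generates its own study material: a sub-volume of default `96^3` voxels at
0.6 mm isotropic spacing (a typical sub-millimetre grid passing the
at-most-1-mm-per-axis resolution check), containing the five markers as solid shapes

* magnets: spheres, radius 1.6 mm, centers ±3.5 mm from the rotor center
  along the indicator direction;
* rotating construct: an annulus of center-line radius 7.5 mm, tube radius
  0.8 mm, in the valve plane;
* RHS marker: sphere, radius 0.9 mm, 11 mm from the rotor center along `+x`;
* distal tip: capsule, radius 0.8 mm, length 4 mm, 20 mm away at 90° from
  the reference axis (so the plane-defining triple is never collinear).

These dimensions are the package's own stand-ins — manufacturer drawings are
not public, and only the angular relationships matter to the measurement.
Two constraints fixed them: the whole constellation must fit the default
volume under arbitrary rotation (with 3 mm translation jitter), and every
pair of shapes must be separated by clearly more than one voxel diagonal
(1.04 mm at 0.6 mm spacing), because a 26-connected component bridges any
narrower gap through diagonal voxel adjacency no matter the threshold. The
chosen constants give every inter-shape gap ≥ 1.6 mm. All of them are
exposed via `valve_geometry()` rather than hard-coded.

The intensity volume is `background_level` 40 with markers at `marker_level`
2000 (soft tissue vs metal on an HU-like scale) and a small brighter core
(`ball_level` 3500, radius 0.5 mm) inside the ball magnet standing in for the
tantalum ball. It is degraded by a separable Gaussian blur of sigma 0.4 mm
(sub-voxel reconstruction softening) and additive Gaussian noise of SD 15,
both seeded. Optional radial streaks are available as a cosmetic stressor.
The label map stores the exact pre-blur rasterization, so ground truth stays
crisp even where intensities smear — the analogue of careful manual
segmentation on artefact-degraded images.

What the phantom does **not** model: beam hardening and real streak physics,
reconstruction kernels, surrounding anatomy (skull, other hardware), partial
rotor shapes, or segmentation errors of a learned model. Passing phantom
tests therefore demonstrates that the geometry pipeline is correct and
robust to pose, rasterization, blur and additive noise — not that any
particular segmenter reaches a particular accuracy on patients.

`make_cohort()` draws each case's setting from a skewed distribution with
mode at setting 4 (extreme pressures are rarely prescribed;
`default_setting_weights()` is 2, 6, 10, 25, 15, 9, 5, 3), then a continuous
truth angle **uniform within the setting's zone** — the physical dial is
continuous, so truths must not cluster at zone centers — an independent
uniform random pose, and a fresh noise seed. Cases are grouped into synthetic
patients of 1–3 scans so `split_cohort()` can demonstrate grouped 80:20
splitting without leakage.

## The threshold segmenter

`segment_markers()` exists so the full chain (intensity volume → labels →
angle → setting) runs without a trained network. It thresholds at 800
(between blurred marker edges and everything tissue-like), labels
26-connected components (diagonal connectivity keeps the thin annulus in one
piece), discards components under 3 voxels, and classifies geometrically:
the largest-extent component is the annulus; the two components nearest the
annulus centroid are the magnets; of the rest, nearest is the RHS marker and
farthest the distal tip (a lone remaining small component is split on 1.5×
the annulus radius). The ball magnet is the magnet containing the brightest
voxel — a phantom-compatible proxy for the tantalum ball; on patient data a
learned segmenter supplies labels 1 vs 2 directly and this heuristic is
never consulted. Unassignable scenes yield partial label maps, which the
pipeline reports as undeterminable with the missing markers named — the same
failure mode a U-Net shows when it misses the few-voxel RHS marker.

## Evaluation conventions

* **Denominator.** Determinable rate, exact accuracy and adjacent accuracy
  all use the full case count as denominator; an undeterminable case counts
  as incorrect. This matches reporting a "useful prediction" fraction over
  all test cases rather than over the determinable subset.
* **Adjacency.** Default adjacency is non-circular (`|a − b| ≤ 1`), i.e.
  clinical pressure adjacency; circular dial adjacency (1 and 8 neighbours)
  is available, because on the physical dial those two settings abut even
  though they are clinically opposite.
* **Intervals.** All rate CIs are Clopper–Pearson exact intervals from beta
  quantiles — conservative by construction, which the coverage simulation
  (p = 0.8, n = 75, 2000 replicates, observed coverage within [93%, 97%])
  confirms.
* **Overlap.** Dice and IoU are 1.0 when a label is empty in both maps and
  0.0 when empty in exactly one; the algebraic identity
  `IoU = DSC/(2 − DSC)` is property-tested to 1e-12.
* **Angle summaries** use the n−1 sample SD and report a single-sample SD as
  `NA`, never 0.

## Problem sizes and numerical tolerances

The test suite and acceptance script use: 100 random rigid poses per setting
for the exact-centroid round trip (tolerance 1e-6°, pure geometry), 200
noiseless phantoms (8 settings × 25 poses) for rasterized recovery, and one
75-case default-noise cohort end to end — sizes chosen to estimate the rates
of interest (≥ 99% and ≥ 90%) with comfortable margin while keeping a full
run in a few minutes on one CPU. Rasterization at 0.6 mm spacing moves
centroid-derived angles by a few tenths of a degree (the worked example's
67.43° vs the exact 67.5°); blur does not move label-map centroids at all
(labels are pre-blur), and default noise enters only through the segmenter's
threshold mask.

## Limitations

* The geometry constants are plausible, not measured; absolute Dice/IoU
  values on phantoms do not transfer to patient data.
* The threshold segmenter is a stand-in. Its heuristics rely on the marker
  constellation being isolated in the sub-volume; it would misbehave inside
  a full head CT with skull and cables, which is out of scope.
* Truth angles near zone cutoffs are intrinsically ambiguous on a continuous
  dial; exact accuracy below adjacent accuracy is a property of the valve,
  not a pipeline defect.
* The angle is computed by 3-D projection onto the valve plane, chosen over
  measuring on a reformatted 2-D slice; for exact centroids the two agree,
  and the projection route avoids a resampling step.
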