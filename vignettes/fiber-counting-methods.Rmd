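---
title: "Fiber counting in phase-contrast micrographs: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiber counting in phase-contrast micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmfiber)
```

## The measurement problem

Airborne fiber concentrations (asbestos monitoring being the canonical
case) are measured by drawing a known volume of air through a membrane
filter, clearing the filter on a slide, and counting fibers in circular
300-µm fields of view under a phase-contrast microscope (PCM) at 400×.
A regulatory *counting criterion* decides which objects count as
fibers: length ≥ 5 µm, width < 3 µm, and aspect ratio ≥ 3. The mean
count per field is then scaled by the ratio of the filter's effective
collection area to the field area, and divided by the sampled air
volume, to give fibers per litre.

`pcmfiber` implements everything downstream of the microscope: turning
segmentation output (from any backend — a trained neural model, or the
built-in classical detector) into fiber pixel groups, measuring each
group, applying the criteria, evaluating detections against expert
polygon annotations, and converting counts to concentrations. A
synthetic scene simulator with pixel-exact ground truth closes the loop
so the whole chain is testable without microscope data.

## Coordinate and calibration conventions

Pixels are 0-based with `x` = column and `y` = row; the pixel at
`(x, y)` has its center at the integer lattice point, and polygon
vertices live in the same continuous space. Rasterization of a polygon
includes every pixel whose center lies inside or on the boundary.

The calibration is a single scalar in µm/pixel, defaulting to 0.3125
(a 10-µm scale division spanning 32 pixels at 400×,
`calibrate_scale(10, 32)`). All lengths are measured in pixel-count
units first and converted by multiplication; with the default scale the
minimum countable length of 5 µm is exactly 16 pixels.

## Segmentation post-processing contracts

Two output shapes are supported, mirroring the two families of
segmentation models used for this task:

* **Semantic** (`semantic_output`): one fiber-probability per pixel.
  `semantic_postprocess()` keeps pixels with probability *strictly
  greater* than 0.5 and splits them into connected components
  (8-connectivity by default so diagonal fiber runs stay intact;
  4-connectivity available).
* **Instance** (`instance_output`): per-object class probability plus a
  soft mask. `instance_postprocess()` keeps instances with class
  probability *strictly above* 0.5 and binarizes each mask at
  *inclusive* 0.8. The asymmetric strict/inclusive pair is deliberate
  and follows the convention the thresholds come from; both are
  configurable.

The classical detector (`classical_detect()`) exists so the pipeline
runs end-to-end deterministically without trained weights. It is an
engineering backend, not a reimplementation of any neural model:
background estimation by heavy Gaussian blur (σ = 15 px), a darkness
map (background − image; PCM fibers are dark cores), and a linear ramp
mapping darkness 0.05–0.15 to probability 0–1. Probabilities outside
the declared field disc are zeroed so the graticule rim is never read
as a fiber. A median denoising step exists but defaults *off*: a 3×3
median erases one-pixel-wide fiber runs, and isolated noise pixels are
cheaper to remove with the minimum-component-size option (default 4 px
in the pipeline). The ramp levels were fixed by inspecting rendered
single-fiber scenes so that the faintest default fiber (0.4 µm ≈ 1.3 px
wide) stays above threshold along its whole length.

## Morphometry: the two width conventions

Every pixel group is summarized by its rotated minimum-area rectangle
(`min_area_rect()`), computed over convex-hull edge orientations with
a half-pixel pad on every side so side lengths count pixels (a 16 × 4
axis-aligned bar measures exactly 16 × 4). Length is always the long
side of this rectangle. Two width conventions are provided:

* **Instance style** (`measure_instance_style()`): the number of group
  pixels on the line through the rectangle center orthogonal to the
  long axis. The line is sampled at unit Euclidean steps and each
  sample is rounded to its nearest pixel; unit (rather than lattice)
  stepping keeps the count orientation-independent — counting lattice
  pixels would inflate a 45° section by √2. If the central section is
  empty (a strongly curved fiber whose rectangle center lies off the
  stroke), the nearest populated section along the long axis is used
  and the candidate is flagged `fallback`.
* **Semantic style** (`measure_semantic_style()`): pixel coordinates
  are rotated into the rectangle frame and binned into unit-width bins
  along the long axis (anchored at the first pixel so integer-spaced
  centers land one per bin); the width is the mean count over
  *non-empty* bins. Empty bins along curved fibers are excluded —
  including them would systematically underestimate the width of
  C-shaped strokes.

For solid straight bars the two conventions agree exactly; they are
tested to recover rendered fiber dimensions within ±1 px at 0°, 30°,
45° and 90°. Aspect ratio is always `length_um / width_um`, so
`aspect_ratio × width_um == length_um` holds to machine precision.

One reading had to be fixed where the conventions are ambiguous: the
rectangle is taken as the *rotated* minimum-area rectangle for both
conventions (an axis-aligned option inflates diagonal fiber lengths by
up to √2 and is not the default), and "center point of the detected
fiber" is read as the rectangle center rather than the mask centroid.

## Counting criteria and concentration

`apply_criteria()` applies the three-part rule with the printed
inclusivities: length ≥ 5 µm (inclusive), width < 3 µm (strict), aspect
≥ 3 (inclusive). The decision is monotone in length and width, which
the suite property-tests. `concentration_fibers_per_L()` computes

$$ c = \bar n \cdot \frac{A_{\mathrm{filter}}}{A_{\mathrm{field}}} \cdot \frac{1}{V} $$

with both areas as circles. The nominal 47-mm membrane filter exposes
an effective collection diameter of 35 mm in the standard holder; that
default reproduces the reference conversion of 5.5 fibers per 300-µm
field → 31.2 fibers/L at 2,400 L. Reported concentrations are rounded
half-up to one decimal (`round_half_up()`), since banker's rounding
differs at the .x5 boundaries regulators care about.

## Evaluation against expert annotations

Expert truth arrives as LabelMe polygon JSON with a two-value label
vocabulary (`countable_fiber` / `subcriteria_fiber`); unknown labels
map to countable with the original label preserved in notes. Matching
is by IoU on pixel sets. The standard union formula
$|A\cap B|/|A\cup B|$ is the default; an alternative
sum-denominator mode $|A\cap B|/(|A|+|B|)$ is kept because some
protocol texts write the ratio that way (identical sets then score 0.5,
so the 0.5 threshold semantics change; the union mode is what the
package's own results use).

Predictions and truths are matched one-to-one, greedily in descending
IoU among pairs at or above the 0.5 threshold, ties broken by smaller
prediction then truth index. Greedy matching can in principle be
sub-optimal in match count, but at an IoU threshold of 0.5 a prediction
can only qualify against two truths if those truths heavily overlap
each other, which annotated fiber sets essentially never do; the suite
verifies greedy = exhaustive-optimal on randomized small instances, and
an exhaustive `method = "optimal"` is available for audits. Matched
pairs are true positives; unmatched truths are *overlooked* (FN),
unmatched predictions *overcounted* (FP). `tabulate_matches()` pools
per-image results by summing tp/fn/fp (micro-averaging) and reports
recall = tp/(tp+fn) and precision = tp/(tp+fp), as integer percentages
rounded half-up. By default only criteria-passing objects enter
matching on both sides; sub-criteria objects can be included for
diagnostics by filtering differently upstream.

The bundled benchmark table (`benchmark_counts()`) carries the
per-image bookkeeping of two published segmentation models on ten
evaluation fields totalling 55 expert-counted fibers; the semantic
model's totals (57 counted, 3 overlooked, 5 overcounted) give 95%
recall and 91% precision under these definitions. The instance model's
totals imply 61.8% / 82.9% under the same equations; the percentages
printed alongside that model in its source could not be derived from
the same bookkeeping and are not reproduced here.

## The synthetic scene simulator

`generate_scene()` renders one field of view with pixel-exact ground
truth. What it emulates, and the defaults that define the simulated
study conditions:

* Geometry: 300-µm field disc centered in a 1600 × 1200 raster at
  0.3125 µm/px. Outside the disc the image is a constant 0.30;
  background inside is 0.62.
* Fibers: count ~ Poisson(5.5) per field, matching the reference
  density of 5.5 countable fibers per field; lengths lognormal around
  15 µm truncated to 6–60 µm; widths uniform 0.4–1.5 µm. Under these
  defaults every fiber satisfies the criteria, so the countable density
  equals the Poisson mean. Waviness 0 gives straight, amosite-like
  fibers; waviness ≈ 0.05 (amplitude/length) gives wavy,
  chrysotile-like centerlines (sinusoidal, 1–2 cycles, rescaled so the
  arc length equals the sampled true length exactly).
* Appearance: each fiber is a stroke of its true width around the
  centerline with butt end caps (so the mask extent equals the true
  length), a 1-px soft edge, a Gaussian bright halo ring just outside
  the core (strength 0.5 × core depth 0.35) imitating the phase halo,
  plus additive Gaussian noise (sd 0.02) inside the disc. The rendering
  style is invented — PCM optics are not simulated — so passing
  end-to-end tests demonstrates the pipeline's correctness on
  controlled imagery, not detector performance on real micrographs.
* Clutter: Poisson(8) compact dark particles, diameters 1–4 µm. These
  are deliberately non-fibrous (aspect ≈ 1) so they exercise the
  criteria filter.
* Placement: fibers are placed wholly inside the disc (bounded retries,
  then an error for fibers that cannot fit); edge-crossing fibers are
  not generated because the edge-counting rules of the underlying
  counting protocol are not implemented. `allow_overlap = FALSE`
  additionally enforces a clearance between objects — the "easy",
  well-separated regime; the default allows crossings, whose merged
  detections are the dominant failure mode of the classical backend,
  as they are for real semantic segmentation.
* Determinism: a `(spec, seed)` pair yields a bit-identical scene; the
  generator saves and restores the caller's RNG state.

Ground truth per fiber records the centerline, true arc-length and
stroke width in µm, the criteria verdict computed from those true
dimensions, and the exact rendered pixel set; a LabelMe annotation set
with stroke-outline polygons is emitted alongside for I/O round-trip
testing.

## Problem sizes used in the validation suite

The shipped tests and the acceptance workflow run the simulator at
640 × 480 px with a 140-µm field (same 0.3125 µm/px scale) and a
handful of scenes per check — small enough to iterate comfortably,
large enough that fields hold ~5 fibers of 6–60 µm. Distribution-mean
checks pool 200 sampled fibers; matching-optimality and
rectangle-fit oracles run hundreds of randomized instances. The
end-to-end check (classical backend, easy non-overlapping scenes,
noise sd 0.01) requires recall and precision ≥ 0.9 against simulator
truth; in practice both reach 1.0 at these settings.

## Numerical corner cases

* `min_area_rect` evaluates hull-edge orientations under the
  pixel-count area `(extent_u + 1)(extent_v + 1)`; a brute-force
  caliper sweep at 0.5° steps bounds it within 1% on random blobs.
  Single pixels give a 1 × 1 rectangle at 0°.
* Undefined rates (no truths, or no predictions) return `NA` rather
  than erroring, and stay `NA` through tabulation.
* Zero-area polygons are skipped with a warning during rasterization;
  overlapping polygons resolve later-shape-wins and the overlap pairs
  are reported.
* Width/length sampling resamples on width ≥ length violations;
  truncated distributions resample up to 100 rounds before erroring.

## Known limitations

* Curved-fiber length is the rectangle long side, not the arc length —
  by design, matching the measurement conventions implemented; a
  strongly wavy fiber therefore measures shorter than its true arc
  length and the simulator's truth records both.
* The classical backend is tuned to the simulator's contrast regime;
  on real micrographs a trained segmentation model should supply
  `semantic_output`/`instance_output` instead.
* No edge-crossing or bundle/split counting rules; no defocus stacks;
  no asbestos-type discrimination (PCM counts fibers, not minerals).
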