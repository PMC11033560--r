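# pcmfiber

Fiber counting in phase-contrast microscope (PCM) images of
airborne-dust filter samples.

Regulatory monitoring of airborne fibers (asbestos being the canonical
target) samples a known air volume through a membrane filter and counts
fibers in circular 300-µm fields of view under a PCM at 400×. An object
counts as a fiber when **length ≥ 5 µm, width < 3 µm, and aspect ratio
≥ 3**. Manual counting is slow and fatiguing; segmentation models can
find the fibers, but everything around the model — turning its output
into measured, criteria-checked, evaluated counts — is exactly the part
that must be reproducible. That part is this package:

* **Segmentation post-processing** — `semantic_postprocess()` (per-pixel
  probability map, threshold > 0.5, connected components) and
  `instance_postprocess()` (class probability > 0.5, soft mask ≥ 0.8)
  turn any backend's output into fiber pixel groups. A deterministic
  classical detector (`classical_detect()`) is included so the pipeline
  runs without trained weights.
* **Morphometry** — `min_area_rect()` fits the rotated minimum-area
  rectangle; `measure_instance_style()` and `measure_semantic_style()`
  implement the two width conventions (central orthogonal section
  count, and mean section count along the long axis); `px_to_um()` /
  `calibrate_scale()` handle the µm/pixel calibration (10 µm = 32 px →
  0.3125 µm/px by default).
* **Counting** — `apply_criteria()`, `count_field()`, and
  `concentration_fibers_per_L()`, which scales the mean per-field count
  by (effective filter area / field area) / air volume:
  5.5 fibers/field on a 47-mm filter (35-mm effective diameter) at
  2,400 L ⇒ **31.2 fibers/L**.
* **Evaluation** — IoU matching (`iou()`, `match_detections()`) of
  predictions to expert LabelMe polygon annotations at threshold 0.5,
  with the counted / overlooked / overcounted bookkeeping and
  micro-averaged `recall()` = TP/(TP+FN) and `precision()` =
  TP/(TP+FP) via `tabulate_matches()`.
* **Synthetic scenes** — `generate_scene()` renders PCM-like fields
  (dark fiber cores with bright halos, straight amosite-like or wavy
  chrysotile-like centerlines, non-fiber particles, noise) with
  pixel-exact ground truth, for end-to-end validation.
* **I/O** — LabelMe polygon JSON (`read_labelme()`/`write_labelme()`),
  JPEG/PNG micrographs (`read_image()`), polygon rasterization, CSV/JSON
  reports.

## Worked example

Simulate a field, detect and measure fibers with the classical backend,
apply the counting criteria, and evaluate against the simulator's own
ground truth:

```r
library(pcmfiber)

spec <- scene_spec(image_size_px = c(640L, 480L), field_diameter_um = 140,
                   noise_sd = 0.01, allow_overlap = FALSE)
scn  <- generate_scene(spec, seed = 42, field_id = "demo")
scn$annotations
#> <annotation_set> demo.png (640 x 480): 9 shapes (9 countable, 0 sub-criteria)

cand <- detect_fibers(scn$image)
head(measurements_table(cand), 4)
#>   id     convention length_um width_um aspect_ratio meets_criteria fallback_flag
#> 1  1 semantic_style      1.86    1.354         1.37          FALSE         FALSE
#> 2  2 semantic_style      1.64    1.125         1.46          FALSE         FALSE
#> 3  3 semantic_style     11.98    1.472         8.14           TRUE         FALSE
#> 4  4 semantic_style     25.89    1.325        19.54           TRUE         FALSE

count_field(cand)
#>   countable subcriteria
#>           9          10
```

The 19 detected groups include the rendered dust particles; the
criteria reject all 10 of them and keep the 9 true fibers. Matching the
countable detections against the ground-truth masks:

```r
truth <- lapply(Filter(function(f) f$is_countable, scn$fibers), `[[`, "pixels")
keep  <- vapply(cand, apply_criteria, TRUE)
evaluate_images(list(demo = cand[keep]), list(demo = truth))
#>  image expert_count counted overlooked overcounted
#>   demo            9       9          0           0
#>  Total            9       9          0           0
#> tp=9 fn=0 fp=0 | recall 100% precision 100%
```

And the concentration conversion for the reference density:

```r
conc <- concentration_fibers_per_L(5.5, sampling_config(air_volume_L = 2400))
round_half_up(conc, 1)
#> [1] 31.2
```

`run_pipeline()` wires these stages together (simulate or load images →
detect → measure → count → evaluate → concentration) from a single
`pipeline_config()`; `inst/cli/pcmfiber.R` exposes the same stages as
shell subcommands (`simulate`, `detect`, `count`, `evaluate`,
`concentration`, `report`).

## Benchmark bookkeeping

`benchmark_counts()` ships the per-image detection bookkeeping of two
published segmentation models (an instance model and a semantic model)
on ten PCM evaluation fields totalling 55 expert-counted fibers.
Pooling the semantic model's table reproduces its headline accuracy:

```r
rep <- tabulate_matches(benchmark_counts("semantic"))
c(rep$tp, rep$fn, rep$fp)        #> 52  3  5
c(rep$recall_pct, rep$precision_pct)  #> 95 91
```

## File dialects

* **LabelMe JSON**: keys `imagePath`, `imageHeight`, `imageWidth`,
  `shapes[]` with `points` (list of `[x, y]`), `label`, `shape_type`
  `"polygon"`. Labels map onto `countable_fiber` / `subcriteria_fiber`
  via a configurable label map.
* **Reports**: CSV/JSON with columns `image, expert_count, counted,
  overlooked, overcounted` plus a totals row.
* **Measurements**: CSV with `id, convention, length_um, width_um,
  aspect_ratio, meets_criteria, fallback_flag`.

See the vignette (`vignettes/fiber-counting-methods.Rmd`) for the
measurement conventions, simulator design, and validation strategy.
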