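# End-to-end orchestration: simulate -> detect -> measure -> count ->
# evaluate -> concentration, plus the bundled benchmark bookkeeping.

#' Detect and measure fibers in one image
#'
#' Runs a segmentation backend, post-processes its output into pixel
#' groups, and measures every group. The default backend is the
#' classical detector ([classical_detect()]); externally produced
#' probability maps or instance outputs can be supplied instead.
#'
#' @param image a [calibrated_image()].
#' @param backend `"classical"`, or a ready-made [semantic_output()] /
#'   [instance_output()].
#' @param convention measurement convention, `"semantic_style"`
#'   (default) or `"instance_style"`.
#' @param p_threshold,connectivity,min_pixels passed to
#'   [semantic_postprocess()]; `min_pixels` defaults to 4 to suppress
#'   speckle from the classical backend.
#' @param detect_params list of extra arguments for
#'   [classical_detect()].
#' @return list of `fiber_candidate` objects.
#' @export
detect_fibers <- function(image, backend = "classical",
                          convention = c("semantic_style",
                                         "instance_style"),
                          p_threshold = 0.5, connectivity = 8,
                          min_pixels = 4, detect_params = list()) {
  convention <- match.arg(convention)
  groups <- if (inherits(backend, "instance_output")) {
    instance_postprocess(backend)
  } else {
    out <- if (inherits(backend, "semantic_output")) backend
           else do.call(classical_detect, c(list(image), detect_params))
    semantic_postprocess(out, p_threshold, connectivity, min_pixels)
  }
  measure <- if (convention == "semantic_style") measure_semantic_style
             else measure_instance_style
  lapply(groups, measure, scale_um_per_px = image$scale_um_per_px)
}

#' Evaluate detections against ground truth for a set of images
#'
#' @param predictions named list (one element per image) of lists of
#'   pixel sets or `fiber_candidate`s.
#' @param truth named list parallel to `predictions`, each element a
#'   list of truth pixel sets.
#' @param iou_threshold,mode passed to [match_detections()].
#' @return a `match_report` from [tabulate_matches()].
#' @export
evaluate_images <- function(predictions, truth, iou_threshold = 0.5,
                            mode = "union") {
  stop_if(length(predictions) != length(truth),
          "predictions and truth must cover the same images")
  as_sets <- function(lst)
    lapply(lst, function(el)
      if (inherits(el, "fiber_candidate")) el$pixels else el)
  per_image <- lapply(seq_along(predictions), function(i)
    match_detections(as_sets(predictions[[i]]), as_sets(truth[[i]]),
                     iou_threshold, mode))
  names(per_image) <- names(predictions) %||%
    as.character(seq_along(predictions))
  tabulate_matches(per_image)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run in one validated list
#' that round-trips through YAML ([read_pipeline_config()] /
#' [write_pipeline_config()]).
#'
#' @param scale_um_per_px calibration (default 0.3125).
#' @param criteria list of [counting_criteria()] arguments.
#' @param sampling list of [sampling_config()] arguments.
#' @param detect list of [classical_detect()] arguments plus
#'   `p_threshold` / `min_pixels`.
#' @param convention measurement convention.
#' @param iou_threshold,iou_mode evaluation matching parameters.
#' @param scene list of [scene_spec()] arguments for simulated runs.
#' @param n_scenes number of fields to simulate when no input images
#'   are given.
#' @param seed master RNG seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(scale_um_per_px = 0.3125,
                            criteria = list(),
                            sampling = list(),
                            detect = list(),
                            convention = "semantic_style",
                            iou_threshold = 0.5, iou_mode = "union",
                            scene = list(), n_scenes = 10, seed = 1) {
  structure(list(scale_um_per_px = scale_um_per_px, criteria = criteria,
                 sampling = sampling, detect = detect,
                 convention = convention, iou_threshold = iou_threshold,
                 iou_mode = iou_mode, scene = scene,
                 n_scenes = n_scenes, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full counting pipeline
#'
#' Either simulates `config$n_scenes` synthetic fields (when
#' `input_dir` is `NULL`) or loads micrographs (and LabelMe annotations
#' when evaluating) from a directory, then detects, measures, applies
#' the counting criteria, evaluates against truth, and converts the
#' mean per-field count to an airborne concentration. Deterministic for
#' a fixed config and seed.
#'
#' @param config a [pipeline_config()].
#' @param input_dir optional directory of images (`.png`/`.jpg`) with
#'   matching `.json` LabelMe files when `evaluate = TRUE`.
#' @param out_dir optional output directory; when given, writes
#'   `measurements.csv`, `report.csv`, `metrics.json`,
#'   `concentration.json` and `run_log.json`.
#' @param evaluate whether to match detections against ground truth
#'   (default `TRUE`).
#' @return list with `measurements` (data.frame), `counts` (per-field
#'   countable counts), `mean_fibers_per_field`, `concentration_f_L`,
#'   and `report` (a `match_report`, when evaluated).
#' @export
run_pipeline <- function(config = pipeline_config(), input_dir = NULL,
                         out_dir = NULL, evaluate = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  criteria <- do.call(counting_criteria, config$criteria)
  sampling <- do.call(sampling_config, config$sampling)
  detect_args <- config$detect
  p_thr <- detect_args$p_threshold %||% 0.5
  min_px <- detect_args$min_pixels %||% 4
  detect_args$p_threshold <- NULL; detect_args$min_pixels <- NULL

  images <- list(); truth <- list()
  if (is.null(input_dir)) {
    spec <- do.call(scene_spec, c(config$scene,
                                  list(scale_um_per_px =
                                         config$scale_um_per_px)))
    for (i in seq_len(config$n_scenes)) {
      scn <- generate_scene(spec, seed = config$seed + i,
                            field_id = sprintf("sim-%03d", i))
      images[[scn$image$field_id]] <- scn$image
      truth[[scn$image$field_id]] <-
        lapply(Filter(function(f) f$is_countable, scn$fibers),
               `[[`, "pixels")
    }
  } else {
    files <- list.files(input_dir, "\\.(png|jpe?g)$", full.names = TRUE)
    stop_if(length(files) == 0, "no images found in ", input_dir)
    for (f in files) {
      im <- read_image(f, config$scale_um_per_px)
      images[[im$field_id]] <- im
      jf <- file.path(input_dir,
                      paste0(tools::file_path_sans_ext(basename(f)),
                             ".json"))
      if (file.exists(jf)) {
        ann <- read_labelme(jf)
        keep <- Filter(function(s) s$label == "countable_fiber",
                       ann$shapes)
        ann2 <- annotation_set(ann$image_ref, ann$image_size, keep)
        mask <- polygons_to_mask(ann2)
        truth[[im$field_id]] <- lapply(
          seq_along(keep),
          function(k) mask_to_pixels(mask == k))
      } else if (evaluate) {
        stop("evaluation requested but annotation file missing: ", jf,
             call. = FALSE)
      }
    }
  }

  meas <- list(); preds <- list(); counts <- integer(0)
  for (id in names(images)) {
    cand <- detect_fibers(images[[id]], convention = config$convention,
                          p_threshold = p_thr, min_pixels = min_px,
                          detect_params = detect_args)
    tab <- measurements_table(cand, criteria)
    if (nrow(tab)) tab <- cbind(image = id, tab)
    meas[[id]] <- tab
    keep <- vapply(cand, apply_criteria, TRUE, criteria = criteria)
    preds[[id]] <- lapply(cand[keep], `[[`, "pixels")
    counts[id] <- sum(keep)
  }
  measurements <- do.call(rbind, meas)
  mean_fpf <- mean(counts)
  conc <- concentration_fibers_per_L(mean_fpf, sampling)

  report <- NULL
  if (evaluate && length(truth) == length(images))
    report <- evaluate_images(preds, truth, config$iou_threshold,
                              config$iou_mode)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(measurements, file.path(out_dir, "measurements.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(mean_fibers_per_field = mean_fpf,
           concentration_fibers_per_L = round_half_up(conc, 1)),
      file.path(out_dir, "concentration.json"),
      auto_unbox = TRUE, digits = NA)
    if (!is.null(report)) {
      write_report(report, file.path(out_dir, "report.csv"))
      jsonlite::write_json(
        list(tp = report$tp, fn = report$fn, fp = report$fp,
             recall = report$recall, precision = report$precision,
             recall_pct = report$recall_pct,
             precision_pct = report$precision_pct),
        file.path(out_dir, "metrics.json"), auto_unbox = TRUE,
        digits = NA)
    }
    jsonlite::write_json(
      list(package_version =
             as.character(utils::packageVersion("pcmfiber")),
           seed = config$seed,
           config_hash = sum(utf8ToInt(paste(deparse(unclass(config)),
                                             collapse = "")))),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE)
  }

  list(measurements = measurements, counts = counts,
       mean_fibers_per_field = mean_fpf,
       concentration_f_L = conc, report = report)
}

#' Bundled benchmark detection bookkeeping
#'
#' Per-image fiber counting results for ten phase-contrast evaluation
#' fields (five amosite-like, five chrysotile-like): the expert
#' analyst's reference counts and, for two published segmentation
#' models (an instance model and a semantic model), the counted /
#' overlooked / overcounted bookkeeping. Shipped as plain CSV in
#' `inst/extdata/`; useful for exercising the evaluation arithmetic
#' without image data.
#'
#' @param model `"semantic"` (the semantic segmentation model),
#'   `"instance"` (the instance segmentation model), or `"both"` for
#'   the raw table.
#' @return data.frame; for a single model, the columns `image`,
#'   `expert_count`, `counted`, `overlooked`, `overcounted` ready for
#'   [tabulate_matches()].
#' @export
benchmark_counts <- function(model = c("semantic", "instance", "both")) {
  model <- match.arg(model)
  raw <- read.csv(system.file("extdata", "benchmark_counts.csv",
                              package = "pcmfiber"))
  if (model == "both") return(raw)
  pre <- if (model == "semantic") "semantic_" else "instance_"
  data.frame(image = raw$image,
             expert_count = raw$expert_count,
             counted = raw[[paste0(pre, "counted")]],
             overlooked = raw[[paste0(pre, "overlooked")]],
             overcounted = raw[[paste0(pre, "overcounted")]])
}
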