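# Fiber morphometry: rotated minimum-bounding rectangle, length/width
# under the instance-style and semantic-style conventions, calibration.

#' Convert a pixel count to micrometres
#'
#' @param n_px pixel count (non-negative real).
#' @param scale_um_per_px calibration, micrometres per pixel.
#' @return `n_px * scale_um_per_px`.
#' @export
px_to_um <- function(n_px, scale_um_per_px = 0.3125) {
  stop_if(any(n_px < 0), "pixel count must be non-negative")
  stop_if(scale_um_per_px <= 0, "scale must be positive")
  n_px * scale_um_per_px
}

#' Derive the pixel calibration from a micrometre scale image
#'
#' @param length_um known physical length (e.g. 10 for one scale-bar
#'   division).
#' @param n_px measured length of the same feature in pixels (e.g. 32).
#' @return micrometres per pixel (`length_um / n_px`; 10/32 = 0.3125).
#' @export
calibrate_scale <- function(length_um, n_px) {
  stop_if(length_um <= 0 || n_px <= 0,
          "length and pixel count must be positive")
  length_um / n_px
}

#' Minimum-area rotated rectangle of a pixel set
#'
#' Finds the rotated rectangle of minimum area enclosing all pixel
#' centers, then pads every side by half a pixel so side lengths count
#' pixels: an axis-aligned bar of 16 x 4 pixels measures exactly
#' 16 x 4. Candidate orientations are the convex-hull edge directions;
#' the orientation minimizing padded area (long + 1)(short + 1 in center
#' extent terms) is chosen. The angle of the long axis is normalized to
#' `[0, 180)` degrees, measured from the +x axis toward +y.
#'
#' @param pixels a [pixel_set()] (non-empty).
#' @return object of class `rotated_rect`: `center` (x, y),
#'   `long_side_px`, `short_side_px`, `angle_deg`.
#' @export
min_area_rect <- function(pixels) {
  stop_if(is.null(pixels) || nrow(pixels) == 0, "empty pixel set")
  pts <- cbind(as.numeric(pixels[, "x"]), as.numeric(pixels[, "y"]))
  if (nrow(pts) == 1) {
    return(structure(list(center = c(x = pts[1, 1], y = pts[1, 2]),
                          long_side_px = 1, short_side_px = 1,
                          angle_deg = 0),
                     class = "rotated_rect"))
  }
  hull <- unique(pts[chull(pts), , drop = FALSE])
  n <- nrow(hull)
  edges <- if (n >= 2) {
    nxt <- c(2:n, 1)
    e <- hull[nxt, , drop = FALSE] - hull
    e[rowSums(e^2) > 0, , drop = FALSE]
  } else matrix(c(1, 0), ncol = 2)
  if (nrow(edges) == 0) edges <- matrix(c(1, 0), ncol = 2)
  angles <- unique(round(atan2(edges[, 2], edges[, 1]) %% pi, 12))
  best <- NULL
  for (th in angles) {
    ct <- cos(th); st <- sin(th)
    u <- pts[, 1] * ct + pts[, 2] * st
    v <- -pts[, 1] * st + pts[, 2] * ct
    eu <- max(u) - min(u); ev <- max(v) - min(v)
    area <- (eu + 1) * (ev + 1)
    if (is.null(best) || area < best$area - 1e-12) {
      cx <- (max(u) + min(u)) / 2; cy <- (max(v) + min(v)) / 2
      best <- list(area = area, theta = th, eu = eu, ev = ev,
                   center = c(x = cx * ct - cy * st,
                              y = cx * st + cy * ct))
    }
  }
  long <- max(best$eu, best$ev) + 1
  short <- min(best$eu, best$ev) + 1
  theta <- if (best$eu >= best$ev) best$theta else best$theta + pi / 2
  structure(list(center = best$center,
                 long_side_px = long, short_side_px = short,
                 angle_deg = (theta * 180 / pi) %% 180),
            class = "rotated_rect")
}

#' @export
print.rotated_rect <- function(x, ...) {
  cat(sprintf("<rotated_rect> %.2f x %.2f px at (%.1f, %.1f), %.1f deg\n",
              x$long_side_px, x$short_side_px,
              x$center["x"], x$center["y"], x$angle_deg))
  invisible(x)
}

# rotate pixel centers into the rect frame: u along long axis, v across
rect_frame <- function(pixels, rect) {
  th <- rect$angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  dx <- as.numeric(pixels[, "x"]) - rect$center["x"]
  dy <- as.numeric(pixels[, "y"]) - rect$center["y"]
  cbind(u = dx * ct + dy * st, v = -dx * st + dy * ct)
}

new_fiber_candidate <- function(pixels, rect, length_px, width_px,
                                scale, convention, fallback = FALSE,
                                source_probability = NA_real_) {
  length_um <- length_px * scale
  width_um <- width_px * scale
  structure(list(
    pixels = pixels, rect = rect,
    length_px = length_px, width_px = width_px,
    length_um = length_um, width_um = width_um,
    aspect_ratio = length_um / width_um,
    convention = convention,
    scale_um_per_px = scale,
    fallback = fallback,
    source_probability = source_probability
  ), class = "fiber_candidate")
}

#' @export
print.fiber_candidate <- function(x, ...) {
  cat(sprintf("<fiber_candidate> [%s] L=%.2f um W=%.2f um AR=%.2f (%d px)\n",
              x$convention, x$length_um, x$width_um, x$aspect_ratio,
              nrow(x$pixels)))
  invisible(x)
}

# Count group pixels on the orthogonal section line at long-axis offset
# cu. Line-sampling rule: walk the line through (center + cu *
# long-axis direction) along the short-axis direction at unit (1-px)
# steps out to short_side/2 + 1, round each sample to the nearest
# pixel, and count samples that land on group pixels. Unit Euclidean
# steps keep the count orientation-independent (a lattice-pixel count
# would inflate diagonal sections by up to sqrt(2)).
section_count <- function(pixels, rect, cu) {
  th <- rect$angle_deg * pi / 180
  long_dir <- c(cos(th), sin(th))
  short_dir <- c(-sin(th), cos(th))
  p0 <- c(rect$center["x"], rect$center["y"]) + cu * long_dir
  kmax <- floor(rect$short_side_px / 2 + 1)
  tt <- -kmax:kmax
  sx <- round(p0[1] + tt * short_dir[1])
  sy <- round(p0[2] + tt * short_dir[2])
  keys_line <- sx + sy * 1e6
  keys_grp <- as.numeric(pixels[, "x"]) + as.numeric(pixels[, "y"]) * 1e6
  sum(keys_line %in% keys_grp)
}

#' Measure a fiber the instance-segmentation way
#'
#' Length is the long side of the rotated minimum-area rectangle
#' ([min_area_rect()]). Width is the number of group pixels on the line
#' through the rectangle center orthogonal to the long axis, rasterized
#' by sampling the line at unit steps and rounding each sample to the
#' nearest pixel (so the count is orientation-independent). If that
#' central section meets no group pixels (strongly curved fibers), the
#' nearest populated section along the long axis is used instead and
#' `fallback` is set.
#'
#' @param pixels a [pixel_set()].
#' @param scale_um_per_px calibration (default 0.3125).
#' @param source_probability optional detection probability carried
#'   through from the segmentation backend.
#' @return a `fiber_candidate` with `convention = "instance_style"`.
#' @export
measure_instance_style <- function(pixels, scale_um_per_px = 0.3125,
                                   source_probability = NA_real_) {
  stop_if(is.null(pixels) || nrow(pixels) == 0, "empty pixel set")
  rect <- min_area_rect(pixels)
  frame <- rect_frame(pixels, rect)
  w <- section_count(pixels, rect, 0)
  fallback <- FALSE
  if (w == 0) {
    fallback <- TRUE
    # nearest populated orthogonal section along the long axis
    for (cu in unique(frame[order(abs(frame[, "u"])), "u"])) {
      w <- section_count(pixels, rect, cu)
      if (w > 0) break
    }
    if (w == 0) w <- 1  # isolated-pixel safeguard
  }
  new_fiber_candidate(pixels, rect, rect$long_side_px, w,
                      scale_um_per_px, "instance_style", fallback,
                      source_probability)
}

#' Measure a fiber the semantic-segmentation way
#'
#' Length is the long side of the rotated minimum-area rectangle. Width
#' is the average, over positions along the long axis, of the number of
#' group pixels in the short-axis direction: pixel coordinates are
#' rotated into the rectangle frame, binned into unit-width bins along
#' the long axis (bin = round of the long-axis coordinate), and the
#' width is the mean pixel count over non-empty bins (empty bins along
#' curved fibers are excluded from the mean).
#'
#' @inheritParams measure_instance_style
#' @return a `fiber_candidate` with `convention = "semantic_style"`.
#' @export
measure_semantic_style <- function(pixels, scale_um_per_px = 0.3125,
                                   source_probability = NA_real_) {
  stop_if(is.null(pixels) || nrow(pixels) == 0, "empty pixel set")
  rect <- min_area_rect(pixels)
  frame <- rect_frame(pixels, rect)
  # unit-width bins along the long axis, anchored at the first pixel so
  # integer-spaced centers land one per bin
  u <- frame[, "u"]
  bins <- floor(u - min(u) + 0.5)
  w <- mean(table(bins))
  new_fiber_candidate(pixels, rect, rect$long_side_px, w,
                      scale_um_per_px, "semantic_style",
                      fallback = FALSE, source_probability)
}

#' Tabulate fiber candidates as a data frame
#'
#' @param candidates list of `fiber_candidate` objects.
#' @param criteria a [counting_criteria()] used for the
#'   `meets_criteria` column.
#' @return data.frame with one row per fiber: id, convention,
#'   length_um, width_um, aspect_ratio, meets_criteria, fallback_flag.
#' @export
measurements_table <- function(candidates, criteria = counting_criteria()) {
  if (length(candidates) == 0) {
    return(data.frame(id = integer(0), convention = character(0),
                      length_um = numeric(0), width_um = numeric(0),
                      aspect_ratio = numeric(0),
                      meets_criteria = logical(0),
                      fallback_flag = logical(0)))
  }
  data.frame(
    id = seq_along(candidates),
    convention = vapply(candidates, `[[`, "", "convention"),
    length_um = vapply(candidates, `[[`, 0, "length_um"),
    width_um = vapply(candidates, `[[`, 0, "width_um"),
    aspect_ratio = vapply(candidates, `[[`, 0, "aspect_ratio"),
    meets_criteria = vapply(candidates, apply_criteria, TRUE,
                            criteria = criteria),
    fallback_flag = vapply(candidates, `[[`, TRUE, "fallback")
  )
}
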