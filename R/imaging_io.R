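# Raster + annotation I/O: micrographs, LabelMe polygon JSON, masks,
# tabular reports.

#' Construct a calibrated field-of-view image
#'
#' Wraps a grayscale intensity raster together with the physical
#' calibration (micrometres per pixel) and an identifier for the field of
#' view. Intensities are stored as a numeric matrix in `[0, 1]` with
#' `pixels[y + 1, x + 1]` addressing the pixel at 0-based `(x, y)`.
#'
#' @param pixels numeric matrix, rows = image height, cols = width.
#' @param scale_um_per_px positive real, micrometres per pixel
#'   (default 0.3125, i.e. 10 um per 32 px at 400x magnification).
#' @param field_id character identifier, e.g. `"Amo-1-B1"`.
#' @param field_diameter_um diameter of the circular field-of-view
#'   graticule in um (default 300); `NA` when the image has no defined
#'   field disc.
#' @return object of class `calibrated_image` with fields `pixels`,
#'   `width_px`, `height_px`, `scale_um_per_px`, `field_id`,
#'   `field_diameter_um`.
#' @export
calibrated_image <- function(pixels, scale_um_per_px = 0.3125,
                             field_id = "field",
                             field_diameter_um = 300) {
  stop_if(!is.matrix(pixels) || !is.numeric(pixels),
          "pixels must be a numeric matrix")
  stop_if(!is.numeric(scale_um_per_px) || scale_um_per_px <= 0,
          "scale_um_per_px must be a positive real")
  structure(list(
    pixels = pixels,
    width_px = ncol(pixels),
    height_px = nrow(pixels),
    scale_um_per_px = as.numeric(scale_um_per_px),
    field_id = as.character(field_id),
    field_diameter_um = as.numeric(field_diameter_um)
  ), class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %s: %d x %d px, %.4f um/px\n",
              x$field_id, x$width_px, x$height_px, x$scale_um_per_px))
  invisible(x)
}

#' Read a micrograph from disk
#'
#' Reads a JPEG/PNG/TIFF raster and attaches the pixel calibration. RGB
#' images are converted to grayscale with the Rec. 709 luma weights
#' (0.2126 R + 0.7152 G + 0.0722 B); grayscale images load unchanged.
#'
#' @param path image file path.
#' @param scale_um_per_px calibration to attach (default 0.3125).
#' @param field_id identifier; defaults to the file name without
#'   extension.
#' @param field_diameter_um field-of-view diameter to attach
#'   (default 300).
#' @return a [calibrated_image()].
#' @export
read_image <- function(path, scale_um_per_px = 0.3125, field_id = NULL,
                       field_diameter_um = 300) {
  stop_if(!file.exists(path), "file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  stop_if(!ext %in% c("jpg", "jpeg", "png", "tif", "tiff"),
          "unsupported raster format: '", ext, "' (use JPEG/PNG/TIFF)")
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3) {
    nch <- dim(dat)[3]
    if (nch >= 3) {
      dat <- 0.2126 * dat[, , 1] + 0.7152 * dat[, , 2] + 0.0722 * dat[, , 3]
    } else {
      dat <- dat[, , 1]
    }
  }
  # EBImage stores [x, y]; transpose to [row = y, col = x]
  px <- t(dat)
  px[px < 0] <- 0; px[px > 1] <- 1
  calibrated_image(px, scale_um_per_px,
                   field_id %||% tools::file_path_sans_ext(basename(path)),
                   field_diameter_um)
}

#' Write a calibrated image to disk
#'
#' @param image a [calibrated_image()].
#' @param path output path; format from extension (PNG/JPEG/TIFF).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  EBImage::writeImage(EBImage::as.Image(t(image$pixels)), path)
  invisible(path)
}

# annotation sets ------------------------------------------------------

#' Fiber annotation labels
#'
#' The two-value vocabulary for expert fiber annotations: fibers meeting
#' the counting criteria (`countable_fiber`) and fibers visible but
#' below the criteria (`subcriteria_fiber`).
#' @export
fiber_labels <- c("countable_fiber", "subcriteria_fiber")

#' Construct an annotation set
#'
#' Expert ground truth for one image: labeled polygons in pixel
#' coordinates. Each shape is a list with `points` (n x 2 numeric matrix,
#' columns x, y), `label` (one of [fiber_labels]) and `notes` (free
#' text, possibly `NA`).
#'
#' @param image_ref image file name the annotations refer to.
#' @param image_size integer pair `(width_px, height_px)`.
#' @param shapes list of shapes as described above.
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(image_ref, image_size, shapes = list()) {
  stop_if(length(image_size) != 2 || any(image_size <= 0),
          "image_size must be a positive (width, height) pair")
  image_size <- as.integer(image_size)
  for (i in seq_along(shapes)) {
    s <- shapes[[i]]
    stop_if(is.null(s$points) || nrow(s$points) < 3,
            "shape ", i, ": polygon must have >= 3 vertices")
    stop_if(!s$label %in% fiber_labels,
            "shape ", i, ": label must be one of ",
            paste(fiber_labels, collapse = ", "))
    pts <- s$points
    stop_if(any(pts[, 1] < 0 | pts[, 1] > image_size[1] |
                  pts[, 2] < 0 | pts[, 2] > image_size[2]),
            "shape ", i, ": vertex outside image bounds")
    colnames(shapes[[i]]$points) <- c("x", "y")
    shapes[[i]]$notes <- s$notes %||% NA_character_
  }
  structure(list(image_ref = as.character(image_ref),
                 image_size = image_size,
                 shapes = shapes),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  lab <- vapply(x$shapes, `[[`, "", "label")
  cat(sprintf("<annotation_set> %s (%d x %d): %d shapes (%d countable, %d sub-criteria)\n",
              x$image_ref, x$image_size[1], x$image_size[2], length(x$shapes),
              sum(lab == "countable_fiber"), sum(lab == "subcriteria_fiber")))
  invisible(x)
}

#' Default LabelMe label map
#'
#' Maps raw LabelMe shape labels onto the two-value fiber vocabulary.
#' Unmapped labels fall back to `countable_fiber` with the original
#' label preserved in the shape's notes.
#' @export
default_label_map <- c(
  fiber = "countable_fiber",
  countable_fiber = "countable_fiber",
  countable = "countable_fiber",
  subcriteria_fiber = "subcriteria_fiber",
  subcriteria = "subcriteria_fiber",
  sub_criteria_fiber = "subcriteria_fiber"
)

#' Read a LabelMe polygon annotation file
#'
#' Parses the LabelMe JSON dialect (keys `imagePath`, `imageHeight`,
#' `imageWidth`, `shapes[].points`/`label`) into an [annotation_set()].
#' Labels are mapped onto the two-value vocabulary through `label_map`;
#' labels absent from the map become `countable_fiber` and the original
#' label is kept in `notes`.
#'
#' @param path JSON file path.
#' @param label_map named character vector, raw label -> vocabulary
#'   label (default [default_label_map]).
#' @return an [annotation_set()].
#' @export
read_labelme <- function(path, label_map = default_label_map) {
  stop_if(!file.exists(path), "file not found: ", path)
  js <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e)
                   stop("malformed JSON in ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  for (key in c("imagePath", "imageHeight", "imageWidth", "shapes"))
    stop_if(is.null(js[[key]]), "LabelMe parse error: missing key '", key, "'")
  shapes <- lapply(seq_along(js$shapes), function(i) {
    sh <- js$shapes[[i]]
    stop_if(is.null(sh$points), "shape ", i, ": missing 'points'")
    pts <- do.call(rbind, lapply(sh$points, unlist))
    stop_if(is.null(pts) || nrow(pts) < 3,
            "validation error: shape ", i, " has fewer than 3 points")
    raw <- as.character(sh$label %||% "fiber")
    mapped <- unname(label_map[raw])
    notes <- if (is.na(mapped)) {
      mapped <- "countable_fiber"
      paste0("original_label=", raw)
    } else NA_character_
    list(points = `colnames<-`(pts, c("x", "y")), label = mapped,
         notes = notes)
  })
  annotation_set(js$imagePath, c(js$imageWidth, js$imageHeight), shapes)
}

#' Write an annotation set as LabelMe JSON
#'
#' Emits the LabelMe polygon-JSON dialect readable by [read_labelme()];
#' vertex coordinates round-trip losslessly.
#'
#' @param annotations an [annotation_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labelme <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  shapes <- lapply(annotations$shapes, function(s) {
    list(label = jsonlite::unbox(s$label),
         points = unname(lapply(seq_len(nrow(s$points)), function(i)
           as.numeric(s$points[i, ]))),
         group_id = NULL,
         shape_type = jsonlite::unbox("polygon"),
         flags = setNames(list(), character(0)),
         description = jsonlite::unbox(
           if (is.na(s$notes)) "" else s$notes))
  })
  js <- list(version = jsonlite::unbox("5.0.0"),
             flags = setNames(list(), character(0)),
             shapes = shapes,
             imagePath = jsonlite::unbox(annotations$image_ref),
             imageData = NULL,
             imageHeight = jsonlite::unbox(annotations$image_size[2]),
             imageWidth = jsonlite::unbox(annotations$image_size[1]))
  ok <- tryCatch({
    writeLines(jsonlite::toJSON(js, null = "null", digits = NA), path)
    TRUE
  }, error = function(e) FALSE)
  stop_if(!ok, "cannot write file: ", path)
  invisible(path)
}

# polygon rasterization ------------------------------------------------

# even-odd point-in-polygon, boundary-inclusive, vectorized over points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # boundary test: point on segment (x1,y1)-(x2,y2)
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    dot <- (px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)
    len2 <- (x2 - x1)^2 + (y2 - y1)^2
    on_edge <- on_edge | (abs(cross) < 1e-9 * max(1, sqrt(len2)) &
                            dot >= -1e-9 & dot <= len2 + 1e-9)
    # ray crossing
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside | on_edge
}

polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Rasterize polygon annotations to a labeled mask
#'
#' Fills each polygon into an integer raster: 0 = background, k = pixels
#' of shape k. Fill rule: a pixel belongs to a shape when its center
#' (x + 0, y + 0 in 0-based continuous coordinates, i.e. the integer
#' lattice point) lies inside or on the polygon boundary. Where shapes
#' overlap, the later shape wins; overlapping shape pairs are reported
#' via the `"overlaps"` attribute. Zero-area polygons are skipped with a
#' warning.
#'
#' @param annotations an [annotation_set()].
#' @param image_size optional `(width, height)` override; defaults to
#'   the annotation set's image size.
#' @return integer matrix `[height, width]` with an `"overlaps"`
#'   attribute (integer matrix of overlapping shape-index pairs).
#' @export
polygons_to_mask <- function(annotations, image_size = NULL) {
  stopifnot(inherits(annotations, "annotation_set"))
  sz <- as.integer(image_size %||% annotations$image_size)
  w <- sz[1]; h <- sz[2]
  mask <- matrix(0L, nrow = h, ncol = w)
  overlaps <- matrix(integer(0), ncol = 2)
  for (k in seq_along(annotations$shapes)) {
    pts <- annotations$shapes[[k]]$points
    if (polygon_area(pts) <= 0) {
      warning("shape ", k, " has zero area; skipped")
      next
    }
    xr <- max(0L, floor(min(pts[, 1]))):min(w - 1L, ceiling(max(pts[, 1])))
    yr <- max(0L, floor(min(pts[, 2]))):min(h - 1L, ceiling(max(pts[, 2])))
    g <- expand.grid(x = xr, y = yr)
    hit <- point_in_polygon(g$x, g$y, pts[, 1], pts[, 2])
    if (!any(hit)) next
    ij <- cbind(g$y[hit] + 1L, g$x[hit] + 1L)
    prev <- unique(mask[ij])
    prev <- prev[prev > 0]
    if (length(prev))
      overlaps <- rbind(overlaps, cbind(prev, k))
    mask[ij] <- k
  }
  attr(mask, "overlaps") <- overlaps
  mask
}

# reports --------------------------------------------------------------

#' Write a per-image detection report
#'
#' Writes the per-image bookkeeping (image, expert count, counted,
#' overlooked, overcounted) plus a totals row, as CSV and/or JSON with a
#' stable column order.
#'
#' @param report data.frame with columns `image`, `expert_count`,
#'   `counted`, `overlooked`, `overcounted` (one row per image), or a
#'   `match_report` from [tabulate_matches()].
#' @param path output path; `.csv` or `.json` decides the format.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "match_report")) report <- report$per_image
  cols <- c("image", "expert_count", "counted", "overlooked", "overcounted")
  stop_if(!all(cols %in% names(report)),
          "report must have columns: ", paste(cols, collapse = ", "))
  report <- report[, cols]
  total <- data.frame(image = "Total",
                      expert_count = sum(report$expert_count),
                      counted = sum(report$counted),
                      overlooked = sum(report$overlooked),
                      overcounted = sum(report$overcounted))
  out <- rbind(report, total)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA)
  } else {
    write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}
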