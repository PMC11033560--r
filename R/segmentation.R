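# Segmentation backends: post-processing contracts for semantic and
# instance model outputs, plus a deterministic classical detector.

#' Semantic segmentation output
#'
#' A per-pixel fiber probability map, as produced by a semantic
#' segmentation model (one probability per pixel that it belongs to a
#' fiber rather than background).
#'
#' @param prob_map numeric matrix `[height, width]` with values in
#'   `[0, 1]`.
#' @return object of class `semantic_output`.
#' @export
semantic_output <- function(prob_map) {
  stop_if(!is.matrix(prob_map) || !is.numeric(prob_map),
          "prob_map must be a numeric matrix")
  stop_if(any(prob_map < 0 | prob_map > 1),
          "probabilities must lie in [0, 1]")
  structure(list(prob_map = prob_map), class = "semantic_output")
}

#' Instance segmentation output
#'
#' A list of detected object instances, each with a bounding box, a
#' class probability, and a soft segmentation mask, as produced by an
#' instance segmentation model.
#'
#' @param instances list; each element has `box` (x0, y0, x1, y1 in
#'   0-based pixel coords, inclusive), `class_probability` in `[0, 1]`,
#'   and `mask`, a numeric matrix in `[0, 1]` — either image-sized or
#'   box-sized.
#' @param image_size integer `(width, height)` pair.
#' @return object of class `instance_output`.
#' @export
instance_output <- function(instances, image_size) {
  image_size <- as.integer(image_size)
  for (i in seq_along(instances)) {
    inst <- instances[[i]]
    stop_if(is.null(inst$mask) || any(inst$mask < 0 | inst$mask > 1),
            "instance ", i, ": mask values must lie in [0, 1]")
    p <- inst$class_probability
    stop_if(is.null(p) || p < 0 || p > 1,
            "instance ", i, ": class probability must lie in [0, 1]")
    b <- inst$box
    stop_if(!is.null(b) && (b[1] < 0 || b[2] < 0 ||
                              b[3] >= image_size[1] || b[4] >= image_size[2]),
            "instance ", i, ": box outside image bounds")
  }
  structure(list(instances = instances, image_size = image_size),
            class = "instance_output")
}

# connected components of a logical mask via igraph; connectivity 4 or 8
label_components <- function(mask, connectivity = 8) {
  stop_if(!connectivity %in% c(4, 8), "connectivity must be 4 or 8")
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  h <- nrow(mask); w <- ncol(mask)
  row <- (idx - 1L) %% h        # 0-based y
  col <- (idx - 1L) %/% h       # 0-based x
  id <- seq_along(idx)          # vertex ids within foreground
  lut <- integer(h * w); lut[idx] <- id
  offs <- list(c(1L, 0L), c(0L, 1L))            # down, right
  if (connectivity == 8)
    offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))  # two diagonals
  edges <- NULL
  for (o in offs) {
    r2 <- row + o[1]; c2 <- col + o[2]
    ok <- r2 >= 0 & r2 < h & c2 >= 0 & c2 < w
    nb <- lut[r2[ok] + 1L + c2[ok] * h]
    keep <- nb > 0
    if (any(keep))
      edges <- rbind(edges, cbind(id[ok][keep], nb[keep]))
  }
  g <- igraph::graph_from_edgelist(
    if (is.null(edges)) matrix(integer(0), ncol = 2) else edges,
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(id) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership[seq_along(id)]
  groups <- split(seq_along(id), memb)
  # deterministic ordering: by smallest linear pixel index in the group
  groups <- groups[order(vapply(groups, function(g0) min(idx[g0]), 0))]
  names(groups) <- NULL
  lapply(groups, function(g0) pixel_set(x = col[g0], y = row[g0]))
}

#' Extract fiber pixel groups from a semantic probability map
#'
#' Thresholds the map at `p_threshold` (strictly greater, matching the
#' "probability greater than 50 percent" convention) and returns the
#' connected components of the surviving pixels.
#'
#' @param out a [semantic_output()] or bare probability matrix.
#' @param p_threshold probability cutoff in `[0, 1]` (default 0.5,
#'   strict).
#' @param connectivity pixel adjacency, 4 or 8 (default 8 so diagonal
#'   fiber runs stay connected).
#' @param min_pixels components smaller than this are dropped
#'   (default 1, i.e. no suppression); drops are reported via the
#'   `"dropped"` attribute.
#' @return list of [pixel_set()]s, ordered by first pixel position.
#' @export
semantic_postprocess <- function(out, p_threshold = 0.5, connectivity = 8,
                                 min_pixels = 1) {
  if (is.matrix(out)) out <- semantic_output(out)
  stopifnot(inherits(out, "semantic_output"))
  stop_if(p_threshold < 0 || p_threshold > 1,
          "p_threshold must lie in [0, 1]")
  groups <- label_components(out$prob_map > p_threshold, connectivity)
  sizes <- vapply(groups, nrow, 0L)
  dropped <- sum(sizes < min_pixels)
  groups <- groups[sizes >= min_pixels]
  attr(groups, "dropped") <- dropped
  groups
}

#' Extract fiber pixel groups from instance segmentation output
#'
#' Keeps instances whose class probability is strictly greater than
#' `class_threshold` ("more than 50 percent"), then for each kept
#' instance takes the pixels whose soft-mask value is greater than or
#' equal to `mask_threshold` ("0.8 or more") — note the asymmetric
#' strict/inclusive comparisons. Instances whose thresholded mask is
#' empty are dropped and counted in the `"dropped"` attribute.
#'
#' @param out an [instance_output()].
#' @param class_threshold class-probability cutoff (default 0.5,
#'   strict).
#' @param mask_threshold soft-mask cutoff (default 0.8, inclusive).
#' @return list of [pixel_set()]s, one per retained instance, with a
#'   `"probabilities"` attribute carrying each instance's class
#'   probability.
#' @export
instance_postprocess <- function(out, class_threshold = 0.5,
                                 mask_threshold = 0.8) {
  stopifnot(inherits(out, "instance_output"))
  stop_if(class_threshold < 0 || class_threshold > 1 ||
            mask_threshold < 0 || mask_threshold > 1,
          "thresholds must lie in [0, 1]")
  groups <- list()
  probs <- numeric(0)
  dropped <- 0L
  for (inst in out$instances) {
    if (!(inst$class_probability > class_threshold)) next
    m <- inst$mask
    sel <- which(m >= mask_threshold, arr.ind = TRUE)
    if (nrow(sel) == 0) { dropped <- dropped + 1L; next }
    x <- sel[, "col"] - 1L
    y <- sel[, "row"] - 1L
    if (!is.null(inst$box) &&
        !identical(dim(m), c(out$image_size[2], out$image_size[1]))) {
      # box-local mask: offset into image coordinates
      x <- x + as.integer(inst$box[1])
      y <- y + as.integer(inst$box[2])
    }
    groups[[length(groups) + 1]] <- pixel_set(x, y)
    probs <- c(probs, inst$class_probability)
  }
  attr(groups, "probabilities") <- probs
  attr(groups, "dropped") <- dropped
  groups
}

#' Classical fiber detector
#'
#' A deterministic, training-free detector producing a pseudo
#' probability map from classical image operations, so the pipeline can
#' run end-to-end without a trained model. The chain: (1) background
#' estimation by heavy Gaussian blur; (2) darkness map = background
#' minus image (phase-contrast fibers are dark cores on a light
#' background); (3) optional 3x3 median filter to suppress
#' single-pixel noise (off by default); (4) linear ramp mapping darkness in
#' `[ramp_lo, ramp_hi]` onto `[0, 1]`, clamped; (5) when the image
#' declares a field disc that fits inside the raster, probabilities
#' outside the disc (minus a 2-px guard band at the rim) are zeroed so
#' the rim itself is never detected as a fiber.
#'
#' @param image a [calibrated_image()].
#' @param bg_sigma Gaussian sigma (px) for background estimation
#'   (default 15).
#' @param ramp_lo,ramp_hi darkness values mapped to probability 0 and 1
#'   (defaults 0.05 and 0.15).
#' @param median_radius radius of an optional median denoising filter
#'   in px (default 0, disabled: a 3x3 median erases one-pixel-wide
#'   fiber runs; single-pixel noise is handled by the minimum
#'   component size in post-processing instead).
#' @return a [semantic_output()].
#' @export
classical_detect <- function(image, bg_sigma = 15, ramp_lo = 0.05,
                             ramp_hi = 0.15, median_radius = 0) {
  stopifnot(inherits(image, "calibrated_image"))
  stop_if(ramp_hi <= ramp_lo, "ramp_hi must exceed ramp_lo")
  px <- image$pixels
  ei <- EBImage::as.Image(t(px))
  bg <- EBImage::gblur(ei, sigma = bg_sigma)
  dark <- t(EBImage::imageData(bg) - EBImage::imageData(ei))
  dark[dark < 0] <- 0
  if (median_radius > 0) {
    dm <- EBImage::medianFilter(EBImage::as.Image(t(dark)), median_radius)
    dark <- t(EBImage::imageData(dm))
  }
  p <- (dark - ramp_lo) / (ramp_hi - ramp_lo)
  p[p < 0] <- 0; p[p > 1] <- 1
  fd <- image$field_diameter_um %||% NA_real_
  if (is.finite(fd)) {
    r_field <- fd / 2 / image$scale_um_per_px
    h2 <- nrow(p); w2 <- ncol(p)
    if (2 * r_field <= min(w2, h2)) {
      cx <- (w2 - 1) / 2; cy <- (h2 - 1) / 2
      xs <- matrix(rep(0:(w2 - 1), each = h2), nrow = h2)
      ys <- matrix(rep(0:(h2 - 1), w2), nrow = h2)
      p[(xs - cx)^2 + (ys - cy)^2 > (r_field - 2)^2] <- 0
    }
  }
  semantic_output(p)
}
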