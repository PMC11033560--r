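# Synthetic phase-contrast field-of-view simulator with pixel-exact
# ground truth: straight (amosite-like) and wavy (chrysotile-like)
# fibers, non-fiber particles, halo rendering, additive noise.

#' Distribution specification for scene parameters
#'
#' A small declarative description of a sampling distribution, with
#' optional truncation bounds enforced by resampling.
#'
#' @param dist one of `"constant"`, `"uniform"`, `"normal"`,
#'   `"lognormal"`, `"poisson"`.
#' @param ... distribution parameters: `value` (constant), `min`/`max`
#'   (uniform), `mean`/`sd` (normal), `meanlog`/`sdlog` (lognormal),
#'   `lambda` (poisson).
#' @param lower,upper optional truncation bounds (resample on
#'   violation).
#' @return object of class `dist_spec`.
#' @export
dist_spec <- function(dist = c("constant", "uniform", "normal",
                               "lognormal", "poisson"),
                      ..., lower = -Inf, upper = Inf) {
  dist <- match.arg(dist)
  structure(list(dist = dist, params = list(...),
                 lower = lower, upper = upper),
            class = "dist_spec")
}

sample_dist <- function(d, n) {
  if (is.numeric(d)) return(rep(d, length.out = n))
  stopifnot(inherits(d, "dist_spec"))
  p <- d$params
  draw <- function(m) switch(d$dist,
    constant = rep(p$value, m),
    uniform = runif(m, p$min, p$max),
    normal = rnorm(m, p$mean, p$sd),
    lognormal = rlnorm(m, p$meanlog, p$sdlog),
    poisson = rpois(m, p$lambda))
  x <- draw(n)
  for (k in 1:100) {
    bad <- x < d$lower | x > d$upper
    if (!any(bad)) break
    x[bad] <- draw(sum(bad))
  }
  stop_if(any(x < d$lower | x > d$upper),
          "could not satisfy truncation bounds after 100 resamples")
  x
}

dist_mean <- function(d) {
  if (is.numeric(d)) return(d)
  p <- d$params
  switch(d$dist,
         constant = p$value,
         uniform = (p$min + p$max) / 2,
         normal = p$mean,
         lognormal = exp(p$meanlog + p$sdlog^2 / 2),
         poisson = p$lambda)
}

#' Scene specification for the synthetic PCM simulator
#'
#' Generative parameters for one simulated field of view. Defaults
#' emulate the standard counting setup: a 300-um-diameter circular
#' field imaged at 0.3125 um/pixel into a 1600 x 1200 raster, with a
#' mean of 5.5 countable fibers per field (Poisson), fiber lengths
#' lognormal around ~15 um (truncated to 6-60 um) and widths uniform
#' on 0.4-1.5 um, so that default fibers always satisfy the counting
#' criteria.
#'
#' @param field_diameter_um field-of-view diameter (default 300).
#' @param image_size_px `(width, height)` in px (default 1600 x 1200).
#' @param scale_um_per_px calibration (default 0.3125).
#' @param n_fibers integer, or a [dist_spec()] (default
#'   Poisson(5.5)).
#' @param length_um_dist,width_um_dist fiber dimension distributions
#'   ([dist_spec()] or a constant); widths must sample below lengths
#'   (violations resampled).
#' @param waviness amplitude-to-length ratio of the sinusoidal
#'   centerline perturbation; 0 = straight amosite-like fibers, ~0.05
#'   = wavy chrysotile-like fibers.
#' @param n_particles integer or [dist_spec()] count of non-fiber
#'   particles (default Poisson(8)).
#' @param particle_size_dist particle diameter distribution in um
#'   (default uniform 1-4).
#' @param noise_sd additive Gaussian noise sd on `[0, 1]` intensities
#'   (default 0.02).
#' @param halo_strength brightness of the phase halo ring relative to
#'   the core depth (default 0.5).
#' @param core_depth intensity dip of the fiber core below background
#'   (default 0.35).
#' @param background background intensity inside the field disc
#'   (default 0.62); outside the disc the image is the constant 0.30.
#' @param allow_overlap whether fibers and particles may overlap each
#'   other (default `TRUE`, emulating real filters where crossing
#'   fibers occur); `FALSE` rejects placements that come within a few
#'   pixels of already-placed objects, the "easy" well-separated
#'   regime.
#' @param seed default RNG seed for this spec (default 1).
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(field_diameter_um = 300,
                       image_size_px = c(1600L, 1200L),
                       scale_um_per_px = 0.3125,
                       n_fibers = dist_spec("poisson", lambda = 5.5),
                       length_um_dist = dist_spec("lognormal",
                                                  meanlog = log(15),
                                                  sdlog = 0.35,
                                                  lower = 6, upper = 60),
                       width_um_dist = dist_spec("uniform",
                                                 min = 0.4, max = 1.5),
                       waviness = 0,
                       n_particles = dist_spec("poisson", lambda = 8),
                       particle_size_dist = dist_spec("uniform",
                                                      min = 1, max = 4),
                       noise_sd = 0.02,
                       halo_strength = 0.5,
                       core_depth = 0.35,
                       background = 0.62,
                       allow_overlap = TRUE,
                       seed = 1L) {
  stop_if(field_diameter_um <= 0 || scale_um_per_px <= 0,
          "field diameter and scale must be positive")
  stop_if(waviness < 0 || noise_sd < 0 || halo_strength < 0,
          "waviness, noise_sd, halo_strength must be non-negative")
  structure(list(field_diameter_um = field_diameter_um,
                 image_size_px = as.integer(image_size_px),
                 scale_um_per_px = scale_um_per_px,
                 n_fibers = n_fibers,
                 length_um_dist = length_um_dist,
                 width_um_dist = width_um_dist,
                 waviness = waviness,
                 n_particles = n_particles,
                 particle_size_dist = particle_size_dist,
                 noise_sd = noise_sd,
                 halo_strength = halo_strength,
                 core_depth = core_depth,
                 background = background,
                 allow_overlap = isTRUE(allow_overlap),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# wavy (or straight) centerline polyline with exact arc length len_px,
# centered at the origin, oriented along +x before rotation by theta
make_centerline <- function(len_px, waviness, theta, n_pts = 33) {
  t <- seq(0, 1, length.out = n_pts)
  if (waviness > 0) {
    cycles <- runif(1, 1, 2)
    phase <- runif(1, 0, 2 * pi)
    y <- waviness * len_px * sin(2 * pi * cycles * t + phase)
  } else {
    y <- rep(0, n_pts)
  }
  x <- t * len_px
  arc <- sum(sqrt(diff(x)^2 + diff(y)^2))
  s <- len_px / arc           # uniform rescale => arc length exact
  x <- x * s; y <- y * s
  x <- x - mean(range(x)); y <- y - mean(range(y))
  ct <- cos(theta); st <- sin(theta)
  cbind(x = x * ct - y * st, y = x * st + y * ct)
}

# resample a polyline at roughly `step`-px spacing (for clearance
# checks between placed objects)
densify <- function(line, step = 2) {
  seg <- sqrt(diff(line[, 1])^2 + diff(line[, 2])^2)
  cum <- c(0, cumsum(seg))
  tt <- seq(0, cum[length(cum)], by = step)
  cbind(approx(cum, line[, 1], tt)$y, approx(cum, line[, 2], tt)$y)
}

min_cross_dist <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(min(d2))
}

# distance from pixel centers (px, py) to a polyline, with butt end
# caps: pixels beyond the perpendicular planes at the two endpoints get
# Inf
polyline_distance <- function(px, py, line) {
  n <- nrow(line)
  d2 <- rep(Inf, length(px))
  for (i in seq_len(n - 1)) {
    ax <- line[i, 1]; ay <- line[i, 2]
    bx <- line[i + 1, 1]; by <- line[i + 1, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    tt <- ((px - ax) * vx + (py - ay) * vy) / len2
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    dx <- px - (ax + tt * vx); dy <- py - (ay + tt * vy)
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  d <- sqrt(d2)
  # butt caps: clip beyond the end planes
  t0 <- line[2, ] - line[1, ]; t1 <- line[n, ] - line[n - 1, ]
  t0 <- t0 / sqrt(sum(t0^2)); t1 <- t1 / sqrt(sum(t1^2))
  before <- (px - line[1, 1]) * t0[1] + (py - line[1, 2]) * t0[2] < 0
  after <- (px - line[n, 1]) * t1[1] + (py - line[n, 2]) * t1[2] > 0
  d[before | after] <- Inf
  d
}

# outline polygon of a stroked centerline (offset +/- width/2)
stroke_outline <- function(line, width_px) {
  n <- nrow(line)
  nxt <- pmin(seq_len(n) + 1L, n)
  prv <- pmax(seq_len(n) - 1L, 1L)
  tang <- line[nxt, , drop = FALSE] - line[prv, , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  nx <- -tang[, 2]; ny <- tang[, 1]
  h <- width_px / 2
  rbind(cbind(line[, 1] + nx * h, line[, 2] + ny * h),
        cbind(rev(line[, 1] - nx * h), rev(line[, 2] - ny * h)))
}

#' Generate one synthetic PCM field of view
#'
#' Samples fiber dimensions and placements from the scene spec, renders
#' them in a phase-contrast-like style (dark Gaussian-edged core, bright
#' halo ring, additive Gaussian noise inside the field disc, constant
#' background outside it), adds non-fiber particles, and returns the
#' image together with pixel-exact ground truth and a LabelMe-style
#' annotation set. Fibers are placed wholly inside the field disc;
#' placements that cannot fit after a bounded number of retries raise
#' an error. Deterministic: the same `(spec, seed)` yields an
#' identical scene.
#'
#' @param spec a [scene_spec()].
#' @param seed integer RNG seed (defaults to `spec$seed`).
#' @param field_id identifier stamped on the image and annotations.
#' @return list with `image` ([calibrated_image()]), `fibers` (list of
#'   ground-truth records: `centerline`, `true_length_um`,
#'   `true_width_um`, `is_countable`, `pixels`), `particles` (list of
#'   pixel sets), `annotations` ([annotation_set()]).
#' @export
generate_scene <- function(spec, seed = spec$seed, field_id = "synthetic") {
  stopifnot(inherits(spec, "scene_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  w <- spec$image_size_px[1]; h <- spec$image_size_px[2]
  sc <- spec$scale_um_per_px
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  r_field <- spec$field_diameter_um / 2 / sc
  stop_if(2 * r_field > min(w, h),
          "field disc (", round(2 * r_field), " px) does not fit the ",
          w, " x ", h, " image; enlarge the image or the um/px scale")

  img <- matrix(0.30, nrow = h, ncol = w)
  xs <- matrix(rep(0:(w - 1), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1), w), nrow = h)
  in_disc <- (xs - cx)^2 + (ys - cy)^2 <= r_field^2
  img[in_disc] <- spec$background

  crit <- counting_criteria()
  n_fib <- round(sample_dist(spec$n_fibers, 1))
  fibers <- list()
  shapes <- list()

  add_stroke <- function(img, line, width_px, depth) {
    pad <- width_px / 2 + 3
    x0 <- max(0, floor(min(line[, 1]) - pad))
    x1 <- min(w - 1, ceiling(max(line[, 1]) + pad))
    y0 <- max(0, floor(min(line[, 2]) - pad))
    y1 <- min(h - 1, ceiling(max(line[, 2]) + pad))
    gx <- rep(x0:x1, times = y1 - y0 + 1)
    gy <- rep(y0:y1, each = x1 - x0 + 1)
    d <- polyline_distance(gx, gy, line)
    half <- width_px / 2
    core <- pmin(1, pmax(0, (half + 0.5 - d)))      # soft 1-px edge
    halo <- exp(-((d - (half + 1.5)) / 1.2)^2)
    halo[d <= half] <- 0
    delta <- -depth * core + spec$halo_strength * depth * halo
    ij <- cbind(gy + 1L, gx + 1L)
    img[ij] <- img[ij] + delta
    mask_sel <- is.finite(d) & d <= half
    list(img = img, pixels = pixel_set(gx[mask_sel], gy[mask_sel]))
  }

  placed_objs <- list()   # dense points + half-width of each object
  for (k in seq_len(n_fib)) {
    placed <- FALSE
    for (try in 1:50) {
      len_um <- sample_dist(spec$length_um_dist, 1)
      wid_um <- sample_dist(spec$width_um_dist, 1)
      for (rs in 1:20) {
        if (wid_um < len_um) break
        wid_um <- sample_dist(spec$width_um_dist, 1)
      }
      len_px <- len_um / sc; wid_px <- wid_um / sc
      theta <- runif(1, 0, pi)
      line <- make_centerline(len_px, spec$waviness, theta)
      r_need <- max(sqrt(rowSums(line^2))) + wid_px / 2 + 2
      if (r_need >= r_field) next   # cannot fit at this size/shape
      r_max <- r_field - r_need
      rr <- sqrt(runif(1)) * r_max
      ang <- runif(1, 0, 2 * pi)
      line <- cbind(x = line[, 1] + cx + rr * cos(ang),
                    y = line[, 2] + cy + rr * sin(ang))
      if (!spec$allow_overlap && length(placed_objs)) {
        dense <- densify(line)
        clear <- all(vapply(placed_objs, function(o)
          min_cross_dist(dense, o$pts) > wid_px / 2 + o$half + 3,
          TRUE))
        if (!clear) next
      }
      placed <- TRUE
      break
    }
    stop_if(!placed, "fiber ", k,
            " could not be placed inside the field after 50 retries ",
            "(fiber longer than the field diameter?)")
    st <- add_stroke(img, line, wid_px, spec$core_depth)
    img <- st$img
    placed_objs[[length(placed_objs) + 1]] <-
      list(pts = densify(line), half = wid_px / 2)
    countable <- apply_criteria(
      list(length_um = len_um, width_um = wid_um,
           aspect_ratio = len_um / wid_um), crit)
    fibers[[k]] <- list(centerline = line,
                        true_length_um = len_um,
                        true_width_um = wid_um,
                        is_countable = countable,
                        pixels = st$pixels)
    poly <- stroke_outline(line, wid_px)
    poly[, 1] <- pmin(pmax(poly[, 1], 0), w)
    poly[, 2] <- pmin(pmax(poly[, 2], 0), h)
    shapes[[k]] <- list(points = `colnames<-`(poly, c("x", "y")),
                        label = if (countable) "countable_fiber"
                                else "subcriteria_fiber",
                        notes = NA_character_)
  }

  # non-fiber particles: compact dark disks inside the field
  n_part <- round(sample_dist(spec$n_particles, 1))
  particles <- list()
  for (k in seq_len(n_part)) {
    dia_px <- sample_dist(spec$particle_size_dist, 1) / sc
    r_max <- r_field - dia_px / 2 - 2
    if (r_max <= 0) next
    pr <- dia_px / 2
    pcx <- pcy <- NA
    for (try in 1:50) {
      rr <- sqrt(runif(1)) * r_max
      ang <- runif(1, 0, 2 * pi)
      qx <- cx + rr * cos(ang); qy <- cy + rr * sin(ang)
      if (!spec$allow_overlap && length(placed_objs)) {
        clear <- all(vapply(placed_objs, function(o)
          min_cross_dist(cbind(qx, qy), o$pts) > pr + o$half + 3, TRUE))
        if (!clear) next
      }
      pcx <- qx; pcy <- qy
      break
    }
    if (is.na(pcx)) next   # crowded field: drop this particle
    x0 <- max(0, floor(pcx - pr - 2)); x1 <- min(w - 1, ceiling(pcx + pr + 2))
    y0 <- max(0, floor(pcy - pr - 2)); y1 <- min(h - 1, ceiling(pcy + pr + 2))
    gx <- rep(x0:x1, times = y1 - y0 + 1)
    gy <- rep(y0:y1, each = x1 - x0 + 1)
    d <- sqrt((gx - pcx)^2 + (gy - pcy)^2)
    core <- pmin(1, pmax(0, pr + 0.5 - d))
    ij <- cbind(gy + 1L, gx + 1L)
    img[ij] <- img[ij] - spec$core_depth * core
    sel <- d <= pr
    if (any(sel))
      particles[[length(particles) + 1]] <- pixel_set(gx[sel], gy[sel])
    placed_objs[[length(placed_objs) + 1]] <-
      list(pts = cbind(pcx, pcy), half = pr)
  }

  if (spec$noise_sd > 0) {
    noise <- matrix(rnorm(h * w, 0, spec$noise_sd), nrow = h)
    img[in_disc] <- img[in_disc] + noise[in_disc]
  }
  img[img < 0] <- 0; img[img > 1] <- 1

  list(image = calibrated_image(img, sc, field_id,
                                spec$field_diameter_um),
       fibers = fibers,
       particles = particles,
       annotations = annotation_set(paste0(field_id, ".png"),
                                    c(w, h), shapes))
}

#' Empirical countable-fiber density of a scene specification
#'
#' Generates `n_scenes` fields (seeds `spec$seed + 1 ... + n_scenes`)
#' and returns the mean number of countable fibers per field, i.e. the
#' quantity that scales to airborne concentration.
#'
#' @param spec a [scene_spec()].
#' @param n_scenes number of fields to simulate (>= 1).
#' @return mean countable fibers per field, with attribute `"counts"`
#'   carrying the per-field counts.
#' @export
scene_to_density <- function(spec, n_scenes) {
  stop_if(n_scenes < 1, "n_scenes must be >= 1")
  counts <- vapply(seq_len(n_scenes), function(i) {
    sc <- generate_scene(spec, seed = spec$seed + i)
    sum(vapply(sc$fibers, `[[`, TRUE, "is_countable"))
  }, 0)
  structure(mean(counts), counts = counts)
}
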