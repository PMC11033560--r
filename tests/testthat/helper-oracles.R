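# Fixture builders and independent brute-force oracles used across the
# suite. Oracles deliberately use different algorithms from the package
# implementation they check.

# solid axis-alignable bar as a pixel set: len x wid pixels, rotated by
# angle_deg about its center; pixels whose centers fall inside the
# rotated len x wid rectangle
render_bar <- function(len, wid, angle_deg = 0, center = c(40, 40)) {
  th <- angle_deg * pi / 180
  pad <- ceiling(len + wid) + 2
  xs <- (round(center[1]) - pad):(round(center[1]) + pad)
  ys <- (round(center[2]) - pad):(round(center[2]) + pad)
  g <- expand.grid(x = xs, y = ys)
  dx <- g$x - center[1]; dy <- g$y - center[2]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  # rect [-0.5, len-0.5] x [-0.5, wid-0.5] in the rotated frame holds
  # exactly len x wid pixel centers at 0/90 degrees
  eps <- 1e-6
  sel <- u >= -0.5 + eps & u <= len - 0.5 - eps &
    v >= -0.5 + eps & v <= wid - 0.5 - eps
  pixel_set(g$x[sel], g$y[sel])
}

# random connected-ish blob: union of a random walk of small squares
random_blob <- function(n_steps = 30, size = 2) {
  x <- 50; y <- 50
  px <- integer(0); py <- integer(0)
  for (i in seq_len(n_steps)) {
    x <- x + sample(-2:2, 1); y <- y + sample(-2:2, 1)
    gx <- rep(x:(x + size), size + 1)
    gy <- rep(y:(y + size), each = size + 1)
    px <- c(px, gx); py <- c(py, gy)
  }
  pixel_set(px, py)
}

# brute-force rotating-caliper rectangle area over a 0.5 degree grid,
# with the pixel-count (+1 per side) convention
oracle_caliper_area <- function(pixels, step_deg = 0.5) {
  pts <- cbind(pixels[, "x"], pixels[, "y"])
  best <- Inf
  for (a in seq(0, 180 - step_deg, by = step_deg)) {
    th <- a * pi / 180
    u <- pts[, 1] * cos(th) + pts[, 2] * sin(th)
    v <- -pts[, 1] * sin(th) + pts[, 2] * cos(th)
    area <- (max(u) - min(u) + 1) * (max(v) - min(v) + 1)
    if (area < best) best <- area
  }
  best
}

# exhaustive flood fill (BFS with an explicit queue) for component
# counting, independent of the igraph path
oracle_component_sizes <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  offs <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  sizes <- integer(0)
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    queue <- start; seen[start] <- TRUE; n <- 0L
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]; n <- n + 1L
      r <- (cur - 1) %% h + 1; c0 <- (cur - 1) %/% h + 1
      for (k in seq_len(nrow(offs))) {
        r2 <- r + offs[k, 1]; c2 <- c0 + offs[k, 2]
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
            mask[r2, c2] && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          queue <- c(queue, (c2 - 1) * h + r2)
        }
      }
    }
    sizes <- c(sizes, n)
  }
  sort(sizes)
}

# angle-summation point-in-polygon (different algorithm from the
# package's ray crossing); valid away from the boundary
oracle_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    a1 <- atan2(vy[i] - py, vx[i] - px)
    a2 <- atan2(vy[j] - py, vx[j] - px)
    d <- a2 - a1
    d <- d - 2 * pi * round(d / (2 * pi))
    total <- total + d
  }
  abs(total) > pi
}

# exhaustive optimal one-to-one assignment: recursion over predictions,
# maximizing the number of pairs with IoU >= threshold
oracle_best_match_count <- function(M, threshold) {
  np <- nrow(M); nt <- ncol(M)
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (np - i + 1) <= best) return(invisible())
    if (i > np) { best <<- max(best, count); return(invisible()) }
    recurse(i + 1, used, count)             # prediction i unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && M[i, j] >= threshold) {
        used[j] <- TRUE
        recurse(i + 1, used, count + 1L)
        used[j] <- FALSE
      }
    }
    invisible()
  }
  recurse(1L, rep(FALSE, nt), 0L)
  best
}

# small scene spec used across tests: 140-um field in a 640x480 raster
# at the standard 0.3125 um/px
test_scene_spec <- function(...) {
  scene_spec(image_size_px = c(640L, 480L), field_diameter_um = 140, ...)
}

# triangle annotation helper
tri_shape <- function(x0, y0, label = "countable_fiber") {
  list(points = cbind(x = c(x0, x0 + 12, x0), y = c(y0, y0, y0 + 8)),
       label = label)
}
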