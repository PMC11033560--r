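test_that("pixel-to-um conversion reproduces the calibration", {
  expect_equal(px_to_um(32, 0.3125), 10)
  expect_equal(px_to_um(0, 0.3125), 0)
  expect_equal(px_to_um(16, 0.3125), 5)   # minimum countable length
  expect_equal(calibrate_scale(10, 32), 0.3125)
  expect_error(px_to_um(-1), "non-negative")
  expect_error(calibrate_scale(10, 0), "positive")
})

test_that("min_area_rect handles bars, symmetry, and degenerate sets", {
  bar <- render_bar(16, 4, 0)
  r <- min_area_rect(bar)
  expect_equal(r$long_side_px, 16)
  expect_equal(r$short_side_px, 4)
  expect_equal(r$angle_deg, 0)

  r90 <- min_area_rect(render_bar(16, 4, 90))
  expect_equal(r90$long_side_px, 16)
  expect_equal(r90$short_side_px, 4)
  expect_equal(r90$angle_deg, 90)

  one <- min_area_rect(pixel_set(5, 7))
  expect_equal(one$long_side_px, 1)
  expect_equal(one$short_side_px, 1)

  # collinear diagonal run
  diag <- pixel_set(0:9, 0:9)
  rd <- min_area_rect(diag)
  expect_equal(rd$short_side_px, 1)
  expect_equal(rd$angle_deg, 45, tolerance = 1e-6)

  expect_error(min_area_rect(pixel_set(integer(0), integer(0))), "empty")
})

test_that("min_area_rect matches a rotating-caliper brute force on random blobs", {
  set.seed(101)
  for (rep in 1:60) {
    b <- random_blob(n_steps = sample(10:40, 1))
    r <- min_area_rect(b)
    expect_lte(r$long_side_px * r$short_side_px,
               oracle_caliper_area(b) * 1.01)
  }
})

test_that("min_area_rect area never exceeds the axis-aligned bounding box", {
  set.seed(11)
  for (rep in 1:20) {
    b <- random_blob()
    r <- min_area_rect(b)
    aabb <- (diff(range(b[, "x"])) + 1) * (diff(range(b[, "y"])) + 1)
    expect_lte(r$long_side_px * r$short_side_px, aabb + 1e-9)
  }
})

test_that("both conventions measure a calibrated bar to the expected um", {
  bar <- render_bar(16, 4, 0)
  for (meas in list(measure_instance_style, measure_semantic_style)) {
    m <- meas(bar, 0.3125)
    expect_equal(m$length_um, 5)
    expect_equal(m$width_um, 1.25)
    expect_equal(m$aspect_ratio, 4)
  }

  px <- measure_instance_style(pixel_set(3, 3), 0.3125)
  expect_equal(px$length_px, 1)
  expect_equal(px$width_px, 1)
  expect_equal(px$aspect_ratio, 1)
})

test_that("semantic width is the mean of orthogonal section counts", {
  # constant-width 20 x 5 bar: every section counts 5
  expect_equal(measure_semantic_style(render_bar(20, 5, 0))$width_px, 5)

  # half the length at width 4, half at width 6 -> mean 5
  half1 <- render_bar(10, 4, 0, center = c(20, 40))
  half2 <- render_bar(10, 6, 0, center = c(30, 40))
  bar <- pixel_set(c(half1[, "x"], half2[, "x"]),
                   c(half1[, "y"], half2[, "y"]))
  expect_equal(measure_semantic_style(bar)$width_px, 5)
})

test_that("instance width falls back to a populated section on C-shapes", {
  # C shape: vertical bar with top and bottom arms; the rect center
  # section (middle of the C opening) holds only the 3-px spine
  xs <- c(rep(0:2, 10),            rep(3:9, each = 3), rep(3:9, each = 3))
  ys <- c(rep(0:9, each = 3),      rep(0:2, 7),        rep(7:9, 7))
  cshape <- pixel_set(xs, ys)
  m <- measure_instance_style(cshape)
  expect_false(m$fallback)   # center line crosses arms or spine here
  expect_gt(m$width_px, 0)

  # two distant parallel bars (gap at the exact center) trigger fallback
  b1 <- render_bar(4, 2, 90, center = c(10, 10))
  b2 <- render_bar(4, 2, 90, center = c(40, 10))
  pair <- pixel_set(c(b1[, "x"], b2[, "x"]), c(b1[, "y"], b2[, "y"]))
  mp <- measure_instance_style(pair)
  expect_true(mp$fallback)
  expect_gt(mp$width_px, 0)
})

test_that("measurements are rotation-equivariant within one pixel", {
  for (wid in c(3, 5)) {
    ref <- NULL
    for (ang in c(0, 30, 45, 90)) {
      m <- measure_semantic_style(render_bar(24, wid, ang))
      if (is.null(ref)) ref <- m
      expect_lt(abs(m$length_px - ref$length_px), 1 + 1e-9)
      expect_lt(abs(m$width_px - ref$width_px), 1 + 1e-9)
    }
  }
})

test_that("aspect ratio times width equals length to machine precision", {
  set.seed(5)
  for (rep in 1:10) {
    b <- random_blob()
    m <- measure_semantic_style(b, 0.3125)
    expect_equal(m$aspect_ratio * m$width_um, m$length_um)
    expect_equal(m$length_um, m$length_px * 0.3125)
  }
})

test_that("instance and semantic widths agree exactly on straight bars", {
  for (dims in list(c(16, 4), c(20, 5), c(9, 3))) {
    for (ang in c(0, 90)) {
      b <- render_bar(dims[1], dims[2], ang)
      expect_equal(measure_instance_style(b)$width_px,
                   measure_semantic_style(b)$width_px)
    }
  }
})

test_that("measurements_table summarizes candidates with criteria verdicts", {
  cands <- list(measure_semantic_style(render_bar(20, 3, 0), 0.3125),
                measure_semantic_style(render_bar(8, 4, 0), 0.3125))
  tab <- measurements_table(cands)
  expect_equal(nrow(tab), 2)
  expect_true(tab$meets_criteria[1])   # 6.25 x 0.94 um
  expect_false(tab$meets_criteria[2])  # 2.5 um long, sub-criteria
  expect_equal(measurements_table(list())$id, integer(0))
})
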