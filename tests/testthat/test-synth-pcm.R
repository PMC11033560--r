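test_that("scenes conserve fiber counts and honor n_fibers = 0", {
  spec <- test_scene_spec(n_fibers = 5)
  scn <- generate_scene(spec, seed = 4)
  expect_length(scn$fibers, 5)
  expect_length(scn$annotations$shapes, 5)

  empty <- generate_scene(test_scene_spec(n_fibers = 0), seed = 4)
  expect_length(empty$fibers, 0)
  expect_length(empty$annotations$shapes, 0)
  expect_gt(length(empty$particles), 0)   # clutter still present
})

test_that("identical spec and seed give bit-identical scenes", {
  spec <- test_scene_spec()
  a <- generate_scene(spec, seed = 99)
  b <- generate_scene(spec, seed = 99)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$fibers, b$fibers)
  expect_identical(a$annotations$shapes, b$annotations$shapes)
  # a different seed gives a different field
  c2 <- generate_scene(spec, seed = 100)
  expect_false(identical(a$image$pixels, c2$image$pixels))
})

test_that("sampled fiber lengths match the requested distribution mean", {
  spec <- test_scene_spec(n_fibers = 10,
                          length_um_dist = dist_spec("uniform",
                                                     min = 8, max = 20),
                          n_particles = 0, noise_sd = 0)
  lens <- unlist(lapply(1:20, function(i)
    vapply(generate_scene(spec, seed = 200 + i)$fibers, `[[`, 0,
           "true_length_um")))
  expect_length(lens, 200)
  mu <- 14; se <- (12 / sqrt(12)) / sqrt(200)
  expect_lt(abs(mean(lens) - mu), 3 * se)
  expect_true(all(lens >= 8 & lens <= 20))
})

test_that("fiber pixels stay inside the field disc; outside is constant", {
  spec <- test_scene_spec()
  scn <- generate_scene(spec, seed = 12)
  w <- scn$image$width_px; h <- scn$image$height_px
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  r <- spec$field_diameter_um / 2 / spec$scale_um_per_px
  for (f in scn$fibers) {
    d <- sqrt((f$pixels[, "x"] - cx)^2 + (f$pixels[, "y"] - cy)^2)
    expect_true(all(d <= r))
  }
  xs <- matrix(rep(0:(w - 1), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1), w), nrow = h)
  outside <- (xs - cx)^2 + (ys - cy)^2 > (r + 2)^2
  expect_equal(unique(scn$image$pixels[outside]), 0.30)
})

test_that("ground-truth countability agrees with the counting criteria", {
  spec <- test_scene_spec(n_fibers = 12,
                          length_um_dist = dist_spec("uniform",
                                                     min = 2, max = 12),
                          width_um_dist = dist_spec("uniform",
                                                    min = 0.3, max = 2))
  crit <- counting_criteria()
  scn <- generate_scene(spec, seed = 77)
  verdicts <- vapply(scn$fibers, `[[`, TRUE, "is_countable")
  oracle <- vapply(scn$fibers, function(f)
    apply_criteria(list(length_um = f$true_length_um,
                        width_um = f$true_width_um,
                        aspect_ratio = f$true_length_um / f$true_width_um),
                   crit), TRUE)
  expect_equal(verdicts, oracle)
  expect_true(any(verdicts) && any(!verdicts))  # the mix is exercised
  # annotation labels mirror the verdicts
  labels <- vapply(scn$annotations$shapes, `[[`, "", "label")
  expect_equal(labels == "countable_fiber", verdicts)
})

test_that("morphometry recovers true dimensions of rendered straight fibers", {
  spec <- test_scene_spec(n_fibers = 1, noise_sd = 0, n_particles = 0)
  sc <- 0.3125
  for (seed in c(3, 8, 15, 22, 31)) {
    scn <- generate_scene(spec, seed = seed)
    f <- scn$fibers[[1]]
    m <- measure_semantic_style(f$pixels, sc)
    expect_lt(abs(m$length_um - f$true_length_um) / sc, 1 + 1e-9,
              label = sprintf("length error (seed %d)", seed))
    expect_lt(abs(m$width_um - f$true_width_um) / sc, 1 + 1e-9,
              label = sprintf("width error (seed %d)", seed))
  }
})

test_that("wavy chrysotile-like fibers render and measure plausibly", {
  spec <- test_scene_spec(n_fibers = 1, waviness = 0.05, noise_sd = 0,
                          n_particles = 0,
                          width_um_dist = dist_spec("constant", value = 1))
  scn <- generate_scene(spec, seed = 10)
  f <- scn$fibers[[1]]
  m <- measure_semantic_style(f$pixels, 0.3125)
  # the rect long side of a wavy fiber is below its arc length
  expect_lte(m$length_um, f$true_length_um + 0.3125)
  # width within ~1 px of the 1-um stroke
  expect_lt(abs(m$width_um - 1), 0.33)
})

test_that("scene density estimates countable fibers per field", {
  fixed <- test_scene_spec(n_fibers = 9, n_particles = 0, noise_sd = 0)
  expect_equal(as.numeric(scene_to_density(fixed, 3)), 9)

  # mixed countable/sub-criteria spec: density equals the stored truth
  mixed <- test_scene_spec(n_fibers = 6,
                           length_um_dist = dist_spec("uniform",
                                                      min = 2, max = 12),
                           n_particles = 0, noise_sd = 0, seed = 5)
  d <- scene_to_density(mixed, 10)
  counts <- attr(d, "counts")
  oracle <- vapply(1:10, function(i) {
    scn <- generate_scene(mixed, seed = mixed$seed + i)
    sum(vapply(scn$fibers, function(f)
      f$true_length_um >= 5 && f$true_width_um < 3 &&
        f$true_length_um / f$true_width_um >= 3, TRUE))
  }, 0)
  expect_equal(counts, oracle)
  expect_equal(as.numeric(d), mean(oracle))
})

test_that("impossible placements error out rather than loop forever", {
  toolong <- test_scene_spec(n_fibers = 1,
                             length_um_dist = dist_spec("constant",
                                                        value = 139))
  expect_error(generate_scene(toolong, seed = 1), "could not be placed")
  toobig <- scene_spec(image_size_px = c(200L, 150L))
  expect_error(generate_scene(toobig, seed = 1), "does not fit")
})
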