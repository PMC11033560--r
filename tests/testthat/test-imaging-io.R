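test_that("LabelMe files parse, map labels, and round-trip losslessly", {
  set.seed(42)
  # build a LabelMe file by hand with raw tool labels
  raw <- list(
    version = "5.0.0", flags = setNames(list(), character(0)),
    shapes = list(
      list(label = "fiber",
           points = list(c(10.5, 20.25), c(30, 20), c(25, 40.75)),
           shape_type = "polygon"),
      list(label = "fiber",
           points = list(c(100, 100), c(140, 100), c(140, 110), c(100, 110)),
           shape_type = "polygon")),
    imagePath = "f1.png", imageHeight = 480, imageWidth = 640)
  f <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(raw, auto_unbox = TRUE, digits = NA), f)

  ann <- read_labelme(f)
  expect_s3_class(ann, "annotation_set")
  expect_length(ann$shapes, 2)
  expect_true(all(vapply(ann$shapes, `[[`, "", "label") == "countable_fiber"))
  expect_equal(ann$shapes[[1]]$points[1, ], c(x = 10.5, y = 20.25))

  # lossless round trip, including awkward fractional vertices
  f2 <- tempfile(fileext = ".json")
  write_labelme(ann, f2)
  ann2 <- read_labelme(f2)
  for (k in 1:2)
    expect_identical(ann2$shapes[[k]]$points, ann$shapes[[k]]$points)
  expect_identical(ann2$image_size, ann$image_size)
  expect_identical(ann2$image_ref, ann$image_ref)

  # empty shape list is valid, not an error
  raw$shapes <- list()
  writeLines(jsonlite::toJSON(raw, auto_unbox = TRUE), f)
  expect_length(read_labelme(f)$shapes, 0)

  # 55-shape set round-trips with identical shape count
  shapes <- lapply(seq_len(55), function(i)
    tri_shape(5 + (i %% 10) * 60, 5 + (i %/% 10) * 80))
  big <- annotation_set("big.png", c(640, 480), shapes)
  write_labelme(big, f2)
  expect_length(read_labelme(f2)$shapes, 55)
})

test_that("malformed LabelMe input fails with informative errors", {
  f <- tempfile(fileext = ".json")
  writeLines("{not json", f)
  expect_error(read_labelme(f), "malformed JSON")

  writeLines(jsonlite::toJSON(list(imagePath = "x.png", shapes = list()),
                              auto_unbox = TRUE), f)
  expect_error(read_labelme(f), "imageHeight")

  two_pt <- list(imagePath = "x.png", imageHeight = 100, imageWidth = 100,
                 shapes = list(list(label = "fiber",
                                    points = list(c(1, 1), c(5, 5)))))
  writeLines(jsonlite::toJSON(two_pt, auto_unbox = TRUE), f)
  expect_error(read_labelme(f), "shape 1")

  # unknown labels survive in notes
  unk <- list(imagePath = "x.png", imageHeight = 100, imageWidth = 100,
              shapes = list(list(label = "dust_mote",
                                 points = list(c(1, 1), c(5, 1), c(3, 6)))))
  writeLines(jsonlite::toJSON(unk, auto_unbox = TRUE), f)
  ann <- read_labelme(f)
  expect_match(ann$shapes[[1]]$notes, "dust_mote")
})

test_that("polygon rasterization matches pixel-center geometry", {
  # axis-aligned 10 x 4 rectangle covers exactly 40 pixel centers
  rect <- annotation_set("r.png", c(50, 50), list(
    list(points = cbind(x = c(0, 9, 9, 0), y = c(0, 0, 3, 3)),
         label = "countable_fiber")))
  m <- polygons_to_mask(rect)
  expect_equal(sum(m == 1), 40)

  # two disjoint rectangles keep distinct labels and pixel counts
  two <- annotation_set("r.png", c(60, 40), list(
    list(points = cbind(x = c(0, 9, 9, 0), y = c(0, 0, 3, 3)),
         label = "countable_fiber"),
    list(points = cbind(x = c(20, 24, 24, 20), y = c(10, 10, 19, 19)),
         label = "subcriteria_fiber")))
  m2 <- polygons_to_mask(two)
  expect_equal(sum(m2 == 1), 40)
  expect_equal(sum(m2 == 2), 50)

  # later shape wins on overlap, and the overlap is reported
  ovl <- annotation_set("r.png", c(30, 30), list(
    list(points = cbind(x = c(0, 9, 9, 0), y = c(0, 0, 9, 9)),
         label = "countable_fiber"),
    list(points = cbind(x = c(5, 14, 14, 5), y = c(5, 5, 14, 14)),
         label = "countable_fiber")))
  m3 <- polygons_to_mask(ovl)
  expect_equal(nrow(attr(m3, "overlaps")), 1)
  expect_equal(m3[8, 8], 2L)  # pixel (7,7) in the overlap -> shape 2
})

test_that("rasterized pixel counts equal an exhaustive point-in-polygon scan", {
  set.seed(7)
  for (rep in 1:5) {
    # random simple (star-shaped) polygon with non-lattice vertices
    nv <- sample(5:9, 1)
    ang <- sort(runif(nv, 0, 2 * pi))
    rad <- runif(nv, 5, 18)
    vx <- 25 + rad * cos(ang) + runif(nv, 0, 0.3)
    vy <- 25 + rad * sin(ang) + runif(nv, 0, 0.3)
    ann <- annotation_set("p.png", c(50, 50), list(
      list(points = cbind(x = vx, y = vy), label = "countable_fiber")))
    m <- polygons_to_mask(ann)
    # oracle: scan every pixel center in the image
    g <- expand.grid(x = 0:49, y = 0:49)
    inside <- mapply(oracle_in_polygon, g$x, g$y,
                     MoreArgs = list(vx = vx, vy = vy))
    expect_equal(sum(m == 1), sum(inside))
  }
})

test_that("zero-area polygons are skipped with a warning", {
  degen <- annotation_set("d.png", c(20, 20), list(
    list(points = cbind(x = c(2, 8, 5), y = c(3, 3, 3)),
         label = "countable_fiber")))
  expect_warning(m <- polygons_to_mask(degen), "zero area")
  expect_equal(sum(m), 0)
})

test_that("micrographs load with calibration; RGB converts by fixed luma", {
  d <- tempdir()
  # grayscale PNG round trip
  img <- calibrated_image(matrix(runif(80 * 60), 60, 80), 0.3125, "g1")
  p1 <- file.path(d, "g1.png")
  write_image(img, p1)
  back <- read_image(p1)
  expect_equal(back$width_px, 80)
  expect_equal(back$height_px, 60)
  expect_equal(back$scale_um_per_px, 0.3125)
  expect_lt(max(abs(back$pixels - img$pixels)), 1 / 255)

  # full-size JPEG loads with the nominal dimensions
  big <- EBImage::as.Image(array(0.5, c(1600, 1200)))
  p2 <- file.path(d, "field.jpg")
  EBImage::writeImage(big, p2)
  ci <- read_image(p2)
  expect_equal(ci$width_px, 1600)
  expect_equal(ci$height_px, 1200)

  # RGB: pure red converts to the 0.2126 luma value
  rgb <- EBImage::as.Image(array(c(rep(1, 40 * 30), rep(0, 40 * 30 * 2)),
                                 c(40, 30, 3)))
  EBImage::colorMode(rgb) <- EBImage::Color
  p3 <- file.path(d, "red.png")
  EBImage::writeImage(rgb, p3)
  red <- read_image(p3)
  expect_equal(unname(red$pixels[1, 1]), 0.2126, tolerance = 0.01)

  expect_error(read_image(file.path(d, "x.bmp")), "file not found")
  file.create(file.path(d, "x.bmp"))
  expect_error(read_image(file.path(d, "x.bmp")), "unsupported")
})

test_that("detection reports have a totals row equal to column sums", {
  set.seed(1)
  rep10 <- data.frame(image = sprintf("img-%02d", 1:10),
                      expert_count = sample(0:9, 10, TRUE),
                      counted = sample(0:9, 10, TRUE),
                      overlooked = sample(0:3, 10, TRUE),
                      overcounted = sample(0:3, 10, TRUE))
  f <- tempfile(fileext = ".csv")
  write_report(rep10, f)
  out <- read.csv(f)
  expect_equal(nrow(out), 11)
  expect_equal(out$image[11], "Total")
  for (col in c("expert_count", "counted", "overlooked", "overcounted"))
    expect_equal(out[[col]][11], sum(rep10[[col]]))

  fj <- tempfile(fileext = ".json")
  write_report(rep10, fj)
  js <- jsonlite::fromJSON(fj)
  expect_equal(nrow(js), 11)
  expect_equal(js$counted[11], sum(rep10$counted))
})
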