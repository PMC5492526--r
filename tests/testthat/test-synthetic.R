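test_that("identical spec and seed give bit-identical images", {
  a <- generate_microarray_image(small_spec(tilt_deg = 5, seed = 1))
  b <- generate_microarray_image(small_spec(tilt_deg = 5, seed = 1))
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  c <- generate_microarray_image(small_spec(tilt_deg = 5, seed = 2))
  expect_false(identical(a$image, c$image))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(123); ref <- runif(3)
  set.seed(123); invisible(generate_microarray_image(small_spec(seed = 9)))
  expect_identical(runif(3), ref)
})

test_that("a single noise-free cell is rendered at the exact canvas center", {
  spec <- synthetic_spec(rows = 1, cols = 1, image_width = 101,
                         image_height = 101, cell_diameter = 30, pitch = 40,
                         tilt_deg = 0, edge_irregularity = 0,
                         cell_gray_levels = 180, speckle_variance = 0,
                         impulse_fraction = 0, illumination_gradient = 0,
                         seed = 1)
  gen <- generate_microarray_image(spec)
  expect_equal(gen$truth$centers$x, 50)
  expect_equal(gen$truth$centers$y, 50)
  expect_equal(nrow(gen$truth$centers), 1L)
  # center pixel carries the cell gray level, corner the background
  expect_equal(gen$image[51, 51, 1] * 255, 180, tolerance = 1)
  expect_equal(gen$image[1, 1, 1] * 255, 30, tolerance = 1)
})

test_that("every rendered cell is brighter than the background", {
  gen <- generate_microarray_image(synthetic_spec(
    rows = 4, cols = 4, image_width = 220, image_height = 220,
    tilt_deg = 2, seed = 3))
  v <- rgb_to_hsv_image(gen$image)$v
  tr <- gen$truth
  x <- matrix(0:(dim(gen$image)[1] - 1), dim(gen$image)[1], dim(gen$image)[2])
  y <- matrix(0:(dim(gen$image)[2] - 1), dim(gen$image)[1], dim(gen$image)[2],
              byrow = TRUE)
  cellpx <- matrix(FALSE, nrow(v), ncol(v))
  for (i in seq_len(nrow(tr$centers))) {
    disk <- (x - tr$centers$x[i])^2 + (y - tr$centers$y[i])^2 <=
      (0.8 * tr$radius)^2
    expect_gt(mean(v[disk]), mean(v[!cellpx & !disk]))
    cellpx <- cellpx | disk
  }
})

test_that("ground-truth centers form the stated affine grid", {
  spec <- small_spec(tilt_deg = 2.5, seed = 4)
  tr <- generate_microarray_image(spec)$truth
  first <- tr$centers[tr$centers$row == 1, ]
  # least-squares slope of the first row recovers the tilt to < 1e-6 deg
  slope <- stats::coef(stats::lm(y ~ x, data = first))[["x"]]
  expect_lt(abs(-atan(slope) * 180 / pi - spec$tilt_deg), 1e-6)
  # constant center-to-center spacing equal to the pitch
  d <- sqrt(diff(first$x)^2 + diff(first$y)^2)
  expect_equal(d, rep(spec$pitch, spec$cols - 1), tolerance = 1e-12)
})

test_that("infeasible specs are rejected", {
  expect_error(synthetic_spec(rows = 0), "positive integers")
  expect_error(synthetic_spec(rows = 2.5), "positive integers")
  expect_error(synthetic_spec(cell_diameter = 50, pitch = 40), "pitch")
  # grid too large for the canvas
  expect_error(synthetic_spec(rows = 6, cols = 6, image_width = 200,
                              image_height = 200), "leave the canvas")
  # fits untilted but a cell would leave the canvas when rotated
  expect_error(synthetic_spec(rows = 6, cols = 6, image_width = 265,
                              image_height = 265, tilt_deg = 6),
               "leave the canvas")
})

test_that("Otsu on the value channel separates cells from background", {
  # under default (mild) noise the value-channel Otsu mask must agree with
  # the true cell disks on at least 95% of cell pixels
  gen <- generate_microarray_image(chip_spec(tilt_deg = 1, seed = 6))
  v <- rgb_to_hsv_image(gen$image)$v
  mask <- otsu_threshold(v)$mask
  tr <- gen$truth
  W <- dim(gen$image)[1]; H <- dim(gen$image)[2]
  x <- matrix(0:(W - 1), W, H); y <- matrix(0:(H - 1), W, H, byrow = TRUE)
  inside <- Reduce(`|`, lapply(seq_len(nrow(tr$centers)), function(i)
    (x - tr$centers$x[i])^2 + (y - tr$centers$y[i])^2 <= (0.9 * tr$radius)^2))
  expect_gt(mean(mask[inside]), 0.95)
})

test_that("write_synthetic produces a PNG that round-trips and a truth sidecar", {
  gen <- generate_microarray_image(small_spec(tilt_deg = 1, seed = 2))
  prefix <- file.path(tempdir(), "synthcase")
  paths <- write_synthetic(gen, prefix)
  expect_true(all(file.exists(paths)))
  back <- read_image(paths[1])
  expect_equal(back, gen$image, tolerance = 1e-9)  # 8-bit quantized render
  side <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(side$truth$tilt_deg, 1)
  expect_length(side$truth$centers$x, 9)
})
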