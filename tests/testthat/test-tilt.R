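test_that("initial bounding rectangle equals the coordinate extremes", {
  m <- matrix(FALSE, 10, 8)
  m[8, 4] <- TRUE   # single pixel at x=7, y=3
  expect_equal(initial_bounding_rect(m),
               list(xmin = 7, xmax = 7, ymin = 3, ymax = 3))
  r <- matrix(FALSE, 25, 15); r[1:20, 1:10] <- TRUE
  expect_equal(initial_bounding_rect(r),
               list(xmin = 0, xmax = 19, ymin = 0, ymax = 9))
  set.seed(41)
  sparse <- matrix(runif(30 * 30) > 0.9, 30, 30)
  idx <- which(sparse, arr.ind = TRUE)
  expect_equal(initial_bounding_rect(sparse),
               list(xmin = min(idx[, 1]) - 1, xmax = max(idx[, 1]) - 1,
                    ymin = min(idx[, 2]) - 1, ymax = max(idx[, 2]) - 1))
  expect_error(initial_bounding_rect(matrix(FALSE, 3, 3)), "empty mask")
})

test_that("rectangle area follows S = (xmax - xmin) * (ymax - ymin)", {
  expect_equal(rect_area(list(xmin = 2, xmax = 10, ymin = 3, ymax = 8)), 40)
  expect_equal(rect_area(list(xmin = 5, xmax = 5, ymin = 7, ymax = 7)), 0)
  # a square rotated by 30 deg has bounding area ~ (s (cos30 + sin30))^2 >= s^2
  s <- 120
  m <- rotated_rect_mask(301, 301, s / 2, s / 2, 30)
  area <- rect_area(initial_bounding_rect(m))
  expect_equal(area, (s * (cos(pi / 6) + sin(pi / 6)))^2, tolerance = 0.03)
  expect_gte(area, s^2)
})

test_that("an axis-aligned rectangle has zero tilt and minimal initial area", {
  m <- matrix(FALSE, 60, 60); m[10:50, 20:40] <- TRUE
  est <- estimate_tilt(m)
  expect_equal(est$angle_deg, 0)
  expect_equal(est$mbr_area, est$initial_area)
})

test_that("tilt of a rasterized rotated rectangle is recovered", {
  m <- rotated_rect_mask(501, 501, 180, 90, 5)
  est <- estimate_tilt(m)
  expect_lt(abs(est$angle_deg - 5), 0.01 + 0.05)
})

test_that("degenerate masks are handled explicitly", {
  expect_error(estimate_tilt(matrix(FALSE, 5, 5)), "empty mask")
  two <- matrix(FALSE, 5, 5); two[2, 2] <- TRUE; two[4, 4] <- TRUE
  expect_warning(est <- estimate_tilt(two), "orientation undefined")
  expect_equal(est$angle_deg, 0)
})

test_that("the MBR area never exceeds the initial area", {
  set.seed(51)
  for (i in 1:8) {
    m <- rotated_rect_mask(201, 201, runif(1, 30, 80), runif(1, 20, 60),
                           runif(1, 0, 40))
    est <- estimate_tilt(m)
    expect_lte(est$mbr_area, est$initial_area)
    expect_equal(est$mbr_area, min(est$trace$area))
  }
})

test_that("estimates are equivariant under an added rotation", {
  # rectangles have a sharp MBR minimum, so rotational consistency is limited
  # only by the fine step and rasterization
  m <- rotated_rect_mask(501, 501, 180, 90, 2)
  base <- estimate_tilt(m)$angle_deg
  for (delta in c(2, 5)) {
    skewed <- rotate_image(m, -delta)  # adds delta of display-CCW skew
    est <- estimate_tilt(skewed)$angle_deg
    expect_lt(abs(est - base - delta), 0.01 + 0.05)
  }
})

test_that("coarse-to-fine search matches an exhaustive fine scan", {
  set.seed(61)
  for (i in 1:4) {
    ang <- runif(1, 2, 40)
    m <- rotated_rect_mask(61, 61, runif(1, 12, 22), runif(1, 6, 12), ang)
    expect_lte(sum(m), 1500)
    est <- estimate_tilt(m)
    ex <- mbr_exhaustive(m, 0.01)
    folded <- if (ex > 45) ex - 90 else ex
    expect_equal(est$angle_deg, folded, tolerance = 1e-9)
  }
})

test_that("rotation by zero is the identity and round-trips preserve content", {
  gen <- generate_microarray_image(small_spec(seed = 3))
  expect_identical(rotate_image(gen$image, 0), gen$image)
  d <- disk_mask(351, 351, 175, 175, 150)   # ~300 px wide disk
  for (theta in c(4, 10)) {
    back <- rotate_image(rotate_image(d, theta), -theta)
    # compare on the common centered canvas
    ox <- (nrow(back) - nrow(d)) %/% 2; oy <- (ncol(back) - ncol(d)) %/% 2
    cropped <- back[ox + seq_len(nrow(d)), oy + seq_len(ncol(d))]
    iou <- sum(cropped & d) / sum(cropped | d)
    expect_gte(iou, 0.98)
  }
})

test_that("correcting by the estimated tilt leaves no residual skew", {
  gen <- generate_microarray_image(chip_spec(tilt_deg = 2, seed = 8))
  est <- estimate_tilt(pretreat(gen$image)$mask)
  corrected <- rotate_image(gen$image, est$angle_deg)
  resid <- estimate_tilt(pretreat(corrected)$mask)
  expect_lte(abs(resid$angle_deg), 0.01 + 0.05)
})
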