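test_that("labeling honors 8- vs 4-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE   # diagonal pair
  expect_equal(max(label_components(m, 8)), 1L)
  expect_equal(max(label_components(m, 4)), 2L)
})

test_that("region summaries report area, centroid and extents", {
  m <- matrix(FALSE, 12, 12)
  m[3:6, 4:9] <- TRUE   # 4 x 6 block: x in 2..5, y in 3..8 (0-based)
  lr <- labeled_regions(label_components(m))
  r <- lr$regions
  expect_equal(nrow(r), 1L)
  expect_equal(r$area, 24L)
  expect_equal(c(r$cx, r$cy), c(3.5, 5.5))
  expect_equal(c(r$xmin, r$xmax, r$ymin, r$ymax), c(2, 5, 3, 8))
  expect_equal(c(r$M, r$N), c(4, 6))
})

test_that("clean_mask applies complement, hole fill and border suppression", {
  all_true <- matrix(TRUE, 6, 6)
  expect_false(any(clean_mask(all_true, complement = TRUE, open_radius = 0,
                              fill_holes = FALSE)))
  # disk with a small interior hole: filling restores the full disk
  d <- disk_mask(41, 41, 20, 20, 12)
  holed <- d; holed[20:22, 20:22] <- FALSE
  filled <- clean_mask(holed, open_radius = 0, fill_holes = TRUE)
  expect_equal(sum(filled), sum(d))
  # blob touching the top edge is removed entirely by border suppression
  b <- matrix(FALSE, 20, 20); b[5:8, 1:4] <- TRUE; b[12:15, 8:11] <- TRUE
  out <- clean_mask(b, open_radius = 0, fill_holes = FALSE,
                    suppress_border = TRUE)
  expect_equal(sum(out), 16L)
  expect_false(any(out[, 1:4]))
})

test_that("morphological opening is anti-extensive and idempotent", {
  set.seed(31)
  for (i in 1:5) {
    m <- matrix(runif(40 * 40) > 0.55, 40, 40)
    o1 <- clean_mask(m, open_radius = 2, fill_holes = FALSE)
    o2 <- clean_mask(o1, open_radius = 2, fill_holes = FALSE)
    expect_true(all(o1 <= m))       # opening only removes foreground
    expect_identical(o1, o2)        # applying twice equals once
  }
})

test_that("mask combination keeps supported components and drops clutter", {
  W <- 60; H <- 60
  disk <- disk_mask(W, H, 30, 30, 11)    # area ~380
  # identical masks: component retained verbatim
  res <- combine_components(disk, disk, min_area = 50,
                            max_area = 10 * sum(disk), min_overlap = 0.3)
  expect_identical(res$mask, disk)
  expect_equal(nrow(res$regions$regions), 1L)
  # a blob with zero saturation support is removed
  v2 <- disk; v2[5:9, 40:41] <- TRUE
  res2 <- combine_components(disk, v2, min_area = 5,
                             max_area = 10 * sum(disk), min_overlap = 0.3)
  expect_identical(res2$mask, disk)
  # nothing survives -> explicit unusable-image error
  empty_s <- matrix(FALSE, W, H)
  expect_error(combine_components(empty_s, v2, min_area = 5,
                                  max_area = 1e5, min_overlap = 0.3),
               "zero surviving components")
})

test_that("pretreatment recovers one component per synthetic cell", {
  gen <- generate_microarray_image(small_spec(tilt_deg = 1.5, seed = 7))
  pre <- pretreat(gen$image, pipeline_config(rows = 3, cols = 3))
  reg <- pre$regions$regions
  expect_equal(nrow(reg), 9L)
  expect_identical(dim(pre$mask), dim(gen$image)[1:2])
  # no border-touching component in the final mask
  lab <- pre$regions$label_map
  expect_equal(sum(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]), 0L)
  # each centroid within cell_diameter / 4 of its ground-truth center
  tr <- gen$truth$centers
  for (i in seq_len(nrow(tr))) {
    d <- sqrt((reg$cx - tr$x[i])^2 + (reg$cy - tr$y[i])^2)
    expect_lt(min(d), 30 / 4)
  }
})

test_that("component count is stable across seeded generations", {
  ok <- vapply(1:15, function(s) {
    gen <- generate_microarray_image(small_spec(tilt_deg = 1, seed = s))
    nrow(pretreat(gen$image)$regions$regions) == 9L
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
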