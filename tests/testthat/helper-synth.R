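# small, fast default fixture: 3x3 grid on a 160x160 canvas
small_spec <- function(tilt_deg = 0, seed = 1L, ...) {
  synthetic_spec(rows = 3L, cols = 3L, image_width = 160L, image_height = 160L,
                 cell_diameter = 30, pitch = 42, tilt_deg = tilt_deg,
                 seed = seed, ...)
}

noise_free <- function(spec_fun = small_spec, ...) {
  spec_fun(..., speckle_variance = 0, impulse_fraction = 0,
           illumination_gradient = 0)
}

# paper-scale 6x6 spec
chip_spec <- function(tilt_deg = 0, seed = 1L, ...) {
  synthetic_spec(rows = 6L, cols = 6L, tilt_deg = tilt_deg, seed = seed, ...)
}

# draw a filled axis-aligned disk mask
disk_mask <- function(w, h, cx, cy, r) {
  x <- matrix(0:(w - 1), w, h)
  y <- matrix(0:(h - 1), w, h, byrow = TRUE)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

# rasterize a filled rectangle rotated by `deg` (display-CCW) about its center
rotated_rect_mask <- function(w, h, half_a, half_b, deg) {
  x <- matrix(0:(w - 1), w, h) - (w - 1) / 2
  y <- matrix(0:(h - 1), w, h, byrow = TRUE) - (h - 1) / 2
  r <- deg * pi / 180
  u <- x * cos(r) - y * sin(r)   # rotate coordinates by -deg
  v <- x * sin(r) + y * cos(r)
  abs(u) <= half_a & abs(v) <= half_b
}

# brute-force Otsu oracle: exhaustive scan of all 256 bin boundaries,
# computing the two-class between-class variance directly
otsu_bruteforce <- function(channel) {
  q <- as.integer(round(channel * 255))
  best_k <- 0L; best_s <- -Inf
  for (k in 0:255) {
    lo <- q[q <= k]; hi <- q[q > k]
    if (length(lo) == 0L || length(hi) == 0L) s <- 0 else {
      w0 <- length(lo) / length(q); w1 <- 1 - w0
      s <- w0 * w1 * (mean(lo) - mean(hi))^2
    }
    if (s > best_s + 1e-12) { best_s <- s; best_k <- k }
  }
  best_k / 255
}

# exhaustive single-pass MBR scan at `step` over [0, 90)
mbr_exhaustive <- function(mask, step) {
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 1L] - 1; y <- idx[, 2L] - 1
  angles <- seq(0, 90 - step, by = step)
  areas <- vapply(angles, function(th) {
    r <- th * pi / 180
    u <- x * cos(r) - y * sin(r)
    v <- x * sin(r) + y * cos(r)
    (max(u) - min(u)) * (max(v) - min(v))
  }, numeric(1))
  angles[which.min(areas)]
}
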