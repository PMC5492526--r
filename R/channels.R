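#' Decompose an RGB image into normalized HSV channels
#'
#' Standard hexcone conversion: `value = max(R,G,B)`, `saturation = 0` where
#' `value = 0` and `(max - min)/max` otherwise, hue in `[0, 1)` by the usual
#' piecewise formula. Reflected-light chip images have a strongly colored
#' background and near-gray cells, so saturation and value carry complementary
#' information: saturation marks where color lives (background), value marks
#' where light lives (cells).
#'
#' @param image A `width x height x 3` array in `[0, 1]`.
#' @return A list with matrices `h`, `s`, `v` (same width/height, values in
#'   `[0, 1]`).
#' @export
rgb_to_hsv_image <- function(image) {
  assert_color_image(image)
  d <- dim(image)[1:2]
  m <- rbind(as.vector(image[, , 1]),
             as.vector(image[, , 2]),
             as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  list(h = matrix(hsv[1L, ], d[1L], d[2L]),
       s = matrix(hsv[2L, ], d[1L], d[2L]),
       v = matrix(hsv[3L, ], d[1L], d[2L]))
}

#' Contrast-adjust a normalized channel
#'
#' Linear stretch mapping the `low` and `high` intensity percentiles to 0 and
#' 1 (with clipping), followed by a pointwise power `gamma`. This is the
#' "parameter adjustment" applied to the saturation and value channels before
#' thresholding; with `low = 0, high = 1, gamma = 1` it is the identity on
#' data spanning `[0, 1]`.
#'
#' @param channel Numeric matrix with values in `[0, 1]`.
#' @param low,high Percentiles in `[0, 1]` mapped to 0 and 1; `low < high`.
#' @param gamma Positive exponent applied after the stretch.
#' @return Adjusted matrix in `[0, 1]`. A degenerate (constant) channel is
#'   returned unchanged with a warning.
#' @export
adjust_channel <- function(channel, low = 0.01, high = 0.99, gamma = 1) {
  if (low >= high) stopf("need low < high (got %g, %g)", low, high)
  if (gamma <= 0) stopf("gamma must be positive")
  q <- stats::quantile(channel, c(low, high), names = FALSE, type = 7)
  if (q[2L] <= q[1L]) {
    warnf("degenerate channel (constant over the stretch range); returned unchanged")
    return(channel)
  }
  out <- (channel - q[1L]) / (q[2L] - q[1L])
  out <- pmin(pmax(out, 0), 1)
  if (gamma != 1) out <- out^gamma
  out
}

#' Otsu threshold of a normalized channel
#'
#' Quantizes the channel to 256 gray bins and selects the bin boundary that
#' maximizes the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`; ties are broken toward the smallest threshold.
#' The foreground mask marks pixels strictly above the threshold.
#'
#' @param channel Numeric matrix with values in `[0, 1]`.
#' @return A list with `threshold` (in `[0, 1]`, a bin value `k/255`) and
#'   `mask` (logical matrix, `TRUE` = above threshold). A constant channel
#'   yields its own value as threshold, an empty mask, and a warning.
#' @export
otsu_threshold <- function(channel) {
  if (anyNA(channel) || min(channel) < 0 || max(channel) > 1)
    stopf("channel must be normalized to [0, 1]")
  q <- as.integer(round(channel * 255))
  if (min(q) == max(q)) {
    warnf("constant channel: empty foreground")
    return(list(threshold = min(q) / 255,
                mask = matrix(FALSE, nrow(channel), ncol(channel))))
  }
  counts <- tabulate(q + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  w0 <- cumsum(p)                       # P(class <= k)
  mu0 <- cumsum(p * levels)             # unnormalized class-0 mean
  mu_t <- mu0[256L]
  w1 <- 1 - w0
  # between-class variance at each candidate boundary k = 0..255
  num <- (mu_t * w0 - mu0)^2
  den <- w0 * w1
  sigma_b <- ifelse(den > 0, num / den, 0)
  k <- which.max(sigma_b) - 1L          # which.max returns the first maximum
  list(threshold = k / 255, mask = matrix(q > k, nrow(channel), ncol(channel)))
}

#' Convert an RGB image to 8-bit gray values
#'
#' @param image A `width x height x 3` array in `[0, 1]`.
#' @param method `"bt601"` for the ITU-R BT.601 luminance
#'   `round(0.299 R + 0.587 G + 0.114 B)` on the 0-255 scale, or `"value"`
#'   for the HSV value channel scaled to 0-255.
#' @return Integer-valued matrix in `[0, 255]`.
#' @export
gray_values <- function(image, method = c("bt601", "value")) {
  assert_color_image(image)
  method <- match.arg(method)
  d <- dim(image)[1:2]
  r <- matrix(round(image[, , 1] * 255), d[1L], d[2L])
  g <- matrix(round(image[, , 2] * 255), d[1L], d[2L])
  b <- matrix(round(image[, , 3] * 255), d[1L], d[2L])
  if (method == "bt601") {
    round(0.299 * r + 0.587 * g + 0.114 * b)
  } else {
    round(pmax(r, pmax(g, b)))
  }
}
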