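#' Specification for a synthetic reflected-light microarray image
#'
#' Collects every generator parameter in one validated object. The defaults
#' emulate the small-format chip images the pipeline targets: a 6 x 6 grid of
#' ~34 px cells at 45 px pitch on a 283 x 287 px canvas, a dark reddish
#' laser-illumination background, multiplicative speckle, salt-and-pepper
#' impulses, an additive illumination ramp, irregular etched cell edges, and
#' one bright blob near the right edge of every cell.
#'
#' @param rows,cols Grid dimensions (positive integers).
#' @param image_width,image_height Canvas size in pixels.
#' @param cell_diameter Nominal cell diameter in pixels (before edge
#'   irregularity).
#' @param pitch Center-to-center spacing in pixels, equal in x and y; must
#'   exceed `cell_diameter`.
#' @param tilt_deg Grid rotation about the image center, degrees; positive is
#'   counterclockwise in display orientation (y down).
#' @param cell_gray_levels Per-cell interior gray level in `[0, 255]`: a
#'   scalar, a `rows x cols` matrix, or `NULL` to sample uniformly from
#'   `[130, 190]` under `seed`.
#' @param bright_spot_offset Displacement (pixels, along +x) of the bright
#'   blob from the cell center; default places it at the cell's right edge.
#' @param bright_spot_diameter Blob FWHM-scale diameter in pixels (the
#'   rendered Gaussian has `sigma = bright_spot_diameter / 2.355` so this is
#'   its full width at half maximum).
#' @param bright_spot_gain Peak intensity added by the blob, gray levels.
#' @param edge_irregularity Amplitude in `[0, 1]` of the random low-order
#'   harmonic perturbation of each cell's radius.
#' @param background_color RGB triple in `[0, 255]`.
#' @param speckle_variance Variance of the multiplicative Gaussian speckle
#'   factor `1 + N(0, speckle_variance)` shared across channels.
#' @param impulse_fraction Fraction of pixels replaced by salt (white) or
#'   pepper (black) impulses, split evenly.
#' @param illumination_gradient Amplitude (on the `[0, 1]` intensity scale)
#'   of an additive diagonal illumination ramp.
#' @param supersample Integer anti-aliasing factor; cells are rasterized on a
#'   `supersample`-times finer grid and block-averaged down.
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#' @return An object of class `synthetic_spec` (a validated list).
#' @seealso [generate_microarray_image()]
#' @export
synthetic_spec <- function(rows = 6L, cols = 6L,
                           image_width = 283L, image_height = 287L,
                           cell_diameter = 34, pitch = 45,
                           tilt_deg = 0,
                           cell_gray_levels = NULL,
                           bright_spot_offset = 0.5 * cell_diameter,
                           bright_spot_diameter = 0.09 * cell_diameter,
                           bright_spot_gain = 70,
                           edge_irregularity = 0.06,
                           background_color = c(30, 10, 10),
                           speckle_variance = 0.02,
                           impulse_fraction = 0.01,
                           illumination_gradient = 0.01,
                           supersample = 4L,
                           seed = 1L) {
  if (rows < 1 || cols < 1 || rows != round(rows) || cols != round(cols))
    stopf("rows and cols must be positive integers")
  if (!(pitch > cell_diameter && cell_diameter > 0))
    stopf("need pitch > cell_diameter > 0 (got pitch=%g, cell_diameter=%g)",
          pitch, cell_diameter)
  if (edge_irregularity < 0 || edge_irregularity > 1)
    stopf("edge_irregularity must be in [0, 1]")
  if (impulse_fraction < 0 || impulse_fraction > 1)
    stopf("impulse_fraction must be in [0, 1]")
  if (speckle_variance < 0) stopf("speckle_variance must be >= 0")
  if (length(background_color) != 3L || any(background_color < 0) ||
      any(background_color > 255))
    stopf("background_color must be an RGB triple in [0, 255]")
  if (!is.null(cell_gray_levels)) {
    g <- cell_gray_levels
    if (length(g) == 1L) g <- matrix(g, rows, cols)
    if (!is.matrix(g) || !all(dim(g) == c(rows, cols)))
      stopf("cell_gray_levels must be scalar or a rows x cols matrix")
    if (any(g < 0) || any(g > 255))
      stopf("cell_gray_levels must lie in [0, 255]")
    cell_gray_levels <- g
  }
  spec <- list(
    rows = as.integer(rows), cols = as.integer(cols),
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    cell_diameter = cell_diameter, pitch = pitch, tilt_deg = tilt_deg,
    cell_gray_levels = cell_gray_levels,
    bright_spot_offset = bright_spot_offset,
    bright_spot_diameter = bright_spot_diameter,
    bright_spot_gain = bright_spot_gain,
    edge_irregularity = edge_irregularity,
    background_color = as.numeric(background_color),
    speckle_variance = speckle_variance,
    impulse_fraction = impulse_fraction,
    illumination_gradient = illumination_gradient,
    supersample = as.integer(supersample),
    seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  # geometric feasibility: every cell (with irregularity headroom) must stay
  # inside the canvas after rotation
  ctr <- grid_centers(spec)
  rmax <- cell_diameter / 2 * (1 + 1.2 * edge_irregularity) + 1
  if (any(ctr$x < rmax) || any(ctr$x > image_width - 1 - rmax) ||
      any(ctr$y < rmax) || any(ctr$y > image_height - 1 - rmax))
    stopf("grid does not fit: a cell rotated by %g deg would leave the canvas",
          tilt_deg)
  spec
}

# True (rotated) cell centers in 0-based pixel coordinates, row-major order.
# Positive tilt rotates the grid counterclockwise in display orientation
# (y down): (dx, dy) -> (dx cos + dy sin, -dx sin + dy cos).
grid_centers <- function(spec) {
  cx <- (spec$image_width - 1) / 2
  cy <- (spec$image_height - 1) / 2
  ij <- expand.grid(col = seq_len(spec$cols), row = seq_len(spec$rows))
  dx <- (ij$col - (spec$cols + 1) / 2) * spec$pitch
  dy <- (ij$row - (spec$rows + 1) / 2) * spec$pitch
  th <- spec$tilt_deg * pi / 180
  data.frame(row = ij$row, col = ij$col,
             x = cx + dx * cos(th) + dy * sin(th),
             y = cy - dx * sin(th) + dy * cos(th))
}

#' Generate a synthetic microarray reflected-light image with ground truth
#'
#' Renders `rows x cols` irregular near-circular cells at the rotated grid
#' positions implied by the spec, each with a bright Gaussian blob displaced
#' toward its right side, on a colored background. Rendering uses
#' `supersample`-fold anti-aliasing; noise is then applied at output
#' resolution in the order: additive illumination ramp, multiplicative
#' speckle, salt-and-pepper impulses. The result is quantized to 8-bit so the
#' in-memory array round-trips exactly through PNG.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `psi_synthetic` with elements
#'   \describe{
#'     \item{image}{`width x height x 3` array in `[0, 1]`, 8-bit quantized.}
#'     \item{truth}{Ground truth: `tilt_deg`, `centers` (data frame with
#'       `row`, `col`, `x`, `y` in 0-based pixels), `radius` (nominal cell
#'       radius, pixels), and `cell_gray_levels` (`rows x cols` matrix).}
#'   }
#' @examples
#' gen <- generate_microarray_image(synthetic_spec(rows = 3, cols = 3,
#'   image_width = 160, image_height = 160, tilt_deg = 1.5, seed = 7))
#' dim(gen$image)
#' head(gen$truth$centers)
#' @export
generate_microarray_image <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    stopf("spec must be created by synthetic_spec()")
  W <- spec$image_width; H <- spec$image_height
  ss <- spec$supersample
  R <- spec$cell_diameter / 2
  n <- spec$rows * spec$cols
  ctr <- grid_centers(spec)

  with_seed(spec$seed, {
    levels <- spec$cell_gray_levels
    if (is.null(levels))
      levels <- matrix(stats::runif(n, 130, 190), spec$rows, spec$cols,
                       byrow = TRUE)
    # low-order radial harmonics (k = 2..4) per cell: amplitude ~ U(0, 1/k),
    # phase ~ U(0, 2*pi); max radial deviation is ~1.08 * edge_irregularity
    harm_amp <- matrix(stats::runif(3L * n), 3L, n) / c(2, 3, 4)
    harm_phi <- matrix(stats::runif(3L * n, 0, 2 * pi), 3L, n)

    fineW <- W * ss; fineH <- H * ss
    intens <- matrix(0, fineW, fineH)   # cell-interior intensity, [0,1]
    cover  <- matrix(0, fineW, fineH)   # cell coverage indicator
    sigma <- spec$bright_spot_diameter / 2.355
    gain <- spec$bright_spot_gain / 255

    for (i in seq_len(n)) {
      x0 <- ctr$x[i]; y0 <- ctr$y[i]
      g <- levels[ctr$row[i], ctr$col[i]] / 255
      rmax <- R * (1 + 1.2 * spec$edge_irregularity)
      # fine-grid index range covering the cell; fine pixel f has image
      # coordinate (f + 0.5) / ss - 0.5 (0-based)
      fx <- max(0L, floor((x0 - rmax - 1) * ss)):min(fineW - 1L, ceiling((x0 + rmax + 1) * ss))
      fy <- max(0L, floor((y0 - rmax - 1) * ss)):min(fineH - 1L, ceiling((y0 + rmax + 1) * ss))
      ux <- (fx + 0.5) / ss - 0.5 - x0
      uy <- (fy + 0.5) / ss - 0.5 - y0
      dxm <- matrix(ux, length(fx), length(fy))
      dym <- matrix(uy, length(fx), length(fy), byrow = TRUE)
      rho <- sqrt(dxm^2 + dym^2)
      phi <- atan2(dym, dxm)
      pert <- harm_amp[1L, i] * cos(2 * phi - harm_phi[1L, i]) +
              harm_amp[2L, i] * cos(3 * phi - harm_phi[2L, i]) +
              harm_amp[3L, i] * cos(4 * phi - harm_phi[3L, i])
      inside <- rho <= R * (1 + spec$edge_irregularity * pert)
      blob <- gain * exp(-((dxm - spec$bright_spot_offset)^2 + dym^2) /
                           (2 * sigma^2))
      val <- pmin(g + blob, 1)
      sub_i <- intens[fx + 1L, fy + 1L]
      sub_c <- cover[fx + 1L, fy + 1L]
      sub_i[inside] <- val[inside]
      sub_c[inside] <- 1
      intens[fx + 1L, fy + 1L] <- sub_i
      cover[fx + 1L, fy + 1L] <- sub_c
    }

    ids <- downsample_mean(intens, ss)
    cds <- downsample_mean(cover, ss)

    img <- array(0, dim = c(W, H, 3L))
    for (ch in 1:3)
      img[, , ch] <- ids + (1 - cds) * spec$background_color[ch] / 255

    if (spec$illumination_gradient != 0) {
      ramp <- outer(seq(0, 1, length.out = W), seq(0, 1, length.out = H),
                    function(a, b) (a + b) / 2) * spec$illumination_gradient
      for (ch in 1:3) img[, , ch] <- img[, , ch] + ramp
    }
    if (spec$speckle_variance > 0) {
      fac <- pmax(0, 1 + stats::rnorm(W * H, 0, sqrt(spec$speckle_variance)))
      for (ch in 1:3) img[, , ch] <- img[, , ch] * fac
    }
    if (spec$impulse_fraction > 0) {
      n_imp <- round(spec$impulse_fraction * W * H)
      if (n_imp > 0) {
        idx <- sample.int(W * H, n_imp)
        val <- stats::rbinom(n_imp, 1L, 0.5)
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[idx] <- val
          img[, , ch] <- plane
        }
      }
    }
    img <- round(pmin(pmax(img, 0), 1) * 255) / 255

    out <- list(
      image = img,
      truth = list(tilt_deg = spec$tilt_deg, centers = ctr, radius = R,
                   cell_gray_levels = levels),
      spec = spec)
    class(out) <- "psi_synthetic"
    out
  })
}

# Block-average a (W*ss) x (H*ss) matrix down to W x H.
downsample_mean <- function(m, ss) {
  if (ss == 1L) return(m)
  W <- nrow(m) / ss; H <- ncol(m) / ss
  out <- matrix(0, W, H)
  for (i in seq_len(ss))
    for (j in seq_len(ss))
      out <- out + m[seq(i, by = ss, length.out = W),
                     seq(j, by = ss, length.out = H)]
  out / ss^2
}

#' Write a synthetic image and its ground-truth sidecar
#'
#' Writes `<prefix>.png` (8-bit RGB) and `<prefix>.json` holding the ground
#' truth (tilt, centers, radius, per-cell gray levels) and the generator
#' parameters.
#'
#' @param gen Result of [generate_microarray_image()].
#' @param prefix Output path prefix (without extension).
#' @return Character vector of the two written paths, invisibly.
#' @export
write_synthetic <- function(gen, prefix) {
  if (!inherits(gen, "psi_synthetic"))
    stopf("gen must come from generate_microarray_image()")
  png_path <- paste0(prefix, ".png")
  json_path <- paste0(prefix, ".json")
  write_image(gen$image, png_path)
  spec <- gen$spec
  spec$cell_gray_levels <- gen$truth$cell_gray_levels
  payload <- list(truth = gen$truth, spec = unclass(spec))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(png_path, json_path))
}
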