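#' Combine saturation- and value-channel masks into the final cell mask
#'
#' The value mask reflects the true cell extent but picks up background
#' clutter; the saturation mask marks reliable cell cores (its white areas run
#' smaller than the real cells) and has already had border objects removed.
#' Components of the value mask are therefore retained only when supported by
#' the saturation mask:
#' \itemize{
#'   \item a component is kept iff its overlap with the saturation foreground
#'     is at least `min_overlap` of its own area, its area is at least
#'     `min_area`, and it does not touch the image border;
#'   \item kept components larger than `max_area` (merged cells, background
#'     leakage) are pruned to their intersection with the saturation mask
#'     dilated by `open_radius` — the "segmentation of large areas" rule.
#' }
#'
#' @param s_mask Cleaned, border-suppressed saturation mask (logical matrix).
#' @param v_mask Cleaned value mask, same shape, border objects not removed.
#' @param min_area,max_area Component area bounds in pixels; `NULL` defaults
#'   to `0.05 x` and `4 x` the median component area of `v_mask`.
#' @param min_overlap Minimum fraction of a component's area covered by
#'   `s_mask` foreground.
#' @param open_radius Disk radius used to dilate `s_mask` when pruning
#'   oversized components.
#' @return A list with `mask` (final logical matrix) and `regions`
#'   ([labeled_regions()] of the final mask).
#' @export
combine_components <- function(s_mask, v_mask, min_area = NULL,
                               max_area = NULL, min_overlap = 0.3,
                               open_radius = 1L) {
  assert_mask(s_mask, "s_mask"); assert_mask(v_mask, "v_mask")
  if (!all(dim(s_mask) == dim(v_mask)))
    stopf("s_mask and v_mask must have the same shape")
  if (!any(v_mask)) stopf("unusable image: zero surviving components")
  lab <- label_components(v_mask, 8L)
  k <- max(lab)
  area <- tabulate(lab[lab > 0L], nbins = k)
  med <- stats::median(area)
  min_area <- min_area %||% (0.05 * med)
  max_area <- max_area %||% (4 * med)
  overlap_px <- vapply(seq_len(k), function(i) sum(s_mask[lab == i]), numeric(1))
  on_border <- seq_len(k) %in% border_labels(lab)
  keep <- (overlap_px / area >= min_overlap) & (area >= min_area) & !on_border
  if (!any(keep)) stopf("unusable image: zero surviving components")

  final <- matrix(FALSE, nrow(v_mask), ncol(v_mask))
  s_dil <- NULL
  for (i in which(keep)) {
    comp <- lab == i
    if (area[i] > max_area) {
      if (is.null(s_dil)) s_dil <- dilate_mask(s_mask, open_radius)
      comp <- comp & s_dil
    }
    final <- final | comp
  }
  if (!any(final)) stopf("unusable image: zero surviving components")
  list(mask = final, regions = labeled_regions(label_components(final, 8L)))
}

#' Pretreatment: RGB reflected-light image to clean binary cell mask
#'
#' Runs the full binarization chain: HSV decomposition, per-channel contrast
#' adjustment, Otsu thresholding with automatic polarity, morphological
#' cleanup (opening, hole filling; border suppression on the saturation mask
#' only), and saturation/value mask combination.
#'
#' Whether a channel's Otsu mask needs complementing depends on whether cells
#' are darker or brighter than the background in that channel. With
#' `polarity = "auto"` the foreground is taken to be the minority class
#' (cells cover less than half the image); `"normal"` keeps the
#' above-threshold class, `"complement"` inverts it.
#'
#' @param image A `width x height x 3` array in `[0, 1]`, or a file path.
#' @param config A [pipeline_config()]; individual arguments below override
#'   its fields when supplied.
#' @param ... Reserved.
#' @return A list of class `pretreat_result`: `mask` (final logical matrix),
#'   `regions` ([labeled_regions()]), `s_mask`, `v_mask` (per-channel cleaned
#'   masks), `s_threshold`, `v_threshold` (Otsu thresholds), and `log`
#'   (character vector of stage diagnostics).
#' @export
pretreat <- function(image, config = pipeline_config(), ...) {
  if (is.character(image)) image <- read_image(image)
  assert_color_image(image)
  logline <- character(0)
  hsv <- rgb_to_hsv_image(image)

  s_adj <- adjust_channel(hsv$s, config$adjust_s$low, config$adjust_s$high,
                          config$adjust_s$gamma)
  v_adj <- adjust_channel(hsv$v, config$adjust_v$low, config$adjust_v$high,
                          config$adjust_v$gamma)

  s_otsu <- otsu_threshold(s_adj)
  v_otsu <- otsu_threshold(v_adj)
  s_raw <- apply_polarity(s_otsu$mask, config$polarity_s)
  v_raw <- apply_polarity(v_otsu$mask, config$polarity_v)
  logline <- c(logline,
    sprintf("otsu thresholds: S=%.4f V=%.4f", s_otsu$threshold, v_otsu$threshold),
    sprintf("foreground fractions after polarity: S=%.3f V=%.3f",
            mean(s_raw), mean(v_raw)))

  s_mask <- clean_mask(s_raw, complement = FALSE,
                       open_radius = config$open_radius,
                       fill_holes = TRUE, suppress_border = TRUE)
  v_mask <- clean_mask(v_raw, complement = FALSE,
                       open_radius = config$open_radius,
                       fill_holes = TRUE, suppress_border = FALSE)

  comb <- combine_components(s_mask, v_mask,
                             min_area = config$min_area,
                             max_area = config$max_area,
                             min_overlap = config$min_overlap,
                             open_radius = config$open_radius)
  logline <- c(logline,
    sprintf("components: v_mask=%d final=%d",
            max(label_components(v_mask, 8L)), nrow(comb$regions$regions)))

  structure(list(mask = comb$mask, regions = comb$regions,
                 s_mask = s_mask, v_mask = v_mask,
                 s_threshold = s_otsu$threshold,
                 v_threshold = v_otsu$threshold,
                 log = logline),
            class = "pretreat_result")
}

# polarity: "auto" takes the minority class as foreground, "normal" keeps
# the above-threshold class, "complement" inverts it
apply_polarity <- function(mask, polarity) {
  switch(polarity,
         auto = if (mean(mask) > 0.5) !mask else mask,
         normal = mask,
         complement = !mask,
         stopf("unknown polarity '%s'", polarity))
}
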