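#' Initial external rectangle of a binary mask
#'
#' Axis-aligned extremes of the foreground pixel coordinates, found by
#' scanning the mask horizontally and vertically — the starting rectangle of
#' the minimum-bounding-rectangle search.
#'
#' @param mask Logical matrix with at least one foreground pixel.
#' @return A list `(xmin, xmax, ymin, ymax)` in 0-based pixel coordinates.
#' @export
initial_bounding_rect <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) stopf("empty mask: no foreground pixels")
  idx <- which(mask, arr.ind = TRUE)
  list(xmin = min(idx[, 1L]) - 1L, xmax = max(idx[, 1L]) - 1L,
       ymin = min(idx[, 2L]) - 1L, ymax = max(idx[, 2L]) - 1L)
}

#' Area of a bounding rectangle
#'
#' `S = (xmax - xmin) * (ymax - ymin)`, the quantity minimized by the tilt
#' search. Extent differences are used exactly as written (no +1 pixel-width
#' correction); only relative comparisons between candidate angles matter.
#'
#' @param rect A list with `xmin`, `xmax`, `ymin`, `ymax`.
#' @return The rectangle area in squared pixels.
#' @export
rect_area <- function(rect) {
  if (rect$xmax < rect$xmin || rect$ymax < rect$ymin)
    stopf("invalid rectangle: max < min")
  (rect$xmax - rect$xmin) * (rect$ymax - rect$ymin)
}

#' Estimate grid tilt by the minimum-bounding-rectangle principal-axis search
#'
#' For each candidate angle theta the foreground coordinates are rotated by
#' `-theta` about the centroid of the initial external rectangle and the area
#' `S(theta) = (xmax - xmin) * (ymax - ymin)` of the axis-aligned bounding
#' rectangle is recorded. A square grid's bounding area is 90-degree periodic,
#' so the search covers `[0, 90)` coarsely, then refines around the coarse
#' minimum. The minimizing angle is the grid tilt; angles above 45 degrees are
#' folded by 90 degrees into `(-45, 45]`.
#'
#' Since the bounding extremes depend only on the convex hull of the
#' foreground, rotations are evaluated on the hull vertices — exact, and far
#' cheaper than resampling the raster at every angle.
#'
#' @param mask Logical matrix with foreground.
#' @param coarse_step Coarse search step, degrees.
#' @param fine_step Fine search step, degrees; `0 < fine_step <= coarse_step`.
#' @param fine_halfwidth Half-width of the fine window around the coarse
#'   minimum, degrees; at least `coarse_step`.
#' @return An object of class `tilt_estimate`: a list with `angle_deg`
#'   (signed, in `(-45, 45]`; positive = counterclockwise grid skew in
#'   display orientation), `mbr_area` (minimal S), `initial_area` (S at 0),
#'   and `trace` (data frame of evaluated `(angle, area)` pairs, ascending
#'   in angle).
#' @export
estimate_tilt <- function(mask, coarse_step = 0.5, fine_step = 0.01,
                          fine_halfwidth = 1) {
  assert_mask(mask)
  if (!any(mask)) stopf("empty mask: no foreground pixels")
  if (!(fine_step > 0 && fine_step <= coarse_step))
    stopf("need 0 < fine_step <= coarse_step")
  if (fine_halfwidth < coarse_step)
    stopf("fine_halfwidth must be >= coarse_step")

  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3L) {
    warnf("fewer than 3 foreground pixels: orientation undefined, returning 0")
    s0 <- mbr_areas(idx[, 1L] - 1, idx[, 2L] - 1, 0, 0, 0)
    return(structure(list(angle_deg = 0, mbr_area = s0, initial_area = s0,
                          trace = data.frame(angle = 0, area = s0)),
                     class = "tilt_estimate"))
  }
  x <- idx[, 1L] - 1
  y <- idx[, 2L] - 1
  rect <- initial_bounding_rect(mask)
  cx <- (rect$xmin + rect$xmax) / 2
  cy <- (rect$ymin + rect$ymax) / 2
  hull <- grDevices::chull(x, y)
  hx <- x[hull]; hy <- y[hull]

  coarse <- seq(0, 90 - coarse_step, by = coarse_step)
  s_coarse <- mbr_areas(hx, hy, cx, cy, coarse)
  th_c <- coarse[which.min(s_coarse)]
  fine <- seq(th_c - fine_halfwidth, th_c + fine_halfwidth, by = fine_step)
  fine <- setdiff(round(fine, 10), round(coarse, 10))
  s_fine <- mbr_areas(hx, hy, cx, cy, fine)

  trace <- rbind(data.frame(angle = coarse, area = s_coarse),
                 data.frame(angle = fine, area = s_fine))
  trace <- trace[order(trace$angle), , drop = FALSE]
  rownames(trace) <- NULL
  best <- which.min(trace$area)          # first minimum = smallest angle
  theta <- trace$angle[best]
  angle <- if (theta > 45) theta - 90 else theta
  structure(list(angle_deg = angle,
                 mbr_area = trace$area[best],
                 initial_area = trace$area[trace$angle == 0][1L],
                 trace = trace),
            class = "tilt_estimate")
}

#' @export
print.tilt_estimate <- function(x, ...) {
  cat(sprintf(paste0("tilt_estimate: angle = %.4f deg ",
                     "(MBR area %.1f, initial %.1f, %d angles evaluated)\n"),
              x$angle_deg, x$mbr_area, x$initial_area, nrow(x$trace)))
  invisible(x)
}

# Bounding-rectangle area after rotating points by -theta (the correcting,
# display-clockwise rotation) about (cx, cy), for each theta (degrees).
# Translation does not change extents, so the center only matters for the
# trace's interpretation, not the area.
mbr_areas <- function(x, y, cx, cy, thetas) {
  dx <- x - cx; dy <- y - cy
  vapply(thetas, function(th) {
    r <- th * pi / 180
    u <- dx * cos(r) - dy * sin(r)
    v <- dx * sin(r) + dy * cos(r)
    (max(u) - min(u)) * (max(v) - min(v))
  }, numeric(1))
}

#' Rotate an image or mask to correct an estimated tilt
#'
#' Rotates the content clockwise (in display orientation, y down) by
#' `angle_deg`, i.e. applies the correction for a positive
#' [estimate_tilt()] result. The canvas is enlarged to hold the full rotated
#' content; color images are interpolated bilinearly, masks nearest-neighbor;
#' out-of-domain pixels take `fill`.
#'
#' @param image A `width x height x 3` array in `[0, 1]` or a logical mask.
#' @param angle_deg Rotation angle in degrees (finite).
#' @param fill Background value for pixels outside the original domain.
#' @return Rotated image or mask (canvas may be larger than the input).
#' @export
rotate_image <- function(image, angle_deg, fill = 0) {
  if (!is.finite(angle_deg)) stopf("angle_deg must be finite")
  is_mask <- is.logical(image)
  if (angle_deg == 0) return(image)
  if (is_mask) {
    rot <- EBImage::rotate(EBImage::Image(image * 1), angle_deg,
                           filter = "none", bg.col = fill)
    EBImage::imageData(rot) > 0.5
  } else {
    assert_color_image(image)
    rot <- EBImage::rotate(EBImage::Image(image, colormode = "Color"),
                           angle_deg, filter = "bilinear", bg.col = fill)
    pmin(pmax(EBImage::imageData(rot), 0), 1)
  }
}
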