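#' Regularize detected cell centroids onto an equidistant grid
#'
#' Centroids are grouped into rows by sorting on y and splitting at gaps
#' larger than half the median nearest-neighbor distance. In the first row,
#' A is the leftmost and B the rightmost centroid; the column abscissae are
#' `Xk = X_A + (k - 1) * (X_B - X_A) / (cols - 1)`, so the horizontal spacing
#' is constant by construction. The first-row ordinate `Y1` is the mean of
#' the first-row centroid ordinates, and subsequent row ordinates follow
#' `Yn = Y1 + (Xn - X1)`: row spacing equals column spacing, so all center
#' distances are equal. For `rows != cols` (requires `allow_rect = TRUE`)
#' the same spacing rule is applied as `Yn = Y1 + (n - 1) * dX`.
#'
#' Grid positions are always filled from this geometry, so a cell whose
#' centroid was lost upstream still receives a measurement position.
#'
#' @param regions A [labeled_regions()] object, or a data frame of centroids
#'   with columns `cx`, `cy`.
#' @param rows,cols Expected grid dimensions; `cols >= 2`.
#' @param allow_rect Permit `rows != cols` (the spacing identity above is
#'   stated for square grids; the rectangular case is an extension).
#' @return An object of class `spot_grid`: a list with `col_x` (length
#'   `cols`), `row_y` (length `rows`), `radius` (`NA` until set, see
#'   [compute_radius()]), `rows`, `cols`.
#' @export
build_grid <- function(regions, rows, cols, allow_rect = FALSE) {
  cent <- if (inherits(regions, "labeled_regions")) regions$regions else regions
  if (!all(c("cx", "cy") %in% names(cent)))
    stopf("regions must provide centroid columns cx, cy")
  if (cols < 2) stopf("cols must be >= 2: column spacing is undefined otherwise")
  if (rows != cols && !allow_rect)
    stopf("rows != cols requires allow_rect = TRUE")
  n <- nrow(cent)
  if (n < 0.8 * rows * cols)
    stopf("only %d usable centroids for a %d x %d grid (need >= %d)",
          n, rows, cols, ceiling(0.8 * rows * cols))

  # row clustering: split sorted ordinates at gaps > half the median
  # nearest-neighbor distance
  dmat <- as.matrix(stats::dist(cent[, c("cx", "cy")]))
  diag(dmat) <- Inf
  gap <- stats::median(apply(dmat, 1L, min)) / 2
  ord <- order(cent$cy)
  ys <- cent$cy[ord]
  grp <- cumsum(c(1, diff(ys) > gap))
  if (max(grp) != rows)
    stopf("row clustering found %d rows, expected %d", max(grp), rows)

  first <- ord[grp == 1L]
  a <- first[which.min(cent$cx[first])]
  b <- first[which.max(cent$cx[first])]
  dx <- (cent$cx[b] - cent$cx[a]) / (cols - 1)
  col_x <- cent$cx[a] + (seq_len(cols) - 1) * dx
  y1 <- mean(cent$cy[first])
  row_y <- y1 + (seq_len(rows) - 1) * dx    # Yn = Y1 + (Xn - X1)
  structure(list(col_x = col_x, row_y = row_y, radius = NA_real_,
                 rows = as.integer(rows), cols = as.integer(cols)),
            class = "spot_grid")
}

#' @export
print.spot_grid <- function(x, ...) {
  cat(sprintf("spot_grid: %d x %d, spacing %.3f px, radius %s\n",
              x$rows, x$cols,
              if (x$cols > 1) x$col_x[2L] - x$col_x[1L] else NA,
              if (is.na(x$radius)) "unset" else sprintf("%.2f px", x$radius)))
  invisible(x)
}

#' Common reduced dot radius from cell bounding boxes
#'
#' Each cell's bounding box has horizontal extent M and vertical extent N;
#' the dot radius is `0.9 * min over cells of min(M, N) / 2`. Halving the
#' smallest extent keeps every dot inside its cell; the 0.9 shrink excludes
#' the irregular edge zone and the bright spot on the right side of the cell.
#'
#' @param regions A [labeled_regions()] object, or a data frame with columns
#'   `M` and `N`.
#' @return The dot radius in pixels.
#' @export
compute_radius <- function(regions) {
  reg <- if (inherits(regions, "labeled_regions")) regions$regions else regions
  if (!all(c("M", "N") %in% names(reg)))
    stopf("regions must provide bounding-box extents M and N")
  if (nrow(reg) < 1L) stopf("no regions: radius undefined")
  0.9 * min(pmin(reg$M, reg$N)) / 2
}
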