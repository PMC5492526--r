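#' Extract and measure the dots defined by a spot grid
#'
#' For each grid position a disk of the grid's common radius is placed at the
#' (rounded) regularized center and the gray statistics of its pixels are
#' measured. One integer disk stencil is shared by all dots, so every
#' measurement uses the same pixel count. Disks must lie fully inside the
#' image and be pairwise disjoint (guaranteed when radius < spacing / 2).
#'
#' @param image Corrected `width x height x 3` array in `[0, 1]`.
#' @param grid A [build_grid()] result with its `radius` set.
#' @param gray Gray conversion passed to [gray_values()]: `"bt601"`
#'   (default) or `"value"`.
#' @return A list of class `spot_measurements`:
#'   \describe{
#'     \item{measurements}{Data frame with `row`, `col` (1-based grid
#'       indices), `center_x`, `center_y` (rounded pixel centers), `radius`,
#'       `pixel_count`, `mean_gray`, `std_gray` (0-255 scale).}
#'     \item{mask}{Logical matrix: union of all dot disks.}
#'     \item{viz}{`width x height x 3` array: original pixels inside the
#'       disks, black elsewhere.}
#'   }
#' @export
extract_spots <- function(image, grid, gray = c("bt601", "value")) {
  assert_color_image(image)
  if (!inherits(grid, "spot_grid")) stopf("grid must be a spot_grid")
  if (is.na(grid$radius)) stopf("grid$radius is unset; call compute_radius()")
  gray <- match.arg(gray)
  W <- dim(image)[1L]; H <- dim(image)[2L]
  r <- grid$radius
  rr <- floor(r)
  off <- expand.grid(dx = -rr:rr, dy = -rr:rr)
  off <- off[off$dx^2 + off$dy^2 <= r^2, , drop = FALSE]

  gv <- gray_values(image, gray)
  mask <- matrix(FALSE, W, H)
  rows_out <- vector("list", grid$rows * grid$cols)
  i <- 0L
  for (rw in seq_len(grid$rows)) {
    for (cl in seq_len(grid$cols)) {
      cx <- round(grid$col_x[cl])
      cy <- round(grid$row_y[rw])
      px <- cx + off$dx
      py <- cy + off$dy
      if (min(px) < 0 || max(px) > W - 1 || min(py) < 0 || max(py) > H - 1)
        stopf("dot (row %d, col %d) exceeds image bounds", rw, cl)
      lin <- cbind(px + 1L, py + 1L)
      if (any(mask[lin]))
        stopf("dot (row %d, col %d) overlaps a previous dot", rw, cl)
      mask[lin] <- TRUE
      vals <- gv[lin]
      i <- i + 1L
      rows_out[[i]] <- data.frame(
        row = rw, col = cl, center_x = cx, center_y = cy,
        radius = r, pixel_count = nrow(off),
        mean_gray = mean(vals),
        std_gray = stats::sd(vals))
    }
  }
  viz <- image
  for (ch in 1:3) viz[, , ch] <- viz[, , ch] * mask
  structure(list(measurements = do.call(rbind, rows_out),
                 mask = mask, viz = viz),
            class = "spot_measurements")
}

#' @export
print.spot_measurements <- function(x, ...) {
  m <- x$measurements
  cat(sprintf("spot_measurements: %d dots, radius %.2f px, %d px each\n",
              nrow(m), m$radius[1L], m$pixel_count[1L]))
  print(utils::head(m, 10), ...)
  invisible(x)
}
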