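#' Label connected foreground components
#'
#' 8-connectivity is the default for foreground objects; 4-connectivity is
#' used for background during hole filling (the standard duality). EBImage's
#' flood-fill labeling is 4-connected, so 8-connectivity is obtained by
#' merging labels that touch diagonally (a small union-find over the label
#' adjacency graph).
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of the same shape; 0 = background, components
#'   numbered contiguously from 1.
#' @export
label_components <- function(mask, connectivity = 8L) {
  assert_mask(mask)
  if (!connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8")
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  storage.mode(lab) <- "integer"
  k <- max(lab)
  if (connectivity == 4L || k <= 1L) return(lab)
  # labels adjacent across either diagonal belong to one 8-connected component
  a1 <- lab[-nrow(lab), -ncol(lab)]; b1 <- lab[-1, -1]       # \ diagonal
  a2 <- lab[-1, -ncol(lab)];        b2 <- lab[-nrow(lab), -1] # / diagonal
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs) > 0L) {
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(k), find, integer(1))
    remap <- match(root, sort(unique(root)))
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

#' Summarize labeled regions
#'
#' Computes, per component: pixel area, centroid (0-based x, y), bounding box,
#' and the bounding-box extents M (horizontal) and N (vertical) that drive the
#' dot-radius rule.
#'
#' @param label_map Integer matrix from [label_components()].
#' @return An object of class `labeled_regions`: a list with `label_map` and
#'   `regions`, a data frame with columns `label`, `area`, `cx`, `cy`,
#'   `xmin`, `xmax`, `ymin`, `ymax`, `M`, `N`.
#' @export
labeled_regions <- function(label_map) {
  k <- max(label_map)
  if (k < 1L) stopf("label map contains no regions")
  idx <- which(label_map > 0L, arr.ind = TRUE)
  lab <- label_map[label_map > 0L]
  x <- idx[, 1L] - 1L
  y <- idx[, 2L] - 1L
  area <- tabulate(lab, nbins = k)
  regions <- data.frame(
    label = seq_len(k),
    area = area,
    cx = as.vector(rowsum(x, lab)) / area,
    cy = as.vector(rowsum(y, lab)) / area,
    xmin = as.vector(tapply(x, lab, min)),
    xmax = as.vector(tapply(x, lab, max)),
    ymin = as.vector(tapply(y, lab, min)),
    ymax = as.vector(tapply(y, lab, max)))
  regions$M <- regions$xmax - regions$xmin + 1L
  regions$N <- regions$ymax - regions$ymin + 1L
  structure(list(label_map = label_map, regions = regions),
            class = "labeled_regions")
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat(sprintf("labeled_regions: %d components on a %d x %d map\n",
              nrow(x$regions), nrow(x$label_map), ncol(x$label_map)))
  print(utils::head(x$regions, 10), ...)
  invisible(x)
}

# labels of components touching any image border
border_labels <- function(label_map) {
  edges <- c(label_map[1L, ], label_map[nrow(label_map), ],
             label_map[, 1L], label_map[, ncol(label_map)])
  sort(unique(edges[edges > 0L]))
}

# fill background components not connected to the border (4-connectivity
# for background, dual to 8-connected foreground)
fill_mask_holes <- function(mask) {
  bg <- EBImage::imageData(EBImage::bwlabel((!mask) * 1))
  storage.mode(bg) <- "integer"
  if (max(bg) == 0L) return(mask)
  keep_bg <- border_labels(bg)
  mask | (bg > 0L & !(bg %in% keep_bg))
}

#' Morphological cleanup of a binary mask
#'
#' Applies, in order: complement, opening with a disk structuring element,
#' hole filling (4-connected background), and border suppression (removal of
#' 8-connected foreground components touching any image edge). Each step is
#' optional; this is the cleanup applied to the thresholded saturation and
#' value channels.
#'
#' @param mask Logical matrix.
#' @param complement If `TRUE`, invert the mask first (the "opposite image").
#' @param open_radius Disk radius in pixels for the opening; 0 skips it.
#' @param fill_holes If `TRUE`, fill enclosed background holes.
#' @param suppress_border If `TRUE`, delete foreground components touching the
#'   image border.
#' @return Cleaned logical matrix of the same shape.
#' @export
clean_mask <- function(mask, complement = FALSE, open_radius = 1L,
                       fill_holes = TRUE, suppress_border = FALSE) {
  assert_mask(mask)
  if (complement) mask <- !mask
  if (open_radius > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2L * as.integer(open_radius) + 1L, "disc")
    mask <- EBImage::imageData(EBImage::opening(mask * 1, brush)) > 0.5
  }
  if (fill_holes && any(mask)) mask <- fill_mask_holes(mask)
  if (suppress_border && any(mask)) {
    lab <- label_components(mask, 8L)
    drop <- border_labels(lab)
    if (length(drop) > 0L) mask <- mask & !(lab %in% drop)
  }
  mask
}

# dilate a mask by a disk of given radius
dilate_mask <- function(mask, radius) {
  if (radius <= 0 || !any(mask)) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")
  EBImage::imageData(EBImage::dilate(mask * 1, brush)) > 0.5
}
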