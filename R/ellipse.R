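#' Direct least-squares ellipse fit to boundary points
#'
#' Fits the conic `a x^2 + b xy + c y^2 + d x + e y + f = 0` minimizing
#' algebraic distance under the ellipse constraint `4ac - b^2 = 1`
#' (Fitzgibbon's direct method, in the numerically stable block form of
#' Halir & Flusser). Coordinates are centered before fitting to keep the
#' scatter matrices well conditioned.
#'
#' @param x,y Numeric vectors of boundary coordinates (at least 6 points,
#'   not collinear).
#' @return A list `(cx, cy, semi_major, semi_minor, orientation_deg)`;
#'   orientation is the major-axis angle in degrees in `(-90, 90]`, measured
#'   from the +x axis toward +y. `NULL` if the fit is degenerate or not an
#'   ellipse.
#' @export
fit_ellipse <- function(x, y) {
  if (length(x) < 6L || length(x) != length(y)) return(NULL)
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my
  d1 <- cbind(xs^2, xs * ys, ys^2)
  d2 <- cbind(xs, ys, 1)
  s1 <- crossprod(d1)
  s2 <- crossprod(d1, d2)
  s3 <- crossprod(d2)
  t3 <- tryCatch(-solve(s3, t(s2)), error = function(e) NULL)
  if (is.null(t3)) return(NULL)
  m <- s1 + s2 %*% t3
  m <- rbind(m[3L, ] / 2, -m[2L, ], m[1L, ] / 2)
  eg <- tryCatch(eigen(m), error = function(e) NULL)
  if (is.null(eg)) return(NULL)
  ev <- Re(eg$vectors)
  cond <- 4 * ev[1L, ] * ev[3L, ] - ev[2L, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) return(NULL)
  a1 <- ev[, ok[1L]]
  coef <- c(a1, as.vector(t3 %*% a1))   # (a, b, c, d, e, f) in centered frame
  geom <- conic_to_ellipse(coef)
  if (is.null(geom)) return(NULL)
  geom$cx <- geom$cx + mx
  geom$cy <- geom$cy + my
  geom
}

# conic (a,b,c,d,e,f) -> geometric ellipse parameters; NULL if degenerate
conic_to_ellipse <- function(k) {
  if (k[1L] + k[3L] < 0) k <- -k   # normalize sign so eigenvalues are positive
  a <- k[1L]; b <- k[2L] / 2; c <- k[3L]; d <- k[4L] / 2; e <- k[5L] / 2; f <- k[6L]
  den <- a * c - b^2
  if (den <= 0) return(NULL)
  cx <- (b * e - c * d) / den
  cy <- (b * d - a * e) / den
  # value of the quadratic form at the center
  mu <- a * cx^2 + 2 * b * cx * cy + c * cy^2 + 2 * d * cx + 2 * e * cy + f
  common <- sqrt((a - c)^2 + 4 * b^2)
  lam1 <- (a + c + common) / 2
  lam2 <- (a + c - common) / 2
  if (lam1 * mu >= 0 || lam2 * mu >= 0) return(NULL)
  ax1 <- sqrt(-mu / lam1)   # shorter semi-axis (lam1 is the larger eigenvalue)
  ax2 <- sqrt(-mu / lam2)
  theta <- atan2(2 * b, a - c) / 2          # major-axis direction
  ang <- theta * 180 / pi + 90              # eigenvector of lam2 is 90 deg off
  ang <- ((ang + 90) %% 180) - 90
  if (ang <= -90) ang <- ang + 180
  list(cx = cx, cy = cy, semi_major = ax2, semi_minor = ax1,
       orientation_deg = ang)
}

# boundary pixels of one labeled region: foreground pixels with a 4-neighbor
# outside the region (or on the image border)
region_boundary <- function(label_map, label) {
  inside <- label_map == label
  padded <- matrix(FALSE, nrow(inside) + 2L, ncol(inside) + 2L)
  padded[2:(nrow(inside) + 1L), 2:(ncol(inside) + 1L)] <- inside
  core <- padded[2:(nrow(inside) + 1L), 2:(ncol(inside) + 1L)] &
    padded[1:nrow(inside), 2:(ncol(inside) + 1L)] &
    padded[3:(nrow(inside) + 2L), 2:(ncol(inside) + 1L)] &
    padded[2:(nrow(inside) + 1L), 1:ncol(inside)] &
    padded[2:(nrow(inside) + 1L), 3:(ncol(inside) + 2L)]
  which(inside & !core, arr.ind = TRUE) - 1L
}

#' Fit ellipses to every labeled cell region
#'
#' The etched cell boundaries are irregular, so each region's boundary pixels
#' are smoothed by a direct least-squares ellipse fit; the fitted parameters
#' (and optionally an eccentricity filter) validate the regions before their
#' centroids drive grid construction.
#'
#' @param regions A [labeled_regions()] object.
#' @return A data frame with one row per fitted region: `label`, `cx`, `cy`,
#'   `semi_major`, `semi_minor`, `orientation_deg`, `eccentricity`. Regions
#'   with fewer than 6 boundary pixels or a degenerate fit are skipped with a
#'   warning and omitted.
#' @export
fit_ellipses <- function(regions) {
  if (!inherits(regions, "labeled_regions"))
    stopf("regions must be a labeled_regions object")
  out <- lapply(regions$regions$label, function(lb) {
    bp <- region_boundary(regions$label_map, lb)
    if (nrow(bp) < 6L) {
      warnf("region %d skipped: only %d boundary pixels (need >= 6)", lb, nrow(bp))
      return(NULL)
    }
    fit <- fit_ellipse(bp[, 1L], bp[, 2L])
    if (is.null(fit)) {
      warnf("region %d skipped: degenerate boundary, no ellipse fit", lb)
      return(NULL)
    }
    data.frame(label = lb, cx = fit$cx, cy = fit$cy,
               semi_major = fit$semi_major, semi_minor = fit$semi_minor,
               orientation_deg = fit$orientation_deg,
               eccentricity = sqrt(1 - (fit$semi_minor / fit$semi_major)^2))
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}
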