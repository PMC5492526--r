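#' Pipeline configuration
#'
#' Every tunable of the pretreatment, tilt-correction and segmentation stages
#' in one validated object. Unknown names are rejected.
#'
#' @param rows,cols Expected grid dimensions.
#' @param adjust_s,adjust_v Contrast adjustment for the saturation / value
#'   channel: lists with `low`, `high` (percentiles) and `gamma`.
#' @param polarity_s,polarity_v Otsu mask polarity per channel: `"auto"`
#'   (foreground = minority class), `"normal"`, or `"complement"`.
#' @param open_radius Disk radius (pixels) for morphological opening and for
#'   the dilation used when pruning oversized components.
#' @param min_area,max_area Component area bounds in pixels; `NULL` = derive
#'   from the median component area (`0.05 x` and `4 x`).
#' @param min_overlap Minimum saturation-mask support fraction for a value
#'   component.
#' @param coarse_step,fine_step,fine_halfwidth Tilt search parameters,
#'   degrees.
#' @param gray Gray conversion for dot measurement: `"bt601"` or `"value"`.
#' @param eccentricity_max If non-`NULL`, drop regions whose fitted ellipse
#'   eccentricity exceeds this before grid construction (off by default).
#' @param allow_rect Permit `rows != cols` grids.
#' @param seed Seed for any randomized debug sampling (reserved; the pipeline
#'   itself is deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(rows = 6L, cols = 6L,
                            adjust_s = list(low = 0.01, high = 0.99, gamma = 1),
                            adjust_v = list(low = 0.01, high = 0.99, gamma = 1),
                            polarity_s = "auto", polarity_v = "auto",
                            open_radius = 1L,
                            min_area = NULL, max_area = NULL,
                            min_overlap = 0.3,
                            coarse_step = 0.5, fine_step = 0.01,
                            fine_halfwidth = 1,
                            gray = "bt601",
                            eccentricity_max = NULL,
                            allow_rect = FALSE,
                            seed = 1L) {
  cfg <- list(rows = as.integer(rows), cols = as.integer(cols),
              adjust_s = adjust_s, adjust_v = adjust_v,
              polarity_s = polarity_s, polarity_v = polarity_v,
              open_radius = open_radius,
              min_area = min_area, max_area = max_area,
              min_overlap = min_overlap,
              coarse_step = coarse_step, fine_step = fine_step,
              fine_halfwidth = fine_halfwidth,
              gray = match.arg(gray, c("bt601", "value")),
              eccentricity_max = eccentricity_max,
              allow_rect = allow_rect,
              seed = as.integer(seed))
  for (ch in c("adjust_s", "adjust_v")) {
    a <- cfg[[ch]]
    if (!is.list(a) || !all(c("low", "high", "gamma") %in% names(a)))
      stopf("%s must be a list with low, high, gamma", ch)
    if (a$low >= a$high) stopf("%s: need low < high", ch)
  }
  if (!cfg$polarity_s %in% c("auto", "normal", "complement") ||
      !cfg$polarity_v %in% c("auto", "normal", "complement"))
    stopf("polarity must be 'auto', 'normal' or 'complement'")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML-like key file
#'
#' A plain-text config with one `key: value` per line (JSON also accepted via
#' a `.json` extension). Unknown keys are rejected; omitted keys take the
#' [pipeline_config()] defaults.
#'
#' @param path Path to a JSON config file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full dot-extraction pipeline
#'
#' Stages: load the RGB image, pretreat to a binary cell mask, estimate the
#' grid tilt by the MBR search, rotate the original image to correct it,
#' pretreat the corrected image, fit ellipses and regularize the centroids
#' onto an equidistant grid, derive the common reduced dot radius, and
#' measure every dot. If `out_dir` is given, [write_report()] is called on
#' the result.
#'
#' @param image Path to a PNG/TIFF/JPEG/BMP file, or a `width x height x 3`
#'   array in `[0, 1]`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for report artifacts.
#' @return An object of class `pipeline_result`: `tilt` ([estimate_tilt()]
#'   result), `grid` ([build_grid()] result with radius set), `measurements`
#'   (data frame, one row per grid position), `ellipses`, `corrected`
#'   (rotated image), `mask` (final corrected-image cell mask), `spots`
#'   (full [extract_spots()] result), `log`, `timings` (per-stage seconds,
#'   informational), and `paths` (written artifacts, if any).
#' @export
run_pipeline <- function(image, config = pipeline_config(), out_dir = NULL) {
  logs <- character(0)
  times <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    times[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  img <- stage("load", {
    if (is.character(image)) read_image(image) else { assert_color_image(image); image }
  })
  pre1 <- stage("pretreatment", pretreat(img, config))
  logs <- c(logs, pre1$log)
  tilt <- stage("tilt_estimation",
                estimate_tilt(pre1$mask, config$coarse_step, config$fine_step,
                              config$fine_halfwidth))
  logs <- c(logs, sprintf("tilt: %.4f deg (MBR area %.0f, initial %.0f)",
                          tilt$angle_deg, tilt$mbr_area, tilt$initial_area))
  corrected <- stage("rotation", rotate_image(img, tilt$angle_deg, fill = 0))
  pre2 <- stage("pretreatment_corrected", pretreat(corrected, config))
  logs <- c(logs, pre2$log)

  seg <- stage("segmentation", {
    regions <- pre2$regions
    ell <- fit_ellipses(regions)
    cent <- regions$regions
    if (!is.null(config$eccentricity_max) && !is.null(ell)) {
      bad <- ell$label[ell$eccentricity > config$eccentricity_max]
      if (length(bad) > 0L) {
        logs <<- c(logs, sprintf("eccentricity filter dropped %d regions",
                                 length(bad)))
        cent <- cent[!cent$label %in% bad, , drop = FALSE]
      }
    }
    grid <- build_grid(cent, config$rows, config$cols,
                       allow_rect = config$allow_rect)
    grid$radius <- compute_radius(cent)
    sp <- extract_spots(corrected, grid, gray = config$gray)
    list(grid = grid, ellipses = ell, spots = sp)
  })
  logs <- c(logs, sprintf("grid spacing %.3f px, dot radius %.3f px",
                          seg$grid$col_x[2L] - seg$grid$col_x[1L],
                          seg$grid$radius))

  res <- structure(list(tilt = tilt, grid = seg$grid,
                        measurements = seg$spots$measurements,
                        ellipses = seg$ellipses,
                        corrected = corrected, mask = pre2$mask,
                        spots = seg$spots, config = config,
                        log = logs, timings = unlist(times),
                        paths = character(0)),
                   class = "pipeline_result")
  if (!is.null(out_dir)) res$paths <- write_report(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0("pipeline_result: tilt %.4f deg, %d x %d grid, ",
                     "radius %.2f px, %d dots\n"),
              x$tilt$angle_deg, x$grid$rows, x$grid$cols, x$grid$radius,
              nrow(x$measurements)))
  invisible(x)
}

#' Write pipeline artifacts
#'
#' Writes `spots.csv` (the measurements), `geometry.json` (the spot grid),
#' `tilt.json` (the tilt estimate including its search trace), `overlay.png`
#' (grid circles drawn on the corrected image) and `run.log`.
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_report <- function(result, out_dir) {
  if (!inherits(result, "pipeline_result"))
    stopf("result must be a pipeline_result")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory %s", out_dir)
  paths <- c(spots = file.path(out_dir, "spots.csv"),
             geometry = file.path(out_dir, "geometry.json"),
             tilt = file.path(out_dir, "tilt.json"),
             overlay = file.path(out_dir, "overlay.png"),
             log = file.path(out_dir, "run.log"))
  utils::write.csv(result$measurements, paths[["spots"]], row.names = FALSE)
  jsonlite::write_json(
    list(col_x = result$grid$col_x, row_y = result$grid$row_y,
         radius = result$grid$radius, rows = result$grid$rows,
         cols = result$grid$cols),
    paths[["geometry"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(angle_deg = result$tilt$angle_deg, mbr_area = result$tilt$mbr_area,
         initial_area = result$tilt$initial_area, trace = result$tilt$trace),
    paths[["tilt"]], auto_unbox = TRUE, digits = NA, dataframe = "columns")
  write_image(draw_grid_overlay(result$corrected, result$grid),
              paths[["overlay"]])
  writeLines(result$log, paths[["log"]])
  invisible(paths)
}

#' Re-read a geometry sidecar as a spot grid
#'
#' @param path Path to a `geometry.json` written by [write_report()].
#' @return A `spot_grid` identical to the one serialized.
#' @export
read_geometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(col_x = as.numeric(g$col_x), row_y = as.numeric(g$row_y),
                 radius = as.numeric(g$radius), rows = as.integer(g$rows),
                 cols = as.integer(g$cols)),
            class = "spot_grid")
}

# draw green grid circles (1 px ring) on a copy of the image
draw_grid_overlay <- function(image, grid) {
  W <- dim(image)[1L]; H <- dim(image)[2L]
  out <- image
  th <- seq(0, 2 * pi, length.out = max(64L, ceiling(8 * grid$radius)))
  for (rw in seq_len(grid$rows)) {
    for (cl in seq_len(grid$cols)) {
      px <- round(grid$col_x[cl] + grid$radius * cos(th))
      py <- round(grid$row_y[rw] + grid$radius * sin(th))
      ok <- px >= 0 & px < W & py >= 0 & py < H
      lin <- cbind(px[ok] + 1L, py[ok] + 1L)
      for (ch in 1:3) {
        plane <- out[, , ch]
        plane[lin] <- if (ch == 2L) 1 else 0
        out[, , ch] <- plane
      }
    }
  }
  out
}
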