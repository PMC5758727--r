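# File formats: multi-page TIFF cubes and parameter maps (with YAML
# sidecars), integer-label PNG masks, CSV ROI tables, YAML pipeline
# configuration, and color-coded FLIRR image rendering.

#' Write / read a TCSPC cube as a multi-page TIFF
#'
#' Pages are time bins; counts are stored as 16-bit samples. A YAML sidecar
#' (`<file>.yaml`) records bin width, period and channel so the cube is
#' self-describing.
#'
#' @param cube Integer array `(rows, cols, bins)` with counts < 65536.
#' @param file Output TIFF path.
#' @param axis [time_axis()] describing the time base.
#' @param channel Channel tag written to the sidecar.
#' @return `file`, invisibly.
#' @export
write_tcspc_tiff <- function(cube, file, axis, channel = "nadh") {
  stopifnot(length(dim(cube)) == 3L, dim(cube)[3] == axis$n_bins)
  if (max(cube) > 65535) stop("write_tcspc_tiff: counts exceed 16-bit range")
  pages <- lapply(seq_len(dim(cube)[3]), function(k) cube[, , k] / 65535)
  tiff::writeTIFF(pages, file, bits.per.sample = 16L)
  yaml::write_yaml(list(n_bins = axis$n_bins, bin_width = axis$bin_width,
                        period = axis$period, channel = channel),
                   paste0(file, ".yaml"))
  invisible(file)
}

#' @rdname write_tcspc_tiff
#' @return For the reader: list with `cube` (integer array) and `axis`,
#'   `channel` from the sidecar.
#' @export
read_tcspc_tiff <- function(file) {
  pages <- tiff::readTIFF(file, all = TRUE)
  meta <- yaml::read_yaml(paste0(file, ".yaml"))
  cube <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) cube[, , k] <- as.integer(round(pages[[k]] * 65535))
  list(cube = cube,
       axis = time_axis(meta$n_bins, meta$bin_width, meta$period),
       channel = meta$channel)
}

#' Write / read per-pixel parameter maps as 32-bit TIFF
#'
#' Each plane holds one parameter map; planes are scaled into \[0, 1\] for
#' storage and the per-plane scale factors plus plane names are recorded in
#' a YAML sidecar. Values round-trip at 32-bit float precision; `NA` pixels
#' are encoded as a sentinel and restored on read.
#'
#' @param maps Named list of numeric matrices (e.g. from [fit_cube()]).
#' @param file Output TIFF path.
#' @return `file`, invisibly.
#' @export
write_parameter_maps <- function(maps, file) {
  stopifnot(is.list(maps), !is.null(names(maps)))
  planes <- list(); scales <- numeric(0)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    storage.mode(m) <- "double"
    sc <- max(abs(m), 1, na.rm = TRUE) * 1.0001  # keep sentinel distinct
    m[is.na(m)] <- sc  # sentinel: exactly 1.0 after scaling is impossible
    planes[[nm]] <- m / sc
    scales[nm] <- sc
  }
  tiff::writeTIFF(unname(planes), file, bits.per.sample = 32L)
  yaml::write_yaml(list(planes = names(maps), scales = as.list(scales)),
                   paste0(file, ".yaml"))
  invisible(file)
}

#' @rdname write_parameter_maps
#' @export
read_parameter_maps <- function(file) {
  pages <- tiff::readTIFF(file, all = TRUE)
  meta <- yaml::read_yaml(paste0(file, ".yaml"))
  out <- list()
  for (k in seq_along(meta$planes)) {
    nm <- meta$planes[[k]]
    sc <- meta$scales[[nm]]
    m <- pages[[k]] * sc
    m[pages[[k]] >= 1 - 1e-7] <- NA_real_
    out[[nm]] <- m
  }
  out
}

#' Write / read an integer label mask as grayscale PNG
#'
#' Labels up to 255 round-trip exactly (8-bit samples).
#'
#' @param labels Integer matrix (0 = background) or logical matrix.
#' @param file Output PNG path.
#' @return `file` invisibly; the reader returns the integer matrix.
#' @export
write_label_png <- function(labels, file) {
  m <- labels
  if (is.logical(m)) m <- m * 1L
  if (max(m) > 255 || any(m < 0)) stop("write_label_png: labels outside 8-bit range")
  png::writePNG(m / 255, file)
  invisible(file)
}

#' @rdname write_label_png
#' @export
read_label_png <- function(file) {
  m <- png::readPNG(file)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Write / read ROI tables as CSV
#'
#' The column set of the ROI/redox tables is the public tabular contract;
#' tables round-trip to identical in-memory data frames (numeric values at
#' full precision).
#'
#' @param tab Data frame.
#' @param file CSV path.
#' @return `file` invisibly; the reader returns the data frame.
#' @export
write_roi_csv <- function(tab, file) {
  utils::write.csv(format(tab, digits = 17, scientific = FALSE, trim = TRUE),
                   file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' @rdname write_roi_csv
#' @export
read_roi_csv <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Validate a pipeline configuration
#'
#' Checks a configuration list (typically from a YAML file) before any stage
#' runs; an invalid configuration fails fast naming the offending key. See
#' `default_pipeline_config()` for the full key set.
#'
#' @param config Named list.
#' @return The validated config (with defaults filled in), invisibly usable.
#' @export
validate_pipeline_config <- function(config) {
  def <- default_pipeline_config()
  for (k in names(def)) if (is.null(config[[k]])) config[[k]] <- def[[k]]
  fail <- function(key, why) {
    stop(errorCondition(sprintf("invalid config key '%s': %s", key, why),
                        class = c("flimredox_config_error", "error", "condition")))
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1) fail("seed", "must be one integer")
  if (!is.numeric(config$scene_size) || config$scene_size < 16) fail("scene_size", "must be >= 16")
  if (!is.numeric(config$n_cells) || config$n_cells < 1) fail("n_cells", "must be >= 1")
  th <- config$thresholds
  for (m in c("mito", "whole_cell")) {
    v <- th[[m]]
    if (is.null(v) || length(v) != 2 || !(v[[1]] >= 0 && v[[1]] < v[[2]])) {
      fail(paste0("thresholds$", m), "must be [lower, upper] with 0 <= lower < upper")
    }
  }
  if (th$mito[[1]] < th$whole_cell[[1]]) {
    fail("thresholds$mito", "mito lower threshold below whole-cell lower threshold")
  }
  cs <- config$categories
  if (!all(c("labels", "lower", "upper") %in% names(cs))) {
    fail("categories", "needs labels, lower, upper")
  }
  rr <- unlist(config$render_range)
  if (!is.numeric(rr) || length(rr) != 2 || rr[[1]] >= rr[[2]]) {
    fail("render_range", "must be [low, high] with low < high")
  }
  if (!is.numeric(config$fit_binning) || config$fit_binning < 0) {
    fail("fit_binning", "must be a non-negative integer")
  }
  if (!is.numeric(config$tau_d) || config$tau_d <= 0) {
    fail("tau_d", "must be a positive lifetime in ns")
  }
  config
}

#' Default pipeline configuration
#'
#' @return Named list accepted by [validate_pipeline_config()]; write it to
#'   YAML with `yaml::write_yaml()` to seed a config file.
#' @export
default_pipeline_config <- function() {
  list(seed = 1L, scene_size = 96L, n_cells = 4L,
       thresholds = list(whole_cell = c(30, 5000), mito = c(400, 5000)),
       fit_binning = 1L,
       min_photons = 300, min_rois = 5,
       treatment = list(d_nadh_mito = 0.12, d_nadh_cyt = 0.10,
                        d_fad_mito = -0.12, d_trp = 0.12, spread = 0.35),
       categories = list(labels = c("Category1", "Category2", "Category3"),
                         lower = c(25, 55, 85), upper = c(55, 85, 125)),
       tau_d = 3.1, margin = 5,
       render_range = c(0, 1.2), colormap = "viridis")
}

#' Read and validate a YAML pipeline configuration
#'
#' @param file YAML path.
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(file) {
  if (!file.exists(file)) {
    stop(errorCondition(paste0("config file not found: ", file),
                        class = c("flimredox_missing_input", "error", "condition")))
  }
  validate_pipeline_config(yaml::read_yaml(file))
}

#' Render a FLIRR map as a color-coded PNG
#'
#' Maps values through a perceptually uniform colormap over a fixed value
#' range, so control and treatment panels rendered with the same range are
#' visually comparable. Out-of-range values are clamped to the range
#' endpoints (count reported via message); invalid (`NA`) pixels take a
#' reserved dark-gray color.
#'
#' @param map Numeric matrix (e.g. from [flirr_pixel_map()]).
#' @param file Output PNG path (`NULL` to skip writing).
#' @param range Fixed value range mapped onto the colormap.
#' @param colormap Palette name for [grDevices::hcl.colors()].
#' @param n_colors Number of colormap levels.
#' @param invalid_color Color for `NA` pixels.
#' @return RGB array `(rows, cols, 3)`, invisibly.
#' @export
render_flirr_map <- function(map, file = NULL, range = c(0, 1.2),
                             colormap = "viridis", n_colors = 256L,
                             invalid_color = grDevices::grey(0.15)) {
  stopifnot(is.matrix(map))
  if (length(map) == 0) stop("render_flirr_map: empty map")
  pal <- grDevices::hcl.colors(n_colors, colormap)
  clamped <- sum(map < range[1] | map > range[2], na.rm = TRUE)
  if (clamped > 0) {
    message(sprintf("render_flirr_map: clamped %d value(s) to [%g, %g]",
                    clamped, range[1], range[2]))
  }
  v <- pmin(pmax(map, range[1]), range[2])
  idx <- 1L + as.integer(round((v - range[1]) / diff(range) * (n_colors - 1L)))
  idx[is.na(idx)] <- 1L  # placeholder; overwritten by the reserved color below
  rgbm <- grDevices::col2rgb(pal)[, idx, drop = FALSE] / 255
  bad <- is.na(map)
  inv <- grDevices::col2rgb(invalid_color)[, 1] / 255
  out <- array(0, dim = c(nrow(map), ncol(map), 3L))
  for (k in 1:3) {
    plane <- matrix(rgbm[k, ], nrow(map), ncol(map))
    plane[bad] <- inv[k]
    out[, , k] <- plane
  }
  if (!is.null(file)) png::writePNG(out, file)
  invisible(out)
}
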