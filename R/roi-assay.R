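# 2x2-pixel thresholded ROI assay: grid generation inside segmented cells
# (nucleus excluded), mitochondrial vs whole-cell threshold presets, and
# per-ROI aggregation of decay-fit parameters.

#' ROI grid configuration
#'
#' Controls the 2x2-pixel ROI selection: photon-count thresholds applied to
#' the mean NAD(P)H count of the four member pixels, the morphology preset
#' the thresholds encode (`"mito"` captures the brighter, more concentrated
#' mitochondrial NAD(P)H signal; `"whole_cell"` the complete cell area minus
#' the nucleus), and how fit parameters are aggregated per ROI.
#'
#' @param lower_threshold,upper_threshold Photon-count window (closed
#'   interval) for the mean count of the 4 pixels; `0 <= lower < upper`.
#' @param morphology `"whole_cell"` or `"mito"`.
#' @param aggregation `"pixel_mean"` (photon-weighted mean of per-pixel fit
#'   parameters) or `"pooled_refit"` (sum the 4 pixel histograms, fit once).
#' @return Object of class `roi_config`.
#' @export
roi_config <- function(lower_threshold = 30, upper_threshold = 5000,
                       morphology = c("whole_cell", "mito"),
                       aggregation = c("pixel_mean", "pooled_refit")) {
  morphology <- match.arg(morphology)
  aggregation <- match.arg(aggregation)
  if (!(lower_threshold >= 0 && lower_threshold < upper_threshold)) {
    stop("roi_config: need 0 <= lower_threshold < upper_threshold")
  }
  structure(list(roi_size = 2L, lower_threshold = lower_threshold,
                 upper_threshold = upper_threshold, morphology = morphology,
                 aggregation = aggregation),
            class = "roi_config")
}

#' Segmentation masks for one field of view
#'
#' @param cell_labels Integer matrix of per-pixel cell ids (0 = background).
#' @param nucleus Logical matrix flagging nuclear pixels. Nuclear pixels must
#'   lie inside labeled cells or background.
#' @return Object of class `segmentation_masks`.
#' @export
segmentation_masks <- function(cell_labels, nucleus = NULL) {
  stopifnot(is.matrix(cell_labels))
  if (any(cell_labels < 0) || any(cell_labels != round(cell_labels))) {
    stop("segmentation_masks: cell labels must be non-negative integers")
  }
  if (is.null(nucleus)) nucleus <- matrix(FALSE, nrow(cell_labels), ncol(cell_labels))
  stopifnot(is.matrix(nucleus), identical(dim(nucleus), dim(cell_labels)))
  nucleus <- nucleus & TRUE  # coerce to logical
  structure(list(cell_labels = cell_labels, nucleus = nucleus),
            class = "segmentation_masks")
}

# Split a matrix into its four 2x2-block corner submatrices. Trailing odd
# row/column is ignored (documented behavior of the grid).
block_corners <- function(m) {
  h2 <- nrow(m) %/% 2L
  w2 <- ncol(m) %/% 2L
  ri <- seq_len(h2) * 2L
  ci <- seq_len(w2) * 2L
  list(tl = m[ri - 1L, ci - 1L, drop = FALSE], tr = m[ri - 1L, ci, drop = FALSE],
       bl = m[ri, ci - 1L, drop = FALSE],      br = m[ri, ci, drop = FALSE],
       h2 = h2, w2 = w2)
}

#' Generate the 2x2-pixel thresholded ROI grid
#'
#' Tiles the image with non-overlapping 2x2 blocks anchored at pixel (0,0).
#' A block becomes an ROI iff all four pixels carry the same nonzero cell
#' label, none is nuclear, and the mean NAD(P)H photon count of the four
#' pixels lies in the closed threshold window. Blocks straddling two cells or
#' cell/background are dropped entirely so every ROI is attributable to
#' exactly one cell. Nuclear exclusion is applied before thresholding.
#'
#' @param nadh_photons Matrix of NAD(P)H photon counts per pixel.
#' @param masks A [segmentation_masks()] of identical dimensions.
#' @param config A [roi_config()].
#' @return Data frame with columns `cell_id`, `grid_row`, `grid_col` (0-based
#'   grid coordinates; pixel block = rows `[2*grid_row, 2*grid_row+2)`, cols
#'   `[2*grid_col, 2*grid_col+2)`), `photons_nadh` (sum over the 4 pixels),
#'   `mean_nadh`, `morphology`; sorted by (cell_id, grid_row, grid_col).
#' @export
generate_roi_grid <- function(nadh_photons, masks, config) {
  stopifnot(is.matrix(nadh_photons), inherits(masks, "segmentation_masks"),
            inherits(config, "roi_config"))
  if (!identical(dim(nadh_photons), dim(masks$cell_labels))) {
    stop("generate_roi_grid: image and mask dimensions differ")
  }
  if (all(masks$cell_labels == 0)) {
    warning("generate_roi_grid: empty label mask; no ROIs generated")
  }
  lb <- block_corners(masks$cell_labels)
  nb <- block_corners(masks$nucleus)
  pb <- block_corners(nadh_photons)
  same_cell <- lb$tl > 0 & lb$tl == lb$tr & lb$tl == lb$bl & lb$tl == lb$br
  no_nuc <- !(nb$tl | nb$tr | nb$bl | nb$br)
  psum <- pb$tl + pb$tr + pb$bl + pb$br
  pmean <- psum / 4
  keep <- same_cell & no_nuc &
    pmean >= config$lower_threshold & pmean <= config$upper_threshold
  idx <- which(keep)
  gr <- (idx - 1L) %% lb$h2          # 0-based grid row
  gc <- (idx - 1L) %/% lb$h2         # 0-based grid col
  out <- data.frame(cell_id = as.integer(lb$tl[idx]),
                    grid_row = as.integer(gr), grid_col = as.integer(gc),
                    photons_nadh = psum[idx], mean_nadh = pmean[idx],
                    morphology = rep(config$morphology, length(idx)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cell_id, out$grid_row, out$grid_col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mitochondrial and whole-cell ROI sets from one grid
#'
#' Applies two threshold presets to the same 2x2 grid. The mitochondrial
#' preset must not have a lower threshold below the whole-cell preset; when
#' the upper thresholds are equal the mitochondrial set is a subset of the
#' whole-cell set.
#'
#' @inheritParams generate_roi_grid
#' @param mito_config,wholecell_config [roi_config()] objects.
#' @return List with elements `mito` and `whole_cell`.
#' @export
dual_morphology_rois <- function(nadh_photons, masks, mito_config,
                                 wholecell_config) {
  if (mito_config$lower_threshold < wholecell_config$lower_threshold) {
    stop(errorCondition(
      "dual_morphology_rois: mito lower threshold below whole-cell lower threshold",
      class = c("flimredox_config_error", "error", "condition")))
  }
  list(mito = generate_roi_grid(nadh_photons, masks, mito_config),
       whole_cell = generate_roi_grid(nadh_photons, masks, wholecell_config))
}

# Linear pixel indices (column-major) of the 4 member pixels of each ROI row.
roi_pixel_indices <- function(rois, dim_img) {
  h <- dim_img[1]
  r0 <- rois$grid_row * 2L + 1L
  c0 <- rois$grid_col * 2L + 1L
  cbind((c0 - 1L) * h + r0,       (c0 - 1L) * h + r0 + 1L,
        c0 * h + r0,              c0 * h + r0 + 1L)
}

#' Attach per-channel ROI photon sums
#'
#' FAD and tryptophan inherit the NAD(P)H-defined ROI footprint; this sums
#' each channel's photon image over the 4 member pixels of every ROI.
#'
#' @param rois ROI table from [generate_roi_grid()].
#' @param images Named list of photon matrices (e.g. `nadh`, `fad`, `trp`).
#' @return The ROI table with one `photons_<channel>` column per image.
#' @export
roi_photon_sums <- function(rois, images) {
  stopifnot(is.list(images), !is.null(names(images)))
  if (nrow(rois) == 0) {
    for (ch in names(images)) rois[[paste0("photons_", ch)]] <- numeric(0)
    return(rois)
  }
  pix <- roi_pixel_indices(rois, dim(images[[1]]))
  for (ch in names(images)) {
    v <- images[[ch]][as.vector(pix)]
    rois[[paste0("photons_", ch)]] <- rowSums(matrix(v, nrow(rois), 4))
  }
  rois
}

#' Count flagged pixels per ROI
#'
#' Number of `TRUE` pixels of a logical mask among the four member pixels of
#' each ROI — e.g. how many ground-truth mitochondrial pixels each ROI
#' covers, to stratify ROIs by compartment purity.
#'
#' @param rois ROI table from [generate_roi_grid()].
#' @param mask Logical matrix.
#' @return Integer vector (0 to 4 per ROI).
#' @export
roi_mask_counts <- function(rois, mask) {
  if (nrow(rois) == 0) return(integer(0))
  pix <- roi_pixel_indices(rois, dim(mask))
  as.integer(rowSums(matrix(mask[as.vector(pix)], nrow(rois), 4)))
}

#' Aggregate decay-fit parameters over ROI member pixels
#'
#' Two modes. `pixel_mean`: each fit parameter is the photon-weighted mean of
#' the four per-pixel values from fitted parameter maps; the a1%/a2%
#' normalization (sum to 1) is preserved because both fractions share the
#' same weights, and `tau_m` is recomputed from the aggregated lifetimes and
#' fractions. `pooled_refit`: the four pixel histograms are summed and fitted
#' once (requires the TCSPC cube). ROIs containing an unfitted or
#' non-converged member pixel (or whose pooled fit fails) are flagged
#' `valid = FALSE` and should be excluded from downstream statistics.
#'
#' @param rois ROI table from [generate_roi_grid()].
#' @param maps Named list per channel of per-pixel parameter maps (each a
#'   named list of matrices `a1_pct`, `a2_pct`, `tau1`, `tau2`, `tau_m`,
#'   `chi2`, `photons`, `converged`), e.g. from [fit_cube()]. Used in
#'   `pixel_mean` mode.
#' @param cubes Named list per channel of TCSPC arrays `(rows, cols, bins)`.
#'   Used in `pooled_refit` mode.
#' @param mode `"pixel_mean"` or `"pooled_refit"`.
#' @param axis,irf,options Decay model objects for `pooled_refit`.
#' @return The ROI table with per-channel columns
#'   `<ch>_a1_pct`, `<ch>_a2_pct`, `<ch>_tau1`, `<ch>_tau2`, `<ch>_tau_m`,
#'   `<ch>_chi2` plus a logical `valid`.
#' @export
aggregate_roi_parameters <- function(rois, maps = NULL, cubes = NULL,
                                     mode = c("pixel_mean", "pooled_refit"),
                                     axis = NULL, irf = NULL,
                                     options = fit_options()) {
  mode <- match.arg(mode)
  pars <- c("a1_pct", "a2_pct", "tau1", "tau2", "tau_m", "chi2")
  if (nrow(rois) == 0) {
    chs <- names(if (mode == "pixel_mean") maps else cubes)
    for (ch in chs) for (p in pars) rois[[paste0(ch, "_", p)]] <- numeric(0)
    rois$valid <- logical(0)
    return(rois)
  }
  valid <- rep(TRUE, nrow(rois))
  if (mode == "pixel_mean") {
    stopifnot(!is.null(maps))
    pix <- roi_pixel_indices(rois, dim(maps[[1]]$a1_pct))
    for (ch in names(maps)) {
      m <- maps[[ch]]
      conv <- matrix(m$converged[as.vector(pix)], nrow(rois), 4)
      ok <- rowSums(!conv | is.na(conv)) == 0
      valid <- valid & ok
      w <- matrix(m$photons[as.vector(pix)], nrow(rois), 4)
      wsum <- rowSums(w)
      agg <- list()
      for (p in c("a1_pct", "a2_pct", "tau1", "tau2")) {
        v <- matrix(m[[p]][as.vector(pix)], nrow(rois), 4)
        agg[[p]] <- rowSums(w * v) / wsum
      }
      agg$tau_m <- agg$tau1 * agg$a1_pct + agg$tau2 * agg$a2_pct
      v <- matrix(m$chi2[as.vector(pix)], nrow(rois), 4)
      agg$chi2 <- rowSums(w * v) / wsum
      for (p in pars) rois[[paste0(ch, "_", p)]] <- agg[[p]]
    }
  } else {
    stopifnot(!is.null(cubes), !is.null(axis), !is.null(irf))
    dim_img <- dim(cubes[[1]])[1:2]
    pix <- roi_pixel_indices(rois, dim_img)
    npx <- prod(dim_img)
    for (ch in names(cubes)) {
      cube <- cubes[[ch]]
      cmat <- matrix(cube, npx, dim(cube)[3])  # pixels x bins
      pooled <- cmat[pix[, 1], , drop = FALSE] + cmat[pix[, 2], , drop = FALSE] +
                cmat[pix[, 3], , drop = FALSE] + cmat[pix[, 4], , drop = FALSE]
      ft <- fit_histograms(pooled, axis, irf, options, channel = ch)
      valid <- valid & ft$converged
      for (p in c("a1_pct", "a2_pct", "tau1", "tau2", "tau_m")) {
        rois[[paste0(ch, "_", p)]] <- ft[[p]]
      }
      rois[[paste0(ch, "_chi2")]] <- ft$chi2
    }
  }
  rois$valid <- valid
  rois
}
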