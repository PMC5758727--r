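# End-to-end assay driver: per-pixel or per-ROI fitting of a field of view,
# redox records per morphology, and paired control/treatment analysis.

#' Fit every pixel of a TCSPC cube
#'
#' Fits the two-component model to each pixel histogram with enough photons.
#' Pixel fits are independent, so the result is identical regardless of
#' execution order. Pixels below the photon minimum (or outside `mask`) are
#' left `NA` with `converged = FALSE`.
#'
#' @param cube TCSPC array `(rows, cols, bins)`.
#' @param axis,irf [time_axis()] and [irf_model()].
#' @param options [fit_options()].
#' @param mask Optional logical matrix restricting which pixels are fitted.
#' @param binning Optional half-width of a square binning kernel: each pixel's
#'   histogram is summed over the `(2*binning+1)^2` neighborhood before
#'   fitting (mirrors spatial binning in TCSPC fitting software; default 0 =
#'   off).
#' @param channel Channel tag.
#' @return Named list of parameter-map matrices: `a1`, `a2`, `a1_pct`,
#'   `a2_pct`, `tau1`, `tau2`, `tau_m`, `chi2`, `photons`, `converged`.
#' @export
fit_cube <- function(cube, axis, irf, options = fit_options(), mask = NULL,
                     binning = 0L, channel = "nadh") {
  d <- dim(cube)
  stopifnot(length(d) == 3L, d[3] == axis$n_bins)
  npx <- d[1] * d[2]
  cmat <- matrix(cube, npx, d[3])
  if (binning > 0) {
    idx <- matrix(seq_len(npx), d[1], d[2])
    acc <- matrix(0, npx, d[3])
    for (dr in -binning:binning) for (dc in -binning:binning) {
      rs <- pmin(pmax(row(idx) + dr, 1L), d[1])
      cs <- pmin(pmax(col(idx) + dc, 1L), d[2])
      acc <- acc + cmat[cbind(as.vector((cs - 1L) * d[1] + rs)), , drop = FALSE]
    }
    cmat <- acc
  }
  do_fit <- if (is.null(mask)) rep(TRUE, npx) else as.vector(mask)
  fits <- data.frame(a1 = rep(NA_real_, npx), a2 = NA_real_, a1_pct = NA_real_,
                     a2_pct = NA_real_, tau1 = NA_real_, tau2 = NA_real_,
                     tau_m = NA_real_, chi2 = NA_real_,
                     photons = rowSums(cmat), converged = FALSE)
  sel <- which(do_fit & fits$photons >= options$min_photons)
  if (length(sel)) {
    ft <- fit_histograms(cmat[sel, , drop = FALSE], axis, irf, options, channel)
    for (p in c("a1", "a2", "a1_pct", "a2_pct", "tau1", "tau2", "tau_m", "chi2",
                "converged")) {
      fits[[p]][sel] <- ft[[p]]
    }
  }
  lapply(fits, function(v) matrix(v, d[1], d[2]))
}

#' Default morphology threshold presets
#'
#' Whole-cell ROIs accept mean NAD(P)H counts in \[30, 5000\]; mitochondrial
#' ROIs require the brighter \[400, 5000\] window. The mitochondrial lower
#' threshold is placed between the 2- and 3-mitochondrial-pixel block means
#' of the default synthetic brightness scale (cytosol 100, mitochondria 600
#' photons/pixel), so selected blocks are at least three-quarters
#' mitochondrial — thresholds must isolate mitochondrial morphology, not
#' merely exceed the cytosolic level. Values are in the synthetic
#' photon-count units of [scene_spec()] and are configuration, not
#' constants; re-derive them for other brightness scales.
#'
#' @param aggregation ROI aggregation mode for both presets.
#' @return List with [roi_config()] elements `mito` and `whole_cell`.
#' @export
default_roi_presets <- function(aggregation = "pooled_refit") {
  list(mito = roi_config(400, 5000, morphology = "mito",
                         aggregation = aggregation),
       whole_cell = roi_config(30, 5000, morphology = "whole_cell",
                               aggregation = aggregation))
}

#' Run the ROI redox assay on one field of view
#'
#' Generates the dual-morphology 2x2 ROI grids from the NAD(P)H photon
#' image, attaches per-channel photon sums, aggregates decay parameters per
#' ROI (pooled refit of summed histograms by default, or photon-weighted
#' pixel means of supplied/true parameter maps), and computes the redox
#' records.
#'
#' @param scene A `flim_scene` (needs cubes for `pooled_refit`).
#' @param presets Morphology presets, see [default_roi_presets()].
#' @param options [fit_options()] for refitting.
#' @param maps Optional named list of per-channel parameter maps for
#'   `pixel_mean` aggregation; defaults to the scene's ground-truth maps
#'   (useful for noise-free pipeline checks).
#' @param fov_id Field-of-view identifier recorded on every record.
#' @param ref [donor_reference()] for E%.
#' @return Data frame of per-ROI redox records for both morphologies, with
#'   `fov_id`, `condition`, `morphology` columns.
#' @export
fov_assay <- function(scene, presets = default_roi_presets(),
                      options = fit_options(), maps = NULL, fov_id = 1L,
                      ref = donor_reference()) {
  stopifnot(inherits(scene, "flim_scene"))
  if (all(c("mito", "whole_cell") %in% names(presets))) {
    rois <- dual_morphology_rois(scene$photons$nadh, scene$masks,
                                 presets$mito, presets$whole_cell)
  } else {
    # single-morphology run (e.g. mitochondrial basis only)
    rois <- lapply(presets, function(cfg)
      generate_roi_grid(scene$photons$nadh, scene$masks, cfg))
  }
  out <- lapply(names(rois), function(m) {
    r <- roi_photon_sums(rois[[m]], scene$photons)
    mode <- presets[[if (m == "mito") "mito" else "whole_cell"]]$aggregation
    if (mode == "pooled_refit") {
      if (is.null(scene$cubes)) {
        stop("fov_assay: pooled_refit aggregation requires a scene with cubes")
      }
      r <- aggregate_roi_parameters(r, cubes = scene$cubes,
                                    mode = "pooled_refit", axis = scene$axis,
                                    irf = scene$irf, options = options)
    } else {
      r <- aggregate_roi_parameters(r, maps = if (is.null(maps)) scene$truth else maps,
                                    mode = "pixel_mean")
    }
    r <- redox_records(r, ref)
    if (nrow(r)) {
      r$fov_id <- fov_id
      r$condition <- scene$condition
    } else {
      r$fov_id <- integer(0); r$condition <- character(0)
    }
    r
  })
  do.call(rbind, out)
}

#' Paired control/treatment responder analysis
#'
#' Runs the assay on a control scene and its treated counterpart (identical
#' field of view), summarizes per cell, categorizes responders from the
#' mitochondrial percent median FLIRR change, and attributes whole-cell
#' excess response to glycolysis.
#'
#' @param control,treated `flim_scene` objects sharing geometry (see
#'   [apply_treatment()]).
#' @param presets,options,maps,fov_id,ref Passed to [fov_assay()].
#' @param scheme [category_scheme()] for responder assignment.
#' @param min_rois Minimum valid ROIs per cell.
#' @param margin Glycolysis-attribution margin in percentage points.
#' @return List: `records` (all ROI records), `summaries` (per-cell medians),
#'   `assignments` (mito-based responder categories), `attribution`
#'   (per-cell whole-cell vs mito increment and call).
#' @export
paired_fov_assay <- function(control, treated, presets = default_roi_presets(),
                             options = fit_options(), maps = NULL,
                             fov_id = 1L, ref = donor_reference(),
                             scheme = category_scheme(), min_rois = 5,
                             margin = 5) {
  rec <- rbind(fov_assay(control, presets, options, maps, fov_id, ref),
               fov_assay(treated, presets, options, maps, fov_id, ref))
  summ <- cell_summaries(rec, min_rois = min_rois)
  assign_mito <- responder_assignments(summ, control$condition,
                                       treated$condition, scheme,
                                       basis = "mito")
  assign_wc <- responder_assignments(summ, control$condition,
                                     treated$condition, scheme,
                                     basis = "whole_cell")
  m <- merge(assign_mito[, c("fov_id", "cell_id", "change_pct")],
             assign_wc[, c("fov_id", "cell_id", "change_pct")],
             by = c("fov_id", "cell_id"), suffixes = c("_mito", "_wc"))
  attribution <- cbind(m, glycolysis_attribution(m$change_pct_mito,
                                                 m$change_pct_wc, margin))
  list(records = rec, summaries = summ, assignments = assign_mito,
       attribution = attribution)
}
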