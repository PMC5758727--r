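# Metabolic readouts per ROI: the fluorescence lifetime redox ratio (FLIRR),
# the classical intensity-based redox ratio, and tryptophan FRET efficiency
# from donor lifetime quenching.

#' Unquenched donor lifetime reference
#'
#' The FRET efficiency calculation compares the measured amplitude-weighted
#' tryptophan lifetime against the unquenched single-donor lifetime; the
#' default 3.1 ns is the published lifetime of tryptophan in solution.
#'
#' @param tau_d Donor-only lifetime in ns (> 0).
#' @return Object of class `donor_reference`.
#' @export
donor_reference <- function(tau_d = 3.1) {
  stopifnot(is.numeric(tau_d), length(tau_d) == 1L, tau_d > 0)
  structure(list(tau_d = tau_d), class = "donor_reference")
}

#' Fluorescence lifetime redox ratio (FLIRR)
#'
#' `FLIRR = NAD(P)H-a2% / FAD-a1%`: the enzyme-bound fraction of NAD(P)H
#' (long-lifetime component) over the enzyme-bound fraction of FAD
#' (short-lifetime component). Rising oxidative phosphorylation increases
#' the numerator and decreases the denominator, so FLIRR increases with
#' metabolic activity. Being built from intensity-normalized fractions it is
#' insensitive to channel-wise photon attenuation, unlike the intensity
#' ratio.
#'
#' @param nadh_a2_pct NAD(P)H bound fraction, in \[0, 1\] (vectorized).
#' @param fad_a1_pct FAD bound fraction, in \[0, 1\].
#' @return Dimensionless ratio; `NA` where the denominator is 0 (the metric
#'   is marked invalid, never infinity).
#' @export
#' @examples
#' flirr(0.3, 0.6)  # 0.5
flirr <- function(nadh_a2_pct, fad_a1_pct) {
  bad <- !is.na(nadh_a2_pct) & (nadh_a2_pct < 0 | nadh_a2_pct > 1)
  bad2 <- !is.na(fad_a1_pct) & (fad_a1_pct < 0 | fad_a1_pct > 1)
  if (any(bad) || any(bad2)) stop("flirr: fractions must lie in [0, 1]")
  out <- nadh_a2_pct / fad_a1_pct
  out[!is.na(fad_a1_pct) & fad_a1_pct == 0] <- NA_real_
  out
}

#' Intensity-based redox ratio
#'
#' The classical FAD/NAD(P)H photon-count ratio on the same ROI footprint.
#' Raw photon sums are used without further normalization. Unlike FLIRR this
#' readout shifts under channel-asymmetric attenuation (depth-dependent
#' scattering, photobleaching, illumination changes).
#'
#' @param fad_photons,nadh_photons Photon counts (vectorized).
#' @return Ratio; `NA` where the NAD(P)H count is 0.
#' @export
intensity_redox_ratio <- function(fad_photons, nadh_photons) {
  if (any(fad_photons < 0, na.rm = TRUE) || any(nadh_photons < 0, na.rm = TRUE)) {
    stop("intensity_redox_ratio: photon counts must be >= 0")
  }
  out <- fad_photons / nadh_photons
  out[!is.na(nadh_photons) & nadh_photons == 0] <- NA_real_
  out
}

#' FRET efficiency from donor lifetime quenching
#'
#' `E% = (1 - tau_m / tau_D) * 100`, where `tau_m` is the amplitude-weighted
#' tryptophan lifetime (the quenched-donor lifetime) and `tau_D` the
#' unquenched donor reference. Negative values (`tau_m > tau_D`) are returned
#' as computed, not clipped, so miscalibration stays visible; flag them with
#' the `valid` logic of [redox_records()].
#'
#' @param trp_tau_m Amplitude-weighted tryptophan lifetime, ns (> 0,
#'   vectorized).
#' @param ref A [donor_reference()].
#' @return Efficiency in percent (<= 100).
#' @export
#' @examples
#' fret_efficiency(1.55)  # 50
fret_efficiency <- function(trp_tau_m, ref = donor_reference()) {
  stopifnot(inherits(ref, "donor_reference"))
  if (any(trp_tau_m <= 0, na.rm = TRUE)) {
    stop("fret_efficiency: tau_m must be positive")
  }
  (1 - trp_tau_m / ref$tau_d) * 100
}

#' Per-ROI redox record table
#'
#' Combines aggregated ROI fit parameters and photon sums into the three
#' metabolic readouts with per-metric validity flags. A metric is invalid
#' when its inputs are missing (unfitted/non-converged ROI), its denominator
#' is zero, or — for E% — the measured lifetime exceeds the donor reference.
#'
#' @param rois ROI table from [aggregate_roi_parameters()] (and
#'   [roi_photon_sums()] for the intensity ratio).
#' @param ref A [donor_reference()].
#' @return The ROI table with columns `flirr`, `intensity_ratio`,
#'   `trp_tau_m`, `trp_e_pct` and logical `flirr_valid`, `intensity_valid`,
#'   `trp_valid`.
#' @export
redox_records <- function(rois, ref = donor_reference()) {
  n <- nrow(rois)
  na <- rep(NA_real_, n)
  nadh_a2 <- if ("nadh_a2_pct" %in% names(rois)) rois$nadh_a2_pct else na
  fad_a1 <- if ("fad_a1_pct" %in% names(rois)) rois$fad_a1_pct else na
  rois$flirr <- flirr(pmin(pmax(nadh_a2, 0), 1), pmin(pmax(fad_a1, 0), 1))
  rois$flirr_valid <- !is.na(rois$flirr) &
    (if ("valid" %in% names(rois)) rois$valid else TRUE)
  if (all(c("photons_fad", "photons_nadh") %in% names(rois))) {
    rois$intensity_ratio <- intensity_redox_ratio(rois$photons_fad, rois$photons_nadh)
  } else rois$intensity_ratio <- na
  rois$intensity_valid <- !is.na(rois$intensity_ratio)
  tm <- if ("trp_tau_m" %in% names(rois)) rois$trp_tau_m else na
  rois$trp_tau_m <- tm
  e <- rep(NA_real_, n)
  ok <- !is.na(tm) & tm > 0
  e[ok] <- fret_efficiency(tm[ok], ref)
  rois$trp_e_pct <- e
  rois$trp_valid <- ok & e >= 0 &
    (if ("valid" %in% names(rois)) rois$valid else TRUE)
  rois
}

#' Per-pixel FLIRR map
#'
#' Divides the NAD(P)H a2% map by the FAD a1% map pixel-wise, for rendering
#' color-coded redox images. Pixels where either fraction is missing or the
#' denominator is zero are `NA`.
#'
#' @param nadh_maps,fad_maps Per-channel parameter-map lists (with `a2_pct`
#'   resp. `a1_pct` matrices), e.g. from [fit_cube()] or a scene's truth.
#' @return Matrix of FLIRR values.
#' @export
flirr_pixel_map <- function(nadh_maps, fad_maps) {
  num <- nadh_maps$a2_pct
  den <- fad_maps$a1_pct
  stopifnot(identical(dim(num), dim(den)))
  out <- num / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}
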