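# Shared fixtures: small axes/IRFs, brute-force oracles, and compact scenes.

ax256 <- time_axis(256)
gauss_irf <- irf_model()
delta_irf <- function(axis) {
  irf_model("measured", curve = c(1, rep(0, axis$n_bins - 1)))
}

# Independent oracle for the periodic decay model: explicit summation of the
# mono-exponential tails of the preceding n_periods excitation pulses,
# followed by a direct O(n^2) circular convolution with the sampled IRF.
brute_force_model <- function(params, irf, axis, n_periods = 200) {
  t <- axis$t
  s <- numeric(axis$n_bins)
  for (m in 0:n_periods) {
    s <- s + params$a1 * exp(-(t + m * axis$period) / params$tau1) +
         params$a2 * exp(-(t + m * axis$period) / params$tau2)
  }
  ic <- irf_curve(irf, axis)
  n <- axis$n_bins
  out <- numeric(n)
  for (k in seq_len(n)) {
    for (l in seq_len(n)) {
      out[k] <- out[k] + ic[l] * s[((k - l) %% n) + 1]
    }
  }
  out + params$background
}

# Brute-force ROI enumeration: scan every 2x2 block and re-check the three
# membership predicates directly.
brute_force_rois <- function(nadh, masks, config) {
  h2 <- nrow(nadh) %/% 2L; w2 <- ncol(nadh) %/% 2L
  rows <- list()
  for (gr in 0:(h2 - 1)) for (gc in 0:(w2 - 1)) {
    rr <- (2 * gr + 1):(2 * gr + 2); cc <- (2 * gc + 1):(2 * gc + 2)
    labs <- masks$cell_labels[rr, cc]
    if (any(labs == 0) || length(unique(as.vector(labs))) != 1) next
    if (any(masks$nucleus[rr, cc])) next
    mn <- mean(nadh[rr, cc])
    if (mn < config$lower_threshold || mn > config$upper_threshold) next
    rows[[length(rows) + 1]] <- data.frame(
      cell_id = labs[1], grid_row = gr, grid_col = gc,
      photons_nadh = sum(nadh[rr, cc]), mean_nadh = mn,
      morphology = config$morphology, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(), grid_row = integer(), grid_col = integer(),
               photons_nadh = numeric(), mean_nadh = numeric(),
               morphology = character(), stringsAsFactors = FALSE)
  out <- out[order(out$cell_id, out$grid_row, out$grid_col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random structured label/nucleus/photon field for ROI oracle checks: blocky
# labels so that some 2x2 blocks are single-cell and others straddle.
random_roi_scene <- function(size = 64, seed = 1) {
  set.seed(seed)
  blocks <- matrix(sample(0:3, (size / 4)^2, replace = TRUE), size / 4)
  labels <- blocks[rep(seq_len(size / 4), each = 4), rep(seq_len(size / 4), each = 4)]
  # jitter boundaries so blocks are not perfectly aligned with the ROI grid
  labels <- labels[c(2:size, 1), ]
  nucleus <- matrix(stats::runif(size^2) < 0.08, size) & labels > 0
  photons <- matrix(stats::rpois(size^2, 60 + 40 * (labels > 0)), size)
  list(photons = photons, masks = segmentation_masks(labels, nucleus))
}

# Two-channel compact scene spec (no tryptophan) for faster fitting tests.
two_channel_spec <- function(size = 96, n_cells = 4, seed = 1, ...) {
  scene_spec(size = size, n_cells = n_cells, seed = seed,
             decay = list(
               nadh = list(tau1 = 0.4, tau2 = 2.5, bound = "long",
                           bound_frac = c(nucleus = 0.20, cytosol = 0.20, mito = 0.32)),
               fad  = list(tau1 = 0.3, tau2 = 2.3, bound = "short",
                           bound_frac = c(nucleus = 0.60, cytosol = 0.60, mito = 0.72))),
             ...)
}
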