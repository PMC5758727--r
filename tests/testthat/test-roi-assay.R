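# 2x2 thresholded ROI grid: membership predicates, brute-force equivalence,
# monotonicity/subset properties, and per-ROI parameter aggregation.

test_that("uniform single-cell image tiles fully; nucleus halves the grid", {
  img <- matrix(100, 8, 8)
  masks <- segmentation_masks(matrix(1L, 8, 8))
  cfg <- roi_config(50, 200)
  rois <- generate_roi_grid(img, masks, cfg)
  expect_equal(nrow(rois), 16)
  expect_equal(rois$photons_nadh, rep(400, 16))

  nuc <- matrix(FALSE, 8, 8); nuc[1:4, ] <- TRUE  # nucleus covers rows 0-3
  rois2 <- generate_roi_grid(img, segmentation_masks(matrix(1L, 8, 8), nuc), cfg)
  expect_equal(nrow(rois2), 8)
  expect_true(all(rois2$grid_row >= 2))
})

test_that("grid equals exhaustive brute-force block enumeration on random scenes", {
  for (seed in 1:3) {
    sc <- random_roi_scene(64, seed)
    cfg <- roi_config(30, 400)
    fast <- generate_roi_grid(sc$photons, sc$masks, cfg)
    slow <- brute_force_rois(sc$photons, sc$masks, cfg)
    expect_equal(fast, slow)
  }
})

test_that("every emitted ROI re-passes the three membership predicates", {
  sc <- random_roi_scene(64, 11)
  cfg <- roi_config(30, 400)
  rois <- generate_roi_grid(sc$photons, sc$masks, cfg)
  expect_lte(nrow(rois), 32 * 32)
  for (i in seq_len(nrow(rois))) {
    rr <- (2 * rois$grid_row[i] + 1):(2 * rois$grid_row[i] + 2)
    cc <- (2 * rois$grid_col[i] + 1):(2 * rois$grid_col[i] + 2)
    labs <- sc$masks$cell_labels[rr, cc]
    expect_true(all(labs == rois$cell_id[i]) && rois$cell_id[i] > 0)
    expect_false(any(sc$masks$nucleus[rr, cc]))
    mn <- mean(sc$photons[rr, cc])
    expect_true(mn >= 30 && mn <= 400)
  }
  # partition: no pixel in two ROIs
  pix <- flimredox:::roi_pixel_indices(rois, dim(sc$photons))
  expect_false(anyDuplicated(as.vector(pix)) > 0)
})

test_that("raising the lower threshold shrinks the ROI set monotonically", {
  sc <- random_roi_scene(64, 4)
  prev <- NULL
  for (lo in c(10, 40, 80, 120)) {
    cur <- generate_roi_grid(sc$photons, sc$masks, roi_config(lo, 500))
    key <- paste(cur$cell_id, cur$grid_row, cur$grid_col)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- paste(cur$cell_id, cur$grid_row, cur$grid_col)
  }
})

test_that("mito set is a subset of the whole-cell set when upper thresholds agree", {
  sc <- random_roi_scene(64, 8)
  both <- dual_morphology_rois(sc$photons, sc$masks,
                               roi_config(90, 500, morphology = "mito"),
                               roi_config(30, 500))
  km <- paste(both$mito$grid_row, both$mito$grid_col)
  kw <- paste(both$whole_cell$grid_row, both$whole_cell$grid_col)
  expect_true(all(km %in% kw))
  # equal configs give identical sets up to the morphology tag
  same <- dual_morphology_rois(sc$photons, sc$masks,
                               roi_config(30, 500, morphology = "mito"),
                               roi_config(30, 500))
  expect_equal(same$mito[setdiff(names(same$mito), "morphology")],
               same$whole_cell[setdiff(names(same$whole_cell), "morphology")])
  # violated threshold ordering is a configuration error
  expect_error(dual_morphology_rois(sc$photons, sc$masks,
                                    roi_config(10, 500, morphology = "mito"),
                                    roi_config(30, 500)),
               class = "flimredox_config_error")
  # everything below the lower thresholds -> two empty sets
  none <- dual_morphology_rois(matrix(1, 64, 64), sc$masks,
                               roi_config(1000, 5000, morphology = "mito"),
                               roi_config(900, 5000))
  expect_equal(nrow(none$mito), 0)
  expect_equal(nrow(none$whole_cell), 0)
})

test_that("empty label mask warns and returns an empty table", {
  expect_warning(
    rois <- generate_roi_grid(matrix(10, 8, 8),
                              segmentation_masks(matrix(0L, 8, 8)),
                              roi_config(0, 100)),
    "empty label mask")
  expect_equal(nrow(rois), 0)
  expect_error(generate_roi_grid(matrix(10, 8, 8),
                                 segmentation_masks(matrix(1L, 6, 6)),
                                 roi_config(0, 100)),
               "dimensions")
})

test_that("pixel-mean aggregation is the photon-weighted mean and preserves a1%+a2% = 1", {
  img <- matrix(100, 4, 4)
  masks <- segmentation_masks(matrix(1L, 4, 4))
  rois <- generate_roi_grid(img, masks, roi_config(0, 1000))
  mk <- function(v) matrix(v, 4, 4)
  maps <- list(nadh = list(
    a1_pct = mk(0.7), a2_pct = mk(0.3), tau1 = mk(0.4), tau2 = mk(2.5),
    tau_m = mk(0.4 * 0.7 + 2.5 * 0.3), chi2 = mk(1),
    photons = mk(100), converged = mk(TRUE)))
  # identical pixels: aggregates equal the pixel values
  agg <- aggregate_roi_parameters(rois, maps = maps, mode = "pixel_mean")
  expect_equal(agg$nadh_a2_pct, rep(0.3, 4))
  expect_equal(agg$nadh_tau_m, rep(0.4 * 0.7 + 2.5 * 0.3, 4))
  expect_true(all(agg$valid))
  # mixed pixels, equal photons: plain mean; fractions stay normalized
  a2 <- mk(0); a2[1:2, 1:2] <- c(0.2, 0.2, 0.4, 0.4)
  maps$nadh$a2_pct <- a2; maps$nadh$a1_pct <- 1 - a2
  agg2 <- aggregate_roi_parameters(rois, maps = maps, mode = "pixel_mean")
  expect_equal(agg2$nadh_a2_pct[agg2$grid_row == 0 & agg2$grid_col == 0], 0.3)
  expect_equal(agg2$nadh_a1_pct + agg2$nadh_a2_pct, rep(1, 4))
  # a non-converged member pixel invalidates its ROI
  conv <- mk(TRUE); conv[1, 1] <- FALSE
  maps$nadh$converged <- conv
  agg3 <- aggregate_roi_parameters(rois, maps = maps, mode = "pixel_mean")
  expect_false(agg3$valid[agg3$grid_row == 0 & agg3$grid_col == 0])
  expect_true(all(agg3$valid[-which(agg3$grid_row == 0 & agg3$grid_col == 0)]))
})

test_that("pooled refit equals a direct fit of the summed histograms", {
  ax <- ax256
  p <- biexp_params(60, 40, 0.4, 2.5)
  set.seed(21)
  cube <- array(0L, dim = c(2, 2, 256))
  for (r in 1:2) for (c in 1:2) {
    cube[r, c, ] <- simulate_decay(p, gauss_irf, ax, 800,
                                   seed = 100 + 2 * r + c)$counts
  }
  img <- matrix(rowSums(matrix(cube, 4, 256)), 2, 2)
  rois <- generate_roi_grid(img, segmentation_masks(matrix(1L, 2, 2)),
                            roi_config(0, 1e6))
  agg <- aggregate_roi_parameters(rois, cubes = list(nadh = cube),
                                  mode = "pooled_refit", axis = ax,
                                  irf = gauss_irf)
  pooled <- decay_histogram(cube[1, 1, ] + cube[2, 1, ] + cube[1, 2, ] + cube[2, 2, ],
                            ax)
  direct <- fit_biexp(pooled, gauss_irf)
  expect_equal(agg$nadh_a2_pct, direct$a2_pct, tolerance = 1e-10)
  expect_equal(agg$nadh_tau2, direct$params$tau2, tolerance = 1e-10)
})

test_that("pooled refit beats pixel-mean aggregation at low per-pixel counts", {
  ax <- ax256
  truth_a2 <- 0.35
  p <- biexp_params(100 * (1 - truth_a2), 100 * truth_a2, 0.4, 2.5)
  n_roi <- 60
  opt <- fit_options(min_photons = 200)
  est_pm <- est_pr <- numeric(n_roi)
  set.seed(77)
  for (i in seq_len(n_roi)) {
    counts <- t(sapply(1:4, function(j)
      simulate_decay(p, gauss_irf, ax, 500, seed = 1e4 + 4 * i + j)$counts))
    pix <- fit_histograms(counts, ax, gauss_irf, opt)
    w <- pix$photons
    est_pm[i] <- sum(w * pix$a2_pct) / sum(w)
    pooled <- decay_histogram(colSums(counts), ax)
    est_pr[i] <- fit_biexp(pooled, gauss_irf, opt)$a2_pct
  }
  rmse <- function(x) sqrt(mean((x - truth_a2)^2))
  expect_lt(rmse(est_pr), rmse(est_pm))
})
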