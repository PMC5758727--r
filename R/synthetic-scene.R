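# Synthetic three-channel FLIM fields of view with known ground truth:
# elliptical cells with concentric nuclei and granular mitochondria,
# channel-specific bi-exponential decay truths per compartment, Poisson
# photon statistics, and a treatment model with per-cell heterogeneity.
#
# Compartment conventions: FAD fluorescence is concentrated in mitochondria
# (weak residual elsewhere); NAD(P)H arises from mitochondria (OXPHOS) and
# cytosol (glycolysis); tryptophan is distributed cell-wide. The nucleus
# emits low but nonzero NAD(P)H so that mask-based exclusion, not intensity
# thresholding, must remove it.

# compartment codes used in the compartment map
COMP_BACKGROUND <- 0L
COMP_NUCLEUS <- 1L
COMP_CYTOSOL <- 2L
COMP_MITO <- 3L

#' Synthetic field-of-view specification
#'
#' Defines the geometry, per-compartment channel brightness (expected
#' photons/pixel), and per-compartment decay truths of a synthetic FLIM
#' scene. The decay truth per channel is (tau1, tau2, bound fraction), where
#' the bound fraction maps to a2% for NAD(P)H (the enzyme-bound form has the
#' long lifetime) and to a1% for FAD and tryptophan (bound/quenched forms
#' have the short lifetime).
#'
#' @param size Image side in pixels (square image).
#' @param n_cells Number of cells to place.
#' @param seed Integer seed controlling geometry and photon noise.
#' @param cell_radius_frac Mean cell semi-axis as a fraction of `size`.
#' @param nucleus_scale Nucleus semi-axes relative to the cell's.
#' @param mito_density Mitochondrial blob centers per cytosol pixel.
#' @param mito_radius Blob stamp radius in pixels.
#' @param brightness Named list per channel of per-compartment expected
#'   photons/pixel (`nucleus`, `cytosol`, `mito`).
#' @param background Named vector of expected background photons/pixel per
#'   channel (outside cells, and added everywhere).
#' @param decay Named list per channel: `tau1`, `tau2` (ns), `bound`
#'   (`"long"` or `"short"`: which component the bound fraction maps to) and
#'   `bound_frac` per compartment.
#' @param cell_jitter_sd Per-cell standard deviation of the bound fractions
#'   around their compartment base values (biological cell-to-cell
#'   variation).
#' @param axis,irf [time_axis()] and [irf_model()] used when TCSPC cubes are
#'   simulated.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(size = 256L, n_cells = 5L, seed = 1L,
                       cell_radius_frac = 0.11, nucleus_scale = 0.45,
                       mito_density = 0.02, mito_radius = 2.5,
                       brightness = list(
                         nadh = c(nucleus = 30, cytosol = 100, mito = 600),
                         fad  = c(nucleus = 15, cytosol = 80,  mito = 300),
                         trp  = c(nucleus = 250, cytosol = 250, mito = 250)),
                       background = c(nadh = 2, fad = 2, trp = 2),
                       decay = list(
                         nadh = list(tau1 = 0.4, tau2 = 2.5, bound = "long",
                                     bound_frac = c(nucleus = 0.20, cytosol = 0.20, mito = 0.32)),
                         fad  = list(tau1 = 0.3, tau2 = 2.3, bound = "short",
                                     bound_frac = c(nucleus = 0.60, cytosol = 0.60, mito = 0.72)),
                         trp  = list(tau1 = 1.0, tau2 = 3.1, bound = "short",
                                     bound_frac = c(nucleus = 0.35, cytosol = 0.35, mito = 0.35))),
                       cell_jitter_sd = 0.02,
                       axis = time_axis(), irf = irf_model()) {
  stopifnot(size >= 16, n_cells >= 1)
  for (ch in names(decay)) {
    bf <- decay[[ch]]$bound_frac
    if (any(bf < 0 | bf > 1)) stop("scene_spec: bound fractions must lie in [0, 1]")
    stopifnot(decay[[ch]]$bound %in% c("long", "short"))
  }
  structure(list(size = as.integer(size), n_cells = as.integer(n_cells),
                 seed = as.integer(seed), cell_radius_frac = cell_radius_frac,
                 nucleus_scale = nucleus_scale, mito_density = mito_density,
                 mito_radius = mito_radius, brightness = brightness,
                 background = background, decay = decay,
                 cell_jitter_sd = cell_jitter_sd, axis = axis, irf = irf),
            class = "scene_spec")
}

#' Per-cell treatment effect model
#'
#' Shifts the bound fractions of the decay truth, emulating a metabolic
#' intervention: NAD(P)H bound fraction rises in mitochondria (OXPHOS) and
#' cytosol (glycolysis), FAD bound fraction falls in mitochondria, and the
#' quenched tryptophan fraction rises in step with NAD(P)H binding (the
#' donor-quenching linkage). Each cell draws its own effect scale from
#' `Normal(1, spread)` (truncated at 0), which is the ground truth for
#' responder heterogeneity; alternatively `cell_scales` pins the scales
#' explicitly (e.g. three response strata).
#'
#' @param d_nadh_mito,d_nadh_cyt Shift of the NAD(P)H bound (a2%) fraction.
#' @param d_fad_mito Shift of the FAD bound (a1%) fraction (typically
#'   negative).
#' @param d_trp Shift of the quenched tryptophan (a1%) fraction.
#' @param spread Cell-to-cell standard deviation of the effect scale.
#' @param cell_scales Optional explicit per-cell scales (recycled).
#' @return Object of class `treatment_effect`.
#' @export
treatment_effect <- function(d_nadh_mito = 0.12, d_nadh_cyt = 0.10,
                             d_fad_mito = -0.12, d_trp = 0.12,
                             spread = 0.35, cell_scales = NULL) {
  structure(list(d_nadh_mito = d_nadh_mito, d_nadh_cyt = d_nadh_cyt,
                 d_fad_mito = d_fad_mito, d_trp = d_trp, spread = spread,
                 cell_scales = cell_scales),
            class = "treatment_effect")
}

# Pixel membership of a rotated ellipse, vectorized over the pixel grid.
ellipse_mask <- function(size, cx, cy, ax, bx, theta) {
  xs <- matrix(rep(seq_len(size), each = size), size, size)  # column index
  ys <- matrix(rep(seq_len(size), size), size, size)         # row index
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / ax)^2 + (v / bx)^2 <= 1
}

# Rejection-sample non-overlapping cell geometry.
place_cells <- function(spec) {
  size <- spec$size
  r0 <- spec$cell_radius_frac * size
  cells <- data.frame(cell_id = integer(), cx = numeric(), cy = numeric(),
                      ax = numeric(), bx = numeric(), theta = numeric())
  tries <- 0L
  while (nrow(cells) < spec$n_cells) {
    tries <- tries + 1L
    if (tries > 5000L) stop("place_cells: could not place non-overlapping cells")
    ax <- r0 * stats::runif(1, 0.85, 1.15)
    bx <- r0 * stats::runif(1, 0.7, 1.0)
    rmax <- max(ax, bx)
    cx <- stats::runif(1, rmax + 2, size - rmax - 2)
    cy <- stats::runif(1, rmax + 2, size - rmax - 2)
    if (nrow(cells) > 0) {
      d <- sqrt((cells$cx - cx)^2 + (cells$cy - cy)^2)
      if (any(d < rmax + pmax(cells$ax, cells$bx) + 2)) next
    }
    cells <- rbind(cells, data.frame(cell_id = nrow(cells) + 1L, cx = cx,
                                     cy = cy, ax = ax, bx = bx,
                                     theta = stats::runif(1, 0, pi)))
  }
  cells
}

# Build label/nucleus/mitochondria/compartment masks from placed geometry.
build_masks <- function(spec, cells) {
  size <- spec$size
  labels <- matrix(0L, size, size)
  nucleus <- matrix(FALSE, size, size)
  mito <- matrix(FALSE, size, size)
  for (i in seq_len(nrow(cells))) {
    g <- cells[i, ]
    cm <- ellipse_mask(size, g$cx, g$cy, g$ax, g$bx, g$theta)
    labels[cm] <- g$cell_id
    nm <- ellipse_mask(size, g$cx, g$cy, g$ax * spec$nucleus_scale,
                       g$bx * spec$nucleus_scale, g$theta)
    nucleus[cm & nm] <- TRUE
    cyt_idx <- which(cm & !nm)
    n_blobs <- stats::rpois(1, spec$mito_density * length(cyt_idx))
    if (n_blobs > 0 && length(cyt_idx) > 0) {
      centers <- sample(cyt_idx, min(n_blobs, length(cyt_idx)), replace = TRUE)
      rr <- ceiling(spec$mito_radius)
      off <- expand.grid(dr = -rr:rr, dc = -rr:rr)
      off <- off[off$dr^2 + off$dc^2 <= spec$mito_radius^2 + 1e-9, ]
      cr <- (centers - 1L) %% size + 1L
      cc <- (centers - 1L) %/% size + 1L
      for (k in seq_len(nrow(off))) {
        r2 <- cr + off$dr[k]; c2 <- cc + off$dc[k]
        ok <- r2 >= 1 & r2 <= size & c2 >= 1 & c2 <= size
        mito[cbind(r2[ok], c2[ok])] <- TRUE
      }
    }
  }
  mito <- mito & labels > 0 & !nucleus  # mitochondria live in the cytosol
  comp <- matrix(COMP_BACKGROUND, size, size)
  comp[labels > 0] <- COMP_CYTOSOL
  comp[nucleus] <- COMP_NUCLEUS
  comp[mito] <- COMP_MITO
  list(labels = labels, nucleus = nucleus, mito = mito, compartment = comp)
}

# Draw per-cell bound fractions: compartment base + cell-level jitter.
draw_cell_fractions <- function(spec, cells) {
  for (ch in names(spec$decay)) {
    bf <- spec$decay[[ch]]$bound_frac
    for (comp in c("nucleus", "cytosol", "mito")) {
      jit <- stats::rnorm(nrow(cells), 0, spec$cell_jitter_sd)
      cells[[paste0(ch, "_", comp)]] <- pmin(pmax(bf[[comp]] + jit, 0.01), 0.99)
    }
  }
  cells
}

comp_name <- function(code) c("nucleus", "cytosol", "mito")[code]

# Realize truth maps, photon images and (optionally) TCSPC cubes from fixed
# geometry and per-cell fractions. Photon noise uses the supplied seed.
realize_scene <- function(spec, cells, masks, seed, cubes = FALSE,
                          condition = "control") {
  size <- spec$size
  set.seed(seed)
  axis <- spec$axis
  n_bins <- axis$n_bins
  channels <- names(spec$decay)
  truth <- list(); photons <- list(); cube_list <- if (cubes) list() else NULL
  lab <- masks$labels; comp <- masks$compartment
  in_cell <- lab > 0
  for (ch in channels) {
    d <- spec$decay[[ch]]
    a1p <- matrix(NA_real_, size, size)
    bright <- matrix(0, size, size)
    for (i in seq_len(nrow(cells))) {
      for (code in c(COMP_NUCLEUS, COMP_CYTOSOL, COMP_MITO)) {
        sel <- lab == cells$cell_id[i] & comp == code
        if (!any(sel)) next
        f <- cells[[paste0(ch, "_", comp_name(code))]][i]
        a1p[sel] <- if (d$bound == "short") f else 1 - f
        bright[sel] <- spec$brightness[[ch]][[comp_name(code)]]
      }
    }
    maps <- list(a1_pct = a1p, a2_pct = 1 - a1p,
                 tau1 = ifelse(in_cell, d$tau1, NA_real_),
                 tau2 = ifelse(in_cell, d$tau2, NA_real_))
    maps$tau_m <- maps$tau1 * maps$a1_pct + maps$tau2 * maps$a2_pct
    maps$chi2 <- ifelse(in_cell, 1, NA_real_)
    maps$brightness <- bright
    bg_rate <- spec$background[[ch]]
    if (cubes) {
      irf_obj <- spec$irf
      cube <- array(0L, dim = c(size, size, n_bins))
      cmat <- matrix(0L, size * size, n_bins)
      ## group pixels sharing one decay truth; one model evaluation per group
      grp <- paste(lab, comp)
      for (g in unique(grp)) {
        sel <- which(grp == g)
        code <- comp[sel[1]]
        if (code == COMP_BACKGROUND) {
          lam <- rep(bg_rate / n_bins, n_bins)
        } else {
          i <- which(cells$cell_id == lab[sel[1]])
          f <- cells[[paste0(ch, "_", comp_name(code))]][i]
          a1 <- if (d$bound == "short") f else 1 - f
          m <- model_decay(biexp_params(a1, 1 - a1, d$tau1, d$tau2, 0),
                           irf_obj, axis)
          b <- spec$brightness[[ch]][[comp_name(code)]]
          lam <- m * b / sum(m) + bg_rate / n_bins
        }
        cmat[sel, ] <- stats::rpois(length(sel) * n_bins,
                                    rep(lam, each = length(sel)))
      }
      cube[] <- cmat
      cube_list[[ch]] <- cube
      photons[[ch]] <- matrix(rowSums(cmat), size, size)
    } else {
      photons[[ch]] <- matrix(stats::rpois(size * size, bright + bg_rate),
                              size, size)
    }
    maps$photons <- photons[[ch]]
    maps$converged <- in_cell
    truth[[ch]] <- maps
  }
  structure(list(spec = spec, cells = cells,
                 masks = segmentation_masks(masks$labels, masks$nucleus),
                 mito_mask = masks$mito, compartment = masks$compartment,
                 photons = photons, truth = truth, cubes = cube_list,
                 axis = axis, irf = spec$irf, condition = condition,
                 photon_seed = seed),
            class = "flim_scene")
}

#' Generate a synthetic field of view
#'
#' Places non-overlapping elliptical cells with concentric nuclei and
#' granular mitochondria, draws per-cell decay truths around the compartment
#' base values, and realizes Poisson photon images (and optionally full
#' per-pixel TCSPC cubes via the decay model). Masks are exactly consistent
#' with the geometry and everything is reproducible under the spec seed.
#'
#' @param spec A [scene_spec()].
#' @param cubes Simulate full TCSPC cubes (`(size, size, n_bins)` arrays per
#'   channel)? Needed for pooled-refit ROI aggregation and per-pixel
#'   fitting; memory scales as `size^2 * n_bins`.
#' @return Object of class `flim_scene`: `cells` (geometry + realized
#'   per-cell bound fractions), `masks` ([segmentation_masks()]),
#'   `mito_mask`, `compartment` map, `photons` (per-channel matrices),
#'   `truth` (per-channel true parameter maps), optional `cubes`.
#' @export
make_fov <- function(spec, cubes = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  cells <- place_cells(spec)
  masks <- build_masks(spec, cells)
  cells <- draw_cell_fractions(spec, cells)
  realize_scene(spec, cells, masks, seed = spec$seed + 1000L, cubes = cubes)
}

#' Apply a treatment effect to a scene
#'
#' Draws one effect scale per cell (the ground truth for responder
#' categories), shifts the per-cell bound fractions accordingly, clips them
#' to \[0.01, 0.99\] (logged via message), and re-realizes photon images and
#' cubes on the identical geometry — mirroring re-imaging of the same field
#' of view after an intervention. Control and treated scenes therefore share
#' masks and cell ids exactly.
#'
#' @param scene A `flim_scene` from [make_fov()].
#' @param effect A [treatment_effect()].
#' @param seed Seed for the per-cell effect draw.
#' @param photon_seed Seed for the re-imaged photon noise (defaults to
#'   `seed + 1`; pass the control scene's `photon_seed` to reproduce its
#'   exact photon realization, e.g. for a zero-effect identity check).
#' @param condition Condition label recorded on the treated scene.
#' @return Treated `flim_scene`; `cells$effect_scale` records each cell's
#'   realized effect scale.
#' @export
apply_treatment <- function(scene, effect, seed = NULL, photon_seed = NULL,
                            condition = "treatment") {
  stopifnot(inherits(scene, "flim_scene"), inherits(effect, "treatment_effect"))
  spec <- scene$spec
  if (is.null(seed)) seed <- spec$seed + 5000L
  if (is.null(photon_seed)) photon_seed <- seed + 1L
  set.seed(seed)
  n <- nrow(scene$cells)
  s <- if (!is.null(effect$cell_scales)) rep_len(effect$cell_scales, n)
       else pmax(stats::rnorm(n, 1, effect$spread), 0)
  cells <- scene$cells
  cells$effect_scale <- s
  clipped <- 0L
  shift <- function(v, dlt) {
    out <- v + dlt
    clipped <<- clipped + sum(out < 0.01 | out > 0.99)
    pmin(pmax(out, 0.01), 0.99)
  }
  cells$nadh_mito <- shift(cells$nadh_mito, effect$d_nadh_mito * s)
  cells$nadh_cytosol <- shift(cells$nadh_cytosol, effect$d_nadh_cyt * s)
  cells$fad_mito <- shift(cells$fad_mito, effect$d_fad_mito * s)
  if ("trp" %in% names(spec$decay)) {
    for (comp in c("nucleus", "cytosol", "mito")) {
      cells[[paste0("trp_", comp)]] <-
        shift(cells[[paste0("trp_", comp)]], effect$d_trp * s)
    }
  }
  if (clipped > 0) {
    message(sprintf("apply_treatment: clipped %d fraction value(s) to [0.01, 0.99]",
                    clipped))
  }
  masks <- list(labels = scene$masks$cell_labels, nucleus = scene$masks$nucleus,
                mito = scene$mito_mask, compartment = scene$compartment)
  out <- realize_scene(spec, cells, masks, seed = photon_seed,
                       cubes = !is.null(scene$cubes), condition = condition)
  out
}

#' Channel-wise photon attenuation of a scene
#'
#' Emulates depth-dependent scattering and absorption: each channel's photon
#' image is scaled deterministically by its attenuation factor (the mean
#' effect on intensity), and TCSPC cubes are thinned binomially (each photon
#' survives independently), so decay shapes are preserved while intensities
#' drop. The intensity redox ratio shifts by exactly `fad / nadh`, while
#' FLIRR — built from intensity-normalized amplitude fractions — is
#' unaffected up to fit noise.
#'
#' @param scene A `flim_scene`.
#' @param nadh,fad,trp Attenuation factors in (0, 1].
#' @param seed Seed for the binomial thinning of cubes.
#' @return Attenuated `flim_scene`.
#' @export
attenuate_scene <- function(scene, nadh = 1, fad = 1, trp = 1, seed = 1L) {
  stopifnot(inherits(scene, "flim_scene"))
  fac <- c(nadh = nadh, fad = fad, trp = trp)
  if (any(fac <= 0 | fac > 1)) stop("attenuate_scene: factors must be in (0, 1]")
  set.seed(seed)
  for (ch in names(scene$photons)) {
    k <- fac[[ch]]
    if (k == 1) next
    scene$photons[[ch]] <- scene$photons[[ch]] * k
    if (!is.null(scene$cubes)) {
      cube <- scene$cubes[[ch]]
      cube[] <- stats::rbinom(length(cube), cube, k)
      scene$cubes[[ch]] <- cube
      scene$truth[[ch]]$photons <- matrix(rowSums(matrix(cube, prod(dim(cube)[1:2]),
                                                         dim(cube)[3])),
                                          dim(cube)[1], dim(cube)[2])
    }
  }
  scene
}

#' Closed-form ground-truth FLIRR per cell and compartment
#'
#' FLIRR truth follows directly from the scene's bound fractions:
#' mitochondrial FLIRR is the cell's NAD(P)H mito a2% over its FAD mito a1%,
#' cytosolic FLIRR likewise from the cytosol fractions. This is the oracle
#' for all recovery tests.
#'
#' @param scene A `flim_scene`.
#' @return Data frame: `cell_id`, `flirr_mito`, `flirr_cytosol`,
#'   `trp_tau_m_mito`, `trp_e_pct_mito`.
#' @export
true_cell_flirr <- function(scene) {
  cells <- scene$cells
  d <- scene$spec$decay$trp
  tau_d <- donor_reference()$tau_d
  tau_m <- if (is.null(d)) rep(NA_real_, nrow(cells)) else
    cells$trp_mito * d$tau1 + (1 - cells$trp_mito) * d$tau2
  data.frame(cell_id = cells$cell_id,
             flirr_mito = cells$nadh_mito / cells$fad_mito,
             flirr_cytosol = cells$nadh_cytosol / cells$fad_cytosol,
             trp_tau_m_mito = tau_m,
             trp_e_pct_mito = (1 - tau_m / tau_d) * 100)
}
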