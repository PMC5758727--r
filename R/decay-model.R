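# Two-component TCSPC decay model: periodic ("incomplete decay") bi-exponential
# convolved with an instrument response, Poisson-likelihood fitting, and the
# derived per-pixel quantities (a1%/a2%, amplitude-weighted lifetime, reduced
# chi-square).

#' TCSPC time axis
#'
#' Describes the timing of a TCSPC record: number of histogram bins, bin
#' width, and the laser repetition period. The default corresponds to a
#' 256-bin record spanning one 12.5 ns period of an 80 MHz pulsed laser.
#'
#' @param n_bins Number of time bins (positive integer).
#' @param bin_width Bin width in ns. Defaults to `period / n_bins` so the
#'   record tiles the excitation period exactly.
#' @param period Laser repetition period in ns (12.5 ns for 80 MHz).
#'
#' @return An object of class `time_axis` with fields `n_bins`, `bin_width`,
#'   `period` and the bin left-edge times `t`.
#' @export
#' @examples
#' ax <- time_axis()
#' ax$bin_width * ax$n_bins  # == 12.5
time_axis <- function(n_bins = 256L, bin_width = NULL, period = 12.5) {
  n_bins <- as.integer(n_bins)
  stopifnot(length(n_bins) == 1L, n_bins > 0L, length(period) == 1L, period > 0)
  if (is.null(bin_width)) bin_width <- period / n_bins
  stopifnot(length(bin_width) == 1L, bin_width > 0)
  if (n_bins * bin_width > period + bin_width + 1e-9) {
    stop("time_axis: record (n_bins * bin_width) must fit inside one excitation period")
  }
  structure(
    list(n_bins = n_bins, bin_width = bin_width, period = period,
         t = (seq_len(n_bins) - 1) * bin_width),
    class = "time_axis"
  )
}

#' Instrument response function model
#'
#' Either an analytic Gaussian IRF (default: centered at 1.0 ns with 0.2 ns
#' FWHM) or a measured per-bin curve. The curve is normalized to unit sum
#' when sampled on a time axis, so the IRF redistributes but never creates
#' photons.
#'
#' @param shape `"gaussian"` or `"measured"`.
#' @param center Gaussian center, ns.
#' @param fwhm Gaussian full width at half maximum, ns (> 0).
#' @param curve Non-negative per-bin amplitudes (measured shape only).
#'
#' @return An object of class `irf_model`.
#' @export
irf_model <- function(shape = c("gaussian", "measured"), center = 1.0,
                      fwhm = 0.2, curve = NULL) {
  shape <- match.arg(shape)
  if (shape == "gaussian") {
    stopifnot(is.numeric(fwhm), length(fwhm) == 1L, fwhm > 0,
              is.numeric(center), length(center) == 1L)
    out <- list(shape = shape, center = center, fwhm = fwhm)
  } else {
    if (is.null(curve) || !is.numeric(curve) || any(!is.finite(curve)) ||
        any(curve < 0) || sum(curve) <= 0) {
      stop("irf_model: measured curve must be non-negative with positive sum")
    }
    out <- list(shape = shape, curve = as.numeric(curve))
  }
  structure(out, class = "irf_model")
}

#' Sample an IRF on a time axis
#'
#' @param irf An [irf_model()].
#' @param axis A [time_axis()].
#' @return Numeric vector of length `axis$n_bins`, non-negative, summing to 1.
#' @export
irf_curve <- function(irf, axis) {
  stopifnot(inherits(irf, "irf_model"), inherits(axis, "time_axis"))
  if (irf$shape == "gaussian") {
    s <- irf$fwhm / (2 * sqrt(2 * log(2)))
    v <- stats::dnorm(axis$t, irf$center, s)
  } else {
    if (length(irf$curve) != axis$n_bins) {
      stop("irf_curve: measured curve length must equal axis$n_bins")
    }
    v <- irf$curve
  }
  v / sum(v)
}

#' TCSPC decay histogram for one pixel, ROI or channel
#'
#' @param counts Non-negative photon counts per time bin. Non-integer values
#'   are accepted (e.g. noiseless model expectations used in validation).
#' @param axis A [time_axis()]; `length(counts)` must equal `axis$n_bins`.
#' @param channel Channel tag: `"nadh"`, `"fad"` or `"trp"`.
#' @return Object of class `decay_histogram` with derived `total_photons`.
#' @export
decay_histogram <- function(counts, axis, channel = c("nadh", "fad", "trp")) {
  channel <- match.arg(channel)
  stopifnot(inherits(axis, "time_axis"))
  counts <- as.numeric(counts)
  if (length(counts) != axis$n_bins) {
    stop("decay_histogram: length(counts) must equal axis$n_bins")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("decay_histogram: counts must be finite and non-negative")
  }
  structure(
    list(counts = counts, axis = axis, channel = channel,
         total_photons = sum(counts)),
    class = "decay_histogram"
  )
}

#' Bi-exponential decay parameters
#'
#' Amplitudes are counts at t = 0 of each component (before the periodic
#' correction); lifetimes in ns; `background` in counts per bin. The
#' canonical ordering `tau1 <= tau2` is enforced by [canonicalize_biexp()],
#' not by this constructor, so that simulation of label-swapped truths is
#' possible.
#'
#' @param a1,a2 Component amplitudes (>= 0).
#' @param tau1,tau2 Component lifetimes in ns (> 0).
#' @param background Constant counts per bin (>= 0).
#' @return Object of class `biexp_params`.
#' @export
biexp_params <- function(a1, a2, tau1, tau2, background = 0) {
  stopifnot(a1 >= 0, a2 >= 0, tau1 > 0, tau2 > 0, background >= 0)
  structure(list(a1 = a1, a2 = a2, tau1 = tau1, tau2 = tau2,
                 background = background),
            class = "biexp_params")
}

#' Enforce the canonical component ordering tau1 <= tau2
#'
#' @param params A [biexp_params()].
#' @return `biexp_params` with components swapped if needed.
#' @export
canonicalize_biexp <- function(params) {
  if (params$tau1 > params$tau2) {
    params <- biexp_params(params$a2, params$a1, params$tau2, params$tau1,
                           params$background)
  }
  params
}

# Periodic single-exponential shape on the axis grid: for pulsed excitation at
# period P every preceding pulse contributes, giving the closed form
# exp(-t/tau) / (1 - exp(-P/tau)) ("incomplete decay" model).
periodic_shape <- function(tau, axis) {
  exp(-axis$t / tau) / (1 - exp(-axis$period / tau))
}

# d(periodic_shape)/d(tau), used for analytic likelihood gradients.
periodic_shape_dtau <- function(tau, axis) {
  P <- axis$period
  cfac <- 1 / (1 - exp(-P / tau))
  s <- exp(-axis$t / tau) * cfac
  s * (axis$t / tau^2 + cfac * exp(-P / tau) * P / tau^2)
}

# Circular convolution with a precomputed fft of the (normalized) IRF.
circ_conv <- function(x, irf_fft) {
  Re(stats::fft(stats::fft(x) * irf_fft, inverse = TRUE)) / length(x)
}

#' Expected counts per bin under the periodic bi-exponential model
#'
#' Each component decays as `exp(-t/tau)` and is summed over all preceding
#' excitation periods via the closed form `1 / (1 - exp(-period/tau))`, then
#' circularly convolved with the normalized IRF; a constant background is
#' added. Lifetimes at or above 50 laser periods are rejected as numerically
#' degenerate.
#'
#' @param params A [biexp_params()].
#' @param irf An [irf_model()].
#' @param axis A [time_axis()].
#' @return Numeric vector of expected counts per bin (all `>= background`).
#' @export
#' @examples
#' ax <- time_axis()
#' m <- model_decay(biexp_params(100, 100, 0.5, 2.5), irf_model(), ax)
model_decay <- function(params, irf, axis) {
  stopifnot(inherits(params, "biexp_params"), inherits(axis, "time_axis"))
  if (max(params$tau1, params$tau2) >= 50 * axis$period) {
    stop("model_decay: lifetime >= 50 laser periods is numerically degenerate")
  }
  irf_fft <- stats::fft(irf_curve(irf, axis))
  s <- params$a1 * periodic_shape(params$tau1, axis) +
       params$a2 * periodic_shape(params$tau2, axis)
  pmax(circ_conv(s, irf_fft), 0) + params$background
}

#' Simulate a Poisson TCSPC histogram
#'
#' Draws independent Poisson counts per bin with mean [model_decay()] scaled
#' so that the expected total equals `total_photons`. Reproducible under a
#' fixed seed.
#'
#' @inheritParams model_decay
#' @param total_photons Expected total photon count (> 0).
#' @param seed Optional integer seed.
#' @param channel Channel tag passed to [decay_histogram()].
#' @return A [decay_histogram()].
#' @export
simulate_decay <- function(params, irf, axis, total_photons, seed = NULL,
                           channel = "nadh") {
  stopifnot(total_photons > 0)
  m <- model_decay(params, irf, axis)
  lam <- m * total_photons / sum(m)
  if (!is.null(seed)) set.seed(seed)
  decay_histogram(stats::rpois(axis$n_bins, lam), axis, channel)
}

#' Intensity-normalized amplitude fractions
#'
#' `a1% = a1 / (a1 + a2)` and `a2% = a2 / (a1 + a2)`: the component shares
#' with the overall fluorescence intensity divided out, so they are invariant
#' under any common rescaling of the amplitudes.
#'
#' @param a1,a2 Non-negative amplitudes, not both zero (vectorized).
#' @return List with numeric elements `a1_pct` and `a2_pct` (fractions in
#'   \[0, 1\] summing to 1).
#' @export
#' @examples
#' normalized_fractions(3, 1)  # a1_pct 0.75, a2_pct 0.25
normalized_fractions <- function(a1, a2) {
  if (any(a1 < 0 | a2 < 0)) stop("normalized_fractions: amplitudes must be >= 0")
  tot <- a1 + a2
  if (any(tot == 0)) stop("normalized_fractions: a1 + a2 must be > 0")
  list(a1_pct = a1 / tot, a2_pct = a2 / tot)
}

#' Amplitude-weighted mean lifetime
#'
#' `tau_m = tau1 * a1% + tau2 * a2%`, the amplitude-weighted average of the
#' two component lifetimes; always bounded by `[tau1, tau2]`. This is the
#' quenched-donor lifetime used in FRET efficiency.
#'
#' @param fit A `biexp_fit` (from [fit_biexp()]) or any list with fields
#'   `tau1`, `tau2`, `a1_pct`.
#' @return Lifetime in ns.
#' @export
amplitude_weighted_lifetime <- function(fit) {
  if (inherits(fit, "biexp_fit")) {
    tau1 <- fit$params$tau1; tau2 <- fit$params$tau2; a1p <- fit$a1_pct
  } else {
    tau1 <- fit$tau1; tau2 <- fit$tau2; a1p <- fit$a1_pct
  }
  tau1 * a1p + tau2 * (1 - a1p)
}

#' Reduced Pearson chi-square of a model against a histogram
#'
#' Pearson statistic `sum((obs - exp)^2 / exp)` over bins whose expectation
#' is at least `floor` (default 1 count), divided by the number of included
#' bins minus the number of free parameters.
#'
#' @param counts Observed counts (vector or [decay_histogram()]).
#' @param expected Model expectation per bin.
#' @param n_free_params Number of fitted parameters.
#' @param floor Minimum expectation for a bin to enter the statistic.
#' @return Dimensionless reduced chi-square.
#' @export
reduced_chi2 <- function(counts, expected, n_free_params, floor = 1) {
  if (inherits(counts, "decay_histogram")) counts <- counts$counts
  stopifnot(length(counts) == length(expected), all(is.finite(expected)))
  keep <- expected >= floor
  n_inc <- sum(keep)
  if (n_inc <= n_free_params) {
    stop("reduced_chi2: fewer included bins than free parameters")
  }
  sum((counts[keep] - expected[keep])^2 / expected[keep]) / (n_inc - n_free_params)
}

#' Fitting options for [fit_biexp()]
#'
#' @param objective `"mle"` (Poisson maximum likelihood, default — correct for
#'   low-count TCSPC data) or `"neyman"` (least squares weighted by
#'   `1/max(obs, 1)`).
#' @param min_photons Histograms with fewer total photons are rejected.
#' @param fit_background Fit the constant background as a free parameter
#'   (initialized from the pre-rise bins). If `FALSE`, the background is fixed
#'   at `background` (or the pre-rise estimate when `background` is `NULL`).
#' @param background Fixed background (counts/bin) when `fit_background = FALSE`.
#' @param tau1_bounds,tau2_bounds Lifetime box constraints in ns.
#' @param maxit Maximum L-BFGS-B iterations.
#' @param mono_tol Lifetime separation (ns) below which the fit is flagged
#'   effectively mono-exponential.
#' @return Object of class `fit_options`.
#' @export
fit_options <- function(objective = c("mle", "neyman"), min_photons = 300,
                        fit_background = TRUE, background = NULL,
                        tau1_bounds = c(0.05, 1.5), tau2_bounds = c(0.8, 8),
                        maxit = 200, mono_tol = 0.05) {
  objective <- match.arg(objective)
  stopifnot(min_photons >= 0, length(tau1_bounds) == 2L, length(tau2_bounds) == 2L,
            tau1_bounds[1] > 0, tau1_bounds[1] < tau1_bounds[2],
            tau2_bounds[1] > 0, tau2_bounds[1] < tau2_bounds[2])
  structure(list(objective = objective, min_photons = min_photons,
                 fit_background = fit_background, background = background,
                 tau1_bounds = tau1_bounds, tau2_bounds = tau2_bounds,
                 maxit = maxit, mono_tol = mono_tol),
            class = "fit_options")
}

# Deterministic initialization: background from the pre-rise region, tau2 from
# a log-linear fit to the record tail, tau1 = tau2 / 5, amplitudes by linear
# least squares given the lifetimes.
init_biexp <- function(y, axis, irf_fft, opt) {
  n <- axis$n_bins
  sm <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  bg0 <- max(min(sm, na.rm = TRUE), 0)
  pk <- which.max(y)
  tail_start <- max(pk + 5L, ceiling(0.6 * n))
  tail_idx <- seq(min(tail_start, n - 5L), n)
  yt <- y[tail_idx] - bg0
  ok <- yt > 0
  tau2_0 <- 2.5
  if (sum(ok) > 5) {
    sl <- stats::coef(stats::lm(log(yt[ok]) ~ axis$t[tail_idx][ok]))[2]
    if (is.finite(sl) && sl < 0) tau2_0 <- -1 / sl
  }
  tau2_0 <- min(max(tau2_0, opt$tau2_bounds[1]), opt$tau2_bounds[2])
  tau1_0 <- min(max(tau2_0 / 5, opt$tau1_bounds[1]), opt$tau1_bounds[2])
  X <- cbind(circ_conv(periodic_shape(tau1_0, axis), irf_fft),
             circ_conv(periodic_shape(tau2_0, axis), irf_fft))
  ab <- tryCatch(qr.solve(X, pmax(y - bg0, 0)), error = function(e) NULL)
  if (is.null(ab) || any(!is.finite(ab))) ab <- rep(sum(y) / n, 2)
  ab <- pmax(ab, 1e-3 * sum(y) / n)
  c(a1 = unname(ab[1]), a2 = unname(ab[2]), tau1 = tau1_0, tau2 = tau2_0,
    bg = bg0)
}

#' Fit a two-component decay to a TCSPC histogram
#'
#' Maximizes the Poisson likelihood of the periodic bi-exponential model
#' (or minimizes Neyman-weighted least squares) with analytic gradients under
#' box constraints, then canonicalizes the result so `tau1 <= tau2`.
#' Histograms below the photon minimum raise a condition of class
#' `flimredox_insufficient_photons` rather than returning a silent fit.
#'
#' @param hist A [decay_histogram()].
#' @param irf An [irf_model()].
#' @param options A [fit_options()].
#' @return Object of class `biexp_fit`: `params` ([biexp_params()]),
#'   `a1_pct`, `a2_pct`, `tau_m`, `chi2_reduced`, `n_photons`, `converged`,
#'   `mono` (effectively mono-exponential flag), `objective`, and the fitted
#'   `expected` curve.
#' @export
#' @examples
#' ax <- time_axis(); irf <- irf_model()
#' h <- simulate_decay(biexp_params(60, 40, 0.4, 2.5), irf, ax, 5000, seed = 1)
#' f <- fit_biexp(h, irf)
#' f$a2_pct
fit_biexp <- function(hist, irf, options = fit_options()) {
  stopifnot(inherits(hist, "decay_histogram"), inherits(options, "fit_options"))
  y <- hist$counts
  if (any(!is.finite(y))) stop("fit_biexp: non-finite counts")
  if (hist$total_photons < options$min_photons) {
    stop(errorCondition(
      sprintf("insufficient photons: %d < minimum %d",
              round(hist$total_photons), round(options$min_photons)),
      class = c("flimredox_insufficient_photons", "error", "condition")))
  }
  axis <- hist$axis
  irf_fft <- stats::fft(irf_curve(irf, axis))
  fit_biexp_core(y, axis, irf_fft, options, channel = hist$channel)
}

# Core fit on a raw count vector with precomputed fft(IRF); shared by the
# per-histogram and per-image entry points.
fit_biexp_core <- function(y, axis, irf_fft, opt, channel = "nadh") {
  p0 <- init_biexp(y, axis, irf_fft, opt)
  free_bg <- isTRUE(opt$fit_background)
  bg_fixed <- if (free_bg) NA_real_ else
    (if (is.null(opt$background)) unname(p0["bg"]) else opt$background)

  lo <- c(0, 0, opt$tau1_bounds[1], opt$tau2_bounds[1])
  hi <- c(Inf, Inf, opt$tau1_bounds[2], opt$tau2_bounds[2])
  clamp <- function(v, j) min(max(v, lo[j]), hi[j])
  # Build a start vector for given lifetimes: amplitudes by linear least
  # squares on the background-subtracted record.
  make_start <- function(tau1, tau2, bg) {
    tau1 <- clamp(tau1, 3); tau2 <- clamp(tau2, 4)
    X <- cbind(circ_conv(periodic_shape(tau1, axis), irf_fft),
               circ_conv(periodic_shape(tau2, axis), irf_fft))
    ab <- tryCatch(qr.solve(X, pmax(y - bg, 0)), error = function(e) NULL)
    if (is.null(ab) || any(!is.finite(ab))) ab <- rep(sum(y) / axis$n_bins, 2)
    ab <- pmax(ab, 1e-3 * sum(y) / axis$n_bins)
    par0 <- c(ab[1], ab[2], tau1, tau2)
    if (free_bg) par0 <- c(par0, bg)
    unname(par0)
  }
  par0 <- unname(p0[1:4])
  if (free_bg) {
    lo <- c(lo, 0); hi <- c(hi, max(y) + 1); par0 <- c(par0, unname(p0["bg"]))
  }

  cache <- new.env(parent = emptyenv())
  cache$key <- ""
  mu_at <- function(p) {
    key <- paste(p, collapse = ",")
    if (!identical(cache$key, key)) {
      cache$c1 <- circ_conv(periodic_shape(p[3], axis), irf_fft)
      cache$c2 <- circ_conv(periodic_shape(p[4], axis), irf_fft)
      bg <- if (free_bg) p[5] else bg_fixed
      cache$mu <- pmax(p[1] * cache$c1 + p[2] * cache$c2 + bg, 1e-12)
      cache$key <- key
    }
    invisible(NULL)
  }
  if (opt$objective == "mle") {
    fn <- function(p) { mu_at(p); sum(cache$mu - y * log(cache$mu)) }
    wfun <- function(mu) 1 - y / mu
  } else {
    w_ney <- 1 / pmax(y, 1)
    fn <- function(p) { mu_at(p); sum(w_ney * (y - cache$mu)^2) }
    wfun <- function(mu) -2 * w_ney * (y - mu)
  }
  gr <- function(p) {
    mu_at(p)
    w <- wfun(cache$mu)
    d1 <- circ_conv(periodic_shape_dtau(p[3], axis), irf_fft)
    d2 <- circ_conv(periodic_shape_dtau(p[4], axis), irf_fft)
    g <- c(sum(w * cache$c1), sum(w * cache$c2),
           p[1] * sum(w * d1), p[2] * sum(w * d2))
    if (free_bg) g <- c(g, sum(w)) else g
  }
  run_start <- function(par0) {
    psc <- c(max(par0[1], 1), max(par0[2], 1), 0.3, 1.5)
    if (free_bg) psc <- c(psc, max(par0[5], 1))
    stats::optim(par0, fn, gr, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = opt$maxit, parscale = psc,
                                factr = 1e4))
  }
  suspect <- function(o) {
    frac <- o$par[1] / (o$par[1] + o$par[2])
    frac < 0.03 || frac > 0.97 ||
      o$par[3] >= opt$tau1_bounds[2] - 1e-6 ||
      o$par[4] <= opt$tau2_bounds[1] + 1e-6
  }
  o <- run_start(par0)
  if (suspect(o)) {
    # degenerate basin (component collapse or lifetime at a bound): retry
    # from alternative deterministic lifetime starts, keep the best objective
    tau2_0 <- p0[["tau2"]]; bg0 <- p0[["bg"]]
    alt <- list(make_start(tau2_0 / 2.5, tau2_0 * 1.3, bg0 / 2),
                make_start(tau2_0 / 8, tau2_0 * 0.9, bg0 / 2))
    for (a in alt) {
      oa <- tryCatch(run_start(a), error = function(e) NULL)
      if (!is.null(oa) && oa$value < o$value - 1e-9) o <- oa
    }
  }
  p <- o$par
  p[1:2] <- pmax(p[1:2], 0)  # guard against -0 eps at the box boundary
  bg <- if (free_bg) max(p[5], 0) else max(bg_fixed, 0)
  params <- canonicalize_biexp(biexp_params(p[1], p[2], p[3], p[4], bg))
  fr <- normalized_fractions(params$a1, params$a2)
  n_free <- 4L + as.integer(free_bg)
  mu <- model_decay(params, NULL_irf_from_fft(irf_fft, axis), axis)
  chi2 <- tryCatch(reduced_chi2(y, mu, n_free), error = function(e) NA_real_)
  at_bound <- p[3] <= opt$tau1_bounds[1] + 1e-6 || p[3] >= opt$tau1_bounds[2] - 1e-6 ||
              p[4] <= opt$tau2_bounds[1] + 1e-6 || p[4] >= opt$tau2_bounds[2] - 1e-6
  tau_m <- params$tau1 * fr$a1_pct + params$tau2 * fr$a2_pct
  structure(
    list(params = params, a1_pct = fr$a1_pct, a2_pct = fr$a2_pct,
         tau_m = tau_m, chi2_reduced = chi2, n_photons = sum(y),
         converged = (o$convergence == 0L) && !at_bound,
         mono = abs(params$tau2 - params$tau1) < opt$mono_tol,
         objective = opt$objective, channel = channel, expected = mu),
    class = "biexp_fit"
  )
}

# Wrap an already-sampled IRF spectrum back into a "measured" irf_model so
# model_decay can be reused for the fitted curve.
NULL_irf_from_fft <- function(irf_fft, axis) {
  curve <- Re(stats::fft(irf_fft, inverse = TRUE)) / axis$n_bins
  irf_model("measured", curve = pmax(curve, 0))
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    "biexp_fit [%s]: tau1=%.3f ns, tau2=%.3f ns, a1%%=%.3f, a2%%=%.3f, tau_m=%.3f ns\n",
    x$channel, x$params$tau1, x$params$tau2, x$a1_pct, x$a2_pct, x$tau_m))
  cat(sprintf("  photons=%d  chi2_red=%.3f  converged=%s%s\n",
              round(x$n_photons), x$chi2_reduced, x$converged,
              if (x$mono) "  [effectively mono-exponential]" else ""))
  invisible(x)
}

#' Fit many histograms sharing one axis and IRF
#'
#' @param counts Matrix, one histogram per row (`ncol == axis$n_bins`).
#' @param axis A [time_axis()].
#' @param irf An [irf_model()].
#' @param options A [fit_options()].
#' @param channel Channel tag recorded on each fit.
#' @return Data frame with one row per histogram: `a1`, `a2`, `tau1`, `tau2`,
#'   `background`, `a1_pct`, `a2_pct`, `tau_m`, `chi2`, `photons`,
#'   `converged`, `mono`. Histograms below the photon minimum yield an
#'   all-`NA` row with `converged = FALSE`.
#' @export
fit_histograms <- function(counts, axis, irf, options = fit_options(),
                           channel = "nadh") {
  stopifnot(is.matrix(counts), ncol(counts) == axis$n_bins)
  irf_fft <- stats::fft(irf_curve(irf, axis))
  n <- nrow(counts)
  out <- data.frame(
    a1 = rep(NA_real_, n), a2 = NA_real_, tau1 = NA_real_, tau2 = NA_real_,
    background = NA_real_, a1_pct = NA_real_, a2_pct = NA_real_,
    tau_m = NA_real_, chi2 = NA_real_, photons = rowSums(counts),
    converged = FALSE, mono = NA
  )
  for (i in seq_len(n)) {
    if (out$photons[i] < options$min_photons) next
    f <- fit_biexp_core(counts[i, ], axis, irf_fft, options, channel)
    out$a1[i] <- f$params$a1; out$a2[i] <- f$params$a2
    out$tau1[i] <- f$params$tau1; out$tau2[i] <- f$params$tau2
    out$background[i] <- f$params$background
    out$a1_pct[i] <- f$a1_pct; out$a2_pct[i] <- f$a2_pct
    out$tau_m[i] <- f$tau_m; out$chi2[i] <- f$chi2_reduced
    out$converged[i] <- f$converged; out$mono[i] <- f$mono
  }
  out
}
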