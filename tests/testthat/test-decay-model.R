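# Decay model: periodic bi-exponential forward model, Poisson simulation,
# likelihood fitting, and the derived per-pixel quantities.

test_that("periodic model matches the brute-force multi-period convolution oracle", {
  cases <- list(
    list(p = biexp_params(100, 100, 0.5, 2.5), irf = gauss_irf),
    list(p = biexp_params(30, 170, 0.4, 3.5, background = 2), irf = gauss_irf),
    list(p = biexp_params(100, 100, 0.5, 2.5), irf = delta_irf(ax256))
  )
  for (cs in cases) {
    m <- model_decay(cs$p, cs$irf, ax256)
    oracle <- brute_force_model(cs$p, cs$irf, ax256)
    expect_lt(max(abs(m - oracle)) / max(oracle), 1e-9)
  }
})

test_that("mono-exponential closed form holds under a delta IRF", {
  A <- 500; tau <- 2.0
  p <- biexp_params(0, A, 1, tau)  # single active component
  m <- model_decay(p, delta_irf(ax256), ax256)
  cfac <- 1 / (1 - exp(-ax256$period / tau))
  expect_equal(m[1], A * cfac, tolerance = 1e-12)
  # geometric sum over the record equals the discrete integral of the decay
  geom <- A * cfac * (1 - exp(-ax256$n_bins * ax256$bin_width / tau)) /
    (1 - exp(-ax256$bin_width / tau))
  expect_equal(sum(m), geom, tolerance = 1e-12)
})

test_that("zero amplitudes give a flat background and long lifetimes are rejected", {
  p <- biexp_params(0, 0, 0.5, 2.5, background = 7)
  expect_equal(model_decay(p, gauss_irf, ax256), rep(7, 256))
  expect_error(model_decay(biexp_params(1, 1, 0.5, 50 * 12.5), gauss_irf, ax256),
               "degenerate")
})

test_that("simulation is reproducible, concentrates at the target total, and is unbiased per bin", {
  p <- biexp_params(60, 40, 0.4, 2.5)
  h1 <- simulate_decay(p, gauss_irf, ax256, 1e6, seed = 42)
  h2 <- simulate_decay(p, gauss_irf, ax256, 1e6, seed = 42)
  expect_identical(h1$counts, h2$counts)
  expect_lt(abs(h1$total_photons - 1e6), 5 * sqrt(1e6))

  # law of large numbers: bin means over replicates approach the model
  m <- model_decay(p, gauss_irf, ax256)
  lam <- m * 5000 / sum(m)
  reps <- sapply(1:500, function(i)
    simulate_decay(p, gauss_irf, ax256, 5000, seed = i)$counts)
  binmean <- rowMeans(reps)
  z <- (binmean - lam) / sqrt(pmax(lam, 1e-12) / 500)
  expect_lt(max(abs(z)), 6)
})

test_that("normalized fractions are exact, scale-invariant, and guarded", {
  expect_equal(normalized_fractions(1, 1), list(a1_pct = 0.5, a2_pct = 0.5))
  expect_equal(normalized_fractions(3, 1), list(a1_pct = 0.75, a2_pct = 0.25))
  for (c in c(0.01, 1, 1e6)) {
    fr <- normalized_fractions(c * 3, c * 1)
    expect_equal(fr$a1_pct, 0.75)
    expect_equal(fr$a1_pct + fr$a2_pct, 1, tolerance = 1e-12)
  }
  expect_error(normalized_fractions(0, 0), "a1 \\+ a2")
  expect_error(normalized_fractions(-1, 2), ">= 0")
})

test_that("amplitude-weighted lifetime follows tau1*a1% + tau2*a2% with its limits", {
  expect_equal(amplitude_weighted_lifetime(list(tau1 = 0.5, tau2 = 2.5, a1_pct = 0.6)), 1.3)
  expect_equal(amplitude_weighted_lifetime(list(tau1 = 0.5, tau2 = 2.5, a1_pct = 1)), 0.5)
  expect_equal(amplitude_weighted_lifetime(list(tau1 = 0.5, tau2 = 2.5, a1_pct = 0)), 2.5)
})

test_that("reduced chi-square: zero at equality, quadratic in residuals, calibrated on Poisson data", {
  expected <- model_decay(biexp_params(60, 40, 0.4, 2.5), gauss_irf, ax256)
  expected <- expected * 5000 / sum(expected)
  expect_equal(reduced_chi2(expected, expected, 4), 0)

  d <- sin(seq_len(256))  # arbitrary residual pattern
  c1 <- reduced_chi2(expected + d, expected, 4)
  c2 <- reduced_chi2(expected + 2 * d, expected, 4)
  expect_equal(c2 / c1, 4, tolerance = 1e-12)

  expect_error(reduced_chi2(rep(1, 4), rep(1, 4), 4), "free parameters")

  # Pearson statistic of the true model on its own Poisson draws has mean ~ 1
  chis <- sapply(1:200, function(i) {
    y <- simulate_decay(biexp_params(60, 40, 0.4, 2.5), gauss_irf, ax256,
                        5000, seed = 1e4 + i)$counts
    reduced_chi2(y, expected, 0)
  })
  expect_gt(mean(chis), 0.9)
  expect_lt(mean(chis), 1.1)
})

test_that("noiseless histograms are recovered to high accuracy", {
  truths <- list(c(a1p = 0.7, tau1 = 0.4, tau2 = 2.5),
                 c(a1p = 0.3, tau1 = 0.6, tau2 = 3.0))
  for (tr in truths) {
    p <- biexp_params(1000 * tr["a1p"], 1000 * (1 - tr["a1p"]),
                      tr["tau1"], tr["tau2"])
    m <- model_decay(p, gauss_irf, ax256)
    h <- decay_histogram(m, ax256)
    f <- fit_biexp(h, gauss_irf)
    expect_lt(abs(f$a1_pct - tr[["a1p"]]), 1e-3)
    expect_lt(abs(f$params$tau1 - tr[["tau1"]]), 1e-3)
    expect_lt(abs(f$params$tau2 - tr[["tau2"]]), 1e-3)
  }
})

test_that("Poisson fits at 5000 photons recover a2% and report calibrated chi-square", {
  p <- biexp_params(70, 30, 0.4, 2.5)
  res <- t(sapply(1:100, function(i) {
    h <- simulate_decay(p, gauss_irf, ax256, 5000, seed = 200 + i)
    f <- fit_biexp(h, gauss_irf)
    c(a2 = f$a2_pct, chi2 = f$chi2_reduced, conv = f$converged)
  }))
  expect_lt(median(abs(res[, "a2"] - 0.3)), 0.03)
  expect_gt(mean(res[, "chi2"]), 0.9)
  expect_lt(mean(res[, "chi2"]), 1.1)
  expect_gt(mean(res[, "conv"]), 0.95)
})

test_that("amplitude fractions are invariant under intensity scaling", {
  p <- biexp_params(60, 40, 0.4, 2.5)
  m <- model_decay(p, gauss_irf, ax256)
  base <- fit_biexp(decay_histogram(m * 10, ax256), gauss_irf)
  for (k in c(3, 50)) {
    f <- fit_biexp(decay_histogram(m * 10 * k, ax256), gauss_irf)
    expect_lt(abs(f$a1_pct - base$a1_pct), 2e-3)
  }
  # Poisson realization scaled by an integer factor
  h <- simulate_decay(p, gauss_irf, ax256, 8000, seed = 5)
  f1 <- fit_biexp(h, gauss_irf)
  f2 <- fit_biexp(decay_histogram(h$counts * 10, ax256), gauss_irf)
  expect_lt(abs(f1$a1_pct - f2$a1_pct), 0.02)
})

test_that("component labeling is canonical: tau1 <= tau2 regardless of truth ordering", {
  p_sorted <- biexp_params(70, 30, 0.4, 2.5)
  p_swapped <- biexp_params(30, 70, 2.5, 0.4)
  m1 <- model_decay(p_sorted, gauss_irf, ax256)
  m2 <- model_decay(p_swapped, gauss_irf, ax256)
  expect_equal(m1, m2, tolerance = 1e-12)  # model symmetric in labels
  f <- fit_biexp(decay_histogram(m2 * 20, ax256), gauss_irf)
  expect_lte(f$params$tau1, f$params$tau2)
  expect_identical(canonicalize_biexp(canonicalize_biexp(p_swapped)),
                   canonicalize_biexp(p_swapped))
})

test_that("fitting guards: photon minimum and non-finite input", {
  h <- simulate_decay(biexp_params(60, 40, 0.4, 2.5), gauss_irf, ax256, 100,
                      seed = 1)
  expect_error(fit_biexp(h, gauss_irf), class = "flimredox_insufficient_photons")
  expect_error(decay_histogram(c(NaN, rep(1, 255)), ax256), "finite")
})

test_that("analytic likelihood gradient matches central finite differences", {
  p <- biexp_params(60, 40, 0.4, 2.5)
  y <- simulate_decay(p, gauss_irf, ax256, 5000, seed = 3)$counts
  irf_fft <- stats::fft(irf_curve(gauss_irf, ax256))
  theta <- c(55, 45, 0.45, 2.3, 0.5)
  nll <- function(th) {
    mu <- pmax(th[1] * flimredox:::circ_conv(flimredox:::periodic_shape(th[3], ax256), irf_fft) +
               th[2] * flimredox:::circ_conv(flimredox:::periodic_shape(th[4], ax256), irf_fft) +
               th[5], 1e-12)
    sum(mu - y * log(mu))
  }
  num <- sapply(seq_along(theta), function(j) {
    e <- rep(0, length(theta)); e[j] <- 1e-6 * max(abs(theta[j]), 1)
    (nll(theta + e) - nll(theta - e)) / (2 * e[j])
  })
  mu <- pmax(theta[1] * flimredox:::circ_conv(flimredox:::periodic_shape(theta[3], ax256), irf_fft) +
             theta[2] * flimredox:::circ_conv(flimredox:::periodic_shape(theta[4], ax256), irf_fft) +
             theta[5], 1e-12)
  w <- 1 - y / mu
  d1 <- flimredox:::circ_conv(flimredox:::periodic_shape_dtau(theta[3], ax256), irf_fft)
  d2 <- flimredox:::circ_conv(flimredox:::periodic_shape_dtau(theta[4], ax256), irf_fft)
  ana <- c(sum(w * flimredox:::circ_conv(flimredox:::periodic_shape(theta[3], ax256), irf_fft)),
           sum(w * flimredox:::circ_conv(flimredox:::periodic_shape(theta[4], ax256), irf_fft)),
           theta[1] * sum(w * d1), theta[2] * sum(w * d2), sum(w))
  expect_equal(ana, num, tolerance = 1e-4)
})

test_that("Neyman-weighted least squares option also recovers the truth", {
  p <- biexp_params(60, 40, 0.4, 2.5)
  h <- simulate_decay(p, gauss_irf, ax256, 2e4, seed = 9)
  f <- fit_biexp(h, gauss_irf, fit_options(objective = "neyman"))
  expect_lt(abs(f$a2_pct - 0.4), 0.05)
  expect_lt(abs(f$params$tau2 - 2.5), 0.2)
})
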