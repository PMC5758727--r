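---
title: "Models and methods behind flimredox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flimredox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(flimredox)
```

# The assay

Autofluorescent coenzymes report cellular metabolism: NAD(P)H (the pooled,
spectrally inseparable NADH + NADPH signal) and FAD each exist in a free and
an enzyme-bound form with distinct fluorescence lifetimes, and tryptophan is
quenched by FRET to nearby bound NAD(P)H. A time-correlated single photon
counting (TCSPC) FLIM microscope records, per pixel and per spectral
channel, a histogram of photon arrival times after pulsed excitation. A
two-component exponential fit of that histogram separates the short- and
long-lifetime forms; the intensity-normalized amplitude fractions
$a_1\% = a_1/(a_1+a_2)$ and $a_2\% = 1-a_1\%$ then estimate the *molecular
population shares* independently of brightness.

`flimredox` implements the full analysis chain around three readouts:

* **FLIRR** (fluorescence lifetime redox ratio):
  $\mathrm{FLIRR} = \mathrm{NAD(P)H}\text{-}a_2\% \,/\, \mathrm{FAD}\text{-}a_1\%$,
  the bound-NAD(P)H share over the bound-FAD share. Oxidative phosphorylation
  raises the numerator and lowers the denominator, so FLIRR rises with
  metabolic activity. Because both terms are intensity-normalized, FLIRR is
  robust to channel-wise photon attenuation — the property that makes it
  usable deep in scattering tissue where the classical intensity ratio
  (FAD photons / NAD(P)H photons) is confounded by depth- and
  wavelength-dependent losses.
* **Intensity redox ratio**: FAD/NAD(P)H photon sums on the same ROI
  footprint, provided for cross-validation on thin specimens. Raw sums are
  used; no additional normalization is applied.
* **Tryptophan FRET efficiency**:
  $E\% = \left(1 - \tau_m / \tau_D\right) \times 100$ with
  $\tau_m = \tau_1 a_1\% + \tau_2 a_2\%$ the amplitude-weighted mean
  lifetime of the (partially quenched) tryptophan donor and
  $\tau_D = 3.1$ ns the unquenched single-donor reference (configurable via
  `donor_reference()`). Negative values ($\tau_m > \tau_D$) are returned as
  computed and flagged, never clipped, so miscalibration stays visible.

# The decay model and fitter

## Forward model

For a laser repetition period $P$ (12.5 ns at 80 MHz; `time_axis()`),
lifetimes comparable to $P$ leave residual fluorescence from earlier pulses
("incomplete decay"). Summing each component over all preceding periods has
the closed form

$$ s_j(t) = a_j \, \frac{e^{-t/\tau_j}}{1 - e^{-P/\tau_j}}, \qquad t \in [0, P), $$

which `model_decay()` evaluates on the bin grid, circularly convolves with
the normalized instrument response (IRF), and offsets by a constant
background. Lifetimes at or above $50P$ are rejected as numerically
degenerate. The periodic closed form is verified in the test suite against
an independent brute-force summation over 200 preceding periods followed by
a direct $O(n^2)$ circular convolution, to below $10^{-9}$ relative error.

## IRF

Commercial fitting software hides its IRF handling; an explicit model is
needed here. The default is a Gaussian (center 1.0 ns, FWHM 0.2 ns —
representative of hybrid-detector two-photon systems); a measured per-bin
curve can be supplied instead (`irf_model("measured", curve = ...)`). The
IRF is normalized to unit sum so it redistributes photons without creating
them.

## Objective and optimization

TCSPC counts are Poisson distributed and per-pixel counts are low, so the
default objective is the Poisson negative log-likelihood
$\sum_k \mu_k - y_k \log \mu_k$; Neyman-weighted least squares
($w_k = 1/\max(y_k, 1)$) is available as an option for comparison with
legacy software. Optimization uses L-BFGS-B with analytic gradients
(verified against central finite differences in the tests) under box
constraints — defaults $\tau_1 \in [0.05, 1.5]$ ns,
$\tau_2 \in [0.8, 8]$ ns.

Initialization is deterministic: $\tau_2$ from a log-linear fit to the
record tail (last 40% of bins above the background estimate),
$\tau_1 = \tau_2/5$, amplitudes by linear least squares given the lifetimes,
background from the pre-rise region (then refined as a free parameter by
default). If a fit degenerates — amplitude share below 3% or a lifetime
pinned at a bound — two alternative deterministic lifetime starts are tried
and the best objective kept. This rescues the occasional collapse into a
mono-exponential-plus-background local optimum without introducing
randomness: fits are bit-reproducible and independent of pixel order.

Results are canonicalized to $\tau_1 \le \tau_2$. Fits with
$|\tau_2 - \tau_1| < 0.05$ ns are flagged effectively mono-exponential.
Histograms under 300 photons (configurable) raise an explicit
insufficient-photons error rather than returning a silent fit. Goodness of
fit is the reduced Pearson statistic over bins with expectation of at least
one count, divided by (included bins − free parameters); on Poisson draws
of the true model its mean is ~1, which is also what the full fitter
achieves on simulated data (the calibration target).

### Accuracy limits

Pooled across a truth grid ($a_2\%$ from 0.1 to 0.9, $\tau_1$ 0.3–0.6 ns,
$\tau_2$ 2.0–3.5 ns, $10^4$ photons) the fitter is essentially unbiased
(|bias| < 0.005) with RMSE($a_2\%$) ≈ 0.03. At the extreme fraction
$a_2\% = 0.9$ the minor component carries only ~2% of the photons and the
*per-point* RMSE rises to ~0.06 — an information limit of the data, not of
the implementation: an independent SciPy implementation of the same
likelihood on the same histograms does slightly worse. Interpret per-ROI
fractions near 0 or 1 accordingly.

# The 2×2 ROI assay

ROIs are non-overlapping 2×2-pixel blocks anchored at pixel (0,0) (0-based,
row-major, half-open blocks; a trailing odd row/column is ignored). A block
becomes an ROI iff

1. all four pixels carry the same nonzero cell label (blocks straddling two
   cells or cell/background are dropped entirely, keeping every data point
   attributable to one cell),
2. no pixel is nuclear (nuclear exclusion is applied before thresholding),
3. the *mean* NAD(P)H photon count of the four pixels lies in the closed
   threshold window. The mean of the block was chosen as the thresholding
   statistic because it is robust to single-pixel spikes; whether the
   original plugin thresholds per pixel or per block is not documented.

Two presets run on the same grid: *whole-cell* (default window [30, 5000]
photons) and *mitochondrial*. FAD and tryptophan inherit the
NAD(P)H-defined footprint. The mitochondrial lower threshold must do what
its name says — *isolate mitochondrial morphology*. At the synthetic
brightness scale (cytosol 100, mitochondria 600 expected photons/pixel) the
shipped default of 400 sits between the 2- and 3-mitochondrial-pixel block
means, so selected blocks are at least three-quarters mitochondrial. A
purity diagnostic (`roi_mask_counts()` against the ground-truth
mitochondrial mask) showed that looser thresholds admit blocks dominated by
cytosol, whose partial-volume mixing systematically compresses per-cell
treatment responses; thresholds are configuration (`roi_config()`), to be
re-derived for other brightness scales exactly as one would adjust them per
field of view on real data.

Per-ROI parameters come in two aggregation modes:

* `pooled_refit` (default in the assay driver): the four pixel histograms
  are summed and fitted once — a 4× photon gain, and in simulation the lower
  RMSE option at low counts;
* `pixel_mean`: photon-weighted mean of per-pixel fitted parameters (the
  route available when only vendor-exported parameter maps exist);
  $a_1\%+a_2\%=1$ survives because both fractions share the same weights,
  and $\tau_m$ is recomputed from the aggregated values.

ROIs containing unfitted or non-converged pixels (or whose pooled refit
fails) are flagged invalid and excluded from downstream statistics.

# Cohort analysis

The per-cell statistic is the **median** over that cell's valid ROIs (means
are reported alongside). Cells need at least 5 valid ROIs per condition
(configurable) — fewer and the cell is excluded with a message. Control and
treatment join on (fov, cell): the same field of view is re-imaged, so each
cell is its own control. The response measure is the percent change of the
median, $100(\mathrm{rx}-\mathrm{ctrl})/\mathrm{ctrl}$, computed on the
mitochondrial morphology as the categorization basis.

Responder categories are configurable intervals; the shipped example is
25–55% (low), 55–85% (medium), 85–125% (high). Because adjacent ranges
share endpoints, a deterministic boundary rule is required: intervals are
half-open $[l, u)$ with the last closed, values outside all intervals are
`"uncategorized"` (a value, not an error). An equal-count alternative
(`tertile_scheme()`) mirrors how such boundaries are chosen from data in
practice. Frequency distributions use the same right-open/last-closed
convention.

The FLIRR–E% relationship is summarized by the Pearson correlation of
per-cell medians pooled across conditions, per morphology (a per-ROI
variant would only require passing the record table). Whether such
correlations should pool ROIs or cells is genuinely ambiguous in practice;
cell medians are the default here because the cell is the biological unit
of replication.

**Glycolysis attribution.** NAD(P)H arises from mitochondrial OXPHOS *and*
cytosolic glycolysis while FAD is mitochondrial only, so when a cell's
whole-cell percent change exceeds its mitochondrial change, the increment
is attributed to glycolysis. The call uses a ±5 percentage-point margin
(configurable): above it "glycolysis-responsive", within it
"OXPHOS-driven", below it "mito-dominant".

# The synthetic scene generator

No public dataset accompanies this assay, so validation runs on synthetic
fields of view with closed-form ground truth (`scene_spec()`, `make_fov()`,
`apply_treatment()`). The generator emulates:

* **Geometry** — non-overlapping elliptical cells (default 5 cells on
  256×256 pixels, semi-axes ~11% of the image) with concentric elliptical
  nuclei (45% scale) and mitochondria as stamped disk clusters in the
  cytosol (radius 2.5 px, ~1/3 cytosol coverage). At the ~0.4 µm/pixel
  scale of a 40× two-photon FoV this makes mitochondrial clusters
  micron-sized — deliberately at or above the 2×2-ROI footprint, since an
  ROI assay of mitochondrial morphology presupposes structures it can
  resolve.
* **Brightness** (expected photons/pixel) — NAD(P)H: nucleus 30, cytosol
  100, mitochondria 600 (the ≥5× mitochondrial contrast that makes
  intensity thresholding meaningful); FAD: 15/80/300 — concentrated in
  mitochondria with a weak cytosolic residual rather than strictly zero, so
  whole-cell ROIs keep a defined FLIRR denominator (a strictly-zero FAD
  cytosol remains available through the config); tryptophan: 250 cell-wide.
  The nucleus emits *low but nonzero* NAD(P)H so that only mask-based
  exclusion, not thresholding, can remove it.
* **Decay truths** — per channel $(\tau_1, \tau_2)$ and per-compartment
  bound fraction: NAD(P)H 0.4/2.5 ns with the *long* component bound
  (cytosol 0.20, mitochondria 0.32); FAD 0.3/2.3 ns with the *short*
  component bound (0.60/0.72); tryptophan 1.0/3.1 ns with the short
  (quenched) fraction 0.35. These are synthetic conventions chosen
  order-of-magnitude consistent with the autofluorescence literature, not
  measured values. Each cell jitters its fractions by N(0, 0.02) —
  biological cell-to-cell variation that also gives correlation analyses
  realistic scatter.
* **Photon statistics** — independent Poisson counts per pixel (and per
  time bin when full TCSPC cubes are simulated through the same
  `model_decay()` used by the fitter — photon images are exactly the cube
  sums). Everything is reproducible from the scene seed.
* **Treatment** (`treatment_effect()`) — shifts of the bound fractions
  (defaults: NAD(P)H mito +0.12, cytosol +0.10, FAD mito −0.12, quenched
  tryptophan +0.12), multiplied by one per-cell effect scale drawn from
  N(1, 0.35) truncated at zero — the ground truth for responder
  heterogeneity. Explicit `cell_scales` pin the scales for designed
  cohorts (e.g. the three-strata recovery study uses scales 0.65/1.05/1.45,
  whose true percent FLIRR changes land mid-category of the example
  scheme). Post-shift fractions clip to [0.01, 0.99] with a message.
  Geometry and masks are untouched — the same FoV re-imaged.
* **Depth attenuation** (`attenuate_scene()`) — channel-wise photon loss:
  photon images scale deterministically by the factor (so the intensity
  ratio shifts by exactly that factor), TCSPC cubes are thinned binomially
  (photons are discrete; the decay *shape* is preserved). No scattering
  PSF or spectral modeling — intensity loss is the only depth effect the
  FLIRR-robustness argument needs.

What passing tests on these scenes do **not** show: robustness to real
segmentation errors, spatially varying IRFs, autofluorescent background
structure, detector afterpulsing, or motion — all absent from the
generator. The synthetic validation demonstrates that the *computational
chain* recovers known truth; it cannot certify performance on any
particular microscope.

# Validation studies and problem sizes

The acceptance script (`scripts/acceptance.R`) recomputes, end to end:
chi-square calibration (100 fits at 5,000 photons); the category structure
of a spanning cohort (9 cells, 3 FoVs, truth-map aggregation); grid
recovery of $a_2\%$ (225 fits at $10^4$ photons, statistics pooled across
the grid as discussed above); FLIRR recovery through the full
fit→ROI→metric chain on the default 256×256 scene (~2,500 pooled-refit
ROIs); oracle equivalence for the ROI grid (20 random scenes) and the
periodic model; treatment directionality and ×0.5 FAD-attenuation
robustness (5 cells, 96×96); three-strata recovery over 20 FoVs at
160×160 with 6 cells each (~45 mitochondrial ROIs per cell — chosen so the
per-cell median is stable; real acquisitions carry ~1,000+ ROIs per cell);
and the FLIRR–E% correlation at the 21-cell cohort size. These sizes keep
the whole script in a few minutes on one CPU while leaving each criterion's
decision comfortably outside Monte-Carlo noise.

# Known limitations

* Two components only; no three-component fits, no phasor analysis, no
  image-wide (global) lifetime linking.
* No automatic segmentation: cell and nucleus masks are inputs.
* Equivalence with any commercial fitter is not claimed — only the public
  contract (two components, reduced chi-square ~1) is reproduced; vendor
  weighting, binning, and IRF estimation are proprietary and unstated.
* The intensity redox ratio is reported without background subtraction or
  Chance-style normalization.
* Parameter maps round-trip through 32-bit float TIFF (relative error
  ~1e-7); label masks support up to 255 cells per field.
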