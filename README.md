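# flimredox

Metabolic imaging analysis for three-channel FLIM/TCSPC microscopy in R.

Cancer cells shift the balance between mitochondrial oxidative
phosphorylation (OXPHOS) and cytosolic glycolysis, and they do so
heterogeneously — cell by cell. Fluorescence lifetime imaging (FLIM) of the
autofluorescent coenzymes NAD(P)H and FAD can read this balance out without
labels: the free and enzyme-bound forms of each coenzyme have distinct
lifetimes, and a two-component fit of each pixel's TCSPC photon-arrival
histogram estimates the bound fractions `a1% = a1/(a1+a2)` and
`a2% = 1 − a1%` independently of brightness.

`flimredox` is for microscopists and image analysts who have (or want to
simulate) per-pixel FLIM data and need the full analysis chain:

* **Decay fitting** — periodic ("incomplete decay") bi-exponential model
  convolved with an explicit IRF, fitted by Poisson maximum likelihood with
  analytic gradients (`fit_biexp()`, `fit_cube()`), reduced chi-square ~ 1
  on calibrated data.
* **FLIRR**, the fluorescence lifetime redox ratio
  `NAD(P)H-a2% / FAD-a1%` — rises with oxidative metabolism and, being
  built from intensity-normalized fractions, is insensitive to the
  depth-dependent photon losses that corrupt the classical intensity ratio
  `FAD/NAD(P)H` (also provided) deep in scattering tissue.
* **Tryptophan FRET efficiency** `E% = (1 − τm/3.1 ns) · 100` from
  amplitude-weighted donor lifetime quenching — an independent marker that
  tracks FLIRR as bound NAD(P)H accumulates.
* **2×2-pixel thresholded ROI assay** inside segmented cells
  (`generate_roi_grid()`): whole-cell (minus nucleus) and mitochondrial
  threshold presets on the NAD(P)H photon image separate OXPHOS from
  whole-cell signal; the excess whole-cell response is attributed to
  glycolysis.
* **Responder cohort analysis** — per-cell median FLIRR, percent median
  change from control to treatment on re-imaged fields of view, and
  categorization into low/medium/high responders (example scheme
  25–55 / 55–85 / 85–125 %).
* **Synthetic ground truth** — a scene generator (`make_fov()`,
  `apply_treatment()`) with cell/nucleus/mitochondria compartments, Poisson
  photon statistics and closed-form true FLIRR, so every stage is testable
  without an acquisition.

## Worked example

```r
library(flimredox)

## one decay fit
ax  <- time_axis()                       # 256 bins over a 12.5 ns period (80 MHz)
irf <- irf_model()                       # Gaussian IRF, 0.2 ns FWHM
truth <- biexp_params(a1 = 68, a2 = 32, tau1 = 0.4, tau2 = 2.5)
h <- simulate_decay(truth, irf, ax, total_photons = 5000, seed = 1)
fit_biexp(h, irf)
#> biexp_fit [nadh]: tau1=0.375 ns, tau2=2.339 ns, a1%=0.666, a2%=0.334, tau_m=1.032 ns
#>   photons=4985  chi2_red=0.984  converged=TRUE

## paired control/treatment field of view
spec <- scene_spec(size = 96, n_cells = 4, seed = 7)
control <- make_fov(spec, cubes = TRUE)
treated <- apply_treatment(control, treatment_effect(), seed = 11)
res <- paired_fov_assay(control, treated)
res$assignments
#>   fov_id cell_id ctrl_median rx_median change_pct      category
#> 1      1       1   0.4957410 0.7215434   45.54846     Category1
#> 2      1       2   0.4785323 0.7935806   65.83638     Category2
#> 3      1       3   0.5220857 0.6189189   18.54738 uncategorized
#> 4      1       4   0.4423055 0.5301516   19.86096 uncategorized
```

The fit recovers the simulated truth (a2% 0.334 vs 0.32, lifetimes within
the photon noise at 5,000 counts) with a calibrated chi-square. In the
paired assay, each cell's percent change of its median mitochondrial FLIRR
reflects its own randomly drawn treatment effect: two cells responded
enough to be categorized (low/medium responders); two fell below the 25%
floor of the example scheme. The whole-cell vs mitochondrial comparison is
in `res$attribution`:

```r
res$attribution[, c("cell_id", "change_pct_mito", "change_pct_wc", "call")]
#>   cell_id change_pct_mito change_pct_wc                  call
#> 1       1        45.54846      39.71514         mito-dominant
#> 2       2        65.83638      51.49835         mito-dominant
#> 3       3        18.54738      30.60601 glycolysis-responsive
#> 4       4        19.86096      31.70842 glycolysis-responsive
```

A command-line interface over the same functions (simulate / fit / roi /
metrics / cohort / render / run-all, with a YAML config and a provenance
manifest) ships at `inst/cli/flimredox-cli.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","flimredox-cli.R",package="flimredox"))')" \
    run-all --config config.yaml --out results/
```

See `vignettes/flimredox-methods.Rmd` for the model, the parameter
conventions, the threshold-setting rationale, and what the synthetic
validation does and does not demonstrate.

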