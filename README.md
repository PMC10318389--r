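# burstkin

Transcriptional burst kinetics from single-cell RNA-seq counts, with
capture efficiency modelled rather than ignored.

## The problem

Most genes are transcribed in bursts: the promoter flips between an
inactive and an active state, and mRNA is made only while active. At steady
state the two-state (telegraph) model gives a Beta-Poisson law for the
transcript count of gene *i* in cell *j*,

```
X_ij ~ Poisson(s_j * ksyn_i * p_i),   p_i ~ Beta(kon_i, koff_i),
```

with all rates relative to effective mRNA decay and `s_j` the relative cell
size. scRNA-seq then observes each transcript with a small, cell-specific
capture probability `beta_j` (often around 6%). Binomial thinning of a
Beta-Poisson variable is again Beta-Poisson with the synthesis rate scaled
by `beta_j * s_j` — so the *correct* likelihood for observed counts is

```
x_ij ~ Poisson(beta_j * s_j * ksyn_i * p_i),   p_i ~ Beta(kon_i, koff_i),
```

and estimators that ignore capture (fitting raw counts as if `beta = 1`)
systematically distort burst size, synthesis and switching rates. burstkin
is for anyone estimating per-gene burst kinetics — burst size `ksyn/koff`
and burst frequency `kon` — from allele-specific or total UMI count
matrices, and for anyone benchmarking such estimators.

## What is in the package

* Exact Beta-Poisson machinery (`dbetapois()`, `dbetapois2()`,
  `bp_factorial_moments()`, `dnb_limit()`) via log-space Gauss–Jacobi
  quadrature matched to the Beta kernel.
* Capture handling: `estimate_beta()` (totals normalized to a mean
  efficiency) and `effective_capture()`.
* A synthetic generator with known truth (`simulate_dataset()`,
  `build_benchmark()`, missing-value masks, allele and nonallele modes).
* Four inference routes sharing one tidy output schema:
  capture-corrected and bare method of moments (`infer_moments()`),
  capture-aware maximum likelihood (`infer_mle()`), rejection ABC
  conditioned on the observed capture vector (`infer_abc()`), and a
  deep-ensemble neural regressor trained on simulations
  (`build_training_corpus()`, `train_ensemble()`, `infer_nn()`).
* AIC/WAIC model selection among Beta-Poisson, negative binomial and
  Poisson (`select_model()`, `waic_from_samples()`,
  `run_selection_experiment()`).
* Benchmark metrics and diagnostics (`compute_metrics()`,
  `two_allele_correlation_check()`, `dropout_vs_mean()`), ggplot2 graphics
  (`autoplot()`, `plot_residuals()`, `plot_dropout_curve()`) and
  broom-style `tidy()` / `glance()` methods.
* TSV/CSV/MatrixMarket count matrix IO with missing-value masks
  (`read_counts()`, `write_counts()`, `filter_genes()`) and a thin CLI
  (`inst/cli/burstkin.R`: simulate | estimate-beta | infer | select-model |
  benchmark | diagnose).

## A worked example

Simulate a small benchmark with known kinetics, estimate per-cell capture
efficiencies from totals, and run the capture-corrected moment estimator:

```r
library(burstkin)

pr <- prior_spec()        # log-uniform kinetics; capture mean 0.06, CV 0.5
ds <- simulate_dataset(pr, n_genes = 40, n_cells = 500, seed = 42)
ds
#> Synthetic burst-kinetics dataset: 40 genes x 500 cells (allele mode)
#>   missing entries: 0

bh <- estimate_beta(ds$counts, mean_beta = 0.06)
head(bh, 3)
#> # A tibble: 3 x 3
#>   cell  total   beta
#>   <chr> <dbl>  <dbl>
#> 1 cell1  1195 0.0445
#> 2 cell2  1488 0.0555
#> 3 cell3  2035 0.0759

est <- infer_moments(ds$counts, bh$beta, n_boot = 200, seed = 43)
dplyr::select(est, gene, ksyn, kon, koff, burst_size, ksyn_lo, ksyn_hi, status)
#> # A tibble: 40 x 8   (first rows shown)
#>   gene   ksyn    kon    koff burst_size ksyn_lo ksyn_hi status
#> 1 gene1 2363.  0.349  2.30        1029.   1978.   2830. ok
#> 2 gene2 2889.  0.514  0.0537     53744.   2852.   2925. ok
#> 3 gene3   NA  NA     NA             NA      NA      NA  degenerate
```

`ksyn`, `kon`, `koff` are rates relative to effective decay; `burst_size`
is `ksyn/koff` (mean transcripts per burst); `*_lo`/`*_hi` are bootstrap
95% intervals; `degenerate` marks genes whose moments are consistent with a
simpler (Poisson-like) law, so no finite telegraph parameters exist — for
lowly expressed genes this is the expected outcome, not an error.

With the generating truth in hand, recovery metrics (log10 scale) come from
`compute_metrics()`:

```r
compute_metrics(est, ds$truth)
#> # A tibble: 3 x 8
#>   method parameter     r2   mae    o95  fw95 n_used n_failed
#> 1 MME    ksyn       0.823 0.111 0.190  0.470     21       19
#> 2 MME    kon        0.767 0.263 0.0952 0.791     21       19
#> 3 MME    koff      -0.212 0.599 0.143  1.66      21       19
```

`r2` and `mae` compare log10 estimates to log10 truth, `o95` is the
fraction of truths outside the 95% intervals, `fw95` the mean interval
width in log10. The pattern shown — synthesis and activation rates well
recovered, `koff` poorly identifiable, roughly half the genes degenerate at
these expression levels — is the expected behaviour at 500 cells and 6%
capture. The simulation-based routes (`infer_abc()`, `infer_nn()`) fit all
genes and carry calibrated intervals; see the vignette in
`vignettes/burst-kinetics.Rmd` for the full method descriptions.

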