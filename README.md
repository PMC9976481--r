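# spiralspread

Population spread, behavioural switching and dispersal kernels for groups of
walking insects in long linear-tunnel arenas.

## The problem

Minute parasitoid wasps (*Trichogramma*), released as groups of a few dozen
individuals at the centre of a 6-m tunnel folded into a double spiral, spread
out over hours by walking. Imaging yields anonymous per-minute detections of
individuals along the tunnel, each reduced to a signed linear distance
$x_{it}$ from the release point, and — when host eggs are present — the
positions and fates of those hosts. Questions of interest: how fast does the
population spread, is spread density-dependent, is the position distribution
Gaussian as classical diffusion predicts, and can the spatial distribution of
parasitism (the dispersal kernel) be predicted from movement?

`spiralspread` implements the full analysis chain plus an agent-based
simulator of the inferred movement process, so that every estimator can be
validated by parameter recovery without any external data:

- **geometry** — double-Archimedean-spiral arena construction, orthogonal
  projection of plate coordinates onto the tunnel skeleton (signed arclength),
  host layouts (diffuse: one egg / 5 cm; clumped: six-egg patches / 30 cm;
  120 eggs either way), distance metrics.
- **simulate** — a switching heterogeneous random walk: agents step with
  mode-specific Gaussian increments (slow "resident" vs fast "explorer"
  modes), convert resident → explorer with a hazard increasing in local
  density and boosted by host contact, revert explorer → resident only when
  isolated and without recent host contact, board hosts within the reactive
  distance and parasitise them with constant hazard $1/\tau$ per
  occupant-minute so that $P(\text{parasitised}\mid T) = 1 - e^{-T/\tau}$,
  and are detected each minute with fixed probability.
- **spread statistics** — mean squared displacement
  $\mathrm{MSD}_t = \sum_i x_{it}^2 / N_t$ over ±7-min moving windows pooled
  across replicates, population quantiles of $|x|$ (front positions),
  diffusion coefficients as the OLS slope of MSD on time (first 30 min
  excluded), continuous two-segment changepoint fits with bootstrap
  significance, replicate-level bootstrap percentile CIs, pairwise Wilcoxon
  rank tests with Benjamini–Hochberg correction.
- **distribution fits** — zero-mean Gaussian mixtures by EM (all component
  means fixed at 0), centred Student-t fits, AIC model selection among
  {Gaussian, 2- and 3-component mixture, Student}, excess-kurtosis and QQ
  Gaussianity diagnostics, and a time-resolved decomposition of the
  population into resident and explorer components (proportion and
  component-wise MSD every 15 min).
- **parasitism** — binned dispersal kernel and its Gaussian fit, dispersal
  coefficient $\sigma$ (RMS distance from the release point to parasitised
  hosts), host discovery times, posterior assignment of each parasitised host
  to an explorer or resident discoverer, the saturating parasitism gain
  function, and Spearman correlations between replicate-level movement and
  parasitism metrics.

All user-facing functions take a data frame first and return tibbles; fitted
objects have broom-style `tidy()` / `glance()` methods and ggplot2
`autoplot()` methods.

## Worked example

```r
library(spiralspread)
library(dplyr)

# simulate the high-density treatment (70 ± 10 wasps, no hosts, 8 h)
sim <- simulate_experiment("high", n_replicates = 20, seed = 1)
set.seed(1)
obs <- thin_detections(sim$detections, 0.33)   # 33% per-minute detection

msd <- compute_msd(obs, window = 7)
fit_piecewise(msd, t_min = 30, B = 200, grid_by = 4, data = obs)
#> <diffusion_fit> over t in [30, 480] min, n = 451
#>   breakpoint at t = 297 min (p = 0.00995)
#>   D before = 20.58, after = 14.54 cm2/min

# positions are leptokurtic and decompose into two centred Gaussians
x400 <- obs$s[obs$t == 400]
select_model(x400)
#> <model_selection> n = 453, winner: gmix2
#>     model k_params    loglik      aic delta_aic
#>     gmix2        3 -2643.163 5292.325  0.000000
#>   student        2 -2644.734 5293.469  1.143726
#>     gmix3        5 -2643.163 5296.325  4.000001
#>  gaussian        1 -2649.649 5301.298  8.972484
```

The changepoint fit says the high-density group spread fast
(20.6 cm²/min) for ~5 h and then slowed to 14.5 cm²/min — the transient
density boost collapsing, while the low-density preset stays linear. The AIC
table says the position distribution at t = 400 min is best described by a
two-component zero-mean Gaussian mixture (a narrow "resident" and a broad
"explorer" component), not by a single Gaussian.

With hosts, the same pipeline adds the dispersal kernel and gain function:

```r
simh <- simulate_experiment("high_diffuse", n_replicates = 20, seed = 1)
k <- dispersal_kernel(simh$hosts)
glance(k)[, c("sigma_dispersal", "gaussian_r2")]
#>   sigma_dispersal gaussian_r2
#> 1        111.2026   0.9840383
```

(Exact numbers vary with the seed; the ones above were produced by the code
shown.)

## Further reading

The methods vignette (`vignettes/spiralspread-methods.Rmd`) describes the
movement model, the estimators, every tunable parameter with its default and
rationale, and known limitations.
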