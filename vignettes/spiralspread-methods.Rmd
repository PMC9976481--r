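---
title: "Models and methods behind spiralspread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spiralspread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`spiralspread` analyses the spatial spread of groups of minute walking
insects released at the centre of a long linear tunnel, and the parasitism
patterns they produce when host eggs line the tunnel. This vignette explains
the models the package implements, the choices made where the design was
genuinely open, and what the built-in simulator does and does not emulate.

## The arena and the linear coordinate

The physical arena is a tunnel of total length $L$ (default 630 cm, 1 cm
wide) folded into an interleaved double Archimedean spiral so that it fits a
60 × 40 cm plate. `build_spiral()` parameterises each arm as $r = b\theta$
with $b$ set by the channel pitch (channel width + wall thickness between
adjacent channels; wall default 0.85 cm, chosen so the default 630 cm arena
fits the plate with margin). Only the arclength structure matters downstream:
all analyses work on the signed arclength $s$ from the central release point
(negative on the left arm). `project_to_skeleton()` maps plate coordinates to
$s$ by nearest-vertex search on the polyline resampled at 0.1 cm, which
bounds the projection error well below the 0.5 cm tolerance the analyses
assume; ties between the two arms are broken by smaller offset, then smaller
$|s|$.

Host layouts are symmetric about the release point: *diffuse* places one egg
every 5 cm starting 2.5 cm from the centre; *clumped* places six co-located
eggs every 30 cm starting 15 cm from the centre. The placement cutoff is
fixed at 300 cm so both modalities contain exactly 120 eggs and therefore the
same mean host density; run to the tunnel tips the layout rules alone would
give unequal counts (126 vs 132), so the cutoff resolves a boundary
ambiguity.

## The switching movement model (simulator)

The simulator is an agent-based discrete-time random walk at the observation
cadence (1-min steps; sub-minute behaviour is unidentifiable from per-minute
detections). Each agent is in one of two behavioural modes with mode-specific
step standard deviations: *resident* ($\sigma_r$, default 0.5 cm min^-1/2)
or *explorer* ($\sigma_e$, default 7 cm min^-1/2). Boundaries at the tunnel
tips reflect. Agents all start resident (with an option for a nonzero initial
explorer fraction), scattered uniformly over 10 cm around the centre, and
switching is suppressed during a 25-min latency phase after release.

Transitions:

* resident → explorer with per-minute hazard
  $h_{re} = a + c\,n_{5} + b\,[\text{host contact} \le 30\ \text{min ago}]$,
  where $n_5$ is the number of neighbours within the 5 cm perception radius.
  Defaults $a = 1.5\times10^{-3}$, $c = 3\times10^{-4}$, $b = 10^{-2}$.
* explorer → resident with hazard $h_{er} = 10^{-2}$, applied only when the
  agent is locally isolated (fewer than 3 neighbours within 5 cm) *and* has
  had no host contact within the 30-min memory window.

This architecture makes the density dependence self-limiting: a dense release
converts quickly to explorers, the explorers dilute themselves in space, lose
their neighbours and revert — the transient "tortoise–hare" acceleration.
The non-density baseline $a$ sustains a slower, steady conversion at low
density, and host contact both accelerates conversion and vetoes reversion,
which is what sustains the elevated spread in host treatments. The hazard
values are not measurable directly from per-minute data; they were chosen
once so that the four default treatments reproduce the qualitative dynamics
the analysis chain is designed to detect (an early high-density advantage, a
high-density slowdown around 4–5 h, sustained spread with hosts, and
explorer fractions in the 0.3–0.95 range) and are fixed thereafter.

Host interaction: an agent passing within the reactive distance (0.4 cm) of
an egg boards it, stops moving, and leaves with probability 0.2 per minute
(mean visit 5 min, a typical host-processing time). After leaving, a 15-min
refractory period suppresses boarding (post-oviposition handling and
travel); crucially the refractory — like every other visiting rule — is
independent of the host's parasitism status, so the per-occupant-minute
parasitism hazard $1/\tau$ (default $\tau$ = 60 min) yields exactly
$P(\text{parasitised} \mid T) = 1 - e^{-T/\tau}$ for cumulated visit time
$T$: a concave gain function saturating near 1 at $T \approx 200$ min.
Detection is an independent Bernoulli thinning (default 33% per
agent-minute) with no spatial bias.

What the simulator does *not* emulate: within-channel 2-D movement and wall
climbing, flight bouts, egg-load dynamics, superparasitism, host-quality
variation, kairomone-mediated attraction to patches, and any persistent
inter-individual differences (all heterogeneity is behavioural and
dynamic). Consequently, passing recovery tests shows the estimators are
correct for this class of switching-diffusion data, not that real data obey
the model. One known consequence: because patches are not attractive at a
distance, the clumped layout (first patch 15 cm out) intercepts far fewer
agent-minutes than the diffuse layout, and simulated clumped parasitism
(~7%) falls well below diffuse (~40%), whereas the two were comparable in
the real experiments. Analyses that compare modalities should treat the
clumped preset as a structurally sparser encounter process, not a calibrated
replica.

## Spread statistics

The mean squared displacement at minute $t$ is
$\mathrm{MSD}_t = \sum_{i=1}^{N_t} x_{it}^2 / N_t$ over all detections
pooled in a ±7-min moving window across replicates; pooling weights each
replicate by its detection count automatically. Windows with no detections
are missing values, never zeros. Population quantiles are empirical
percentiles of $|x|$ (linear interpolation) over the same windows — the
distance containing a given percentage of detected individuals.

The diffusion coefficient $D$ is the OLS slope of MSD on time with the first
30 min excluded (initial conditions and latency), reported in cm² min⁻¹ and
m² h⁻¹ (× 0.006). This mirrors the operational definition used for such
arenas — the raw slope, without the factor-2 convention of 1-D diffusion
theory.

`fit_piecewise()` fits a continuous two-segment line with the breakpoint
found by grid search over interior observed times (5% edge margins;
edge-adjacent optima are flagged unreliable). Significance against the
single-line null uses either

* a residual bootstrap of the relative RSS improvement — appropriate for a
  plain series with approximately independent noise, or
* a replicate bootstrap (when the underlying detections are supplied):
  whole replicates are resampled, the windowed MSD series and the two-segment
  fit recomputed, and the two-sided percentile test asks whether the slope
  change $D_\text{after} - D_\text{before}$ excludes zero. This is the
  appropriate test for pooled multi-replicate series, whose moving-window
  noise is smooth and autocorrelated (a residual bootstrap there is wildly
  anticonservative).

Bootstrap confidence intervals always resample whole replicates (B = 2000 by
default), never individual detections, which are autocorrelated within a
replicate. Between-treatment comparisons use pairwise Wilcoxon tests on
per-replicate statistics with Benjamini–Hochberg correction; since
treatments are unpaired replicate sets, the rank-sum (Mann–Whitney) form is
used.

## Position-distribution models

Classical diffusion predicts centred Gaussian positions. The package fits,
by maximum likelihood on positions pooled with *no* time window (to avoid
pseudoreplication), four candidate centred families: the Gaussian, zero-mean
Gaussian mixtures with 2 or 3 components, and the zero-location Student t
(the many-component scale-mixture limit). AIC parameter counts are 1, 3, 5
and 2 respectively (all means fixed at zero; mixtures have $2K-1$ free
parameters).

The mixture EM fixes every component mean at 0 and updates weights and
scales; scales are initialised at $\{0.5, 2\}\times$ the sample SD with
seeded multiplicative jitter over 5 multi-starts, convergence at a
log-likelihood gain below $10^{-8}$ or 500 iterations. Components are sorted
by scale; the narrow component is interpreted as the *resident* mode and the
broad one as the *explorer* mode. Fits whose scales differ by less than 10%
are flagged effectively unimodal (weights then barely identifiable), and
collapsed scales or vanishing weights are flagged degenerate. The Student
fit optimises (log scale, log df) with the df capped at 1000, the Gaussian
limit.

Leptokurtosis is quantified as excess kurtosis about zero,
$m_4/m_2^2 - 3$ with moments taken about the release point, plus decile
deviations from the fitted centred Gaussian. A 50/50 scale mixture of
variances $v_1, v_2$ has closed-form excess kurtosis
$3\,\mathbb{E}[v^2]/\mathbb{E}[v]^2 - 3$ (≈ 2.88 for variances 25 and
2500), which anchors the diagnostic's unit tests. The per-replicate
normalisation option rescales each replicate to unit variance before
pooling: replicate-level variance heterogeneity then loses its kurtosis
while a genuine within-replicate mixture stays leptokurtic.

`track_components()` applies the K = 2 fit every 15 min to 10-min windows,
giving the explorer proportion $\pi_e(t)$ and scales $\sigma_r(t),
\sigma_e(t)$; the explorer-component MSD is $\sigma_e^2(t)$, the natural
component analogue of the pooled MSD for a centred component. Estimates
before 60 min are flagged unreliable (the distribution is still close to
Gaussian then, so the decomposition is weakly identified). Replicate
bootstrap CIs (B = 600) warm-start the EM at the point estimate. Note that
the decomposition is positional: an agent that reverted far from the centre
continues to be attributed mostly to the broad component, so $\pi_e(t)$
estimates the *distributional* explorer share, which can exceed the share of
agents currently in explorer mode.

## From movement to parasitism

The dispersal kernel bins hosts by signed position (30-cm bins, the clumped
patch spacing) and computes the parasitised fraction per bin; a centred
Gaussian $A e^{-s^2/2\sigma^2}$ is least-squares fitted to the binned
fractions. The dispersal coefficient `sigma_dispersal` is the RMS distance
of parasitised hosts from the release point, i.e. the SD of the kernel taken
about its centre (for hosts at ±80 cm it is 80, as the release-point-centred
definition requires).

Each discovered host is assigned a discoverer type from the component
trajectory: with $\phi$ the centred Gaussian density,
$$p_e(s, t) = \frac{\pi_e(t)\,\phi(s;\sigma_e(t))}
{\pi_e(t)\,\phi(s;\sigma_e(t)) + (1-\pi_e(t))\,\phi(s;\sigma_r(t))},$$
interpolated linearly between grid times; the label is *explorer* when
$p_e > 0.5$, and hosts discovered before the 60-min reliability time (or
where the mixture is degenerate) stay unassigned. "Immediate proximity" to a
host, for on-host spatial profiles, means within the 0.4 cm reactive
distance along the linear coordinate. Smoothed trends (discovery times,
on-host fractions, gain curve) use loess as a generic local smoother — only
the trend is used downstream, so the smoother class is immaterial.

The gain curve bins hosts by total visit time with exact binomial CIs and
fits $p(T) = a(1 - e^{-T/\tau})$ by binomial maximum likelihood, providing
the saturation diagnostic (fitted asymptote and the value at 200 min).
Replicate-level analyses correlate the 98% population front at the end of
the run, the fraction of hosts parasitised, and the dispersal coefficient,
with Spearman rank correlations (reported as $\rho^2$).

## Numerical choices and problem sizes

Quantiles use R's default linear-interpolation convention; EM ties and
degeneracies are flagged rather than silently dropped; the breakpoint grid
is snapped to observed times so noiseless changepoints are recovered
exactly; bootstrap p-values use the add-one convention $(1 + \#\{\ge
\text{obs}\})/(B+1)$.

The test-suite simulations are sized to validate each estimator in minutes
on a single core: diffusion recovery uses 20 replicates × 70 agents × 480
min, mixture model selection uses 50 trials at n = 4000, changepoint power
uses 20 noisy series at B = 200, and the end-to-end four-treatment
reproduction runs the full 20/20/20/22-replicate design once at a fixed
seed. The acceptance script re-runs the full design from scratch and writes
every headline quantity it computes.

## Known limitations

* The simulator's behavioural hazards are phenomenological; only their
  qualitative consequences (density dependence, transiency, host
  sustainment) are constrained.
* Clumped-layout parasitism is structurally lower than diffuse (no patch
  attraction), unlike the comparable rates observed in real arenas.
* The positional resident/explorer decomposition conflates current mode with
  movement history at late times (see above); discoverer assignment
  therefore measures distributional attribution, validated at ≥ 80% accuracy
  against ground truth only for well-separated scales.
* Published diffusion coefficients for such arenas are sometimes quoted in
  units inconsistent with the corresponding final MSD by orders of
  magnitude; the package always reports both cm² min⁻¹ and m² h⁻¹ and makes
  no attempt to match any particular printed absolute value.
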