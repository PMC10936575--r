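---
title: "Counterfactual attribution of avoided wildfire impacts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual attribution of avoided wildfire impacts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firefar)
```

## The attribution model

`firefar` treats fuel-treatment effectiveness as an event-attribution
problem. The event of interest is "final fire size exceeds a threshold
*s*". Two worlds are compared: a reference landscape with exceedance
probability $p_0(s)$ and a comparison landscape with $p_1(s)$. The
package computes, across the whole range of thresholds,

$$\mathrm{FAR}(s) = 1 - \frac{p_0(s)}{p_1(s)}, \qquad
  \mathrm{RR}(s) = \frac{p_1(s)}{p_0(s)},$$

the fraction of attributable risk and the relative risk. The two are
linked by $\mathrm{FAR} = 1 - 1/\mathrm{RR}$ wherever both are finite, an
identity the test suite checks at machine precision.

The framing is symmetric in time. In a retrospective reanalysis the
factual landscape (with its real history of treatment and prior fire) is
the reference $p_0$ and the counterfactual untreated landscape is $p_1$;
attribution then measures avoided impact. In a prospective evaluation of
hypothetical treatments the roles reverse: the treated landscape becomes
$p_0$ and the present untreated landscape $p_1$, and the same statistics
read as attributable benefit. Because both conventions are legitimate and
produce reciprocal RR values, the package **never infers direction**: every
entry point (`scenario_pair()`, the CLI `--direction` flag) requires the
caller to declare which ensemble plays $p_0$, and the declaration is
stored verbatim in every report.

### Assumptions

- Each ensemble is an i.i.d. sample of final fire sizes from its
  scenario's event distribution. For paired replay experiments the
  replicates on the two landscapes may in reality share stochastic inputs
  (e.g. the same spot-fire draws); the bundled Las Conchas fixture carries
  no pairing information, so the two ensembles are treated as independent
  samples. This only affects the bootstrap (which resamples the two
  ensembles independently), not the point curves.
- Fire sizes are strictly positive, finite, and measured in hectares
  throughout. There is no unit-conversion layer.

## Exceedance estimation

Each ensemble's size distribution is estimated with a Gaussian kernel
density and integrated into an exceedance curve; an exact counting
estimator runs alongside as an oracle.

**Bandwidth.** Default is Scott's rule, $\hat\sigma\, n^{-1/5}$ with
$\hat\sigma$ the sample standard deviation — the common default for
univariate Gaussian KDEs. Silverman's rule (`stats::bw.nrd0`) and explicit
numeric bandwidths (ha) are accepted wherever a bandwidth is taken. For
the 10-member Las Conchas ensembles the two rules differ by a few percent
of the bandwidth; the package's own checks use ±3% tolerances on event
sizes precisely to absorb this rule ambiguity.

**Grid.** All curves of one analysis share a single grid of 512 equally
spaced sizes spanning the pooled sample range padded by 3 bandwidths on
each side (≥ 99.7% of each edge kernel's mass) and floored at 0. Using one
grid makes FAR and RR pointwise well-defined; 512 points keeps
interpolation error on event sizes far below the sampling noise of small
ensembles.

**Truncation.** Kernel mass that falls below size 0 (or beyond the padded
grid) is removed by truncation and the density renormalised to unit
trapezoidal integral on the grid. For the bundled data the sample minimum
sits roughly 30 bandwidths above zero, so the correction is negligible —
but it is deterministic, which boundary reflection would also be and
adaptive schemes would not. Renormalisation guarantees the exceedance
curve starts at 1 at the grid's lower end.

**Integration.** Exceedance is the composite-trapezoid integral of the
density from each grid point to the grid maximum, clamped to [0, 1]. The
fixed-grid trapezoid is grid-exact, reproducible and monotone by
construction; adaptive quadrature would buy nothing at 512 points.

**Convention.** Exceedance is strict, $P(X > s)$. For the continuous KDE
this is immaterial; the empirical estimator adopts the same convention so
the two pathways are comparable, and a threshold equal to a sample value
excludes that value from the count.

**Degenerate inputs.** Zero-variance ensembles are rejected by name at
grid construction and density estimation (no bandwidth rule is defined for
them); ensembles with fewer than two sizes are rejected at construction.

## Curve statistics

**Percentile events.** The s-th percentile event size inverts the
exceedance curve at $1 - s$ by monotone linear interpolation; targets
outside the curve's attainable range raise an error that states the range.

**FAR crossings.** FAR curves need not be monotone, so the size at which
FAR "reaches" a level is defined as the *first attainment scanning upward
in size*, linearly interpolated between the bracketing grid points; an
exact grid-point hit returns that point.

**Numerical floor.** Ratios are flagged, never thrown, so curves stay
total: where $p_1 \le 10^{-12}$ FAR and RR are `NA` (undefined); where
only $p_0 \le 10^{-12}$, RR is `Inf`. The floor separates true zeros of
the counting estimator from KDE tail dust; $10^{-12}$ sits far below any
probability resolvable from the ensemble sizes involved yet far above
double-precision noise. In JSON reports `NA` serializes as `null` and
infinities as the explicit strings `"Inf"`/`"-Inf"`, restored on read.

**Bootstrap.** Uncertainty bands are nonparametric: the ensemble members
(not KDE draws) are resampled with replacement, independently per
ensemble; the full curve is recomputed per replicate with the same rule
and the same fixed grid; pointwise percentile intervals are taken at the
requested coverage (default 95%, 1,000 replicates). The seed is mandatory
— identical seeds give identical bands. Grid points undefined in more than
half the replicates get an unavailable (`NA`) band. For 10-member
ensembles this is the simplest defensible uncertainty statement; it
ignores any real pairing between the two ensembles (see Assumptions).

**RR scale.** RR is reported on the natural scale; the RR plot offers a
log axis because RR typically spans orders of magnitude across the upper
tail, where linear axes hide the structure.

## The synthetic ensemble generator

The simulator exists to make the attribution pipeline testable end to end,
not to predict fires. It is a discrete-time percolation model on a raster
landscape: each burning cell attempts once to ignite each of its four edge
neighbours; the attempt succeeds with the spread probability of the
*target* cell's fuel state (treatment slows fire entering treated fuel),
multiplied by a per-fire weather factor; burned cells never reburn.
A 4-neighbour bond-percolation model is the simplest spread process with a
percolation threshold, which is exactly what makes treatment effects on
*extreme* sizes realisable: shifting the effective spread probability
across the threshold converts landscape-spanning fires into contained
ones.

Default parameters, all overridable:

| parameter | default | meaning |
|---|---|---|
| grid | 64 × 64 cells, 10 ha/cell | toy landscape, runs in seconds |
| `p_spread_untreated` | 0.35 | per-neighbour ignition probability into untreated fuel; subcritical at median weather (the bond-percolation threshold on the square lattice is 1/2) |
| `treatment_multiplier` | 0.3 | factor on spread probability into treated cells |
| `weather_sigma` | 0.5 | SD of log of a per-fire lognormal (median-1) weather multiplier; pushes roughly the windiest quarter of fires supercritical, producing a heavy upper tail |
| `max_steps` | 10,000 | hard iteration cap |

The weather multiplier is drawn once per fire and shared across scenarios
at the same fire index (common random numbers), emulating between-event
weather variability in large-fire simulation systems; its lognormal form
is a stand-in, as no distributional detail is available for the systems it
imitates. Ignition sites are likewise shared. Spread randomness is shared
through pre-drawn *edge uniforms*: each directed cell-to-neighbour attempt
happens at most once per fire, so one uniform per (cell, direction) fully
determines a fire given the landscape. Reusing that matrix across
scenarios yields a monotone coupling — adding treatment can only shrink
the burned set of the same fire — which maximises paired power and makes
ordering properties exact rather than statistical.

What the generator does **not** emulate: real fuel heterogeneity and
continuity, spread physics (Rothermel-type behaviour), spotting,
suppression, weather evolution within a fire, and spatially optimised
treatment placement. Consequently, pipeline tests built on it demonstrate
that the statistics behave correctly on data with the right *structure*
(paired scenarios, one stochastically dominating the other, heavy upper
tails), not that any real landscape has a particular FAR.

## Problem sizes used by the checks

The package's tests run the Las Conchas analysis at its native size
(10 + 10 members, 512-point grid), KDE-versus-oracle convergence and
lognormal risk-recovery at 10,000 synthetic draws, bootstrap comparisons
at 120–150 replicates on 10- and 1,000-member ensembles, and the
treatment-extent experiment at 2,000 fires per scenario on the default
64 × 64 landscape — sizes at which every statistic involved is stable yet
the whole suite completes in well under a minute.

## Known limitations

- Ten-member ensembles are at the lower edge of what a KDE can smooth;
  bandwidth-rule choice moves event sizes by a few percent, which is why
  event-size checks carry ±3% tolerances. Users with larger ensembles
  should expect far tighter agreement between the KDE and counting
  pathways.
- The bootstrap understates uncertainty if the two ensembles are actually
  paired, and percentile intervals on 10 members are rough.
- No parametric tail modelling (GEV/GPD) is provided; beyond the largest
  simulated size the KDE tail is pure kernel shape and RR values there
  should not be over-read.
- The scalar "FAR of a scenario" is not well-defined without a threshold;
  reports therefore expose FAR at user-specified sizes, percentile events
  and level crossings rather than one number per scenario.
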