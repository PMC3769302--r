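---
title: "Assessing global change risk to forest carbon stocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing global change risk to forest carbon stocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbonrisk)
library(dplyr)
```

## The problem and the model

National forest inventories report, for each of the five UNFCCC forest
ecosystem carbon pools — live aboveground biomass, live belowground biomass,
dead wood, forest floor and soil organic carbon — a total stock (Tg) and a
network of plot-level carbon density estimates (Mg ha⁻¹). The question this
package addresses is how to *screen* those pools for global-change risk at
continental scale: which pools deserve only periodic monitoring, and which
warrant active adaptation or mitigation planning?

carbonrisk implements a risk-matrix framework in which risk is the
combination of

* **consequence** — the size of the pool's national stock \(S_p\) (Tg): the
  magnitude of carbon that could move from sink to source; and
* **likelihood** — the pool's variability across climate zones, measured as
  the coefficient of variation of per-zone median densities,

\[
\mathrm{CV}_p \;=\; 100 \cdot \frac{s(m_{p1},\dots,m_{pk})}{\bar m_p},
\]

where \(m_{pz}\) is the median density of pool \(p\) among the plots in
Koeppen-Geiger climate zone \(z\), \(\bar m_p\) the arithmetic mean of those
zone medians and \(s\) the sample standard deviation (n − 1 denominator).
The rationale: if a location's climate shifts from one zone to another, the
contemporary spread of median densities *between* zones indicates how much
that pool's stock could plausibly change; a pool whose density differs
little across climates is insensitive to zone reshuffling, whatever its
within-zone scatter.

Three numerical conventions matter and are fixed throughout:

* the zone medians enter the CV **unweighted** — one entry per zone,
  regardless of how many plots or hectares the zone holds;
* the standard deviation uses the sample (n − 1) denominator;
* medians use the conventional mean-of-central-order-statistics rule for
  even counts.

The first two are not cosmetic: an area-weighted or population-SD variant
produces visibly different likelihood values (e.g. ~39% instead of ~43% for
live aboveground biomass on the bundled US tables), and the defaults here
are the ones that reproduce the published US national assessment from its
printed zone medians (see `us_zone_medians_2010()` and the package tests).

## Projecting to 2100

Two projections give the future epoch of the matrix.

**Stocks.** `project_stocks()` fits, per pool, an ordinary least-squares
line through the annual national stock series (the 1990-present greenhouse
gas inventory reporting period) and extrapolates to the target year
(default 2100). Years are centred on the first series year, so the
intercept is the fitted stock in that reference year. This is a
deliberately parsimonious baseline — it ignores sink saturation,
disturbance and land-use change, and a declining series can legitimately
project negative (flagged with a warning, not an error).

**Likelihood.** `project_cv_future()` re-computes the across-zone CV after
a *zone-shift imputation* (`impute_future_densities()`): every plot whose
projected future zone differs from its current zone is assigned, for every
pool, the **current** median density of its future zone; unchanged plots
keep their empirical densities. Zone medians are then re-grouped by the
future zone assignment and the same CV statistic applied. The embedded
assumption is that today's climates persist in 2100 but at different
locations, so future variability is driven entirely by the contemporary
distribution of densities among climates.

Two guarantees pin this pipeline down, and both are enforced by tests:

* **no-shift fixed point** — if no plot changes zone, the future CV is
  *identical* (to the bit) to the current CV;
* **value provenance** — every density in the imputed table is either the
  plot's original value or a current zone median; the imputation can never
  invent a value.

A future zone that has plots but no complete set of current medians (an
"orphan" zone) cannot be imputed; the default policy is an error listing
the zones, with an opt-in `policy = "drop"` that removes the affected plots
and reports the count. The future median of a zone pools empirical and
imputed values with equal weight; no alternative mixing rule is offered
because none is obviously better at this level of abstraction.

## The response grid

`classify_risk()` bins each pool's (CV, stock) point into a grid of
societal-response categories, ordered by proactivity:

`periodically_monitor` < `annually_monitor_develop_strategies` <
`initiate_adaptation_mitigation` < `robust_mitigation`.

Published presentations of such matrices draw the grid without numeric
thresholds, so the default grid here is a calibration choice: the *minimal*
grid consistent with the categorical statements of the published 2010 US
assessment — one likelihood break at a CV of 60% and one consequence break
at 10,000 Tg, with low-stock pools assigned to periodic monitoring at any
CV, and high-stock pools split between annual monitoring (CV < 60) and
initiating adaptation/mitigation (CV ≥ 60). Under it, soil organic carbon
(17,572 Tg, CV 70.9) falls in `initiate_adaptation_mitigation`, live
aboveground biomass (14,541 Tg, CV 43.1) in
`annually_monitor_develop_strategies`, and the three smaller pools in
`periodically_monitor` — exactly the published assignments.
`robust_mitigation` is reachable only through user-supplied finer grids
(`response_grid()` or a YAML config via `read_grid_config()`).

Conventions: bins are left-closed (a point exactly on a break falls in the
upper, more proactive bin); the label matrix must be non-decreasing in
proactivity along both axes, which the constructor enforces and which makes
category rank monotone in (stock, CV). `assess_risk()` adds the 2010→2100
trajectory per pool (Δstock, ΔCV) and flags a pool as moving "more
proactive" when its category rank did not fall and neither delta is
negative.

## What the synthetic generator emulates — and what it does not

The paper-scale inputs (125,000 real plots, the EPA annual series) are not
redistributable, so `generate_plot_table()` and `generate_stock_series()`
produce synthetic inputs with the statistical structure the analysis
relies on:

* **Plot network.** `n_plots` systematically-sampled plots, each
  representing 2,428 ha (the US network's expansion factor). Default zone
  weights (2% equatorial, 8% arid, 34% warm temperate fully humid, 6% warm
  temperate summer dry, 40% snow fully humid, 10% snow summer dry) are a
  plausible allocation of conterminous-US forest plots across the six main
  Koeppen-Geiger groups; they affect only cell sample sizes, not the
  medians being estimated.
* **Densities.** Log-normal per pool and zone, parameterised by the
  *median*: log-location = log of the configured zone median (defaults:
  the published 2010 medians), log-scale σ per pool. Median
  parameterisation makes the published median table the direct calibration
  input. Defaults σ = 1.0 for live aboveground, live belowground and dead
  wood, and σ = 0.6 for forest floor and soil: a log-normal has SD > mean
  exactly when σ > √(ln 2) ≈ 0.8326, and the published national univariate
  statistics show SD > mean for the first three pools and SD < mean for
  the last two. No plot-level dispersion per zone is published, so σ is a
  calibration choice, not a measured value. Pools are drawn independently
  per plot (no published cross-pool correlation structure to emulate).
* **Zone shifts.** The future zone is drawn per plot from a
  zone-transition matrix. The default, `warming_transition(0.5)`, moves
  each plot to its warmer/drier analog zone with probability one half —
  the magnitude used in published illustrations of strong-forcing
  scenarios; identity and custom matrices are one argument away.
* **Stock series.** Linear trend plus Gaussian noise per pool over
  1990–2010. Defaults anchor the 2010 value at the published 2010 totals,
  set the slope so an OLS projection at 2100 lands on the published 2100
  totals, and add noise with SD equal to 1% of the 2010 total — a
  "near-linear" series like the inventory one.

Determinism: one stream seeded from `seed`; zones are drawn first, then
pool densities sequentially in canonical pool order, so appending a pool
leaves earlier pools' draws unchanged, and identical configs give
byte-identical CSV output.

What the generator deliberately does **not** model: spatial coordinates and
spatial autocorrelation, stratified variance-reduction estimation, per-tree
allometry, cross-pool correlation, disturbance events, and non-linear stock
dynamics. Passing tests therefore demonstrate that the *pipeline* is
correct and well-calibrated on data with the assumed distributional shape —
not that real forest carbon behaves log-normally within zones or linearly
over a century.

## Problem sizes and calibration checks

Desk-scale defaults are used throughout: 5,000 plots for examples, 50,000
for calibration checks (the tests and the acceptance script), with the full
125,000 supported. Parameter-recovery checks draw the 50,000 plots with
*balanced* zone allocation (one sixth per zone) rather than the realistic
unbalanced default: recovery of every (pool, zone) median within 5% is a
statement about estimator calibration, and a balanced design gives every
cell the same ~8,300 plots and hence the same precision (relative standard
error of a log-normal sample median ≈ 1.2533·σ/√n ≈ 1.4% at σ = 1), instead
of letting the verdict hinge on the random occupancy of a 2% zone.

## Reproducing a published-style national assessment

The bundled reference tables let the whole matrix be built from literal
published values, bypassing plot-level computation:

```{r national}
res <- run_assessment(
  stocks_current = us_stocks_2010(),
  stocks_future  = us_stocks_2100(),
  cv_current     = us_cv_2010(),
  cv_future      = us_cv_2100(),
  epochs = c("2010", "2100")
)
res$assessment |>
  select(pool, epoch, stock_tg, cv_pct, category, d_stock_tg, d_cv_pct)
```

And end-to-end on synthetic data:

```{r synthetic}
cfg <- sim_config(n_plots = 5000, seed = 42)
res <- run_assessment(
  plots = generate_plot_table(cfg),
  series = generate_stock_series(cfg),
  epochs = c("2010", "2100")
)
res$assessment |> filter(epoch == "2100") |>
  select(pool, stock_tg, cv_pct, category, more_proactive)
```

```{r figure, fig.width = 7, fig.height = 4.5}
plot_risk_matrix(res$assessment, res$grid)
```

## Known limitations

* The CV-of-zone-medians likelihood is a screening statistic, not a
  probability; coarse future climate rasters can deflate it, and pools
  whose densities are partly modelled (rather than measured) can understate
  disturbance-driven variation.
* Linear stock extrapolation over 90 years is an upper-bound bookkeeping
  device, not a forecast, particularly for soil organic carbon.
* The default response grid is calibrated to one published national
  assessment; any operational use should supply thresholds negotiated for
  its own scale and stakeholders.
* No uncertainty is propagated onto the CV or the projections; the
  framework compares point estimates.
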