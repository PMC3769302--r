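# carbonrisk

Risk screening for forest carbon stocks under global change.

National forest inventories track five UNFCCC carbon pools — live
aboveground biomass, live belowground biomass, dead wood, forest floor and
soil organic carbon. `carbonrisk` turns a plot-level inventory overlaid on
current and projected Köppen-Geiger climate zones into a
consequence-by-likelihood **risk matrix** for those pools:

* **Consequence** is the pool's national stock total *S* (Tg) — the
  magnitude of carbon at risk of moving from sink to source.
* **Likelihood** is the pool's across-zone coefficient of variation of
  median carbon density,
  `CV = 100 · s(m₁, …, m_k) / mean(m₁, …, m_k)` (percent), where `m_z` is
  the median density (Mg ha⁻¹) of the pool among the plots in climate zone
  `z`, one unweighted entry per zone, and `s` the sample (n−1) standard
  deviation. Large spread among climates means a climate-zone shift can
  move the pool a long way.

For the future epoch, stock totals are projected by per-pool ordinary
least-squares on the annual national stock series, and the future CV is
obtained by **zone-shift imputation**: a plot whose climate zone changes is
assigned the *current* median density of its future zone, then the same CV
statistic is applied to medians grouped by future zone. Each (stock, CV)
point is finally binned by a response grid into ordered societal-response
categories, from `periodically_monitor` up to `robust_mitigation`.

The package also ships a synthetic inventory generator (log-normal
plot densities parameterised by zone medians, configurable zone-shift
scenarios, near-linear stock series) so the entire pipeline is testable
and demonstrable without any external data, plus bundled published US
national reference tables (2010 zone medians, 2010/2100 stock totals and
CVs) as plain CSV.

## Worked example: the published US national assessment

The likelihood statistic, computed from the bundled 2010 per-zone median
densities:

```r
library(carbonrisk)
library(dplyr)

across_zone_cv(us_zone_medians_2010()) |> mutate(cv_pct = round(cv_pct, 1))
#> # A tibble: 5 × 3
#>   pool         cv_pct n_zones
#>   <chr>         <dbl>   <int>
#> 1 live_ag        43.1       6
#> 2 live_bg        44.6       6
#> 3 dead_wood      55.1       6
#> 4 forest_floor   53.4       6
#> 5 soc            70.9       6
```

Soil organic carbon is by far the most variable pool across climates
(CV ≈ 71%), the live pools the least (≈ 43–45%). Feeding the published
stock totals and CVs for both epochs through the risk matrix:

```r
res <- run_assessment(
  stocks_current = us_stocks_2010(),
  stocks_future  = us_stocks_2100(),
  cv_current     = us_cv_2010(),
  cv_future      = us_cv_2100(),
  epochs = c("2010", "2100")
)
res$assessment |>
  select(pool, epoch, stock_tg, cv_pct, category, d_stock_tg, d_cv_pct)
#> # A tibble: 10 × 7
#>    pool         epoch stock_tg cv_pct category               d_stock_tg d_cv_pct
#>    <chr>        <chr>    <dbl>  <dbl> <ord>                       <dbl>    <dbl>
#>  1 live_ag      2010     14541   43.1 annually_monitor_deve…         NA   NA
#>  2 live_ag      2100     21657   43.3 annually_monitor_deve…       7116    0.200
#>  3 live_bg      2010      2876   44.6 periodically_monitor           NA   NA
#>  4 live_bg      2100      4282   45.1 periodically_monitor         1406    0.5
#>  5 dead_wood    2010      2627   55.2 periodically_monitor           NA   NA
#>  6 dead_wood    2100      3298   55.6 periodically_monitor          671    0.400
#>  7 forest_floor 2010      4941   53.4 periodically_monitor           NA   NA
#>  8 forest_floor 2100      5275   57.6 periodically_monitor          334    4.20
#>  9 soc          2010     17572   70.9 initiate_adaptation_m…         NA   NA
#> 10 soc          2100     18903   73   initiate_adaptation_m…       1331    2.10
```

Reading it: soil organic carbon combines the largest stock (17,572 Tg)
with the highest likelihood, landing in *initiate adaptation/mitigation*;
live aboveground biomass has a large stock but moderate CV (*annually
monitor / develop strategies*); the three smaller pools need only periodic
monitoring. Between 2010 and 2100 every pool gains stock and CV —
all five drift toward more proactive response (`more_proactive` is `TRUE`
for each), with forest floor showing the largest likelihood increase
(+4.2 CV points). `plot_risk_matrix(res$assessment)` draws the matrix with
the 2010→2100 trajectory arrows.

The same `run_assessment()` call runs end-to-end from plot-level data:
pass `plots =` (a plot table) and `series =` (an annual stock series), and
medians, CVs, imputation and projections are computed rather than supplied.
`sim_config()` + `generate_plot_table()` / `generate_stock_series()`
simulate such inputs; a thin command-line wrapper is included:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "carbonrisk.R", package = "carbonrisk"))')" \
  simulate --out sim --n-plots 5000 --seed 1
Rscript "$(Rscript -e 'cat(system.file("cli", "carbonrisk.R", package = "carbonrisk"))')" \
  assess --plots sim/plots.csv --series sim/stock_series.csv --out out
```

See `vignettes/forest-carbon-risk.Rmd` for the model, its assumptions and
the calibration choices.

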