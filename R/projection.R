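# Stock projection by per-pool ordinary least squares, and projection of the
# future likelihood statistic via zone-shift median imputation.

#' Project stock totals to a target year by linear regression
#'
#' Fits, per pool, an ordinary least-squares regression of annual national
#' stock (Tg) on calendar year and evaluates the fitted line at
#' `target_year`. Years are centred on the first series year so the
#' intercept is the fitted stock in that reference year. A deliberately
#' parsimonious baseline: it extrapolates recent inventory trends and
#' ignores saturation, disturbance and land-use change.
#'
#' @param series A stock series (see [read_stock_series()]).
#' @param target_year Calendar year to project to (default 2100).
#' @return Tibble with columns `pool`, `intercept_tg`, `slope_tg_per_yr`,
#'   `projected_stock_tg`, `target_year`, `reference_year`. Negative
#'   projections are allowed but raise a warning naming the pools.
#' @export
#' @examples
#' series <- tibble::tibble(
#'   pool = "live_ag", year = c(1990, 2000, 2010), stock_tg = c(0, 10, 20)
#' )
#' project_stocks(series, 2100)
project_stocks <- function(series, target_year = 2100) {
  validate_stock_series(series)
  ref <- min(series$year)
  out <- series |>
    group_by(pool) |>
    group_modify(function(d, key) {
      if (dplyr::n_distinct(d$year) < 2) {
        analysis_error(
          sprintf("pool '%s': need >= 2 distinct years to fit a trend",
                  key$pool),
          "carbonrisk_insufficient_years"
        )
      }
      fit <- lm(stock_tg ~ x, data = data.frame(x = d$year - ref,
                                                stock_tg = d$stock_tg))
      b <- coef(fit)
      tibble(
        intercept_tg = unname(b[1]),
        slope_tg_per_yr = unname(b[2]),
        projected_stock_tg = unname(b[1] + b[2] * (target_year - ref))
      )
    }) |>
    ungroup() |>
    mutate(target_year = target_year, reference_year = ref) |>
    arrange(pool_rank(pool))
  neg <- out$pool[out$projected_stock_tg < 0]
  if (length(neg) > 0) {
    warn(sprintf("projected stock is negative for pool(s): %s", toString(neg)))
  }
  out
}

#' Impute plot densities under a climate zone shift
#'
#' Applies the zone-shift imputation rule that drives the future likelihood
#' estimate: a plot whose projected future zone differs from its current
#' zone is assigned, for every pool, the *current* median density of its
#' future zone; plots whose zone does not change keep their empirical
#' densities. Future variability is thus based entirely on today's
#' distribution of densities among climates, assuming current climates
#' persist in 2100 but at different locations.
#'
#' A future zone with no current median for some required pool cannot be
#' imputed ("orphan" zone -- e.g. a zone whose future extent includes plots
#' but whose current extent held none). `policy = "error"` (default) fails
#' listing the zones; `policy = "drop"` drops the affected plots and reports
#' the count.
#'
#' @param plots A plot table with future zone assignments.
#' @param current_medians Zone medians computed from the same table's
#'   current zones ([zone_medians()]).
#' @param policy Orphan-zone policy, `"error"` or `"drop"`.
#' @return The plot table with densities replaced where imputed, plus one
#'   logical flag column `imputed_<pool>` per pool.
#' @export
impute_future_densities <- function(plots, current_medians,
                                    policy = c("error", "drop")) {
  policy <- match.arg(policy)
  pools <- intersect(carbon_pools(), unique(current_medians$pool))
  med <- matrix(NA_real_,
                nrow = length(pools),
                ncol = length(unique(current_medians$zone)),
                dimnames = list(pools, unique(current_medians$zone)))
  keep <- current_medians$pool %in% pools
  med[cbind(current_medians$pool[keep], current_medians$zone[keep])] <-
    current_medians$median[keep]
  changed <- plots$zone_future != plots$zone_current
  covered <- colnames(med)[colSums(is.na(med)) == 0]
  orphan <- changed & !(plots$zone_future %in% covered)
  if (any(orphan)) {
    zones <- sort(unique(plots$zone_future[orphan]))
    if (policy == "error") {
      analysis_error(
        sprintf("future zone(s) without a complete set of current medians: %s",
                toString(zones)),
        "carbonrisk_orphan_zone"
      )
    }
    inform(sprintf(
      "dropping %d plot(s) whose future zone has no current median (%s)",
      sum(orphan), toString(zones)
    ))
    plots <- plots[!orphan, , drop = FALSE]
    changed <- changed[!orphan]
  }
  out <- plots
  for (p in pools) {
    dens <- out[[p]]
    dens[changed] <- med[p, out$zone_future[changed]]
    out[[p]] <- dens
    out[[paste0("imputed_", p)]] <- changed
  }
  out
}

#' Project the across-zone CV to the future epoch
#'
#' Pipeline composition for the future likelihood statistic:
#' current zone medians -> zone-shift imputation
#' ([impute_future_densities()]) -> medians regrouped by *future* zone ->
#' [across_zone_cv()]. With `cv_mode = "pooled"` the final step is instead
#' the plot-level [pooled_cv()] over the imputed table (sensitivity
#' analysis, not the default statistic).
#'
#' @param plots A plot table with current and future zone assignments.
#' @param policy Orphan-zone policy passed to [impute_future_densities()].
#' @param cv_mode `"zone_median"` (default) or `"pooled"`.
#' @param pools Pools to analyse.
#' @return A CV table (columns `pool`, `cv_pct`, `n_zones`) with epoch
#'   `"future"`.
#' @export
project_cv_future <- function(plots, policy = c("error", "drop"),
                              cv_mode = c("zone_median", "pooled"),
                              pools = carbon_pools()) {
  policy <- match.arg(policy)
  cv_mode <- match.arg(cv_mode)
  cur <- zone_medians(plots, "current", pools = pools)
  imp <- impute_future_densities(plots, cur, policy = policy)
  if (cv_mode == "pooled") {
    out <- pooled_cv(imp, pools = pools, epoch = "future")
  } else {
    fut <- zone_medians(imp, "future", pools = pools, epoch = "future")
    out <- across_zone_cv(fut)
  }
  out
}
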