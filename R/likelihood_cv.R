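# Likelihood metric: per-zone median carbon densities and the across-zone
# coefficient of variation of those medians.

analysis_error <- function(msg, class) {
  abort(msg, class = c(class, "carbonrisk_analysis_error"))
}

#' Median carbon density per pool and climate zone
#'
#' Groups plot-level densities by climate zone -- either the current or the
#' projected-future assignment -- and returns the sample median per
#' (pool, zone). Missing densities are excluded; a (pool, zone) cell exists
#' only where at least one non-missing plot falls in it. For even counts the
#' median is the mean of the two central order statistics.
#'
#' @param plots A plot table (see [read_plot_table()]).
#' @param zone_field Which zone assignment to group by: `"current"` or
#'   `"future"`.
#' @param pools Pools to summarise (default: all five). A pool with zero
#'   non-missing densities overall is an error naming the pool.
#' @param epoch Epoch label attached to the result (defaults to
#'   `zone_field`).
#' @return Tibble with columns `pool`, `zone`, `median` (Mg/ha), `n_plots`,
#'   carrying an `"epoch"` attribute.
#' @export
#' @examples
#' plots <- generate_plot_table(sim_config(n_plots = 500, seed = 1))
#' zone_medians(plots, "current")
zone_medians <- function(plots, zone_field = c("current", "future"),
                         pools = carbon_pools(), epoch = NULL) {
  zone_field <- match.arg(zone_field)
  if (nrow(plots) == 0) {
    analysis_error("plot table is empty", "carbonrisk_empty_input")
  }
  zcol <- paste0("zone_", zone_field)
  long <- tidyr::pivot_longer(plots[, c(zcol, pools)],
                              cols = tidyr::all_of(pools),
                              names_to = "pool", values_to = "density")
  out <- long |>
    filter(!is.na(density)) |>
    group_by(pool, zone = .data[[zcol]]) |>
    summarise(median = median(density), n_plots = dplyr::n(), .groups = "drop") |>
    arrange(pool_rank(pool), zone_rank(zone))
  absent <- setdiff(pools, unique(out$pool))
  if (length(absent) > 0) {
    analysis_error(
      sprintf("pool(s) with no non-missing densities: %s", toString(absent)),
      "carbonrisk_empty_pool"
    )
  }
  attr(out, "epoch") <- if (is.null(epoch)) zone_field else epoch
  out
}

#' Across-zone coefficient of variation of zone medians
#'
#' The framework's likelihood statistic: for each pool, take the vector of
#' per-zone median densities (one entry per zone, unweighted by plot count
#' or forest area) and compute `cv = 100 * s / m` where `m` is the
#' arithmetic mean and `s` the sample standard deviation (n-1 denominator).
#' Higher across-zone variability is read as a greater likelihood that the
#' pool's stock changes when climate zones shift.
#'
#' @param medians A zone-median table from [zone_medians()] or
#'   [read_zone_medians()].
#' @return Tibble with columns `pool`, `cv_pct` (percent, full precision),
#'   `n_zones`, carrying the input's `"epoch"` attribute. Values are
#'   conventionally reported rounded to one decimal; rounding is left to the
#'   caller.
#' @export
#' @examples
#' across_zone_cv(us_zone_medians_2010())
across_zone_cv <- function(medians) {
  out <- medians |>
    group_by(pool) |>
    summarise(cv_pct = {
      m <- mean(median)
      k <- dplyr::n()
      if (k < 2) {
        analysis_error(
          sprintf("pool '%s': need medians from >= 2 zones, got %d",
                  pool[1], k),
          "carbonrisk_insufficient_zones"
        )
      }
      if (m == 0) {
        analysis_error(sprintf("pool '%s': CV undefined, mean median is 0",
                               pool[1]),
                       "carbonrisk_undefined_cv")
      }
      100 * sd(median) / m
    }, n_zones = dplyr::n(), .groups = "drop") |>
    arrange(pool_rank(pool))
  attr(out, "epoch") <- attr(medians, "epoch")
  out
}

#' Pooled plot-level coefficient of variation
#'
#' Sensitivity-analysis alternative to [across_zone_cv()]: the CV computed
#' over all plot-level densities of a pool, ignoring zone structure
#' (`100 * sd / mean` with n-1 denominator). Not the framework's default
#' likelihood metric.
#'
#' @param plots A plot table.
#' @param pools Pools to summarise.
#' @param epoch Epoch label for the result.
#' @return Tibble with columns `pool`, `cv_pct`, `n_zones` (here the number
#'   of distinct zones the plots occupy, for schema compatibility).
#' @export
pooled_cv <- function(plots, pools = carbon_pools(), epoch = "current") {
  long <- tidyr::pivot_longer(plots[, c("zone_current", pools)],
                              cols = tidyr::all_of(pools),
                              names_to = "pool", values_to = "density")
  out <- long |>
    filter(!is.na(density)) |>
    group_by(pool) |>
    summarise(
      cv_pct = 100 * sd(density) / mean(density),
      n_zones = dplyr::n_distinct(zone_current),
      .groups = "drop"
    ) |>
    arrange(pool_rank(pool))
  attr(out, "epoch") <- epoch
  out
}
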