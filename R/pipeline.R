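# End-to-end orchestration: simulate inputs, run the full assessment,
# write every intermediate product as CSV.

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the full risk assessment pipeline
#'
#' Composes the whole analysis: current zone medians and across-zone CV
#' from the plot table; per-pool linear projection of the stock series to
#' `target_year`; future CV via zone-shift imputation; and the risk-matrix
#' assessment of both epochs. Inputs can be supplied at two levels:
#'
#' * **plot-network mode** -- `plots` (+ `series`): medians, CVs and
#'   projections are computed from the data;
#' * **literal mode** -- published summary tables are passed directly:
#'   `zone_medians_current` for the current CV, `stocks_current`,
#'   `stocks_future` and `cv_future` bypass the corresponding computation
#'   (e.g. to reproduce a published national assessment from its printed
#'   tables).
#'
#' In plot-network mode the current stock total defaults to the observed
#' series value in its latest year, and the future total to the regression
#' projection.
#'
#' @param plots Plot table, or `NULL` in literal mode.
#' @param series Annual stock series, or `NULL` if both stock tables are
#'   given.
#' @param zone_medians_current Optional zone-median table overriding the
#'   plot-derived one.
#' @param stocks_current,stocks_future Optional stock tables (Tg) per
#'   epoch.
#' @param cv_current,cv_future Optional CV tables per epoch (e.g. published
#'   values at their printed precision), bypassing the computation.
#' @param grid A [response_grid()].
#' @param target_year Projection year (default 2100).
#' @param cv_mode `"zone_median"` or `"pooled"` (see [project_cv_future()]).
#' @param orphan_policy Orphan-zone policy for imputation.
#' @param epochs Length-2 epoch labels for the report.
#' @param pools Pools to assess; defaults to the pools for which any input
#'   provides data.
#' @param out_dir If non-`NULL`, write `report.csv` plus every intermediate
#'   (`zone_medians_current.csv`, `cv_current.csv`, `projection.csv`,
#'   `imputed_plots.csv`, `cv_future.csv`) into this directory.
#' @param quiet Suppress per-stage log messages (default `TRUE`; logging
#'   goes to the message stream).
#' @return A list with elements `assessment`, `points_current`,
#'   `points_future`, `zone_medians_current`, `cv_current`, `projection`,
#'   `imputed_plots`, `cv_future`, `grid` (computed entries `NULL` when
#'   bypassed).
#' @export
#' @examples
#' cfg <- sim_config(n_plots = 400, seed = 11)
#' res <- run_assessment(plots = generate_plot_table(cfg),
#'                       series = generate_stock_series(cfg))
#' res$assessment
run_assessment <- function(plots = NULL, series = NULL,
                           zone_medians_current = NULL,
                           stocks_current = NULL, stocks_future = NULL,
                           cv_current = NULL, cv_future = NULL,
                           grid = default_response_grid(),
                           target_year = 2100,
                           cv_mode = c("zone_median", "pooled"),
                           orphan_policy = c("error", "drop"),
                           epochs = c("current", as.character(target_year)),
                           pools = NULL,
                           out_dir = NULL, quiet = TRUE) {
  cv_mode <- match.arg(cv_mode)
  orphan_policy <- match.arg(orphan_policy)

  if (is.null(plots) && is.null(zone_medians_current) && is.null(cv_current)) {
    config_error("need a plot table, a current zone-median table, or a current CV table")
  }
  if (is.null(series) && (is.null(stocks_current) || is.null(stocks_future))) {
    config_error("need either a stock series or both epoch stock tables")
  }
  if (is.null(plots) && is.null(cv_future)) {
    config_error("future CV requires a plot table (or pass cv_future directly)")
  }

  if (is.null(pools)) {
    pools <- if (!is.null(plots)) {
      dens <- as.matrix(plots[carbon_pools()])
      carbon_pools()[colSums(!is.na(dens)) > 0]
    } else if (!is.null(zone_medians_current)) {
      intersect(carbon_pools(), unique(zone_medians_current$pool))
    } else {
      intersect(carbon_pools(), unique(cv_current$pool))
    }
  }

  if (is.null(zone_medians_current) && !is.null(plots)) {
    zone_medians_current <- zone_medians(plots, "current", pools = pools,
                                         epoch = epochs[1])
    log_stage(quiet, "zone medians (current): %d (pool, zone) cells from %d plots",
              nrow(zone_medians_current), nrow(plots))
  }
  if (is.null(cv_current)) {
    cv_current <- across_zone_cv(zone_medians_current)
  }
  log_stage(quiet, "current CV: %d pools over up to %d zones",
            nrow(cv_current), max(cv_current$n_zones))

  projection <- NULL
  if (!is.null(series)) {
    series <- series[series$pool %in% pools, , drop = FALSE]
    projection <- project_stocks(series, target_year = target_year)
    log_stage(quiet, "projection: OLS on %d series points, target %d",
              nrow(series), target_year)
    if (is.null(stocks_current)) {
      latest <- series |>
        group_by(pool) |>
        slice_max(year, n = 1, with_ties = FALSE) |>
        ungroup() |>
        select(pool, stock_tg)
      stocks_current <- latest
    }
    if (is.null(stocks_future)) {
      stocks_future <- projection |>
        transmute(pool, stock_tg = projected_stock_tg)
    }
  }

  imputed_plots <- NULL
  if (is.null(cv_future)) {
    imputed_plots <- impute_future_densities(plots, zone_medians_current,
                                             policy = orphan_policy)
    if (cv_mode == "pooled") {
      cv_future <- pooled_cv(imputed_plots, pools = pools, epoch = epochs[2])
    } else {
      fut_med <- zone_medians(imputed_plots, "future", pools = pools,
                              epoch = epochs[2])
      cv_future <- across_zone_cv(fut_med)
    }
    log_stage(quiet, "future CV: %d plots, %d imputed",
              nrow(imputed_plots),
              sum(imputed_plots$zone_future != imputed_plots$zone_current))
  }

  points_current <- inner_join(stocks_current, cv_current, by = "pool") |>
    select(pool, stock_tg, cv_pct)
  points_future <- inner_join(stocks_future, cv_future, by = "pool") |>
    select(pool, stock_tg, cv_pct)
  assessment <- assess_risk(
    points_current[points_current$pool %in% pools, ],
    points_future[points_future$pool %in% pools, ],
    grid = grid, epochs = epochs
  )
  log_stage(quiet, "assessment: %d pools x 2 epochs", length(pools))

  result <- list(
    assessment = assessment,
    points_current = points_current, points_future = points_future,
    zone_medians_current = zone_medians_current, cv_current = cv_current,
    projection = projection, imputed_plots = imputed_plots,
    cv_future = cv_future, grid = grid
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_assessment(assessment, file.path(out_dir, "report.csv"))
    if (!is.null(zone_medians_current)) {
      write_zone_medians(zone_medians_current,
                         file.path(out_dir, "zone_medians_current.csv"))
    }
    write_cv_table(cv_current, file.path(out_dir, "cv_current.csv"))
    write_cv_table(cv_future, file.path(out_dir, "cv_future.csv"))
    if (!is.null(projection)) {
      write_projection(projection, file.path(out_dir, "projection.csv"))
    }
    if (!is.null(imputed_plots)) {
      write_imputed_plots(imputed_plots, file.path(out_dir, "imputed_plots.csv"))
    }
    log_stage(quiet, "wrote report and intermediates to %s", out_dir)
  }
  invisible(result)
}

#' Write projection results as CSV
#'
#' Columns: `pool`, `intercept_tg`, `slope_tg_per_yr`,
#' `projected_stock_tg`, `target_year`, `reference_year`.
#'
#' @param projection Result of [project_stocks()].
#' @param path Output CSV path.
#' @export
write_projection <- function(projection, path) {
  fields <- c(
    list(c("pool", "intercept_tg", "slope_tg_per_yr", "projected_stock_tg",
           "target_year", "reference_year")),
    lapply(seq_len(nrow(projection)), function(i) {
      c(projection$pool[i],
        fmt_num(projection$intercept_tg[i]),
        fmt_num(projection$slope_tg_per_yr[i]),
        fmt_num(projection$projected_stock_tg[i]),
        fmt_num(projection$target_year[i]),
        fmt_num(projection$reference_year[i]))
    })
  )
  write_csv_lines(fields, path)
}

#' Write an imputed plot table as CSV
#'
#' The plot-table schema plus one `imputed_<pool>` flag column per pool
#' present (values `true`/`false`).
#'
#' @param imputed Result of [impute_future_densities()].
#' @param path Output CSV path.
#' @export
write_imputed_plots <- function(imputed, path) {
  flag_cols <- grep("^imputed_", names(imputed), value = TRUE)
  base_cols <- plot_table_columns()
  cols <- c(
    list(imputed$plot_id, imputed$zone_current, imputed$zone_future,
         fmt_num(imputed$expansion_ha)),
    lapply(carbon_pools(), function(p) fmt_num(imputed[[p]])),
    lapply(flag_cols, function(f) tolower(as.character(imputed[[f]])))
  )
  lines <- c(
    paste(c(base_cols, flag_cols), collapse = ","),
    if (nrow(imputed) > 0) do.call(paste, c(cols, sep = ","))
  )
  write_lines_raw(lines, path)
}

#' Generate and write a synthetic data set
#'
#' Runs [generate_plot_table()] and [generate_stock_series()] and writes
#' `plots.csv` and `stock_series.csv` to `out_dir`. Deterministic given the
#' config.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `plots`, `series`, and the file paths.
#' @export
run_simulation <- function(config, out_dir) {
  validate_sim_config(config)
  plots <- generate_plot_table(config)
  series <- generate_stock_series(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plots_path <- file.path(out_dir, "plots.csv")
  series_path <- file.path(out_dir, "stock_series.csv")
  write_plot_table(plots, plots_path)
  write_stock_series(series, series_path)
  invisible(list(plots = plots, series = series,
                 plots_path = plots_path, series_path = series_path))
}
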