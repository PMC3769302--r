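# Synthetic national-inventory generator: FIA-like plot networks, zone-shift
# scenarios and annual stock series with the statistical structure the
# downstream analysis assumes.

config_error <- function(msg) abort(msg, class = "carbonrisk_config_error")

default_pool_sigma <- function() {
  # log-scale dispersion; > sqrt(ln 2) forces SD > mean for a log-normal,
  # matching the published national univariate statistics where SD exceeds
  # the mean for the live and dead-wood pools but not litter/soil
  c(live_ag = 1.0, live_bg = 1.0, dead_wood = 1.0,
    forest_floor = 0.6, soc = 0.6)
}

default_zone_weights <- function() {
  # plausible conterminous-US forest-plot shares by main climate group:
  # humid temperate and snow zones dominate, equatorial is marginal
  c(equatorial = 0.02, arid = 0.08,
    warm_temperate_fully_humid = 0.34, warm_temperate_summer_dry = 0.06,
    snow_fully_humid = 0.40, snow_summer_dry = 0.10)
}

default_zone_medians_matrix <- function() {
  m <- us_zone_medians_2010()
  zones <- koppen_zones()
  out <- matrix(NA_real_, nrow = length(carbon_pools()), ncol = length(zones),
                dimnames = list(carbon_pools(), zones))
  out[cbind(m$pool, m$zone)] <- m$median
  out
}

#' Warming zone-shift transition matrix
#'
#' Builds a zone-to-zone transition matrix for the default six
#' Koeppen-Geiger groups in which each plot moves, with probability `p`, to
#' the warmer (or drier) analog of its current zone -- snow zones to the
#' matching warm temperate zone, warm temperate fully-humid to equatorial,
#' warm temperate summer-dry to arid -- and otherwise stays put. Equatorial
#' and arid plots have no warmer analog and stay. This is an illustrative
#' strong-warming scenario; real applications supply zone assignments
#' derived from climate projections.
#'
#' @param p Probability that a plot with a warmer analog changes zone, in
#'   \[0, 1\].
#' @return A 6x6 row-stochastic matrix with zone labels on both dimensions.
#' @export
#' @examples
#' warming_transition(0.5)
warming_transition <- function(p = 0.5) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    config_error("p must be a probability in [0, 1]")
  }
  zones <- koppen_zones()
  analog <- c(
    equatorial = NA, arid = NA,
    warm_temperate_fully_humid = "equatorial",
    warm_temperate_summer_dry = "arid",
    snow_fully_humid = "warm_temperate_fully_humid",
    snow_summer_dry = "warm_temperate_summer_dry"
  )
  m <- diag(length(zones))
  dimnames(m) <- list(zones, zones)
  for (z in zones) {
    if (!is.na(analog[[z]])) {
      m[z, z] <- 1 - p
      m[z, analog[[z]]] <- p
    }
  }
  m
}

#' Simulation configuration for the synthetic plot network
#'
#' Bundles and validates every parameter of the synthetic national
#' inventory. Defaults emulate the US network: one plot per 2,428 ha,
#' per-pool log-normal density distributions whose zone medians equal the
#' published 2010 medians ([us_zone_medians_2010()]), heavy tails (SD >
#' mean) for the live and dead-wood pools, a strong-warming zone-shift
#' scenario in which half the plots change zone
#' ([warming_transition()]`(0.5)`), and a near-linear 1990--2010 annual
#' stock series anchored at the published 2010 totals with slope chosen so
#' an ordinary least-squares projection reaches the published 2100 totals.
#'
#' @param n_plots Number of plots (default 5,000 for desk-scale work;
#'   networks up to the real ~125,000 are supported).
#' @param zone_labels Ordered zone identifiers.
#' @param zone_weights Probability of a plot falling in each zone; sums
#'   to 1.
#' @param pool_zone_medians Pool-by-zone matrix of median carbon density
#'   (Mg/ha).
#' @param pool_sigma Named per-pool log-scale standard deviation
#'   (dimensionless).
#' @param zone_transition Zone-by-zone transition probability matrix (rows
#'   sum to 1) giving each plot's future zone distribution.
#' @param expansion_ha Area each plot represents (ha).
#' @param series_years Consecutive calendar years of the annual stock
#'   series.
#' @param series_intercept_tg,series_slope_tg_per_yr,series_noise_sd_tg
#'   Named per-pool linear-trend parameters of the stock series (Tg, Tg/yr,
#'   Tg); the intercept is the expected stock in the first series year.
#' @param seed Integer seed; all generator output is deterministic given the
#'   config.
#' @return A validated object of class `"sim_config"`.
#' @seealso [generate_plot_table()], [generate_stock_series()]
#' @export
sim_config <- function(n_plots = 5000,
                       zone_labels = koppen_zones(),
                       zone_weights = default_zone_weights(),
                       pool_zone_medians = default_zone_medians_matrix(),
                       pool_sigma = default_pool_sigma(),
                       zone_transition = warming_transition(0.5),
                       expansion_ha = 2428,
                       series_years = 1990:2010,
                       series_intercept_tg = NULL,
                       series_slope_tg_per_yr = NULL,
                       series_noise_sd_tg = NULL,
                       seed = 1L) {
  pools <- rownames(pool_zone_medians)
  if (is.null(series_slope_tg_per_yr) || is.null(series_intercept_tg) ||
      is.null(series_noise_sd_tg)) {
    s2010 <- us_stocks_2010()
    s2100 <- us_stocks_2100()
    tot10 <- setNames(s2010$stock_tg, s2010$pool)[carbon_pools()]
    tot00 <- setNames(s2100$stock_tg, s2100$pool)[carbon_pools()]
    slope <- (tot00 - tot10) / 90
    if (is.null(series_slope_tg_per_yr)) series_slope_tg_per_yr <- slope
    if (is.null(series_intercept_tg)) {
      series_intercept_tg <- tot10 - slope * (2010 - min(series_years))
    }
    if (is.null(series_noise_sd_tg)) series_noise_sd_tg <- 0.01 * tot10
  }
  cfg <- structure(
    list(
      n_plots = n_plots,
      zone_labels = zone_labels,
      zone_weights = zone_weights,
      pool_zone_medians = pool_zone_medians,
      pool_sigma = pool_sigma,
      zone_transition = zone_transition,
      expansion_ha = expansion_ha,
      series_years = series_years,
      series_intercept_tg = series_intercept_tg,
      series_slope_tg_per_yr = series_slope_tg_per_yr,
      series_noise_sd_tg = series_noise_sd_tg,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config An object to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with(config, {
    if (!is.numeric(n_plots) || length(n_plots) != 1 || n_plots < 1 ||
        n_plots != round(n_plots)) {
      config_error("n_plots must be a positive integer")
    }
    if (length(zone_labels) < 1 || anyDuplicated(zone_labels) ||
        any(!nzchar(zone_labels))) {
      config_error("zone_labels must be non-empty and unique")
    }
    if (length(zone_weights) != length(zone_labels) ||
        any(zone_weights < 0) || any(zone_weights > 1) ||
        abs(sum(zone_weights) - 1) > 1e-9) {
      config_error("zone_weights must be probabilities over zone_labels summing to 1")
    }
    if (is.null(rownames(pool_zone_medians)) ||
        !all(zone_labels %in% colnames(pool_zone_medians))) {
      config_error("pool_zone_medians must have pool rownames and cover every zone")
    }
    if (any(is.na(pool_zone_medians[, zone_labels])) ||
        any(pool_zone_medians[, zone_labels] <= 0)) {
      config_error("pool_zone_medians must be strictly positive for every (pool, zone)")
    }
    pools <- rownames(pool_zone_medians)
    if (!all(pools %in% names(pool_sigma)) || any(pool_sigma[pools] <= 0)) {
      config_error("pool_sigma must be strictly positive for every pool")
    }
    if (!all(zone_labels %in% rownames(zone_transition)) ||
        !all(zone_labels %in% colnames(zone_transition))) {
      config_error(sprintf(
        "zone_transition must cover zones: %s",
        toString(setdiff(zone_labels, rownames(zone_transition)))
      ))
    }
    tm <- zone_transition[zone_labels, zone_labels, drop = FALSE]
    if (any(tm < 0) || any(tm > 1) || any(abs(rowSums(tm) - 1) > 1e-9)) {
      config_error("zone_transition rows must be probability distributions summing to 1")
    }
    if (!is.numeric(expansion_ha) || expansion_ha <= 0) {
      config_error("expansion_ha must be strictly positive")
    }
    if (length(series_years) < 2) {
      config_error("series_years must span at least two years")
    }
    for (nm in c("series_intercept_tg", "series_slope_tg_per_yr",
                 "series_noise_sd_tg")) {
      v <- get(nm)
      if (!all(pools %in% names(v))) {
        config_error(sprintf("%s must be named for every pool", nm))
      }
    }
    if (any(series_noise_sd_tg < 0)) {
      config_error("series_noise_sd_tg must be non-negative")
    }
  })
  invisible(config)
}

#' Generate a synthetic plot table
#'
#' Draws an FIA-like plot network from a [sim_config()]:
#' * each plot's current zone is drawn from `zone_weights`;
#' * its future zone from the `zone_transition` row of the current zone;
#' * each pool's carbon density from a log-normal distribution with
#'   log-location `log(pool_zone_medians[pool, current zone])` -- so the
#'   distribution's median equals the configured zone median -- and
#'   log-scale `pool_sigma[pool]`.
#'
#' The random stream is seeded once from `config$seed`; zones are drawn
#' first, then pool densities sequentially in the row order of
#' `pool_zone_medians`, so appending a new pool leaves earlier pools' draws
#' unchanged. Output is fully deterministic given the config.
#'
#' @param config A [sim_config()].
#' @return A plot table tibble (see [read_plot_table()] for the schema).
#' @export
#' @examples
#' plots <- generate_plot_table(sim_config(n_plots = 100, seed = 7))
#' head(plots)
generate_plot_table <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_plots
  zones <- config$zone_labels
  cur <- sample(zones, n, replace = TRUE, prob = config$zone_weights)
  tm <- config$zone_transition
  fut <- character(n)
  for (z in zones) {  # zone loop in fixed label order keeps draws reproducible
    idx <- which(cur == z)
    if (length(idx) > 0) {
      fut[idx] <- sample(zones, length(idx), replace = TRUE, prob = tm[z, zones])
    }
  }
  out <- tibble(
    plot_id = sprintf("P%06d", seq_len(n)),
    zone_current = cur,
    zone_future = fut,
    expansion_ha = rep(config$expansion_ha, n)
  )
  pools <- rownames(config$pool_zone_medians)
  for (p in pools) {
    med <- config$pool_zone_medians[p, cur]
    out[[p]] <- rlnorm(n, meanlog = log(med), sdlog = config$pool_sigma[[p]])
  }
  for (p in setdiff(carbon_pools(), pools)) {
    out[[p]] <- NA_real_
  }
  out[plot_table_columns()[plot_table_columns() %in% names(out)]]
}

#' Generate a synthetic annual stock series
#'
#' For each pool and each year `y` in `series_years`, draws
#' `stock = intercept + slope * (y - first_year) + N(0, noise_sd)` (Tg).
#' Deterministic given the config; pools are generated in canonical order
#' from one seeded stream.
#'
#' @param config A [sim_config()].
#' @return A stock series tibble (see [read_stock_series()]).
#' @export
generate_stock_series <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  years <- config$series_years
  y0 <- min(years)
  pools <- rownames(config$pool_zone_medians)
  rows <- lapply(pools, function(p) {
    tibble(
      pool = p,
      year = years,
      stock_tg = config$series_intercept_tg[[p]] +
        config$series_slope_tg_per_yr[[p]] * (years - y0) +
        rnorm(length(years), 0, config$series_noise_sd_tg[[p]])
    )
  })
  bind_rows(rows)
}

#' Read a simulation configuration from a YAML/JSON file
#'
#' Scalar fields map directly to [sim_config()] arguments; `pool_sigma` and
#' the series parameters are pool-keyed mappings; `pool_zone_medians` is a
#' pool-keyed mapping of zone-keyed values; `zone_transition` a zone-keyed
#' mapping of zone-keyed probabilities (unstated cells default to 0).
#' Omitted fields keep the [sim_config()] defaults.
#'
#' @param path Path to a YAML (or JSON) file.
#' @return A validated [sim_config()].
#' @export
sim_config_from_file <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("n_plots", "zone_labels", "expansion_ha", "seed")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$series_years)) {
    ys <- unlist(raw$series_years)
    args$series_years <- if (length(ys) == 2) ys[1]:ys[2] else ys
  }
  for (nm in c("zone_weights", "pool_sigma", "series_intercept_tg",
               "series_slope_tg_per_yr", "series_noise_sd_tg")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$pool_zone_medians)) {
    pools <- names(raw$pool_zone_medians)
    zones <- unique(unlist(lapply(raw$pool_zone_medians, names)))
    m <- matrix(NA_real_, length(pools), length(zones),
                dimnames = list(pools, zones))
    for (p in pools) m[p, names(raw$pool_zone_medians[[p]])] <-
        unlist(raw$pool_zone_medians[[p]])
    args$pool_zone_medians <- m
  }
  if (!is.null(raw$zone_transition)) {
    from <- names(raw$zone_transition)
    to <- unique(unlist(lapply(raw$zone_transition, names)))
    zs <- union(from, to)
    m <- matrix(0, length(zs), length(zs), dimnames = list(zs, zs))
    for (z in from) m[z, names(raw$zone_transition[[z]])] <-
        unlist(raw$zone_transition[[z]])
    args$zone_transition <- m
  }
  do.call(sim_config, args)
}
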