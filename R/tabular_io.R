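# Data model and bit-exact CSV readers/writers for plot tables, stock series,
# stock tables, zone-median tables and CV tables.
#
# Conventions (fixed by schema, no auto-detection):
#   * CSV, UTF-8, comma separator, mandatory header row, "\n" line endings.
#   * Densities are Mg/ha, stock totals Tg (1 Tg = 1e6 Mg).
#   * Missing density = empty cell on write; "" or "NA" accepted on read.
#   * Numbers are written with 6 significant digits so writers are
#     byte-deterministic.

plot_table_columns <- function() {
  c("plot_id", "zone_current", "zone_future", "expansion_ha", carbon_pools())
}

schema_error <- function(msg) {
  abort(msg, class = "carbonrisk_schema_error")
}

io_error <- function(msg) {
  abort(msg, class = "carbonrisk_io_error")
}

fmt_num <- function(x) {
  out <- formatC(x, digits = 6, format = "g")
  out[is.na(x)] <- ""
  out
}

read_csv_strict <- function(path, required, numeric_cols) {
  if (!file.exists(path)) {
    io_error(sprintf("file not found: %s", path))
  }
  raw <- tryCatch(
    read.csv(path, colClasses = "character", check.names = FALSE,
             na.strings = NULL, fileEncoding = "UTF-8"),
    error = function(e) io_error(sprintf("cannot read %s: %s", path, conditionMessage(e)))
  )
  unknown <- setdiff(names(raw), required)
  if (length(unknown) > 0) {
    schema_error(sprintf("%s: unknown column(s): %s", path, toString(unknown)))
  }
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    schema_error(sprintf("%s: missing column(s): %s", path, toString(missing)))
  }
  for (col in numeric_cols) {
    cell <- trimws(raw[[col]])
    cell[cell %in% c("", "NA")] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad) > 0) {
      schema_error(sprintf(
        "%s: non-numeric value '%s' in column '%s', row %d",
        path, cell[bad[1]], col, bad[1]
      ))
    }
    raw[[col]] <- num
  }
  tibble::as_tibble(raw[required])
}

write_lines_raw <- function(lines, path) {
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) io_error(sprintf("cannot write %s", path)))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

write_csv_lines <- function(fields, path) {
  write_lines_raw(vapply(fields, paste, character(1), collapse = ","), path)
}

#' Read and write plot tables
#'
#' A plot table is the pipeline's central input: one row per inventory plot
#' with its current and projected-future climate zone assignment, the area
#' the plot represents (expansion factor, ha), and the carbon density
#' (Mg/ha) of each of the five pools, possibly missing where a pool was not
#' sampled on that plot.
#'
#' Columns: `plot_id`, `zone_current`, `zone_future`, `expansion_ha`,
#' `live_ag`, `live_bg`, `dead_wood`, `forest_floor`, `soc`.
#'
#' Validation enforced on read and before write: unique non-empty `plot_id`,
#' non-empty zone labels, `expansion_ha >= 0`, densities `>= 0` where
#' present, and at least one pool present per record. Violations raise a
#' schema error naming the offending row/column.
#'
#' @param path Path to a CSV file.
#' @param plots A plot table (tibble) as returned by [read_plot_table()] or
#'   [generate_plot_table()].
#' @return `read_plot_table()` returns a tibble; `write_plot_table()`
#'   (invisibly) the path written.
#' @export
read_plot_table <- function(path) {
  tbl <- read_csv_strict(path, plot_table_columns(),
                         numeric_cols = c("expansion_ha", carbon_pools()))
  validate_plot_table(tbl, context = path)
  tbl
}

#' @rdname read_plot_table
#' @export
write_plot_table <- function(plots, path) {
  validate_plot_table(plots)
  cols <- c(
    list(plots$plot_id, plots$zone_current, plots$zone_future,
         fmt_num(plots$expansion_ha)),
    lapply(carbon_pools(), function(p) fmt_num(plots[[p]]))
  )
  lines <- c(
    paste(plot_table_columns(), collapse = ","),
    do.call(paste, c(cols, sep = ","))
  )
  if (nrow(plots) == 0) lines <- lines[1]
  write_lines_raw(lines, path)
}

validate_plot_table <- function(plots, context = "plot table") {
  missing <- setdiff(plot_table_columns(), names(plots))
  if (length(missing) > 0) {
    schema_error(sprintf("%s: missing column(s): %s", context, toString(missing)))
  }
  dup <- plots$plot_id[duplicated(plots$plot_id)]
  if (length(dup) > 0) {
    schema_error(sprintf("%s: duplicate plot_id: %s", context,
                         toString(unique(dup))))
  }
  if (any(!nzchar(plots$plot_id) | is.na(plots$plot_id))) {
    schema_error(sprintf("%s: empty plot_id", context))
  }
  for (zcol in c("zone_current", "zone_future")) {
    if (any(!nzchar(plots[[zcol]]) | is.na(plots[[zcol]]))) {
      schema_error(sprintf("%s: empty value in column '%s'", context, zcol))
    }
  }
  if (any(is.na(plots$expansion_ha) | plots$expansion_ha < 0)) {
    bad <- which(is.na(plots$expansion_ha) | plots$expansion_ha < 0)[1]
    schema_error(sprintf("%s: invalid expansion_ha in row %d", context, bad))
  }
  for (p in carbon_pools()) {
    bad <- which(!is.na(plots[[p]]) & plots[[p]] < 0)
    if (length(bad) > 0) {
      schema_error(sprintf("%s: negative density in column '%s', row %d",
                           context, p, bad[1]))
    }
  }
  if (nrow(plots) > 0) {
    dens <- as.matrix(plots[carbon_pools()])
    empty <- which(rowSums(!is.na(dens)) == 0)
    if (length(empty) > 0) {
      schema_error(sprintf("%s: row %d has no carbon density for any pool",
                           context, empty[1]))
    }
  }
  invisible(plots)
}

#' Read and write annual stock series
#'
#' A stock series records the national total carbon stock of each pool (Tg)
#' for each year of an inventory reporting period, e.g. 1990--2010. It is
#' the input to the per-pool linear stock projection ([project_stocks()]).
#'
#' Columns: `pool`, `year`, `stock_tg`. `(pool, year)` must be unique, pools
#' must be among [carbon_pools()], and each pool needs at least two distinct
#' years (otherwise no trend can be fit).
#'
#' @param path Path to a CSV file.
#' @param series A stock series tibble.
#' @return `read_stock_series()` returns a tibble sorted by pool (canonical
#'   order) and year.
#' @export
read_stock_series <- function(path) {
  tbl <- read_csv_strict(path, c("pool", "year", "stock_tg"),
                         numeric_cols = c("year", "stock_tg"))
  validate_stock_series(tbl, context = path)
  arrange(tbl, pool_rank(pool), year)
}

#' @rdname read_stock_series
#' @export
write_stock_series <- function(series, path) {
  validate_stock_series(series)
  series <- arrange(series, pool_rank(pool), year)
  fields <- c(
    list(c("pool", "year", "stock_tg")),
    lapply(seq_len(nrow(series)), function(i) {
      c(series$pool[i], fmt_num(series$year[i]), fmt_num(series$stock_tg[i]))
    })
  )
  write_csv_lines(fields, path)
}

validate_stock_series <- function(series, context = "stock series") {
  if (nrow(series) == 0) {
    schema_error(sprintf("%s: empty series", context))
  }
  bad_pool <- setdiff(unique(series$pool), carbon_pools())
  if (length(bad_pool) > 0) {
    schema_error(sprintf("%s: unknown pool(s): %s", context, toString(bad_pool)))
  }
  if (any(is.na(series$year)) || any(is.na(series$stock_tg))) {
    schema_error(sprintf("%s: missing year or stock_tg", context))
  }
  key <- paste(series$pool, series$year)
  if (anyDuplicated(key)) {
    schema_error(sprintf("%s: duplicate (pool, year): %s", context,
                         key[duplicated(key)][1]))
  }
  n_years <- tapply(series$year, series$pool, function(y) length(unique(y)))
  if (any(n_years < 2)) {
    schema_error(sprintf("%s: pool '%s' has fewer than 2 distinct years",
                         context, names(n_years)[which(n_years < 2)[1]]))
  }
  invisible(series)
}

#' Read and write stock tables
#'
#' A stock table holds one total national stock (Tg) per pool for a named
#' epoch -- e.g. the published 2010 inventory totals ([us_stocks_2010()]).
#' Columns: `pool`, `stock_tg`; pools unique and among [carbon_pools()],
#' totals non-negative.
#'
#' @param path Path to a CSV file.
#' @param stocks A stock table tibble.
#' @export
read_stock_table <- function(path) {
  tbl <- read_csv_strict(path, c("pool", "stock_tg"), numeric_cols = "stock_tg")
  validate_stock_table(tbl, context = path)
  arrange(tbl, pool_rank(pool))
}

#' @rdname read_stock_table
#' @export
write_stock_table <- function(stocks, path) {
  validate_stock_table(stocks)
  stocks <- arrange(stocks, pool_rank(pool))
  fields <- c(
    list(c("pool", "stock_tg")),
    lapply(seq_len(nrow(stocks)), function(i) {
      c(stocks$pool[i], fmt_num(stocks$stock_tg[i]))
    })
  )
  write_csv_lines(fields, path)
}

validate_stock_table <- function(stocks, context = "stock table") {
  if (nrow(stocks) == 0) {
    schema_error(sprintf("%s: empty stock table", context))
  }
  bad_pool <- setdiff(unique(stocks$pool), carbon_pools())
  if (length(bad_pool) > 0) {
    schema_error(sprintf("%s: unknown pool(s): %s", context, toString(bad_pool)))
  }
  if (anyDuplicated(stocks$pool)) {
    schema_error(sprintf("%s: duplicate pool", context))
  }
  if (any(is.na(stocks$stock_tg) | stocks$stock_tg < 0)) {
    schema_error(sprintf("%s: stock_tg must be non-negative", context))
  }
  invisible(stocks)
}

#' Read and write zone-median tables
#'
#' The on-disk layout mirrors the published presentation: one row per pool,
#' one column per climate zone, cells holding the median carbon density
#' (Mg/ha); empty cells mark (pool, zone) combinations with no sampled
#' plots. In memory the table is long -- columns `pool`, `zone`, `median`,
#' `n_plots` -- with an `"epoch"` attribute. Plot counts are not part of the
#' wide layout, so `n_plots` is `NA` after a read; no downstream operation
#' uses it.
#'
#' @param path Path to a CSV file.
#' @param medians A zone-median table as returned by [zone_medians()].
#' @param epoch Epoch label attached to the table on read.
#' @export
read_zone_medians <- function(path, epoch = "current") {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = NULL, fileEncoding = "UTF-8")
  if (!"pool" %in% names(raw) || ncol(raw) < 2) {
    schema_error(sprintf("%s: expected a 'pool' column plus zone columns", path))
  }
  zones <- setdiff(names(raw), "pool")
  long <- tidyr::pivot_longer(tibble::as_tibble(raw), cols = tidyr::all_of(zones),
                              names_to = "zone", values_to = "median")
  long$median[trimws(long$median) %in% c("", "NA")] <- NA_character_
  num <- suppressWarnings(as.numeric(long$median))
  bad <- which(!is.na(long$median) & is.na(num))
  if (length(bad) > 0) {
    schema_error(sprintf("%s: non-numeric median '%s' (pool %s, zone %s)",
                         path, long$median[bad[1]], long$pool[bad[1]],
                         long$zone[bad[1]]))
  }
  long$median <- num
  out <- long |>
    filter(!is.na(median)) |>
    mutate(n_plots = NA_integer_) |>
    arrange(pool_rank(pool), zone_rank(zone))
  if (any(out$median < 0)) {
    schema_error(sprintf("%s: negative median", path))
  }
  attr(out, "epoch") <- epoch
  out
}

#' @rdname read_zone_medians
#' @export
write_zone_medians <- function(medians, path) {
  zones <- unique(medians$zone[order(zone_rank(medians$zone))])
  pools <- unique(medians$pool[order(pool_rank(medians$pool))])
  wide <- matrix(NA_real_, nrow = length(pools), ncol = length(zones),
                 dimnames = list(pools, zones))
  wide[cbind(medians$pool, medians$zone)] <- medians$median
  fields <- c(
    list(c("pool", zones)),
    lapply(pools, function(p) c(p, fmt_num(wide[p, ])))
  )
  write_csv_lines(fields, path)
}

#' Read and write CV tables
#'
#' A CV table holds the across-zone coefficient of variation (%) of median
#' carbon density per pool -- the framework's likelihood axis -- plus the
#' number of zones entering each statistic. Columns: `pool`, `cv_pct`,
#' `n_zones`.
#'
#' @param path Path to a CSV file.
#' @param cvs A CV table as returned by [across_zone_cv()].
#' @export
read_cv_table <- function(path) {
  tbl <- read_csv_strict(path, c("pool", "cv_pct", "n_zones"),
                         numeric_cols = c("cv_pct", "n_zones"))
  if (any(is.na(tbl$cv_pct) | tbl$cv_pct < 0)) {
    schema_error(sprintf("%s: cv_pct must be non-negative", path))
  }
  arrange(tbl, pool_rank(pool))
}

#' @rdname read_cv_table
#' @export
write_cv_table <- function(cvs, path) {
  cvs <- arrange(cvs, pool_rank(pool))
  fields <- c(
    list(c("pool", "cv_pct", "n_zones")),
    lapply(seq_len(nrow(cvs)), function(i) {
      c(cvs$pool[i], fmt_num(cvs$cv_pct[i]), fmt_num(cvs$n_zones[i]))
    })
  )
  write_csv_lines(fields, path)
}
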