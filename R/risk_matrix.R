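# Consequence x likelihood risk matrix: classify each pool's (stock, CV)
# point into a societal-response category and report epoch trajectories.

#' Ordered societal-response categories
#'
#' The response scale of the risk matrix, from least to most proactive:
#' periodically monitor < annually monitor / develop strategies < initiate
#' adaptation/mitigation < robust mitigation.
#'
#' @return Character vector of four category labels in increasing
#'   proactivity.
#' @export
risk_categories <- function() {
  c("periodically_monitor",
    "annually_monitor_develop_strategies",
    "initiate_adaptation_mitigation",
    "robust_mitigation")
}

#' Response grid for the risk matrix
#'
#' A response grid partitions the (likelihood, consequence) plane into
#' labelled cells: `cv_breaks` (percent) cut the likelihood axis,
#' `stock_breaks` (Tg) the consequence axis, and `categories` labels each
#' cell, rows indexing stock bins from low to high and columns CV bins from
#' low to high. Bins are left-closed: a point exactly on a break falls in
#' the upper bin.
#'
#' The default is the minimal grid consistent with the published 2010
#' national assessment: one CV break at 60% and one stock break at
#' 10,000 Tg, with low-stock pools assigned to periodic monitoring
#' regardless of CV, and high-stock pools split between annual monitoring
#' (CV < 60) and initiating adaptation/mitigation (CV >= 60).
#' `robust_mitigation` is reachable only through user-supplied finer grids.
#' The label matrix must be monotone non-decreasing in proactivity along
#' both axes; the constructor enforces this.
#'
#' @param cv_breaks Strictly ascending CV thresholds (percent).
#' @param stock_breaks Strictly ascending stock thresholds (Tg).
#' @param categories Character matrix of labels from [risk_categories()],
#'   `length(stock_breaks) + 1` rows by `length(cv_breaks) + 1` columns.
#' @return An object of class `"response_grid"`.
#' @export
#' @examples
#' default_response_grid()
response_grid <- function(cv_breaks, stock_breaks, categories) {
  if (length(cv_breaks) < 1 || is.unsorted(cv_breaks, strictly = TRUE)) {
    config_error("cv_breaks must be non-empty and strictly ascending")
  }
  if (length(stock_breaks) < 1 || is.unsorted(stock_breaks, strictly = TRUE)) {
    config_error("stock_breaks must be non-empty and strictly ascending")
  }
  categories <- as.matrix(categories)
  if (nrow(categories) != length(stock_breaks) + 1 ||
      ncol(categories) != length(cv_breaks) + 1) {
    config_error(sprintf(
      "categories must be a %d x %d matrix (stock bins x cv bins)",
      length(stock_breaks) + 1, length(cv_breaks) + 1
    ))
  }
  bad <- setdiff(unique(as.vector(categories)), risk_categories())
  if (length(bad) > 0) {
    config_error(sprintf("unknown categories: %s", toString(bad)))
  }
  ranks <- matrix(match(categories, risk_categories()), nrow(categories))
  row_mono <- all(apply(ranks, 1, function(r) !is.unsorted(r)))
  col_mono <- all(apply(ranks, 2, function(r) !is.unsorted(r)))
  if (!row_mono || !col_mono) {
    config_error("categories must be non-decreasing in proactivity along both axes")
  }
  structure(
    list(cv_breaks = cv_breaks, stock_breaks = stock_breaks,
         categories = categories),
    class = "response_grid"
  )
}

#' @rdname response_grid
#' @export
default_response_grid <- function() {
  response_grid(
    cv_breaks = 60,
    stock_breaks = 10000,
    categories = matrix(
      c("periodically_monitor", "periodically_monitor",
        "annually_monitor_develop_strategies", "initiate_adaptation_mitigation"),
      nrow = 2, byrow = TRUE
    )
  )
}

#' @export
print.response_grid <- function(x, ...) {
  cat("Response grid:\n")
  cat("  cv breaks (%):   ", toString(x$cv_breaks), "\n")
  cat("  stock breaks (Tg):", toString(x$stock_breaks), "\n")
  rn <- c(paste0("< ", x$stock_breaks[1]),
          paste0(">= ", x$stock_breaks))
  cn <- c(paste0("< ", x$cv_breaks[1]), paste0(">= ", x$cv_breaks))
  m <- x$categories
  dimnames(m) <- list(stock_tg = rn[seq_len(nrow(m))],
                      cv_pct = cn[seq_len(ncol(m))])
  print(m, quote = FALSE)
  invisible(x)
}

#' Classify (stock, CV) points into response categories
#'
#' Bins each pool's total stock (consequence) and across-zone CV
#' (likelihood) by the grid's breaks -- left-closed bins, values at or
#' above the last break in the top bin -- and returns the cell's response
#' category. Vectorised over points.
#'
#' @param stock_tg Numeric vector of stock totals (Tg).
#' @param cv_pct Numeric vector of CVs (percent), same length.
#' @param grid A [response_grid()].
#' @return Ordered factor of categories with levels [risk_categories()].
#' @export
#' @examples
#' classify_risk(17572, 70.9, default_response_grid())
classify_risk <- function(stock_tg, cv_pct, grid = default_response_grid()) {
  stopifnot(inherits(grid, "response_grid"),
            length(stock_tg) == length(cv_pct))
  row <- findInterval(stock_tg, grid$stock_breaks) + 1L
  col <- findInterval(cv_pct, grid$cv_breaks) + 1L
  factor(grid$categories[cbind(row, col)],
         levels = risk_categories(), ordered = TRUE)
}

#' Assess pools across two epochs in the risk matrix
#'
#' Classifies each pool's (stock, CV) point in both epochs, and reports the
#' trajectory between them: the stock change `d_stock_tg`, its percent
#' change `pct_stock_change`, the absolute CV change `d_cv_pct`, and a
#' `more_proactive` flag set when the later epoch's category rank is at
#' least the earlier one's and neither stock nor CV decreased -- the
#' pattern of a pool drifting toward stronger societal response.
#'
#' @param points_current,points_future Tibbles with columns `pool`,
#'   `stock_tg`, `cv_pct` (one row per pool; pool sets must match).
#' @param grid A [response_grid()].
#' @param epochs Length-2 character vector of epoch labels.
#' @return Tibble with one row per pool and epoch: `pool`, `epoch`,
#'   `stock_tg`, `cv_pct`, `category` (ordered factor), and on the later
#'   epoch's rows `d_stock_tg`, `pct_stock_change`, `d_cv_pct`,
#'   `more_proactive` (`NA` on the earlier epoch's rows).
#' @export
#' @examples
#' cur <- dplyr::left_join(us_stocks_2010(),
#'                         across_zone_cv(us_zone_medians_2010()), by = "pool")
#' fut <- dplyr::left_join(us_stocks_2100(), us_cv_2100(), by = "pool")
#' assess_risk(cur, fut)
assess_risk <- function(points_current, points_future,
                        grid = default_response_grid(),
                        epochs = c("2010", "2100")) {
  stopifnot(length(epochs) == 2)
  for (pts in list(points_current, points_future)) {
    missing <- setdiff(c("pool", "stock_tg", "cv_pct"), names(pts))
    if (length(missing) > 0) {
      schema_error(sprintf("points need columns: %s", toString(missing)))
    }
  }
  only_cur <- setdiff(points_current$pool, points_future$pool)
  only_fut <- setdiff(points_future$pool, points_current$pool)
  if (length(only_cur) > 0 || length(only_fut) > 0) {
    analysis_error(
      sprintf("pool(s) present in one epoch only: %s",
              toString(c(only_cur, only_fut))),
      "carbonrisk_epoch_mismatch"
    )
  }
  cur <- points_current |>
    select(pool, stock_tg, cv_pct) |>
    mutate(epoch = epochs[1])
  fut <- points_future |>
    select(pool, stock_tg, cv_pct) |>
    mutate(epoch = epochs[2])
  cur$category <- classify_risk(cur$stock_tg, cur$cv_pct, grid)
  fut$category <- classify_risk(fut$stock_tg, fut$cv_pct, grid)
  idx <- match(fut$pool, cur$pool)
  fut <- fut |>
    mutate(
      d_stock_tg = stock_tg - cur$stock_tg[idx],
      pct_stock_change = 100 * d_stock_tg / cur$stock_tg[idx],
      d_cv_pct = cv_pct - cur$cv_pct[idx],
      more_proactive = as.integer(category) >= as.integer(cur$category[idx]) &
        d_stock_tg >= 0 & d_cv_pct >= 0
    )
  cur <- cur |>
    mutate(d_stock_tg = NA_real_, pct_stock_change = NA_real_,
           d_cv_pct = NA_real_, more_proactive = NA)
  bind_rows(cur, fut) |>
    arrange(pool_rank(pool), match(epoch, epochs))
}

#' Write a risk-assessment report as CSV
#'
#' Columns: `pool`, `epoch`, `stock_tg`, `cv_pct`, `category`,
#' `d_stock_tg`, `pct_stock_change`, `d_cv_pct`, `more_proactive`. Numbers
#' use 6 significant digits; empty cells mark the earlier epoch's undefined
#' trajectory fields. Deterministic: the same assessment always yields
#' byte-identical files.
#'
#' @param assessment Result of [assess_risk()].
#' @param path Output CSV path.
#' @export
write_assessment <- function(assessment, path) {
  fields <- c(
    list(c("pool", "epoch", "stock_tg", "cv_pct", "category",
           "d_stock_tg", "pct_stock_change", "d_cv_pct", "more_proactive")),
    lapply(seq_len(nrow(assessment)), function(i) {
      mp <- assessment$more_proactive[i]
      c(assessment$pool[i], assessment$epoch[i],
        fmt_num(assessment$stock_tg[i]), fmt_num(assessment$cv_pct[i]),
        as.character(assessment$category[i]),
        fmt_num(assessment$d_stock_tg[i]),
        fmt_num(assessment$pct_stock_change[i]),
        fmt_num(assessment$d_cv_pct[i]),
        if (is.na(mp)) "" else tolower(as.character(mp)))
    })
  )
  write_csv_lines(fields, path)
}

#' Read a response grid from a YAML/JSON file
#'
#' Expected keys: `cv_breaks`, `stock_breaks` (ascending numeric lists) and
#' `categories`, a list of rows (low to high stock), each a list of labels
#' (low to high CV).
#'
#' @param path Path to a YAML (or JSON) file.
#' @return A validated [response_grid()].
#' @export
read_grid_config <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  for (nm in c("cv_breaks", "stock_breaks", "categories")) {
    if (is.null(raw[[nm]])) {
      schema_error(sprintf("%s: missing grid key '%s'", path, nm))
    }
  }
  cats <- do.call(rbind, lapply(raw$categories, unlist))
  response_grid(unlist(raw$cv_breaks), unlist(raw$stock_breaks), cats)
}
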