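test_that("the default grid reproduces the published 2010 response categories", {
  stocks <- setNames(us_stocks_2010()$stock_tg, us_stocks_2010()$pool)
  cvs <- printed_cv_2010()
  grid <- default_response_grid()
  got <- classify_risk(stocks[names(cvs)], cvs, grid)
  expect_equal(
    as.character(got),
    c("annually_monitor_develop_strategies",  # live AG: large stock, CV < 60
      "periodically_monitor",                 # live BG
      "periodically_monitor",                 # dead wood
      "periodically_monitor",                 # forest floor
      "initiate_adaptation_mitigation")       # SOC: large stock, CV >= 60
  )
})

test_that("points exactly on a break fall in the upper bin", {
  grid <- default_response_grid()
  expect_equal(as.character(classify_risk(10000, 60, grid)),
               "initiate_adaptation_mitigation")
  expect_equal(as.character(classify_risk(9999.999, 59.999, grid)),
               "periodically_monitor")
  expect_equal(as.character(classify_risk(10000, 59.999, grid)),
               "annually_monitor_develop_strategies")
})

test_that("grid construction rejects malformed and non-monotone grids", {
  expect_error(response_grid(c(60, 50), 10000,
                             matrix("periodically_monitor", 2, 3)),
               class = "carbonrisk_config_error")
  expect_error(response_grid(60, 10000, matrix("periodically_monitor", 3, 3)),
               "2 x 2", class = "carbonrisk_config_error")
  expect_error(response_grid(60, 10000,
                             matrix(c("periodically_monitor", "nonsense",
                                      "periodically_monitor",
                                      "periodically_monitor"), 2)),
               class = "carbonrisk_config_error")
  # proactivity decreasing along the cv axis in the top row: invalid
  expect_error(response_grid(60, 10000, matrix(
    c("periodically_monitor", "periodically_monitor",
      "initiate_adaptation_mitigation", "annually_monitor_develop_strategies"),
    2, byrow = TRUE)), "non-decreasing", class = "carbonrisk_config_error")
})

test_that("category rank is monotone when stock and cv both increase", {
  grid <- default_response_grid()
  set.seed(3)
  for (i in 1:25) {
    stocks <- sort(runif(6, 0, 25000))
    cvs <- sort(runif(6, 0, 100))
    ranks <- as.integer(classify_risk(stocks, cvs, grid))
    expect_false(is.unsorted(ranks))
  }
})

test_that("assessment computes trajectories and flags proactive movement", {
  cur <- tibble::tibble(pool = c("live_ag", "soc"),
                        stock_tg = c(9000, 12000), cv_pct = c(55, 59))
  fut <- tibble::tibble(pool = c("live_ag", "soc"),
                        stock_tg = c(11000, 12500), cv_pct = c(56, 61))
  out <- assess_risk(cur, fut, epochs = c("now", "later"))
  later <- out[out$epoch == "later", ]
  # live_ag crosses the stock break: one-step category escalation
  expect_equal(as.integer(later$category[later$pool == "live_ag"]) -
                 as.integer(out$category[out$epoch == "now" &
                                           out$pool == "live_ag"]), 1L)
  # soc crosses the cv break from annually_monitor to initiate
  expect_equal(as.character(later$category[later$pool == "soc"]),
               "initiate_adaptation_mitigation")
  expect_equal(later$d_stock_tg, c(2000, 500))
  expect_equal(later$d_cv_pct, c(1, 2))
  expect_true(all(later$more_proactive))
})

test_that("identical epochs give zero trajectories and unchanged categories", {
  pts <- tibble::tibble(pool = carbon_pools(),
                        stock_tg = c(14541, 2876, 2627, 4941, 17572),
                        cv_pct = c(43.1, 44.6, 55.2, 53.4, 70.9))
  out <- assess_risk(pts, pts)
  fut <- out[out$epoch == "2100", ]
  expect_true(all(fut$d_stock_tg == 0))
  expect_true(all(fut$d_cv_pct == 0))
  expect_true(all(fut$more_proactive))  # rank unchanged, deltas zero
  expect_identical(as.character(fut$category),
                   as.character(out$category[out$epoch == "2010"]))
})

test_that("mismatched pool sets across epochs are an error", {
  cur <- tibble::tibble(pool = c("live_ag", "soc"),
                        stock_tg = c(1, 2), cv_pct = c(3, 4))
  expect_error(assess_risk(cur, cur[1, ]), "soc",
               class = "carbonrisk_epoch_mismatch")
})

test_that("assessment reports are written deterministically with empty current-epoch deltas", {
  cur <- tibble::tibble(pool = "live_ag", stock_tg = 14541, cv_pct = 43.1)
  fut <- tibble::tibble(pool = "live_ag", stock_tg = 21657, cv_pct = 43.3)
  out <- assess_risk(cur, fut)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_assessment(out, p1)
  write_assessment(out, p2)
  expect_identical(readLines(p1), readLines(p2))
  lines <- readLines(p1)
  expect_equal(lines[1],
               "pool,epoch,stock_tg,cv_pct,category,d_stock_tg,pct_stock_change,d_cv_pct,more_proactive")
  expect_match(lines[2], ",,,$")        # 2010 row: no deltas
  expect_match(lines[3], "7116")        # 2100 row carries the stock delta
  expect_match(lines[3], "true$")
})

test_that("a response grid round-trips through a YAML config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "cv_breaks: [50, 70]",
    "stock_breaks: [5000, 15000]",
    "categories:",
    "  - [periodically_monitor, periodically_monitor, annually_monitor_develop_strategies]",
    "  - [periodically_monitor, annually_monitor_develop_strategies, initiate_adaptation_mitigation]",
    "  - [annually_monitor_develop_strategies, initiate_adaptation_mitigation, robust_mitigation]"
  ), path)
  grid <- read_grid_config(path)
  expect_s3_class(grid, "response_grid")
  expect_equal(as.character(classify_risk(17572, 70.9, grid)),
               "robust_mitigation")
})
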