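test_that("bundled 2010 national reference tables parse to the published values", {
  stocks <- us_stocks_2010()
  expect_equal(
    setNames(stocks$stock_tg, stocks$pool)[carbon_pools()],
    c(live_ag = 14541, live_bg = 2876, dead_wood = 2627,
      forest_floor = 4941, soc = 17572)
  )
  med <- us_zone_medians_2010()
  expect_equal(nrow(med), 30)  # 5 pools x 6 zones, all cells populated
  expect_equal(med$median[med$pool == "live_ag" & med$zone == "equatorial"], 14.02)
  expect_equal(med$median[med$pool == "soc" & med$zone == "equatorial"], 158.01)
  expect_identical(attr(med, "epoch"), "2010")
})

test_that("plot table round-trips through write and read, including missing cells", {
  plots <- full_pool_plots()
  plots$dead_wood[2] <- NA  # missing density becomes an empty cell
  path <- withr::local_tempfile(fileext = ".csv")
  write_plot_table(plots, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(plots) + 1)
  expect_match(lines[3], ",,", fixed = TRUE)
  back <- read_plot_table(path)
  expect_equal(as.data.frame(back), as.data.frame(plots))
})

test_that("writers are byte-deterministic", {
  plots <- generate_plot_table(sim_config(n_plots = 50, seed = 9))
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_plot_table(plots, p1)
  write_plot_table(plots, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("an empty plot table writes a header-only file", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_plot_table(full_pool_plots()[0, ], path)
  expect_equal(readLines(path),
               "plot_id,zone_current,zone_future,expansion_ha,live_ag,live_bg,dead_wood,forest_floor,soc")
})

test_that("plot table schema violations are rejected with the offending row/column named", {
  path <- withr::local_tempfile(fileext = ".csv")

  dup <- full_pool_plots()
  dup$plot_id[2] <- dup$plot_id[1]
  write.csv(dup, path, row.names = FALSE, na = "")
  expect_error(read_plot_table(path), "duplicate plot_id",
               class = "carbonrisk_schema_error")

  neg <- full_pool_plots()
  neg$soc[3] <- -1
  write.csv(neg, path, row.names = FALSE, na = "")
  expect_error(read_plot_table(path), "negative density.*'soc', row 3",
               class = "carbonrisk_schema_error")

  extra <- full_pool_plots()
  extra$bogus <- 1
  write.csv(extra, path, row.names = FALSE, na = "")
  expect_error(read_plot_table(path), "unknown column.*bogus",
               class = "carbonrisk_schema_error")

  gap <- full_pool_plots()
  gap[2, carbon_pools()] <- NA_real_
  write.csv(gap, path, row.names = FALSE, na = "")
  expect_error(read_plot_table(path), "row 2 has no carbon density",
               class = "carbonrisk_schema_error")

  expect_error(read_plot_table(file.path(tempdir(), "does-not-exist.csv")),
               class = "carbonrisk_io_error")
})

test_that("NA strings and empty cells both read as missing, and are never written as 'NA'", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "plot_id,zone_current,zone_future,expansion_ha,live_ag,live_bg,dead_wood,forest_floor,soc",
    "X1,arid,arid,2428,5,NA,,1,2"
  ), path)
  tbl <- read_plot_table(path)
  expect_true(is.na(tbl$live_bg))
  expect_true(is.na(tbl$dead_wood))
  out <- withr::local_tempfile(fileext = ".csv")
  write_plot_table(tbl, out)
  expect_false(any(grepl("NA", readLines(out))))
})

test_that("stock series validation catches duplicates, unknown pools, single years", {
  s <- tibble::tibble(pool = "live_ag", year = c(1990, 1990), stock_tg = c(1, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(s, path, row.names = FALSE)
  expect_error(read_stock_series(path), "duplicate",
               class = "carbonrisk_schema_error")

  s <- tibble::tibble(pool = "litter", year = c(1990, 2000), stock_tg = c(1, 2))
  write.csv(s, path, row.names = FALSE)
  expect_error(read_stock_series(path), "unknown pool",
               class = "carbonrisk_schema_error")

  s <- tibble::tibble(pool = "live_ag", year = 1990, stock_tg = 1)
  write.csv(s, path, row.names = FALSE)
  expect_error(read_stock_series(path), "fewer than 2 distinct years",
               class = "carbonrisk_schema_error")

  writeLines("pool,year,stock_tg", path)
  expect_error(read_stock_series(path), "empty",
               class = "carbonrisk_schema_error")
})

test_that("stock series and stock tables round-trip", {
  series <- generate_stock_series(sim_config(n_plots = 10, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_stock_series(series, path)
  back <- read_stock_series(path)
  expect_equal(back$stock_tg, series$stock_tg, tolerance = 1e-5)  # 6 sig digits
  expect_equal(back$year, series$year)

  stocks <- us_stocks_2010()
  write_stock_table(stocks, path)
  expect_equal(as.data.frame(read_stock_table(path)), as.data.frame(stocks))
})

test_that("zone-median and CV tables round-trip through the wide published layout", {
  med <- us_zone_medians_2010()
  path <- withr::local_tempfile(fileext = ".csv")
  write_zone_medians(med, path)
  back <- read_zone_medians(path, epoch = "2010")
  expect_equal(back$median, med$median)
  expect_equal(back$pool, med$pool)
  expect_equal(back$zone, med$zone)

  # sparse table: an absent (pool, zone) cell survives a round trip as absent
  sparse <- med[!(med$pool == "soc" & med$zone == "arid"), ]
  write_zone_medians(sparse, path)
  back <- read_zone_medians(path)
  expect_equal(nrow(back), 29)
  expect_false(any(back$pool == "soc" & back$zone == "arid"))

  cvs <- across_zone_cv(med)
  write_cv_table(cvs, path)
  back <- read_cv_table(path)
  expect_equal(back$cv_pct, cvs$cv_pct, tolerance = 1e-5)
})
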