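# Small in-code fixtures shared across test files.

# four-plot, two-zone toy: zone A densities (1, 3), zone B (10, 30);
# plot A2 shifts A -> B. Hand-computable medians and imputation results.
toy_shift_plots <- function() {
  tibble::tibble(
    plot_id = c("A1", "A2", "B1", "B2"),
    zone_current = c("A", "A", "B", "B"),
    zone_future = c("A", "B", "B", "B"),
    expansion_ha = 2428,
    live_ag = c(1, 3, 10, 30),
    live_bg = NA_real_, dead_wood = NA_real_,
    forest_floor = NA_real_, soc = NA_real_
  )
}

# minimal valid plot table with all five pools over two zones
full_pool_plots <- function(n_per_zone = 2) {
  zones <- rep(c("snow_fully_humid", "arid"), each = n_per_zone)
  n <- length(zones)
  tibble::tibble(
    plot_id = sprintf("F%02d", seq_len(n)),
    zone_current = zones,
    zone_future = zones,
    expansion_ha = 2428,
    live_ag = seq(10, by = 5, length.out = n),
    live_bg = seq(2, by = 1, length.out = n),
    dead_wood = seq(3, by = 2, length.out = n),
    forest_floor = seq(5, by = 3, length.out = n),
    soc = seq(40, by = 20, length.out = n)
  )
}

# published 2010 across-zone CVs, rounded to one decimal as printed
printed_cv_2010 <- function() {
  c(live_ag = 43.1, live_bg = 44.6, dead_wood = 55.2,
    forest_floor = 53.4, soc = 70.9)
}

# independent two-pass CV oracle (percent, n-1 denominator)
cv_oracle <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s2 <- sum((x - m)^2) / (n - 1)
  100 * sqrt(s2) / m
}

# closed-form OLS oracle via normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx * sx)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}
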