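#' The five UNFCCC forest carbon pools
#'
#' Canonical identifiers, in canonical order, for the five forest ecosystem
#' carbon pools used throughout the package: live aboveground biomass, live
#' belowground biomass, dead wood (standing and downed), forest floor
#' (litter), and soil organic carbon.
#'
#' @return Character vector of five pool ids.
#' @export
#' @examples
#' carbon_pools()
carbon_pools <- function() {
  c("live_ag", "live_bg", "dead_wood", "forest_floor", "soc")
}

#' Display labels for carbon pools
#'
#' @return Named character vector mapping pool ids to human-readable labels.
#' @export
pool_labels <- function() {
  c(
    live_ag = "Live aboveground",
    live_bg = "Live belowground",
    dead_wood = "Dead wood",
    forest_floor = "Forest floor",
    soc = "Soil organic C"
  )
}

#' Default Koeppen-Geiger main climate zone set
#'
#' The six main-class Koeppen-Geiger groups covering conterminous-US forest
#' land: equatorial, arid, warm temperate (fully humid), warm temperate
#' (summer dry), snow (fully humid), snow (summer dry). Any non-empty, unique
#' set of zone labels can be used instead; this is the default vocabulary.
#'
#' @return Character vector of six zone ids.
#' @export
koppen_zones <- function() {
  c(
    "equatorial", "arid",
    "warm_temperate_fully_humid", "warm_temperate_summer_dry",
    "snow_fully_humid", "snow_summer_dry"
  )
}

# rank helper: canonical ordering for pools/zones, unknown zones sort last,
# alphabetically, so writers stay deterministic for user-defined zone sets
pool_rank <- function(p) match(p, carbon_pools())
zone_rank <- function(z) {
  r <- match(z, koppen_zones())
  r[is.na(r)] <- length(koppen_zones()) + rank(z[is.na(r)], ties.method = "min")
  r
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "carbonrisk", mustWork = TRUE)
  path
}

#' Published US national reference tables (2010 and 2100)
#'
#' Accessors for the national-scale reference values bundled with the package
#' as plain CSV under `inst/extdata`:
#'
#' * `us_zone_medians_2010()` — median carbon density (Mg/ha) per pool and
#'   Koeppen-Geiger zone for the 2010 epoch, from the US national forest
#'   inventory.
#' * `us_stocks_2010()` / `us_stocks_2100()` — total national stock per pool
#'   (Tg) for 2010 (inventory estimate) and 2100 (linear projection).
#' * `us_cv_2010()` / `us_cv_2100()` — across-zone coefficient of variation
#'   per pool (%): the published 2010 values (one decimal, as printed) and
#'   the 2100 projection under the A1F1 zone-shift scenario.
#'
#' These serve both as literal inputs for reproducing the published national
#' assessment and as calibration defaults for [sim_config()].
#'
#' @return A [zone_medians] table, a stock table, or a CV table (tibbles).
#' @seealso [read_zone_medians()], [read_stock_table()], [read_cv_table()]
#' @export
us_zone_medians_2010 <- function() {
  read_zone_medians(extdata("us_zone_medians_2010.csv"), epoch = "2010")
}

#' @rdname us_zone_medians_2010
#' @export
us_stocks_2010 <- function() read_stock_table(extdata("us_stocks_2010.csv"))

#' @rdname us_zone_medians_2010
#' @export
us_stocks_2100 <- function() read_stock_table(extdata("us_stocks_2100.csv"))

#' @rdname us_zone_medians_2010
#' @export
us_cv_2010 <- function() {
  out <- read_cv_table(extdata("us_cv_2010.csv"))
  attr(out, "epoch") <- "2010"
  out
}

#' @rdname us_zone_medians_2010
#' @export
us_cv_2100 <- function() {
  out <- read_cv_table(extdata("us_cv_2100.csv"))
  attr(out, "epoch") <- "2100"
  out
}
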