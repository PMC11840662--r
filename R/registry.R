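# Controlled vocabularies shared across modules -------------------------------

#' Controlled vocabularies
#'
#' Land-cover classes, oil crops, staple crops and climate zones used across
#' the package. Land cover is stored as per-pixel fractions so a 5-arcmin
#' pixel can hold forest and cropland at once.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
cover_classes <- c(
  "bare", "grassland", "shrubland",
  "annual_crop_rainfed", "annual_crop_irrigated",
  "perennial_crop_rainfed", "perennial_crop_irrigated",
  "forest", "urban", "water", "wetland"
)

#' @rdname vocabularies
#' @export
includable_covers <- c(
  "bare", "grassland", "shrubland",
  "annual_crop_rainfed", "annual_crop_irrigated",
  "perennial_crop_rainfed", "perennial_crop_irrigated",
  "forest"
)

#' @rdname vocabularies
#' @export
oil_crops <- c("oil_palm", "soybean", "sunflower", "rapeseed")

#' @rdname vocabularies
#' @export
staple_crops <- c("wheat", "maize", "rice", "legumes", "tubers")

#' @rdname vocabularies
#' @export
climate_zones <- c("boreal", "temperate", "tropical_moist", "tropical_dry")

annual_covers    <- c("annual_crop_rainfed", "annual_crop_irrigated")
perennial_covers <- c("perennial_crop_rainfed", "perennial_crop_irrigated")

#' Parameter registry
#'
#' All scalar constants of the analysis in one auditable list: per-capita
#' consumption rates, SSP2 population, oil/seed extraction ratios, food-use
#' shares, current production, and the carbon-accounting constants (orchard
#' biomass stocks, the oil-palm regrowth stock, peat drainage emission
#' factors, the 25-year amortization horizon). Every pipeline output embeds
#' the registry it was computed with, so a run is auditable from its artifacts.
#'
#' @param ... Named overrides for any top-level entry, e.g.
#'   `default_registry(population_2050_millions = 9500)`.
#'
#' @return A named list of class `oilscape_registry`.
#'
#' @details Units: rates kg/capita/yr, production Mt/yr, carbon stocks
#'   Mg C/ha, peat emission factors Mg C/ha/yr. The worst suitability class
#'   still eligible for allocation is 5 ("moderate"); classes 6-8 are
#'   excluded. `orchard_maturity_yr` (30) is carried for audit but unused:
#'   orchard conversion books the full at-maturity stock.
#'
#' @examples
#' reg <- default_registry()
#' reg$food_use_share[["palm"]]
#' @export
default_registry <- function(...) {
  reg <- list(
    population_2050_millions = 9187,
    # per-capita food consumption, kg/capita/yr (2018-2020 global averages)
    current_rates = c(
      palm = 2.4, palm_kernel = 0.19,
      rapeseed = 1.24, soybean = 3.14, sunflower = 1.55, other = 2.79
    ),
    # EAT-Lancet reference intakes, g/day
    eat_palm_intake_g_day = 6.8,
    eat_unsaturated_intake_g_day = 40,
    # mass of oil extracted per mass of harvested seed
    oil_seed_ratio = c(soybean = 0.20, rapeseed = 0.35, sunflower = 0.35),
    # share of soybean seed that goes to crushing at all
    soybean_seed_to_oil_share = 0.84,
    # share of each oil's production destined for direct food use
    food_use_share = c(palm = 0.25, rapeseed = 0.38, soybean = 0.41, sunflower = 0.61),
    # current global production, Mt/yr
    current_production_mt = c(
      palm = 73.5, palm_kernel = 8, soybean = 58, rapeseed = 25, sunflower = 20
    ),
    # eligibility: suitability class must be <= this (1 best .. 8 unsuitable)
    max_suitability_class = 5,
    # carbon accounting
    amortization_yr = 25,
    orchard_agb_mgc_ha = c(
      temperate = 63, tropical_moist = 21, tropical_dry = 9, boreal = 9
    ),
    orchard_maturity_yr = 30,
    palm_stock_mgc_ha = 40,
    palm_stock_age_yr = 25,
    peat_ef_mgc_ha_yr = c(boreal = 0.2, temperate = 1.1, tropical = 2.0),
    c_to_co2 = 44 / 12
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(reg))
    if (length(unknown)) {
      abort(paste0("Unknown registry entries: ", paste(unknown, collapse = ", ")))
    }
    reg[names(dots)] <- dots
  }
  validate_registry(reg)
  structure(reg, class = "oilscape_registry")
}

validate_registry <- function(reg) {
  stopifnot(
    reg$population_2050_millions > 0,
    all(reg$current_rates >= 0),
    all(reg$oil_seed_ratio > 0), all(reg$oil_seed_ratio <= 1),
    reg$soybean_seed_to_oil_share > 0, reg$soybean_seed_to_oil_share <= 1,
    all(reg$food_use_share > 0), all(reg$food_use_share <= 1),
    all(reg$current_production_mt >= 0),
    reg$amortization_yr > 0,
    all(reg$orchard_agb_mgc_ha >= 0),
    all(sort(names(reg$orchard_agb_mgc_ha)) == sort(climate_zones)),
    reg$palm_stock_mgc_ha >= 0,
    all(reg$peat_ef_mgc_ha_yr >= 0),
    reg$c_to_co2 > 0
  )
  invisible(reg)
}

#' @export
print.oilscape_registry <- function(x, ...) {
  cat("<oilscape parameter registry>\n")
  cat("  population 2050:", x$population_2050_millions, "million\n")
  cat("  food-use shares:",
      paste(names(x$food_use_share), x$food_use_share, sep = "=", collapse = " "), "\n")
  cat("  amortization:", x$amortization_yr, "yr; palm stock:",
      x$palm_stock_mgc_ha, "Mg C/ha\n")
  invisible(x)
}
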