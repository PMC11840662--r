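# Land-use-change carbon accounting -------------------------------------------
#
# Annualized CO2 from converting the consumed covers: forest biomass loss at
# the country carbon density, orchard (perennial-crop) biomass loss at the
# climate-zone stock, both amortized over the 25-year crop tenure and netted
# (floored at zero per land unit) against the oil-palm regrowth sink; peat
# drainage as a perpetual annual soil flux. Bare/grass/shrub/annual covers
# carry zero biomass flux; non-peat soil, dead wood and litter pools are
# never counted.

zero_stock_covers <- c("bare", "grassland", "shrubland",
                       "annual_crop_rainfed", "annual_crop_irrigated")

collapse_peat_zone <- function(zone) {
  if_else(zone %in% c("tropical_moist", "tropical_dry"), "tropical", zone)
}

# net amortized biomass emission per hectare, Mg CO2/yr
biomass_rate_co2_ha <- function(stock_mgc_ha, crop, registry, net_floor = TRUE) {
  sink <- if_else(crop == "oil_palm", registry$palm_stock_mgc_ha, 0)
  net <- if (net_floor) pmax(stock_mgc_ha - sink, 0) else stock_mgc_ha - sink
  net / registry$amortization_yr * registry$c_to_co2
}

#' Annual emissions from forest conversion
#'
#' One twenty-fifth of the biomass carbon stock lost at conversion, as CO2.
#' Conversion to oil palm is netted against the palm regrowth sink (stock at
#' maturity over the same horizon), floored at zero per land unit.
#'
#' @param area_ha Converted forest area, hectares.
#' @param c_density_mgc_ha Above- plus below-ground biomass carbon, Mg C/ha.
#' @param crop Destination crop.
#' @param registry A [default_registry()].
#' @return Mg CO2/yr, vectorized.
#' @examples
#' forest_annual_emissions(1, 100, "soybean") # 100/25 * 44/12 = 14.67
#' forest_annual_emissions(1, 100, "oil_palm") # (100-40)/25 * 44/12 = 8.80
#' @export
forest_annual_emissions <- function(area_ha, c_density_mgc_ha, crop,
                                    registry = default_registry()) {
  if (any(area_ha < 0) || any(c_density_mgc_ha < 0)) {
    abort("areas and carbon densities must be non-negative")
  }
  area_ha * biomass_rate_co2_ha(c_density_mgc_ha, crop, registry)
}

#' Annual emissions from perennial-cropland conversion
#'
#' The orchard's at-maturity above-ground biomass stock (by climate zone) is
#' treated as lost and amortized over the 25-year tenure, with the same
#' oil-palm sink netting as forest conversion.
#'
#' @param area_ha Converted orchard area, hectares.
#' @param climate_zone One of [climate_zones].
#' @param crop Destination crop.
#' @param registry A [default_registry()].
#' @return Mg CO2/yr, vectorized.
#' @examples
#' perennial_annual_emissions(1, "temperate", "soybean") # 63/25 * 44/12 = 9.24
#' @export
perennial_annual_emissions <- function(area_ha, climate_zone, crop,
                                       registry = default_registry()) {
  if (!all(climate_zone %in% climate_zones)) abort("unknown climate zone")
  stock <- registry$orchard_agb_mgc_ha[climate_zone]
  area_ha * biomass_rate_co2_ha(unname(stock), crop, registry)
}

#' Annual soil emissions from peat drainage
#'
#' Ongoing annual flux (not amortized): area times the climate-zone emission
#' factor (boreal 0.2, temperate 1.1, tropical 2.0 Mg C/ha/yr), as CO2.
#' Additive to the biomass loss of whatever cover overlays the peat.
#'
#' @param area_ha Drained peat area, hectares.
#' @param climate_zone One of [climate_zones] (the tropical zones share one
#'   factor).
#' @param registry A [default_registry()].
#' @return Mg CO2/yr, vectorized.
#' @examples
#' peat_annual_emissions(1, "tropical_moist") # 2 * 44/12 = 7.33
#' @export
peat_annual_emissions <- function(area_ha, climate_zone,
                                  registry = default_registry()) {
  if (!all(climate_zone %in% climate_zones)) abort("unknown climate zone")
  ef <- registry$peat_ef_mgc_ha_yr[collapse_peat_zone(climate_zone)]
  area_ha * unname(ef) * registry$c_to_co2
}

#' Emissions ledger for a set of allocations
#'
#' Converts the consumed-cover detail of one or more allocations into an
#' annualized CO2 ledger per crop x prior cover x mechanism
#' (`forest_biomass`, `perennial_biomass`, `peat_soil`, `palm_sink_credit`;
#' zero-stock covers -- bare, grassland, shrubland, annual cropland -- and the
#' existing-palm slice appear under mechanism `none` with zero flux).
#' The sink credit appears as negative rows bounded so the *net* biomass
#' emission per land unit is never negative (set `net_floor = FALSE` to book
#' the full credit); it is never netted against the peat soil flux. Zero-
#' stock covers appear with their consumed area and zero flux; the
#' existing-palm slice carries no LUC and no peat flux.
#'
#' @param results An `oilscape_allocation` or a list of them.
#' @param world The world they were computed on.
#' @param registry A [default_registry()].
#' @param cover_order,trim_overshoot Passed to the cover-consumption detail,
#'   see [cover_breakdown()].
#' @param net_floor Floor net biomass emissions at zero per land unit.
#' @return Tibble of class `oilscape_emissions` with `crop`, `cover`,
#'   `mechanism`, `area_ha`, `c_mt_yr`, `co2_mt_yr`.
#' @export
emissions_ledger <- function(results, world, registry = default_registry(),
                             cover_order = "proportional",
                             trim_overshoot = FALSE, net_floor = TRUE) {
  if (inherits(results, "oilscape_allocation")) results <- list(results)
  amort <- registry$amortization_yr
  ratio <- registry$c_to_co2
  rows <- purrr::map_dfr(results, function(res) {
    detail <- consumption_detail(res, world, cover_order, trim_overshoot)
    if (!nrow(detail)) return(tibble())
    info <- world$pixels %>%
      select("pixel", "country_id", "climate_zone", "peat_fraction") %>%
      left_join(world$carbon, by = "country_id")
    if (any(is.na(info$c_density_mgc_ha[info$pixel %in% detail$pixel]))) {
      bad <- unique(info$country_id[is.na(info$c_density_mgc_ha)])
      abort(paste0("no carbon density for country ", paste(bad, collapse = ", ")))
    }
    d <- detail %>% left_join(info, by = "pixel")
    sink <- if (res$crop == "oil_palm") registry$palm_stock_mgc_ha else 0
    stock <- dplyr::case_when(
      d$cover == "forest" ~ d$c_density_mgc_ha,
      d$cover %in% perennial_covers ~
        unname(registry$orchard_agb_mgc_ha[d$climate_zone]),
      TRUE ~ 0
    )
    credit <- if (net_floor) pmin(stock, sink) else rep(sink, length(stock))
    credit[stock == 0] <- 0 # sink credited only against biomass losses
    mech <- dplyr::case_when(
      d$cover == "forest" ~ "forest_biomass",
      d$cover %in% perennial_covers ~ "perennial_biomass",
      TRUE ~ "none"
    )
    gross <- tibble(
      crop = res$crop, cover = d$cover, mechanism = mech,
      area_ha = d$area_ha,
      c_mt_yr = d$area_ha * stock / amort / 1e6
    )
    credit_rows <- tibble(
      crop = res$crop, cover = d$cover, mechanism = "palm_sink_credit",
      area_ha = d$area_ha,
      c_mt_yr = -d$area_ha * credit / amort / 1e6
    ) %>% filter(.data$c_mt_yr != 0)
    peat_rows <- d %>%
      filter(.data$cover != "existing_palm") %>%
      mutate(
        peat_ha = .data$area_ha * .data$peat_fraction,
        ef = unname(registry$peat_ef_mgc_ha_yr[collapse_peat_zone(.data$climate_zone)])
      ) %>%
      summarise(
        crop = res$crop, cover = "peat_overlay", mechanism = "peat_soil",
        area_ha = sum(.data$peat_ha),
        c_mt_yr = sum(.data$peat_ha * .data$ef) / 1e6
      )
    dplyr::bind_rows(gross, credit_rows, peat_rows)
  })
  if (!nrow(rows)) {
    rows <- tibble(crop = character(), cover = character(),
                   mechanism = character(), area_ha = numeric(),
                   c_mt_yr = numeric())
  }
  ledger <- rows %>%
    group_by(.data$crop, .data$cover, .data$mechanism) %>%
    summarise(
      area_ha = sum(.data$area_ha),
      c_mt_yr = sum(.data$c_mt_yr),
      .groups = "drop"
    ) %>%
    mutate(co2_mt_yr = .data$c_mt_yr * ratio)
  structure(ledger, class = c("oilscape_emissions", class(tibble())),
            registry = registry)
}

#' @method glance oilscape_emissions
#' @export
glance.oilscape_emissions <- function(x, ...) {
  x %>%
    group_by(.data$crop) %>%
    summarise(
      co2_mt_yr = sum(.data$co2_mt_yr),
      forest_mha = sum(.data$area_ha[.data$mechanism == "forest_biomass" &
                                       .data$cover == "forest"]) / 1e6,
      peat_mha = sum(.data$area_ha[.data$mechanism == "peat_soil"]) / 1e6,
      .groups = "drop"
    )
}

#' @method tidy oilscape_emissions
#' @export
tidy.oilscape_emissions <- function(x, ...) as_tibble(x)

#' @rdname autoplot-oilscape
#' @method autoplot oilscape_emissions
#' @export
autoplot.oilscape_emissions <- function(object, ...) {
  df <- as_tibble(object) %>%
    group_by(.data$crop, .data$mechanism) %>%
    summarise(co2_mt_yr = sum(.data$co2_mt_yr), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$crop, y = .data$co2_mt_yr,
                                   fill = .data$mechanism)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = expression(Mt ~ CO[2] ~ yr^-1), fill = NULL) +
    ggplot2::theme_minimal()
}
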