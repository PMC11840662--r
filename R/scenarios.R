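# Demand scenarios ------------------------------------------------------------
#
# Per-capita consumption rates -> 2050 food-oil demand (Mt) under the current
# and EAT-Lancet rate sets, with 0/25/50/100% of palm + palm-kernel food use
# replaced by a production-share-weighted blend of rapeseed, soybean and
# sunflower oil. Demands are carried unrounded; presentation rounding happens
# only in format_demand_table().

oil_labels <- c("palm", "palm_kernel", "rapeseed", "soybean", "sunflower", "other")
unsaturated_oils <- c("rapeseed", "soybean", "sunflower")

#' Convert a daily intake to an annual per-capita rate
#'
#' @param intake_g_day Intake in g/capita/day.
#' @return kg/capita/yr (`intake * 365 / 1000`). The EAT-Lancet palm intake of
#'   6.8 g/day annualizes to 2.482 kg (displayed as 2.5); 40 g/day of
#'   unsaturated oils annualizes to 14.6 kg.
#' @export
annualize_rate <- function(intake_g_day) {
  if (any(intake_g_day < 0)) abort("intake must be non-negative")
  intake_g_day * 365 / 1000
}

#' Current per-capita consumption rates
#'
#' @param registry A [default_registry()].
#' @return Tibble with `oil`, `rate_kg_yr`, `scenario = "current"`.
#' @export
current_rates <- function(registry = default_registry()) {
  tibble(
    oil = names(registry$current_rates),
    rate_kg_yr = unname(registry$current_rates),
    scenario = "current"
  )
}

#' Break EAT-Lancet intake totals into per-oil rates
#'
#' The EAT-Lancet diet gives one palm-oil intake and one unsaturated-oil
#' intake. The palm total is split into palm vs palm-kernel oil by their
#' current shares; the unsaturated total is split across rapeseed, soybean,
#' sunflower and other oils by their current shares.
#'
#' @param total_unsat_rate,total_palm_rate Annual totals, kg/capita/yr.
#' @param current Tibble from [current_rates()] (or same shape).
#' @return Tibble with `oil`, `rate_kg_yr`, `scenario = "eat_lancet"`.
#' @export
split_eat_rates <- function(total_unsat_rate, total_palm_rate,
                            current = current_rates()) {
  get <- function(oils) {
    v <- current$rate_kg_yr[match(oils, current$oil)]
    if (any(is.na(v))) abort("current rates missing for some oils")
    v
  }
  palm_share <- get(c("palm", "palm_kernel"))
  unsat_share <- get(c(unsaturated_oils, "other"))
  if (sum(palm_share) <= 0 || sum(unsat_share) <= 0) {
    abort("current shares are all zero; cannot allocate EAT totals")
  }
  tibble(
    oil = c("palm", "palm_kernel", unsaturated_oils, "other"),
    rate_kg_yr = c(
      total_palm_rate * palm_share / sum(palm_share),
      total_unsat_rate * unsat_share / sum(unsat_share)
    ),
    scenario = "eat_lancet"
  ) %>%
    arrange(match(.data$oil, oil_labels))
}

#' Project a per-capita rate to 2050 demand
#'
#' @param rate_kg_yr kg/capita/yr.
#' @param population_millions Population in millions (SSP2 2050: 9187).
#' @return Demand in Mt/yr: `rate * population / 1000`.
#' @export
project_demand <- function(rate_kg_yr, population_millions) {
  if (any(rate_kg_yr < 0) || any(population_millions < 0)) {
    abort("rate and population must be non-negative")
  }
  rate_kg_yr * population_millions / 1000
}

#' Weights for distributing replaced palm oil
#'
#' The palm mass removed under a replacement scenario is allocated to
#' rapeseed, soybean and sunflower proportionally to their current *food*
#' production, i.e. production x food-use share, normalized.
#'
#' @param registry A [default_registry()].
#' @return Tibble with `oil` and `weight` (weights sum to 1).
#' @export
replacement_weights <- function(registry = default_registry()) {
  prod <- registry$current_production_mt[unsaturated_oils]
  share <- registry$food_use_share[unsaturated_oils]
  w <- prod * share
  if (sum(w) <= 0) abort("zero total food production among substitute oils")
  tibble(oil = unsaturated_oils, weight = unname(w / sum(w)))
}

#' Apply a palm-replacement fraction to a base demand table
#'
#' Scales palm and palm-kernel demand by `1 - fraction` and distributes the
#' replaced mass across the three substitute oils by `weights`; total
#' palm + main-unsaturated demand is conserved.
#'
#' @param base Tibble with `oil`, `demand_mt` at 0% replacement.
#' @param fraction Replacement fraction in [0, 1].
#' @param weights Tibble from [replacement_weights()].
#' @return Tibble with `oil`, `demand_mt`, `replacement`.
#' @export
apply_replacement <- function(base, fraction, weights = replacement_weights()) {
  if (fraction < 0 || fraction > 1) abort("replacement fraction must be in [0, 1]")
  palm_mask <- base$oil %in% c("palm", "palm_kernel")
  replaced <- sum(base$demand_mt[palm_mask]) * fraction
  out <- base
  out$demand_mt[palm_mask] <- base$demand_mt[palm_mask] * (1 - fraction)
  idx <- match(weights$oil, out$oil)
  out$demand_mt[idx] <- out$demand_mt[idx] + replaced * weights$weight
  out$replacement <- fraction
  out
}

#' Build the full demand-scenario table
#'
#' The eight scenarios of the analysis: {current, EAT-Lancet} consumption
#' rates x {0, 25, 50, 100}% palm replacement, projected to the 2050 SSP2
#' population. "Other" oils are reported but never allocated to land.
#'
#' @param registry A [default_registry()].
#' @param fractions Replacement fractions.
#' @return A tibble of class `oilscape_scenarios` with columns
#'   `rate_scenario`, `replacement`, `oil`, `rate_kg_yr`, `demand_mt`.
#' @examples
#' scen <- build_scenario_table()
#' scen %>% glance()
#' @export
build_scenario_table <- function(registry = default_registry(),
                                 fractions = c(0, 0.25, 0.5, 1)) {
  cur <- current_rates(registry)
  eat <- split_eat_rates(
    annualize_rate(registry$eat_unsaturated_intake_g_day),
    annualize_rate(registry$eat_palm_intake_g_day),
    cur
  )
  w <- replacement_weights(registry)
  pop <- registry$population_2050_millions
  out <- purrr::map_dfr(list(cur, eat), function(rates) {
    base <- rates %>% mutate(demand_mt = project_demand(.data$rate_kg_yr, pop))
    purrr::map_dfr(fractions, function(f) {
      apply_replacement(
        base %>% select("oil", "demand_mt"), f, w
      ) %>%
        mutate(
          rate_scenario = rates$scenario[1],
          rate_kg_yr = rates$rate_kg_yr[match(.data$oil, rates$oil)]
        )
    })
  }) %>%
    select("rate_scenario", "replacement", "oil", "rate_kg_yr", "demand_mt")
  structure(out, class = c("oilscape_scenarios", class(tibble())),
            registry = registry)
}

#' Presentation rounding of the demand table
#'
#' Wide layout with one column per rate-scenario x replacement combination,
#' components rounded to 0.1 Mt and the summary rows (total palm, total main
#' unsaturated, palm + unsaturated, grand total) computed over the *rounded*
#' components, the convention used in published summary tables. Unrounded
#' demands stay available in the long table for audit.
#'
#' @param scenarios A [build_scenario_table()] result.
#' @return A tibble, one row per oil or summary line.
#' @export
format_demand_table <- function(scenarios) {
  wide <- scenarios %>%
    mutate(
      cell = round(.data$demand_mt, 1),
      col = paste0(.data$rate_scenario, "_", .data$replacement * 100, "pct")
    ) %>%
    select("oil", "col", "cell") %>%
    tidyr::pivot_wider(names_from = "col", values_from = "cell")
  num_cols <- setdiff(names(wide), "oil")
  sum_row <- function(oils, label) {
    vals <- lapply(wide[num_cols], function(v) sum(v[wide$oil %in% oils]))
    dplyr::bind_cols(tibble(oil = label), as_tibble(vals))
  }
  dplyr::bind_rows(
    wide %>% filter(.data$oil %in% c("palm", "palm_kernel")),
    sum_row(c("palm", "palm_kernel"), "total_palm"),
    wide %>% filter(.data$oil %in% unsaturated_oils),
    sum_row(unsaturated_oils, "total_main_unsaturated"),
    sum_row(c("palm", "palm_kernel", unsaturated_oils), "total_palm_and_unsaturated"),
    wide %>% filter(.data$oil == "other"),
    sum_row(oil_labels, "total")
  )
}

#' @method glance oilscape_scenarios
#' @export
glance.oilscape_scenarios <- function(x, ...) {
  x %>%
    group_by(.data$rate_scenario, .data$replacement) %>%
    summarise(
      total_mt = sum(.data$demand_mt),
      palm_mt = sum(.data$demand_mt[.data$oil %in% c("palm", "palm_kernel")]),
      unsaturated_mt = sum(.data$demand_mt[.data$oil %in% unsaturated_oils]),
      .groups = "drop"
    )
}

#' @method tidy oilscape_scenarios
#' @export
tidy.oilscape_scenarios <- function(x, ...) as_tibble(x)

#' @rdname autoplot-oilscape
#' @method autoplot oilscape_scenarios
#' @export
autoplot.oilscape_scenarios <- function(object, ...) {
  df <- as_tibble(object) %>%
    filter(.data$oil != "other") %>%
    mutate(
      oil = factor(.data$oil, levels = oil_labels),
      replacement = factor(paste0(.data$replacement * 100, "%"),
                           levels = paste0(c(0, 25, 50, 100), "%"))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$replacement, y = .data$demand_mt,
                                   fill = .data$oil)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~.data$rate_scenario) +
    ggplot2::labs(x = "palm-oil replacement", y = "food-oil demand (Mt/yr)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
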