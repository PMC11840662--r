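# End-to-end orchestration -----------------------------------------------------
#
# world (synthetic or read) -> demand scenarios -> per-crop allocation ->
# emissions ledger -> staple displacement, with one seed driving everything
# and the registry serialized into every artifact bundle.

#' Per-crop demands of a scenario table
#'
#' Maps oils onto land-bearing crops: palm + palm-kernel demand is one
#' oil-palm demand (kernel gets no separate land); "other" oils are reported
#' in the demand table but never allocated.
#'
#' @param scenarios A [build_scenario_table()] result.
#' @return Tibble with `rate_scenario`, `replacement`, `crop`, `demand_mt`.
#' @export
crop_demands <- function(scenarios) {
  scenarios %>%
    filter(.data$oil != "other") %>%
    mutate(crop = dplyr::recode(.data$oil,
      palm = "oil_palm", palm_kernel = "oil_palm",
      soybean = "soybean", sunflower = "sunflower", rapeseed = "rapeseed"
    )) %>%
    group_by(.data$rate_scenario, .data$replacement, .data$crop) %>%
    summarise(demand_mt = sum(.data$demand_mt), .groups = "drop")
}

#' Run the full pipeline on a world
#'
#' Generates (or takes) a world, builds the demand-scenario table, allocates
#' every scenario x palm-mode combination, and derives the emissions ledger
#' and staple-displacement report. Because a synthetic landscape cannot
#' absorb global Mt-scale demands, demands are mapped onto the world by a
#' single multiplicative scale; `demand_scale = "auto"` (default) picks the
#' scale so that the largest per-crop demand across the scenario set uses
#' `target_utilization` of that crop's attributed food-oil capacity, keeping
#' every scenario feasible while leaving the scenario *ratios* untouched.
#'
#' @param world An `oilscape_world`, or `NULL` to generate one from `config`.
#' @param config A [world_config()] used when `world` is `NULL` (its seed is
#'   the run's single source of randomness).
#' @param registry A [default_registry()].
#' @param fractions Palm-replacement fractions.
#' @param palm_modes Which oil-palm priority modes to run.
#' @param cover_order Within-pixel cover consumption order, see
#'   [cover_breakdown()].
#' @param demand_scale `"auto"` or a positive number multiplying all Mt
#'   demands before allocation.
#' @param target_utilization Capacity share used by the auto scale.
#' @param out_dir If non-`NULL`, write the CSV artifact bundle and a JSON
#'   manifest there.
#' @param allow_shortfall If `FALSE` (default) an infeasible allocation
#'   aborts the run; if `TRUE` it is flagged in the land table instead.
#' @return An `oilscape_run`: list with `scenarios`, `land`, `emissions`,
#'   `displacement`, `results` (nested allocations), `demand_scale`, `seed`,
#'   `registry`, `world`.
#' @examples
#' \donttest{
#' run <- run_pipeline(config = world_config(n_rows = 40, n_cols = 40, seed = 3))
#' run$land
#' }
#' @export
run_pipeline <- function(world = NULL, config = world_config(),
                         registry = default_registry(),
                         fractions = c(0, 0.25, 0.5, 1),
                         palm_modes = c("yield", "proximity"),
                         cover_order = "proportional",
                         demand_scale = "auto", target_utilization = 0.6,
                         out_dir = NULL, allow_shortfall = FALSE) {
  if (is.null(world)) world <- generate_world(config)
  seed <- attr(world, "config")$seed %||% config$seed
  scen <- build_scenario_table(registry, fractions)
  demands <- crop_demands(scen)
  mask <- build_mask(world, registry)
  attribution <- attribute_crops(mask)

  pool_capacity <- mask %>%
    inner_join(attribution, by = c("pixel", "crop")) %>%
    filter(.data$included) %>%
    group_by(.data$crop) %>%
    summarise(capacity_mt = sum(.data$available_ha * .data$food_oil_yield_t_ha) / 1e6,
              .groups = "drop")
  if (identical(demand_scale, "auto")) {
    peak <- demands %>%
      group_by(.data$crop) %>%
      summarise(max_mt = max(.data$demand_mt), .groups = "drop") %>%
      left_join(pool_capacity, by = "crop")
    if (any(is.na(peak$capacity_mt)) || any(peak$capacity_mt <= 0)) {
      abort("world has no attributed capacity for at least one crop")
    }
    demand_scale <- target_utilization * min(peak$capacity_mt / peak$max_mt)
  }
  if (!is.numeric(demand_scale) || demand_scale <= 0) {
    abort("demand_scale must be 'auto' or a positive number")
  }

  combos <- demands %>%
    distinct(.data$rate_scenario, .data$replacement)
  results <- list()
  land_rows <- list()
  emis_rows <- list()
  disp_rows <- list()
  for (i in seq_len(nrow(combos))) {
    rs <- combos$rate_scenario[i]; f <- combos$replacement[i]
    dem <- demands %>% filter(.data$rate_scenario == rs, .data$replacement == f)
    for (pm in palm_modes) {
      allocs <- purrr::map(oil_crops, function(cp) {
        d <- dem$demand_mt[dem$crop == cp] * demand_scale
        rank_and_allocate(world, cp, d,
                          mode = if (cp == "oil_palm") pm else "yield",
                          registry = registry,
                          mask = mask, attribution = attribution)
      })
      names(allocs) <- oil_crops
      bad <- purrr::keep(allocs, ~ .x$infeasible)
      if (length(bad) && !allow_shortfall) {
        abort(paste0("infeasible allocation for ",
                     paste(names(bad), collapse = ", "),
                     " in scenario ", rs, " / ", f * 100, "% (",
                     pm, " mode); rerun with allow_shortfall = TRUE"))
      }
      key <- paste(rs, f, pm, sep = "|")
      results[[key]] <- allocs
      land_rows[[key]] <- purrr::map_dfr(allocs, function(a) {
        bd <- cover_breakdown(a, world, cover_order)
        glance(a) %>%
          mutate(
            rate_scenario = rs, replacement = f, palm_mode = pm,
            area_mha = .data$area_ha / 1e6,
            forest_mha = sum(bd$area_ha[bd$cover == "forest"]) / 1e6,
            annual_crop_mha = sum(bd$area_ha[bd$cover %in% annual_covers]) / 1e6,
            existing_palm_mha = attr(bd, "existing_palm_ha") / 1e6,
            peat_mha = attr(bd, "peat_overlap_ha") / 1e6
          )
      })
      led <- emissions_ledger(allocs, world, registry, cover_order)
      emis_rows[[key]] <- glance(led) %>%
        mutate(rate_scenario = rs, replacement = f, palm_mode = pm)
      disp_rows[[key]] <- staple_displacement(allocs, world, cover_order) %>%
        mutate(rate_scenario = rs, replacement = f, palm_mode = pm)
    }
  }
  run <- structure(
    list(
      scenarios = scen,
      land = dplyr::bind_rows(land_rows),
      emissions = dplyr::bind_rows(emis_rows),
      displacement = dplyr::bind_rows(disp_rows),
      results = results,
      demand_scale = demand_scale,
      seed = seed,
      registry = registry,
      world = world
    ),
    class = "oilscape_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write the artifact bundle of a run
#'
#' CSVs for the demand table (long and presentation layouts), land totals
#' with cover breakdown, emissions summary and staple displacement, plus a
#' JSON manifest embedding the seed, the demand scale and the full parameter
#' registry for audit. Units are fixed in the column names (Mt oil, Mha
#' land, Mt CO2/yr).
#'
#' @param run An `oilscape_run`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_csv(as_tibble(run$scenarios), file.path(out_dir, "demand_long.csv"),
                   progress = FALSE)
  readr::write_csv(format_demand_table(run$scenarios),
                   file.path(out_dir, "demand_table.csv"), progress = FALSE)
  readr::write_csv(run$land, file.path(out_dir, "land_totals.csv"), progress = FALSE)
  readr::write_csv(run$emissions, file.path(out_dir, "emissions_summary.csv"),
                   progress = FALSE)
  readr::write_csv(run$displacement, file.path(out_dir, "displacement.csv"),
                   progress = FALSE)
  manifest <- list(
    seed = run$seed,
    demand_scale = run$demand_scale,
    registry = unclass(run$registry),
    n_rows = run$world$n_rows, n_cols = run$world$n_cols,
    cell_deg = run$world$cell_deg
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.oilscape_run <- function(x, ...) {
  cat("<oilscape run> seed ", x$seed, ", demand scale ",
      format(x$demand_scale, digits = 4), "\n", sep = "")
  totals <- x$land %>%
    group_by(.data$rate_scenario, .data$replacement, .data$palm_mode) %>%
    summarise(area_mha = sum(.data$area_mha), .groups = "drop")
  print(totals, n = nrow(totals))
  invisible(x)
}

#' @method glance oilscape_run
#' @export
glance.oilscape_run <- function(x, ...) {
  land <- x$land %>%
    group_by(.data$rate_scenario, .data$replacement, .data$palm_mode) %>%
    summarise(
      area_mha = sum(.data$area_mha),
      forest_mha = sum(.data$forest_mha),
      .groups = "drop"
    )
  emis <- x$emissions %>%
    group_by(.data$rate_scenario, .data$replacement, .data$palm_mode) %>%
    summarise(co2_mt_yr = sum(.data$co2_mt_yr), .groups = "drop")
  land %>% left_join(emis, by = c("rate_scenario", "replacement", "palm_mode"))
}
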