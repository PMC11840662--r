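# Pixel-level land allocation --------------------------------------------------
#
# Inclusion/exclusion -> attribution -> priority ranking -> greedy accumulation
# of food-oil production until demand is met. Pixels are consumed whole, in a
# deterministic total order; the overshoot past demand is reported rather than
# trimmed (the within-pixel cover-order modes can trim the marginal pixel's
# *breakdown* on request, see cover_breakdown()).

#' Food-oil yield per hectare
#'
#' Converts attainable yield into food-oil production per hectare: seed
#' yields are scaled by the oil/seed extraction ratio (plus, for soybean, the
#' share of seed that is crushed at all), oil-palm yields are already oil;
#' every crop is then scaled by its food-use share so the land charged to a
#' demand is the land needed for the *food* fraction of production.
#'
#' @param crop Crop label(s) in [oil_crops].
#' @param attainable_yield Attainable yield, t/ha/yr (seed; oil for oil palm).
#' @param registry A [default_registry()].
#' @return Food-oil yield, t/ha/yr, vectorized.
#' @examples
#' food_oil_yield("soybean", 3.0) # 3.0 * 0.84 * 0.20 * 0.41
#' food_oil_yield("oil_palm", 4.0) # 4.0 * 0.25
#' @export
food_oil_yield <- function(crop, attainable_yield, registry = default_registry()) {
  if (any(attainable_yield < 0)) abort("attainable yield must be non-negative")
  unknown <- setdiff(unique(crop), oil_crops)
  if (length(unknown)) {
    abort(paste0("unknown oil crop(s): ", paste(unknown, collapse = ", ")))
  }
  fs <- registry$food_use_share
  osr <- registry$oil_seed_ratio
  factor <- dplyr::case_when(
    crop == "oil_palm" ~ fs[["palm"]],
    crop == "soybean" ~ registry$soybean_seed_to_oil_share * osr[["soybean"]] * fs[["soybean"]],
    crop == "rapeseed" ~ osr[["rapeseed"]] * fs[["rapeseed"]],
    crop == "sunflower" ~ osr[["sunflower"]] * fs[["sunflower"]]
  )
  attainable_yield * factor
}

#' Eligibility mask
#'
#' Applies the inclusion and exclusion criteria per pixel and crop: a pixel
#' is included for a crop iff it has nonzero area under an includable cover
#' (bare, grassland, shrubland, annual and perennial cropland, forest -- not
#' urban, water or wetland) and the crop's suitability class is at most 5
#' ("moderate"); class 6 ("marginal") or worse excludes the pixel outright.
#'
#' @param world An `oilscape_world`.
#' @param registry A [default_registry()].
#' @return Tibble with one row per pixel x crop: `pixel`, `crop`,
#'   `suitability`, `attainable_yield`, `food_oil_yield_t_ha`,
#'   `available_ha` (pixel area times includable cover fraction), `included`,
#'   and `reason` (`included` / `excluded_suitability` / `excluded_cover`).
#' @export
build_mask <- function(world, registry = default_registry()) {
  px <- world$pixels
  inc_frac <- rowSums(as.matrix(px[paste0("cover_", includable_covers)]))
  avail <- px$pixel_area_ha * inc_frac
  world$crops %>%
    mutate(
      available_ha = avail[.data$pixel],
      food_oil_yield_t_ha = food_oil_yield(.data$crop, .data$attainable_yield, registry),
      reason = dplyr::case_when(
        .data$suitability > registry$max_suitability_class ~ "excluded_suitability",
        avail[.data$pixel] <= 0 ~ "excluded_cover",
        TRUE ~ "included"
      ),
      included = .data$reason == "included"
    )
}

#' Attribute each pixel to one oil crop
#'
#' Among the crops for which a pixel is included, the pixel goes to the crop
#' with the best (lowest) suitability class; ties go to the crop with the
#' highest attainable food-oil yield, then to a fixed crop order for
#' determinism. Pixels included for no crop get `NA`.
#'
#' @param mask Tibble from [build_mask()].
#' @return Tibble with `pixel` and `crop` (`NA` when unattributed).
#' @export
attribute_crops <- function(mask) {
  attributed <- mask %>%
    filter(.data$included) %>%
    mutate(crop_rank = match(.data$crop, oil_crops)) %>%
    group_by(.data$pixel) %>%
    arrange(.data$suitability, dplyr::desc(.data$food_oil_yield_t_ha),
            .data$crop_rank, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("pixel", "crop")
  tibble(pixel = sort(unique(mask$pixel))) %>%
    left_join(attributed, by = "pixel")
}

#' Rank pixels and allocate land until demand is met
#'
#' Sorts the pixels attributed to `crop` by the priority criteria -- better
#' suitability class first, then higher attainable yield (mode `"yield"`), or
#' for oil palm optionally higher existing-palm share before yield (mode
#' `"proximity"`, emulating expansion adjacent to existing plantations) --
#' and consumes whole pixels in that order, accumulating food-oil production
#' (available area x food-oil yield) until it reaches `demand_mt`.
#'
#' @param world An `oilscape_world`.
#' @param crop One of [oil_crops].
#' @param demand_mt Food-oil demand to satisfy, Mt/yr.
#' @param mode `"yield"` or (oil palm only) `"proximity"`.
#' @param registry A [default_registry()].
#' @param mask,attribution Optional precomputed [build_mask()] /
#'   [attribute_crops()] results, so a scenario sweep reuses them.
#' @param proximity_first If `TRUE`, proximity mode ranks existing-palm share
#'   above suitability; default keeps suitability dominant.
#' @return An `oilscape_allocation`: the selected pixels in priority order
#'   with cumulative production, total area and production, overshoot past
#'   demand, the marginal pixel's threshold characteristics, and -- when the
#'   world cannot meet the demand -- an `infeasible` flag with the shortfall
#'   (all eligible pixels selected, no error).
#' @examples
#' w <- make_toy_world("five_pixel_line")
#' a <- rank_and_allocate(w, "soybean", demand_mt = 3e-5)
#' glance(a)
#' @export
rank_and_allocate <- function(world, crop, demand_mt, mode = c("yield", "proximity"),
                              registry = default_registry(),
                              mask = NULL, attribution = NULL,
                              proximity_first = FALSE) {
  mode <- match.arg(mode)
  if (demand_mt < 0) abort("demand must be non-negative")
  if (mode == "proximity" && crop != "oil_palm") {
    abort("proximity mode is defined only for oil palm")
  }
  if (is.null(mask)) mask <- build_mask(world, registry)
  if (is.null(attribution)) attribution <- attribute_crops(mask)
  crop_label <- crop
  pool <- mask %>%
    filter(.data$crop == crop_label, .data$included) %>%
    inner_join(attribution %>% filter(.data$crop == crop_label),
               by = c("pixel", "crop")) %>%
    left_join(world$pixels %>% select("pixel", "existing_palm_share"), by = "pixel")
  ord <- if (mode == "proximity" && proximity_first) {
    order(-pool$existing_palm_share, pool$suitability,
          -pool$attainable_yield, pool$pixel)
  } else if (mode == "proximity") {
    order(pool$suitability, -pool$existing_palm_share,
          -pool$attainable_yield, pool$pixel)
  } else {
    order(pool$suitability, -pool$attainable_yield, pool$pixel)
  }
  pool <- pool[ord, ] %>%
    mutate(
      production_mt = .data$available_ha * .data$food_oil_yield_t_ha / 1e6,
      cum_production_mt = cumsum(.data$production_mt),
      priority = row_number()
    )
  total_capacity <- if (nrow(pool)) pool$cum_production_mt[nrow(pool)] else 0
  infeasible <- total_capacity < demand_mt
  n_sel <- if (demand_mt == 0) {
    0L
  } else if (infeasible) {
    nrow(pool)
  } else {
    which(pool$cum_production_mt >= demand_mt)[1]
  }
  selected <- head(pool, n_sel) %>%
    select("pixel", "priority", "suitability", "attainable_yield",
           "food_oil_yield_t_ha", "existing_palm_share", "available_ha",
           "production_mt", "cum_production_mt")
  production <- if (n_sel) selected$cum_production_mt[n_sel] else 0
  threshold <- if (n_sel) {
    m <- selected[n_sel, ]
    list(suitability = m$suitability, attainable_yield = m$attainable_yield,
         existing_palm_share = if (mode == "proximity") m$existing_palm_share else NA_real_,
         pixel = m$pixel)
  } else {
    list(suitability = NA_integer_, attainable_yield = NA_real_,
         existing_palm_share = NA_real_, pixel = NA_integer_)
  }
  structure(
    list(
      crop = crop, mode = mode, demand_mt = demand_mt,
      selected = selected,
      n_pixels = n_sel,
      area_ha = sum(selected$available_ha),
      production_mt = production,
      overshoot_mt = max(0, production - demand_mt),
      infeasible = infeasible,
      shortfall_mt = max(0, demand_mt - total_capacity),
      threshold = threshold,
      registry = registry
    ),
    class = "oilscape_allocation"
  )
}

#' @export
print.oilscape_allocation <- function(x, ...) {
  cat("<oilscape allocation> ", x$crop, " (", x$mode, " mode): ",
      x$n_pixels, " pixels, ", format(x$area_ha, digits = 4), " ha, ",
      format(x$production_mt, digits = 4), " Mt food oil (demand ",
      format(x$demand_mt, digits = 4), ")",
      if (x$infeasible) paste0(" INFEASIBLE, shortfall ",
                               format(x$shortfall_mt, digits = 4), " Mt"),
      "\n", sep = "")
  invisible(x)
}

#' @method tidy oilscape_allocation
#' @export
tidy.oilscape_allocation <- function(x, ...) x$selected

#' @method glance oilscape_allocation
#' @export
glance.oilscape_allocation <- function(x, ...) {
  tibble(
    crop = x$crop, mode = x$mode, demand_mt = x$demand_mt,
    n_pixels = x$n_pixels, area_ha = x$area_ha,
    production_mt = x$production_mt, overshoot_mt = x$overshoot_mt,
    infeasible = x$infeasible, shortfall_mt = x$shortfall_mt,
    threshold_suitability = x$threshold$suitability,
    threshold_yield = x$threshold$attainable_yield
  )
}

# Per-pixel consumed-area detail, long over cover classes. The existing-palm
# slice (oil palm only) is carved proportionally out of the includable covers
# as a zero-LUC "existing_palm" category. With trim = FALSE every selected
# pixel contributes its full available area, so all cover orders coincide;
# with trim = TRUE the marginal pixel is charged only the area needed to meet
# demand, drawn from its covers per `cover_order`.
consumption_detail <- function(result, world,
                               cover_order = c("proportional", "forest_first", "forest_last"),
                               trim_overshoot = FALSE) {
  cover_order <- match.arg(cover_order)
  sel <- result$selected
  if (!nrow(sel)) {
    return(tibble(pixel = integer(), cover = character(), area_ha = numeric()))
  }
  px <- world$pixels[match(sel$pixel, world$pixels$pixel), ]
  inc_cols <- paste0("cover_", includable_covers)
  A <- as.matrix(px[inc_cols]) * px$pixel_area_ha
  colnames(A) <- includable_covers
  consumed <- sel$available_ha
  if (trim_overshoot && result$n_pixels > 0 && !result$infeasible) {
    m <- result$n_pixels
    before <- if (m > 1) sel$cum_production_mt[m - 1] else 0
    frac <- if (sel$production_mt[m] > 0) {
      (result$demand_mt - before) / sel$production_mt[m]
    } else 1
    consumed[m] <- consumed[m] * max(0, min(1, frac))
  }
  e <- if (result$crop == "oil_palm") {
    pmin(px$existing_palm_share * px$pixel_area_ha, consumed)
  } else {
    rep(0, nrow(px))
  }
  new_area <- consumed - e
  avail_total <- rowSums(A)
  # carve the zero-LUC slice proportionally out of the covers
  Ar <- A * ifelse(avail_total > 0, (avail_total - e) / avail_total, 0)
  Ar_total <- rowSums(Ar)
  out <- matrix(0, nrow(px), length(includable_covers),
                dimnames = list(NULL, includable_covers))
  full <- new_area >= Ar_total - 1e-9
  out[full, ] <- Ar[full, , drop = FALSE]
  part <- which(!full)
  if (length(part)) {
    ord <- switch(cover_order,
      proportional = NULL,
      forest_first = c("forest", setdiff(includable_covers, "forest")),
      forest_last = c(setdiff(includable_covers, "forest"), "forest")
    )
    for (i in part) {
      if (is.null(ord)) {
        out[i, ] <- if (Ar_total[i] > 0) Ar[i, ] * new_area[i] / Ar_total[i] else 0
      } else {
        left <- new_area[i]
        for (k in ord) {
          take <- min(Ar[i, k], left)
          out[i, k] <- take
          left <- left - take
        }
      }
    }
  }
  detail <- as_tibble(out) %>%
    mutate(pixel = px$pixel, existing_palm = e) %>%
    tidyr::pivot_longer(-"pixel", names_to = "cover", values_to = "area_ha")
  detail
}

#' Prior-land-cover breakdown of an allocation
#'
#' Splits the consumed area of each selected pixel across its prior land
#' covers (plus the zero-LUC `existing_palm` slice for oil palm) and reports
#' class totals, the peat overlay of the newly converted area, and the
#' existing-palm overlap.
#'
#' @param result An `oilscape_allocation`.
#' @param world The world it was computed on.
#' @param cover_order How the marginal pixel's covers are consumed when
#'   `trim_overshoot = TRUE`: `"proportional"` (default), `"forest_first"` or
#'   `"forest_last"`. With whole-pixel consumption (the default) all three
#'   coincide.
#' @param trim_overshoot If `TRUE`, charge the marginal pixel only the area
#'   needed to meet demand exactly.
#' @return Tibble with `cover`, `area_ha`, `area_mha`; attributes
#'   `peat_overlap_ha`, `existing_palm_ha` and `total_ha`.
#' @export
cover_breakdown <- function(result, world,
                            cover_order = c("proportional", "forest_first", "forest_last"),
                            trim_overshoot = FALSE) {
  detail <- consumption_detail(result, world, cover_order, trim_overshoot)
  agg <- detail %>%
    group_by(.data$cover) %>%
    summarise(area_ha = sum(.data$area_ha), .groups = "drop") %>%
    mutate(area_mha = .data$area_ha / 1e6)
  new_by_pixel <- detail %>%
    filter(.data$cover != "existing_palm") %>%
    group_by(.data$pixel) %>%
    summarise(new_ha = sum(.data$area_ha), .groups = "drop")
  peat <- new_by_pixel %>%
    left_join(world$pixels %>% select("pixel", "peat_fraction"), by = "pixel") %>%
    summarise(x = sum(.data$new_ha * .data$peat_fraction)) %>%
    pull(.data$x)
  structure(
    agg,
    peat_overlap_ha = if (length(peat)) peat else 0,
    existing_palm_ha = sum(agg$area_ha[agg$cover == "existing_palm"]),
    total_ha = sum(agg$area_ha)
  )
}
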