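# Independent brute-force reference for the allocation algorithm.
# Deliberately naive: explicit pairwise comparator + selection-sort scan over
# the raw world tables, with the oil-conversion constants written out inline.

oracle_food_factor <- function(crop) {
  switch(crop,
    oil_palm = 0.25,
    soybean = 0.84 * 0.20 * 0.41,
    rapeseed = 0.35 * 0.38,
    sunflower = 0.35 * 0.61,
    stop("unknown crop")
  )
}

# eligibility + attribution straight from the definitions, one pixel at a time
oracle_pool <- function(world, crop) {
  px <- world$pixels
  inc <- paste0("cover_", c(
    "bare", "grassland", "shrubland", "annual_crop_rainfed",
    "annual_crop_irrigated", "perennial_crop_rainfed",
    "perennial_crop_irrigated", "forest"
  ))
  pool <- list()
  for (p in px$pixel) {
    avail <- px$pixel_area_ha[px$pixel == p] * sum(unlist(px[px$pixel == p, inc]))
    if (avail <= 0) next
    cands <- world$crops[world$crops$pixel == p & world$crops$suitability <= 5, ]
    if (!nrow(cands)) next
    cands$foy <- mapply(function(cp, y) y * oracle_food_factor(cp),
                        cands$crop, cands$attainable_yield)
    best <- cands[order(cands$suitability, -cands$foy,
                        match(cands$crop, oil_crops)), ][1, ]
    if (best$crop != crop) next
    pool[[length(pool) + 1]] <- data.frame(
      pixel = p, suitability = best$suitability,
      yield = best$attainable_yield, foy = best$foy,
      palm_share = px$existing_palm_share[px$pixel == p],
      available_ha = avail
    )
  }
  if (!length(pool)) return(NULL)
  do.call(rbind, pool)
}

oracle_better <- function(a, b, mode) {
  if (a$suitability != b$suitability) return(a$suitability < b$suitability)
  if (mode == "proximity" && a$palm_share != b$palm_share) {
    return(a$palm_share > b$palm_share)
  }
  if (a$yield != b$yield) return(a$yield > b$yield)
  a$pixel < b$pixel
}

oracle_allocate <- function(world, crop, demand_mt, mode = "yield") {
  pool <- oracle_pool(world, crop)
  sel <- integer(0)
  cum <- 0
  area <- 0
  threshold <- NULL
  while (!is.null(pool) && nrow(pool) > 0 && (cum < demand_mt)) {
    best_i <- 1
    for (i in seq_len(nrow(pool))) {
      if (oracle_better(pool[i, ], pool[best_i, ], mode)) best_i <- i
    }
    b <- pool[best_i, ]
    sel <- c(sel, b$pixel)
    cum <- cum + b$available_ha * b$foy / 1e6
    area <- area + b$available_ha
    threshold <- b
    pool <- pool[-best_i, , drop = FALSE]
  }
  if (demand_mt == 0) {
    sel <- integer(0); cum <- 0; area <- 0; threshold <- NULL
  }
  list(
    selected = sel, production_mt = cum, area_ha = area,
    overshoot_mt = max(0, cum - demand_mt),
    infeasible = cum < demand_mt,
    threshold_pixel = if (is.null(threshold)) NA_integer_ else threshold$pixel
  )
}

# small deterministic fixture: palm clusters sit on converted (grassland)
# land while the high-yield frontier is forested; used for the mode-contrast
# checks
mode_contrast_world <- function() {
  n <- 16 # 4 x 4
  px <- tibble::tibble(
    pixel = 1:n,
    row = rep(1:4, each = 4), col = rep(1:4, times = 4),
    lat = 0, lon = 0, pixel_area_ha = 100
  )
  for (nm in paste0("cover_", cover_classes)) px[[nm]] <- 0
  converted <- px$pixel <= 8
  px$cover_grassland[converted] <- 1
  px$cover_forest[!converted] <- 1
  px$peat_fraction <- 0
  px$country_id <- 1L
  px$climate_zone <- "tropical_moist"
  px$existing_palm_share <- ifelse(converted, 0.4, 0)
  for (nm in paste0("staple_", staple_crops)) px[[nm]] <- 0
  crops <- tibble::tibble(
    pixel = 1:n, crop = "oil_palm", suitability = 2L,
    attainable_yield = ifelse(converted, 3.0, 4.0)
  )
  carbon <- tibble::tibble(country_id = 1L, c_density_mgc_ha = 120)
  new_world(px, crops, carbon, 4, 4)
}
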