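# Eligibility, attribution, greedy allocation, cover breakdown

test_that("food-oil yield applies extraction and food-use scaling", {
  expect_equal(food_oil_yield("soybean", 3.0), 3.0 * 0.84 * 0.20 * 0.41)
  expect_equal(food_oil_yield("oil_palm", 4.0), 1.0)
  expect_equal(food_oil_yield("rapeseed", 2.0), 2.0 * 0.35 * 0.38)
  expect_equal(food_oil_yield("sunflower", 0), 0)
  expect_error(food_oil_yield("coconut", 1), "unknown")
})

test_that("exclusion criteria drop water pixels and marginal suitability", {
  w <- tiny_world(
    covers = list(
      c(water = 1),                 # pure water -> excluded
      c(forest = 0.4, urban = 0.6), # 40% usable
      c(grassland = 1)              # suitability 6 -> excluded
    ),
    crops = tibble::tibble(
      pixel = 1:3, crop = "soybean",
      suitability = c(3L, 3L, 6L), attainable_yield = c(2, 2, 2)
    )
  )
  m <- build_mask(w)
  expect_equal(m$reason, c("excluded_cover", "included", "excluded_suitability"))
  expect_equal(m$available_ha[2], 0.4 * 100)
})

test_that("attribution picks the best class, breaking ties by food-oil yield", {
  w <- tiny_world(
    covers = rep(list(c(grassland = 1)), 3),
    crops = dplyr::bind_rows(
      tibble::tibble(pixel = 1, crop = c("oil_palm", "soybean"),
                     suitability = c(2L, 4L), attainable_yield = c(3, 3)),
      # class tie at 3: sunflower food oil 2*0.35*0.61=0.427 beats
      # soybean 3*0.84*0.2*0.41=0.207
      tibble::tibble(pixel = 2, crop = c("soybean", "sunflower"),
                     suitability = c(3L, 3L), attainable_yield = c(3, 2)),
      tibble::tibble(pixel = 3, crop = c("soybean", "rapeseed"),
                     suitability = c(8L, 8L), attainable_yield = c(0, 0))
    ),
    zone = "tropical_moist"
  )
  att <- attribute_crops(build_mask(w))
  expect_equal(att$crop, c("oil_palm", "sunflower", NA))
})

test_that("allocation on the five-pixel line matches the brute-force oracle", {
  w <- make_toy_world("five_pixel_line")
  foy <- function(y) y * 0.84 * 0.20 * 0.41
  # demand sized so exactly three pixels are needed
  demand <- (100 * foy(3.0) + 100 * foy(2.5) + 0.5 * 100 * foy(2.0)) / 1e6
  a <- rank_and_allocate(w, "soybean", demand)
  o <- oracle_allocate(w, "soybean", demand)
  expect_equal(a$selected$pixel, o$selected)
  expect_equal(a$selected$pixel, c(1L, 2L, 3L)) # suitability then yield
  expect_equal(a$production_mt, o$production_mt)
  expect_equal(a$area_ha, o$area_ha)
  expect_equal(a$overshoot_mt, o$overshoot_mt)
  expect_equal(a$threshold$pixel, o$threshold_pixel)
  expect_equal(a$threshold$suitability, 2L)
})

test_that("zero demand selects nothing; excess demand flags infeasibility", {
  w <- make_toy_world("five_pixel_line")
  a0 <- rank_and_allocate(w, "soybean", 0)
  expect_equal(a0$n_pixels, 0L)
  expect_equal(a0$overshoot_mt, 0)
  cap <- sum(100 * w$crops$attainable_yield * 0.84 * 0.20 * 0.41) / 1e6
  a <- rank_and_allocate(w, "soybean", cap + 1e-9)
  expect_true(a$infeasible)
  expect_equal(a$n_pixels, 5L) # all eligible pixels selected
  expect_gt(a$shortfall_mt, 0)
  expect_error(rank_and_allocate(w, "soybean", -1), "non-negative")
  expect_error(rank_and_allocate(w, "soybean", 1, mode = "proximity"), "oil palm")
})

test_that("selections are nested and non-decreasing in demand", {
  w <- generate_world(world_config(n_rows = 15, n_cols = 15, seed = 21))
  demands <- c(0.0001, 0.0005, 0.002, 0.01)
  prev <- integer(0)
  prev_area <- 0
  for (d in demands) {
    a <- rank_and_allocate(w, "soybean", d)
    if (a$infeasible) break
    expect_true(all(prev %in% a$selected$pixel))
    expect_gte(a$area_ha, prev_area)
    prev <- a$selected$pixel
    prev_area <- a$area_ha
  }
})

test_that("every non-selected included pixel is worse than the marginal one", {
  w <- generate_world(world_config(n_rows = 12, n_cols = 12, seed = 31))
  mask <- build_mask(w)
  att <- attribute_crops(mask)
  a <- rank_and_allocate(w, "sunflower", 0.001, mask = mask, attribution = att)
  if (!a$infeasible && a$n_pixels > 0) {
    thr <- a$threshold
    pool <- mask %>%
      dplyr::inner_join(att, by = c("pixel", "crop")) %>%
      dplyr::filter(crop == "sunflower", included,
                    !pixel %in% a$selected$pixel)
    worse <- pool$suitability > thr$suitability |
      (pool$suitability == thr$suitability &
         pool$attainable_yield < thr$attainable_yield) |
      (pool$suitability == thr$suitability &
         pool$attainable_yield == thr$attainable_yield &
         pool$pixel > thr$pixel)
    expect_true(all(worse))
  }
})

test_that("proximity mode prefers existing palm within a suitability class", {
  w <- mode_contrast_world()
  # demand needing ~6 pixels of ~100 ha
  demand <- 5.5 * 100 * 4.0 * 0.25 / 1e6
  ay <- rank_and_allocate(w, "oil_palm", demand, mode = "yield")
  ap <- rank_and_allocate(w, "oil_palm", demand, mode = "proximity")
  oy <- oracle_allocate(w, "oil_palm", demand, mode = "yield")
  op <- oracle_allocate(w, "oil_palm", demand, mode = "proximity")
  expect_equal(ay$selected$pixel, oy$selected)
  expect_equal(ap$selected$pixel, op$selected)
  # yield mode heads for the forested frontier, proximity for converted land
  forest_ha <- function(a) {
    bd <- cover_breakdown(a, w)
    sum(bd$area_ha[bd$cover == "forest"])
  }
  expect_lt(forest_ha(ap), forest_ha(ay))
})

test_that("cover breakdown splits, conserves, and carves the palm slice", {
  w <- tiny_world(
    covers = list(c(forest = 0.3, grassland = 0.5, urban = 0.2)),
    crops = tibble::tibble(pixel = 1, crop = "soybean",
                           suitability = 2L, attainable_yield = 2),
    peat = 0.25
  )
  a <- rank_and_allocate(w, "soybean", 1e-9)
  bd <- cover_breakdown(a, w)
  expect_equal(sum(bd$area_ha), 80) # the includable 80% of 100 ha
  expect_equal(bd$area_ha[bd$cover == "forest"], 30)
  expect_equal(bd$area_ha[bd$cover == "grassland"], 50)
  expect_equal(attr(bd, "peat_overlap_ha"), 80 * 0.25)
  # palm: existing share is consumed as a zero-LUC slice
  wp <- tiny_world(
    covers = list(c(forest = 0.5, grassland = 0.5)),
    crops = tibble::tibble(pixel = 1, crop = "oil_palm",
                           suitability = 2L, attainable_yield = 3),
    zone = "tropical_moist", palm_share = 0.2
  )
  ap <- rank_and_allocate(wp, "oil_palm", 1e-9)
  bdp <- cover_breakdown(ap, wp)
  expect_equal(attr(bdp, "existing_palm_ha"), 20)
  expect_equal(sum(bdp$area_ha), 100)
  expect_equal(bdp$area_ha[bdp$cover == "forest"], 40) # 50 scaled by 80/100
})

test_that("cover-order modes act on the trimmed marginal pixel", {
  w <- tiny_world(
    covers = list(c(forest = 0.5, grassland = 0.5)),
    crops = tibble::tibble(pixel = 1, crop = "soybean",
                           suitability = 2L, attainable_yield = 2)
  )
  # demand for 40 of the 100 available hectares
  demand <- 40 * 2 * 0.84 * 0.20 * 0.41 / 1e6
  a <- rank_and_allocate(w, "soybean", demand)
  ff <- cover_breakdown(a, w, cover_order = "forest_first", trim_overshoot = TRUE)
  fl <- cover_breakdown(a, w, cover_order = "forest_last", trim_overshoot = TRUE)
  pp <- cover_breakdown(a, w, cover_order = "proportional", trim_overshoot = TRUE)
  expect_equal(sum(ff$area_ha), 40, tolerance = 1e-6)
  expect_equal(ff$area_ha[ff$cover == "forest"], 40, tolerance = 1e-6)
  expect_equal(fl$area_ha[fl$cover == "forest"], 0, tolerance = 1e-6)
  expect_equal(pp$area_ha[pp$cover == "forest"], 20, tolerance = 1e-6)
  # default whole-pixel consumption: all orders coincide
  whole <- cover_breakdown(a, w)
  expect_equal(sum(whole$area_ha), 100)
})
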