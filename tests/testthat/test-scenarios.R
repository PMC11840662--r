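# Demand arithmetic: rates, splits, projection, replacement

test_that("daily intakes annualize correctly", {
  expect_equal(annualize_rate(6.8), 2.482)
  expect_equal(round(annualize_rate(6.8), 1), 2.5)
  expect_equal(annualize_rate(40), 14.6)
  expect_equal(annualize_rate(0), 0)
  expect_error(annualize_rate(-1), "non-negative")
})

test_that("EAT totals split proportionally to current shares", {
  eat <- split_eat_rates(14.6, annualize_rate(6.8))
  r <- function(o) eat$rate_kg_yr[eat$oil == o]
  expect_equal(r("soybean"), 5.25, tolerance = 0.01)
  expect_equal(r("rapeseed"), 2.08, tolerance = 0.01)
  expect_equal(r("sunflower"), 2.60, tolerance = 0.01)
  expect_equal(r("other"), 4.67, tolerance = 0.01)
  # allocated rates sum back to the given totals
  expect_equal(r("palm") + r("palm_kernel"), annualize_rate(6.8), tolerance = 1e-9)
  expect_equal(sum(eat$rate_kg_yr[eat$oil %in% c("rapeseed", "soybean",
                                                 "sunflower", "other")]),
               14.6, tolerance = 1e-9)
  # proportionality constant identical across oils
  cur <- current_rates()
  ratio <- r("soybean") / cur$rate_kg_yr[cur$oil == "soybean"]
  for (o in c("rapeseed", "sunflower", "other")) {
    expect_equal(r(o) / cur$rate_kg_yr[cur$oil == o], ratio, tolerance = 1e-9)
  }
  # equal shares split evenly
  eq <- tibble::tibble(
    oil = c("palm", "palm_kernel", "rapeseed", "soybean", "sunflower", "other"),
    rate_kg_yr = 1, scenario = "current"
  )
  s <- split_eat_rates(10, 2, eq)
  expect_equal(s$rate_kg_yr[s$oil == "soybean"], 2.5)
  zero <- dplyr::mutate(eq, rate_kg_yr = 0)
  expect_error(split_eat_rates(10, 2, zero), "zero")
})

test_that("demand projection matches the SSP2 population arithmetic", {
  expect_equal(round(project_demand(2.4, 9187)), 22)
  expect_equal(project_demand(17.10, 9187), 157, tolerance = 0.2)
  expect_equal(project_demand(0, 9187), 0)
})

test_that("replacement weights are food-production shares", {
  w <- replacement_weights()
  expect_equal(sum(w$weight), 1)
  expect_equal(w$weight[w$oil == "soybean"], 0.523, tolerance = 1e-3)
  expect_equal(w$weight[w$oil == "rapeseed"], 0.209, tolerance = 1e-3)
  expect_equal(w$weight[w$oil == "sunflower"], 0.268, tolerance = 1e-3)
  reg <- default_registry(
    current_production_mt = c(palm = 1, palm_kernel = 1, soybean = 10,
                              rapeseed = 10, sunflower = 10),
    food_use_share = c(palm = 0.5, rapeseed = 0.5, soybean = 0.5, sunflower = 0.5)
  )
  expect_equal(replacement_weights(reg)$weight, rep(1 / 3, 3))
})

test_that("palm replacement conserves the palm + unsaturated total", {
  scen <- build_scenario_table()
  main <- c("palm", "palm_kernel", "rapeseed", "soybean", "sunflower")
  tot <- scen %>%
    dplyr::filter(oil %in% main) %>%
    dplyr::group_by(rate_scenario, replacement) %>%
    dplyr::summarise(mt = sum(demand_mt), .groups = "drop")
  for (rs in c("current", "eat_lancet")) {
    v <- tot$mt[tot$rate_scenario == rs]
    expect_lt(max(v) - min(v), 1e-9)
  }
  # palm total halves at 50% replacement; identity at 0%
  palm50 <- scen %>%
    dplyr::filter(rate_scenario == "current", replacement == 0.5,
                  oil %in% c("palm", "palm_kernel"))
  expect_equal(sum(palm50$demand_mt), 11.9, tolerance = 0.01)
  base <- tibble::tibble(oil = main, demand_mt = c(20, 2, 10, 30, 15))
  expect_equal(apply_replacement(base, 0)$demand_mt, base$demand_mt)
})

test_that("unsaturated demand rises and palm falls with the replacement fraction", {
  scen <- build_scenario_table()
  for (rs in c("current", "eat_lancet")) {
    for (o in c("rapeseed", "soybean", "sunflower")) {
      v <- scen %>%
        dplyr::filter(rate_scenario == rs, oil == o) %>%
        dplyr::arrange(replacement) %>%
        dplyr::pull(demand_mt)
      expect_true(all(diff(v) > 0))
    }
    p <- scen %>%
      dplyr::filter(rate_scenario == rs, oil == "palm") %>%
      dplyr::arrange(replacement) %>%
      dplyr::pull(demand_mt)
    expect_true(all(diff(p) < 0))
  }
})

test_that("the printed-table cells that follow from printed inputs reproduce", {
  scen <- build_scenario_table()
  d <- function(rs, f, oils) {
    sum(scen$demand_mt[scen$rate_scenario == rs & scen$replacement == f &
                         scen$oil %in% oils])
  }
  expect_equal(d("current", 0, "palm"), 22, tolerance = 0.05)
  expect_equal(d("current", 0, c("palm", "palm_kernel")), 23.8, tolerance = 0.05)
  expect_equal(d("eat_lancet", 0, c("palm", "palm_kernel")), 22.8, tolerance = 0.05)
  expect_equal(d("eat_lancet", 0, c("rapeseed", "soybean", "sunflower")),
               91.2, tolerance = 0.1)
  expect_equal(d("current", 0, unique(scen$oil)), 104, tolerance = 0.5)
  expect_equal(d("eat_lancet", 0, unique(scen$oil)), 157, tolerance = 0.5)
  # presentation table sums over rounded components
  tab <- format_demand_table(scen)
  expect_equal(tab$eat_lancet_0pct[tab$oil == "total_main_unsaturated"], 91.2)
  expect_equal(tab$eat_lancet_0pct[tab$oil == "total_palm"], 22.8)
})
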