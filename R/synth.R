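# Synthetic landscape generator ----------------------------------------------
#
# Emulates the structure of the real input stack (suitability correlated with
# attainable yield, latitude-banded climate zones, Voronoi countries,
# clustered peat and existing-palm patches, per-pixel cover mixtures summing
# to 1) without attempting to match real-world distributions. Spatial
# autocorrelation comes from bilinear interpolation of coarse Gaussian noise.

#' Configuration for the synthetic world generator
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param seed RNG seed; the whole world is deterministic given the seed.
#' @param n_countries Number of Voronoi-generated countries.
#' @param lat_north,lat_south Latitude span of the grid, degrees; the cell
#'   size is `(lat_north - lat_south) / n_rows` so a modest grid still spans
#'   boreal-to-tropical climate bands.
#' @param zone_edges Absolute-latitude band edges `c(boreal_above, tropics_below)`.
#' @param corr_length Spatial correlation length in pixels for all smoothed
#'   fields.
#' @param suitability_prevalence Named list (per crop) of length-8 prevalence
#'   vectors over suitability classes 1..8, each summing to 1.
#' @param yield_range Named list (per crop) of `c(min, max)` attainable yield,
#'   t/ha/yr (seed yield; oil yield for oil palm).
#' @param cover_alpha Named Dirichlet concentration parameters, one per
#'   land-cover class.
#' @param peat_hotspots,peat_max_fraction Number of clustered peat patches and
#'   their peak per-pixel fraction.
#' @param palm_clusters Number of existing-palm clusters (placed in the
#'   tropical band, on palm-eligible and preferentially already-converted
#'   pixels; where a cluster lands, forest cover is converted to perennial
#'   cropland in proportion to the palm share, since a standing plantation is
#'   converted land). `NULL` (default) scales the count with grid area,
#'   one cluster per ~800 pixels.
#' @param carbon_density_range `c(min, max)` country forest biomass carbon
#'   density, Mg C/ha.
#' @param staple_intensity Fraction of a pixel's annual-crop area carrying the
#'   five staple crops, on average.
#' @return A validated `oilscape_world_config` list.
#' @export
world_config <- function(n_rows = 100, n_cols = 100, seed = 1,
                         n_countries = 8,
                         lat_north = 70, lat_south = -70,
                         zone_edges = c(55, 30),
                         corr_length = 8,
                         suitability_prevalence = NULL,
                         yield_range = NULL,
                         cover_alpha = NULL,
                         peat_hotspots = 5, peat_max_fraction = 0.8,
                         palm_clusters = NULL,
                         carbon_density_range = c(40, 180),
                         staple_intensity = 0.6) {
  default_prev <- c(0.05, 0.10, 0.15, 0.15, 0.15, 0.15, 0.10, 0.15)
  if (is.null(suitability_prevalence)) {
    suitability_prevalence <- setNames(
      rep(list(default_prev), length(oil_crops)), oil_crops
    )
  }
  if (is.null(yield_range)) {
    # oil palm in t oil/ha (up to 4); annuals in t seed/ha, so food-oil per
    # hectare stays well below palm's (the 4 vs 0.6-0.8 t oil/ha regime)
    yield_range <- list(
      oil_palm = c(1.0, 4.0), soybean = c(1.0, 4.2),
      sunflower = c(0.8, 2.3), rapeseed = c(0.8, 2.3)
    )
  }
  if (is.null(cover_alpha)) {
    cover_alpha <- c(
      bare = 0.5, grassland = 2, shrubland = 1.5,
      annual_crop_rainfed = 1.5, annual_crop_irrigated = 0.5,
      perennial_crop_rainfed = 0.5, perennial_crop_irrigated = 0.3,
      forest = 3, urban = 0.3, water = 0.5, wetland = 0.4
    )
  }
  if (is.null(palm_clusters)) {
    palm_clusters <- max(2, round(n_rows * n_cols / 800))
  }
  cfg <- list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    seed = as.integer(seed), n_countries = as.integer(n_countries),
    lat_north = lat_north, lat_south = lat_south, zone_edges = zone_edges,
    corr_length = corr_length,
    suitability_prevalence = suitability_prevalence,
    yield_range = yield_range, cover_alpha = cover_alpha,
    peat_hotspots = as.integer(peat_hotspots),
    peat_max_fraction = peat_max_fraction,
    palm_clusters = as.integer(palm_clusters),
    carbon_density_range = carbon_density_range,
    staple_intensity = staple_intensity
  )
  validate_world_config(cfg)
  structure(cfg, class = "oilscape_world_config")
}

validate_world_config <- function(cfg) {
  stopifnot(
    cfg$n_rows >= 1, cfg$n_cols >= 1, cfg$n_countries >= 1,
    cfg$lat_north > cfg$lat_south,
    cfg$corr_length >= 1,
    cfg$peat_hotspots >= 0, cfg$palm_clusters >= 0,
    cfg$peat_max_fraction >= 0, cfg$peat_max_fraction <= 1,
    cfg$carbon_density_range[1] >= 0,
    diff(cfg$carbon_density_range) >= 0,
    cfg$staple_intensity >= 0, cfg$staple_intensity <= 1,
    all(names(cfg$cover_alpha) %in% cover_classes),
    all(cfg$cover_alpha > 0)
  )
  for (p in cfg$suitability_prevalence) {
    if (length(p) != 8 || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      abort("each suitability prevalence vector must have 8 non-negative entries summing to 1")
    }
  }
  for (r in cfg$yield_range) {
    if (length(r) != 2 || any(r < 0) || r[2] < r[1]) {
      abort("yield ranges must be non-negative c(min, max)")
    }
  }
  invisible(cfg)
}

# spatially autocorrelated standard-normal-ish field: bilinear interpolation
# of coarse white noise plus a small nugget to break ties
smooth_field <- function(n_rows, n_cols, scale) {
  nrc <- max(2L, ceiling(n_rows / scale) + 1L)
  ncc <- max(2L, ceiling(n_cols / scale) + 1L)
  coarse <- matrix(rnorm(nrc * ncc), nrc, ncc)
  ri <- if (n_rows == 1) rep(1, 1) else 1 + (seq_len(n_rows) - 1) * (nrc - 1) / (n_rows - 1)
  ci <- if (n_cols == 1) rep(1, 1) else 1 + (seq_len(n_cols) - 1) * (ncc - 1) / (n_cols - 1)
  r0 <- pmin(floor(ri), nrc - 1); rf <- ri - r0
  c0 <- pmin(floor(ci), ncc - 1); cf <- ci - c0
  f <- matrix(0, n_rows, n_cols)
  for (i in seq_len(n_rows)) {
    a <- coarse[r0[i], ]; b <- coarse[r0[i] + 1, ]
    rowv <- a * (1 - rf[i]) + b * rf[i]
    f[i, ] <- rowv[c0] * (1 - cf) + rowv[c0 + 1] * cf
  }
  f + rnorm(n_rows * n_cols, sd = 0.15)
}

# rank-transform a field to uniform (exact marginal, deterministic ties)
to_uniform <- function(f) {
  matrix(rank(as.vector(f), ties.method = "first") / (length(f) + 1),
         nrow(f), ncol(f))
}

radial_bumps <- function(n_rows, n_cols, centers, peak, sigma) {
  out <- matrix(0, n_rows, n_cols)
  if (nrow(centers) == 0) return(out)
  rows <- matrix(seq_len(n_rows), n_rows, n_cols)
  cols <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
  for (i in seq_len(nrow(centers))) {
    d2 <- (rows - centers$row[i])^2 + (cols - centers$col[i])^2
    out <- out + peak[i] * exp(-d2 / (2 * sigma[i]^2))
  }
  out
}

#' Generate a synthetic world
#'
#' Builds a full landscape (covers, peat, countries, climate zones, existing
#' palm, staples) plus per-crop suitability and attainable-yield layers and a
#' country carbon table, deterministically from `config$seed`. Suitability
#' fields are spatially autocorrelated; attainable yield is positively
#' rank-correlated with suitability; oil-palm suitability is confined to the
#' tropical band; existing palm occurs only on palm-eligible pixels and
#' clusters preferentially on already-converted (low-forest) land.
#'
#' @param config A [world_config()].
#' @return An `oilscape_world`.
#' @examples
#' w <- generate_world(world_config(n_rows = 20, n_cols = 20, seed = 7))
#' w
#' @export
generate_world <- function(config = world_config()) {
  validate_world_config(config)
  set.seed(config$seed)
  nr <- config$n_rows; nc <- config$n_cols
  cell_deg <- (config$lat_north - config$lat_south) / nr
  lat <- config$lat_north - cell_deg / 2 - (seq_len(nr) - 1) * cell_deg
  lon <- -180 + cell_deg / 2 + (seq_len(nc) - 1) * cell_deg
  lat_px <- rep(lat, each = nc)

  # climate zones: latitude bands, moist/dry tropics split by a wetness field
  wet <- to_uniform(smooth_field(nr, nc, config$corr_length))
  zone_mat <- matrix("temperate", nr, nc)
  zone_mat[abs(lat) > config$zone_edges[1], ] <- "boreal"
  trop <- abs(lat) < config$zone_edges[2]
  zone_mat[trop, ] <- ifelse(wet[trop, , drop = FALSE] > 0.45,
                             "tropical_moist", "tropical_dry")
  zone <- as.vector(t(zone_mat))
  tropical <- zone %in% c("tropical_moist", "tropical_dry")

  # Voronoi countries
  seeds <- tibble(
    row = sample.int(nr, config$n_countries, replace = TRUE),
    col = sample.int(nc, config$n_countries, replace = TRUE)
  )
  rows_px <- rep(seq_len(nr), each = nc)
  cols_px <- rep(seq_len(nc), times = nr)
  d2 <- sapply(seq_len(config$n_countries), function(i) {
    (rows_px - seeds$row[i])^2 + (cols_px - seeds$col[i])^2
  })
  d2 <- matrix(d2, nrow = nr * nc)
  country <- max.col(-d2, ties.method = "first")

  # cover fractions: Dirichlet draws with spatially modulated concentrations
  alpha <- config$cover_alpha[cover_classes]
  gmat <- sapply(cover_classes, function(k) {
    u <- as.vector(t(to_uniform(smooth_field(nr, nc, config$corr_length))))
    rgamma(nr * nc, shape = alpha[[k]] * (0.5 + 1.5 * u)) + 1e-12
  })
  gmat <- matrix(gmat, nrow = nr * nc)
  cover <- gmat / rowSums(gmat)
  colnames(cover) <- cover_cols()

  # peat hotspots
  peat <- matrix(0, nr, nc)
  if (config$peat_hotspots > 0) {
    centers <- tibble(
      row = sample.int(nr, config$peat_hotspots, replace = TRUE),
      col = sample.int(nc, config$peat_hotspots, replace = TRUE)
    )
    sigma <- runif(config$peat_hotspots, 1, max(2, config$corr_length / 2))
    peak <- runif(config$peat_hotspots, 0.5, 1) * config$peat_max_fraction
    peat <- pmin(radial_bumps(nr, nc, centers, peak, sigma), config$peat_max_fraction)
  }
  peat_px <- as.vector(t(peat))

  # per-crop suitability + yields
  crops <- purrr::map_dfr(oil_crops, function(cp) {
    prev <- config$suitability_prevalence[[cp]]
    u <- as.vector(t(to_uniform(smooth_field(nr, nc, config$corr_length))))
    cls <- findInterval(u, cumsum(prev)[1:7]) + 1L
    if (cp == "oil_palm") cls[!tropical] <- 8L
    yr <- config$yield_range[[cp]]
    quality <- (8 - cls) / 7
    yld <- (yr[1] + (yr[2] - yr[1]) * quality) * runif(nr * nc, 0.7, 1.0)
    yld[cls == 8L] <- 0
    tibble(pixel = seq_len(nr * nc), crop = cp,
           suitability = cls, attainable_yield = yld)
  })

  # existing palm: clusters on palm-eligible tropical pixels, biased towards
  # already-converted (low-forest) land
  palm_share <- rep(0, nr * nc)
  palm_cls <- crops$suitability[crops$crop == "oil_palm"]
  eligible <- tropical & palm_cls <= 5L
  if (config$palm_clusters > 0 && any(eligible)) {
    w <- (1 - cover[, "cover_forest"])^2 * eligible
    centers_idx <- sample.int(nr * nc, config$palm_clusters,
                              replace = TRUE, prob = w + 1e-9)
    centers <- tibble(row = rows_px[centers_idx], col = cols_px[centers_idx])
    sigma <- runif(config$palm_clusters, 1, 2.5)
    peak <- runif(config$palm_clusters, 0.3, 0.6)
    palm_share <- as.vector(t(radial_bumps(nr, nc, centers, peak, sigma)))
    palm_share <- pmin(palm_share, 0.8)
    palm_share[!eligible] <- 0
    palm_share[palm_share < 0.01] <- 0
    # a standing plantation is converted land: where palm sits, move forest
    # cover into perennial cropland in proportion to the palm share
    shift <- cover[, "cover_forest"] * palm_share
    cover[, "cover_forest"] <- cover[, "cover_forest"] - shift
    cover[, "cover_perennial_crop_rainfed"] <-
      cover[, "cover_perennial_crop_rainfed"] + shift
  }

  area <- pixel_area_ha(lat_px, cell_deg)
  annual_area <- area * (cover[, "cover_annual_crop_rainfed"] +
                         cover[, "cover_annual_crop_irrigated"])
  staple_total <- annual_area * config$staple_intensity * runif(nr * nc, 0.5, 1)
  sw <- matrix(rgamma(nr * nc * 5, shape = 1) + 1e-12, ncol = 5)
  sw <- sw / rowSums(sw)
  staples <- sw * staple_total
  colnames(staples) <- staple_cols()

  px <- tibble(
    pixel = seq_len(nr * nc), row = rows_px, col = cols_px,
    lat = lat_px, lon = lon[cols_px], pixel_area_ha = area
  )
  px <- dplyr::bind_cols(px, as_tibble(cover))
  px$peat_fraction <- peat_px
  px$country_id <- as.integer(country)
  px$climate_zone <- zone
  px$existing_palm_share <- palm_share
  px <- dplyr::bind_cols(px, as_tibble(staples))

  carbon <- tibble(
    country_id = seq_len(config$n_countries),
    c_density_mgc_ha = runif(config$n_countries,
                             config$carbon_density_range[1],
                             config$carbon_density_range[2])
  )
  w <- new_world(px, crops, carbon, nr, nc, cell_deg)
  attr(w, "config") <- config
  w
}

# ---- documented toy fixtures -------------------------------------------------

toy_registry <- c("five_pixel_line", "two_country_forest", "palm_vs_annuals")

toy_pixels <- function(n_rows, n_cols, area_ha, zone = "temperate") {
  n <- n_rows * n_cols
  px <- tibble(
    pixel = seq_len(n),
    row = rep(seq_len(n_rows), each = n_cols),
    col = rep(seq_len(n_cols), times = n_rows),
    lat = 0, lon = 0, pixel_area_ha = area_ha
  )
  for (nm in cover_cols()) px[[nm]] <- 0
  px$cover_grassland <- 1
  px$peat_fraction <- 0
  px$country_id <- 1L
  px$climate_zone <- zone
  px$existing_palm_share <- 0
  for (nm in staple_cols()) px[[nm]] <- 0
  px
}

#' Tiny hand-set fixture worlds
#'
#' Fully enumerated worlds (<= 10 x 10) whose correct allocation and
#' emissions answers can be brute-forced in test code:
#' \describe{
#'   \item{five_pixel_line}{1 x 5 grassland strip, soybean only, hand-set
#'     suitabilities and seed yields, 100 ha pixels.}
#'   \item{two_country_forest}{2 x 2 all-forest grid split between two
#'     countries with biomass carbon densities 100 and 50 Mg C/ha, 10 ha
#'     pixels, soybean class 3.}
#'   \item{palm_vs_annuals}{2 x 4 tropical-moist grassland grid encoding the
#'     oil-yield contrast between oil palm (4 t oil/ha) and the annual oil
#'     crops (0.6-0.8 t oil/ha).}
#' }
#'
#' @param name Fixture name, one of the registry above.
#' @return An `oilscape_world`.
#' @export
make_toy_world <- function(name) {
  if (!name %in% toy_registry) {
    abort(paste0("unknown toy world '", name, "'; registry: ",
                 paste(toy_registry, collapse = ", ")))
  }
  if (name == "five_pixel_line") {
    px <- toy_pixels(1, 5, area_ha = 100)
    crops <- tibble(
      pixel = 1:5, crop = "soybean",
      suitability = c(1L, 2L, 2L, 3L, 5L),
      attainable_yield = c(3.0, 2.5, 2.0, 2.2, 1.0)
    )
    carbon <- tibble(country_id = 1L, c_density_mgc_ha = 100)
    return(new_world(px, crops, carbon, 1, 5))
  }
  if (name == "two_country_forest") {
    px <- toy_pixels(2, 2, area_ha = 10)
    px$cover_grassland <- 0
    px$cover_forest <- 1
    px$country_id <- c(1L, 2L, 1L, 2L)
    crops <- tibble(
      pixel = 1:4, crop = "soybean",
      suitability = 3L, attainable_yield = c(2.0, 2.0, 1.5, 1.5)
    )
    carbon <- tibble(country_id = 1:2, c_density_mgc_ha = c(100, 50))
    return(new_world(px, crops, carbon, 2, 2))
  }
  # palm_vs_annuals
  px <- toy_pixels(2, 4, area_ha = 100, zone = "tropical_moist")
  crops <- dplyr::bind_rows(
    tibble(pixel = 1:8, crop = "oil_palm", suitability = 2L, attainable_yield = 4.0),
    tibble(pixel = 1:8, crop = "soybean", suitability = 3L, attainable_yield = 4.2),
    tibble(pixel = 1:8, crop = "rapeseed", suitability = 3L, attainable_yield = 2.0),
    tibble(pixel = 1:8, crop = "sunflower", suitability = 3L, attainable_yield = 2.0)
  )
  carbon <- tibble(country_id = 1L, c_density_mgc_ha = 80)
  new_world(px, crops, carbon, 2, 4)
}
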