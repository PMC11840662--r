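# Gridded world container -----------------------------------------------------
#
# Grid convention: cell-center registered, north-up, row 1 = northernmost row.
# A world is a list of three tibbles (pixels, crops, carbon) plus the grid
# geometry; the tibbles are what users pipe into dplyr.

#' Spherical cell area in hectares
#'
#' Area of a lat-lon grid cell centred at `lat` with angular size `cell_deg`,
#' on a spherical Earth of authalic radius. The area of the spherical zone
#' slice is \eqn{R^2 \Delta\lambda (\sin\phi_2 - \sin\phi_1)}; it is symmetric
#' in +/-lat and shrinks with the cosine of latitude.
#'
#' @param lat Cell-center latitude(s), degrees, in [-90, 90].
#' @param cell_deg Cell size in degrees (default 5 arcmin = 1/12 degree).
#' @return Area in hectares, vectorized over `lat`.
#' @examples
#' pixel_area_ha(0) # ~8570 ha for a 5-arcmin cell on the equator
#' @export
pixel_area_ha <- function(lat, cell_deg = 1 / 12) {
  if (any(abs(lat) > 90)) abort("latitudes must lie in [-90, 90]")
  r_authalic <- 6371007.2 # metres
  phi1 <- pmax(-90, lat - cell_deg / 2) * pi / 180
  phi2 <- pmin(90, lat + cell_deg / 2) * pi / 180
  dlam <- cell_deg * pi / 180
  area_m2 <- r_authalic^2 * dlam * (sin(phi2) - sin(phi1))
  area_m2 / 1e4
}

#' Assemble a landscape world
#'
#' Bundles the per-pixel landscape table, the per-crop suitability/yield
#' table and the country carbon table into one validated object.
#'
#' @param pixels Tibble with one row per pixel: `pixel`, `row`, `col`, `lat`,
#'   `lon`, `pixel_area_ha`, one `cover_<class>` column per land-cover class
#'   (fractions summing to 1), `peat_fraction`, `country_id`, `climate_zone`,
#'   `existing_palm_share`, and one `staple_<crop>` column per staple
#'   (harvested hectares).
#' @param crops Tibble with `pixel`, `crop`, `suitability` (integer 1-8,
#'   1 = very high, 8 = not suitable) and `attainable_yield` (t/ha/yr; seed
#'   yield for annual crops, oil yield for oil palm).
#' @param carbon Tibble with `country_id` and `c_density_mgc_ha` (above- plus
#'   below-ground forest biomass carbon, Mg C/ha).
#' @param n_rows,n_cols Grid dimensions.
#' @param cell_deg Cell size in degrees.
#' @return An object of class `oilscape_world`.
#' @export
new_world <- function(pixels, crops, carbon, n_rows, n_cols, cell_deg = 1 / 12) {
  world <- structure(
    list(
      pixels = as_tibble(pixels), crops = as_tibble(crops),
      carbon = as_tibble(carbon),
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      cell_deg = cell_deg
    ),
    class = "oilscape_world"
  )
  validate_world(world)
  world
}

cover_cols  <- function() paste0("cover_", cover_classes)
staple_cols <- function() paste0("staple_", staple_crops)

#' Validate a landscape world
#'
#' Checks every structural invariant: cover fractions sum to 1 (±1e-6) and
#' lie in [0, 1], areas positive, staple harvested area within the pixel,
#' suitability an integer in 1..8 with zero yield at class 8, and a carbon
#' entry for every country present on the grid.
#'
#' @param world An `oilscape_world`.
#' @return `world`, invisibly; aborts with a message on the first violation.
#' @export
validate_world <- function(world) {
  px <- world$pixels
  needed <- c(
    "pixel", "row", "col", "lat", "lon", "pixel_area_ha",
    cover_cols(), "peat_fraction", "country_id", "climate_zone",
    "existing_palm_share", staple_cols()
  )
  missing <- setdiff(needed, names(px))
  if (length(missing)) {
    abort(paste0("pixels table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(px) != world$n_rows * world$n_cols) {
    abort("pixels table must have one row per grid cell")
  }
  cf <- as.matrix(px[cover_cols()])
  if (any(cf < -1e-9 | cf > 1 + 1e-9)) abort("cover fractions must lie in [0, 1]")
  if (any(abs(rowSums(cf) - 1) > 1e-6)) abort("cover fractions must sum to 1 per pixel")
  if (any(px$pixel_area_ha <= 0)) abort("pixel areas must be positive")
  if (any(px$peat_fraction < 0 | px$peat_fraction > 1)) {
    abort("peat_fraction must lie in [0, 1]")
  }
  if (any(px$existing_palm_share < 0 | px$existing_palm_share > 1)) {
    abort("existing_palm_share must lie in [0, 1]")
  }
  if (!all(px$climate_zone %in% climate_zones)) {
    abort("climate_zone must be boreal/temperate/tropical_moist/tropical_dry")
  }
  st <- as.matrix(px[staple_cols()])
  if (any(st < 0)) abort("staple areas must be non-negative")
  if (any(rowSums(st) > px$pixel_area_ha * (1 + 1e-9))) {
    abort("staple harvested area exceeds pixel area")
  }
  cr <- world$crops
  if (!all(cr$crop %in% oil_crops)) abort("unknown oil crop in crops table")
  if (any(cr$suitability != round(cr$suitability)) ||
      any(cr$suitability < 1 | cr$suitability > 8)) {
    abort("suitability must be an integer in 1..8")
  }
  if (any(cr$attainable_yield < 0)) abort("attainable yields must be non-negative")
  if (any(cr$attainable_yield[cr$suitability == 8] != 0)) {
    abort("yield must be zero where suitability is 8 (not suitable)")
  }
  if (!all(unique(px$country_id) %in% world$carbon$country_id)) {
    abort("every country on the grid needs a carbon-density entry")
  }
  if (any(world$carbon$c_density_mgc_ha < 0)) abort("carbon densities must be >= 0")
  invisible(world)
}

#' @export
print.oilscape_world <- function(x, ...) {
  cat("<oilscape world> ", x$n_rows, "x", x$n_cols, " grid (",
      format(x$cell_deg * 60, digits = 3), " arcmin cells), ",
      nrow(x$carbon), " countries, crops: ",
      paste(unique(x$crops$crop), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# total attainable food-oil capacity per crop, Mt (eligible pixels only)
world_capacity_mt <- function(world, registry = default_registry()) {
  mask <- build_mask(world, registry)
  mask %>%
    filter(.data$included) %>%
    mutate(prod_mt = .data$available_ha * .data$food_oil_yield_t_ha / 1e6) %>%
    group_by(crop = .data$crop) %>%
    summarise(capacity_mt = sum(.data$prod_mt), .groups = "drop")
}
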