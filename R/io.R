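# Plain-text raster I/O and grid harmonization -------------------------------
#
# Each layer is a dense matrix CSV (row 1 = northernmost row); grid geometry
# and the layer inventory live in layer_spec.yaml. Layers finer than the
# reference grid by an integer factor are aggregated on read: area-weighted
# mean for continuous and fraction layers, area-weighted mode for categorical
# layers. The country carbon table is a two-column CSV.

write_matrix_csv <- function(mat, path) {
  df <- as.data.frame(mat)
  names(df) <- paste0("c", seq_len(ncol(mat)))
  readr::write_csv(df, path, progress = FALSE)
}

read_matrix_csv <- function(path, what = c("numeric", "integer", "character")) {
  what <- match.arg(what)
  ctype <- switch(what,
    numeric = readr::cols(.default = readr::col_double()),
    integer = readr::cols(.default = readr::col_integer()),
    character = readr::cols(.default = readr::col_character())
  )
  as.matrix(readr::read_csv(path, col_types = ctype, progress = FALSE))
}

#' Aggregate a fine layer onto the reference grid
#'
#' Collapses an integer-factor-finer matrix onto the reference grid with
#' area weighting: continuous and fraction layers by the area-weighted mean
#' (which conserves per-class area for cover fractions), categorical layers
#' by the area-weighted mode.
#'
#' @param mat Fine matrix with dimensions `factor` times the reference grid.
#' @param factor Integer refinement factor (1 = already on the reference grid).
#' @param lat_north Latitude of the center of the northernmost *reference*
#'   row, degrees.
#' @param cell_deg Reference cell size, degrees.
#' @param method `"mean"` for continuous/fraction layers, `"mode"` for
#'   categorical layers.
#' @return Matrix on the reference grid.
#' @export
harmonize_layer <- function(mat, factor, lat_north, cell_deg = 1 / 12,
                            method = c("mean", "mode")) {
  method <- match.arg(method)
  k <- as.integer(factor)
  if (k == 1L) return(mat)
  if (nrow(mat) %% k != 0 || ncol(mat) %% k != 0) {
    abort("fine layer dimensions must be an integer multiple of the factor")
  }
  n_rows <- nrow(mat) / k
  n_cols <- ncol(mat) / k
  fine_cell <- cell_deg / k
  # latitude of each fine row center, aligned inside the coarse cells
  lat_fine <- lat_north + cell_deg / 2 - fine_cell / 2 -
    (seq_len(nrow(mat)) - 1) * fine_cell
  w_row <- pixel_area_ha(lat_fine, fine_cell)
  W <- matrix(w_row, nrow = nrow(mat), ncol = ncol(mat))
  block_sum <- function(m) {
    m2 <- rowsum(m, rep(seq_len(n_rows), each = k))
    t(rowsum(t(m2), rep(seq_len(n_cols), each = k)))
  }
  if (method == "mean") {
    block_sum(mat * W) / block_sum(W)
  } else {
    labels <- sort(unique(as.vector(mat)))
    scores <- lapply(labels, function(l) block_sum(W * (mat == l)))
    pick <- array(unlist(scores), dim = c(n_rows, n_cols, length(labels)))
    idx <- apply(pick, c(1, 2), which.max)
    matrix(labels[idx], nrow = n_rows, ncol = n_cols)
  }
}

world_layer_names <- function() {
  c(cover_cols(), "peat_fraction", "existing_palm_share", staple_cols())
}

#' Write a world to a directory of plain-text layers
#'
#' Serializes every gridded layer as a matrix CSV, the country carbon table
#' as CSV, and the grid geometry plus layer inventory as `layer_spec.yaml`.
#' [read_world()] round-trips the result (bit-identical categorical layers,
#' <= 1e-6 relative error on continuous layers).
#'
#' @param world An `oilscape_world`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  px <- world$pixels
  to_mat <- function(v, mode = "numeric") {
    matrix(v, nrow = world$n_rows, ncol = world$n_cols, byrow = TRUE)
  }
  layers <- list()
  for (nm in world_layer_names()) {
    write_matrix_csv(to_mat(px[[nm]]), file.path(dir, paste0(nm, ".csv")))
    layers[[nm]] <- list(file = paste0(nm, ".csv"), kind = "continuous", factor = 1L)
  }
  write_matrix_csv(to_mat(px$country_id), file.path(dir, "country_id.csv"))
  layers[["country_id"]] <- list(file = "country_id.csv", kind = "categorical", factor = 1L)
  write_matrix_csv(to_mat(px$climate_zone), file.path(dir, "climate_zone.csv"))
  layers[["climate_zone"]] <- list(file = "climate_zone.csv", kind = "categorical", factor = 1L)
  for (cp in unique(world$crops$crop)) {
    sub <- world$crops %>% filter(.data$crop == cp) %>% arrange(.data$pixel)
    write_matrix_csv(to_mat(sub$suitability), file.path(dir, paste0("suitability_", cp, ".csv")))
    write_matrix_csv(to_mat(sub$attainable_yield), file.path(dir, paste0("yield_", cp, ".csv")))
    layers[[paste0("suitability_", cp)]] <-
      list(file = paste0("suitability_", cp, ".csv"), kind = "categorical", factor = 1L)
    layers[[paste0("yield_", cp)]] <-
      list(file = paste0("yield_", cp, ".csv"), kind = "continuous", factor = 1L)
  }
  readr::write_csv(world$carbon, file.path(dir, "country_carbon.csv"), progress = FALSE)
  spec <- list(
    grid = list(
      n_rows = world$n_rows, n_cols = world$n_cols, cell_deg = world$cell_deg,
      lat_north = max(px$lat), lon_west = min(px$lon),
      registration = "cell-center", orientation = "north-up; row 1 = northernmost"
    ),
    crops = as.list(unique(world$crops$crop)),
    layers = layers
  )
  yaml::write_yaml(spec, file.path(dir, "layer_spec.yaml"))
  invisible(dir)
}

#' Read a world from a directory of plain-text layers
#'
#' Reads the layer inventory in `layer_spec.yaml`, harmonizes any layer
#' declared at an integer-factor finer resolution onto the reference grid
#' (see [harmonize_layer()]), and reassembles a validated world.
#'
#' @param dir Directory written by [write_world()] (layers may have been
#'   replaced by finer versions with an adjusted `factor` in the spec).
#' @return An `oilscape_world`.
#' @export
read_world <- function(dir) {
  spec_path <- file.path(dir, "layer_spec.yaml")
  if (!file.exists(spec_path)) abort(paste0("no layer_spec.yaml in ", dir))
  spec <- yaml::read_yaml(spec_path)
  g <- spec$grid
  if (!identical(g$registration, "cell-center")) {
    abort("layer_spec grid registration must be 'cell-center'")
  }
  crops <- unlist(spec$crops)
  need <- c(world_layer_names(), "country_id", "climate_zone",
            paste0("suitability_", crops), paste0("yield_", crops))
  missing <- setdiff(need, names(spec$layers))
  if (length(missing)) {
    abort(paste0("mandatory layer(s) missing from layer_spec: ",
                 paste(missing, collapse = ", ")))
  }
  get_layer <- function(nm, what) {
    entry <- spec$layers[[nm]]
    path <- file.path(dir, entry$file)
    if (!file.exists(path)) abort(paste0("layer file missing: ", entry$file))
    mat <- read_matrix_csv(path, what)
    method <- if (identical(entry$kind, "categorical")) "mode" else "mean"
    out <- harmonize_layer(mat, entry$factor %||% 1L, g$lat_north, g$cell_deg, method)
    if (!all(dim(out) == c(g$n_rows, g$n_cols))) {
      abort(paste0("layer ", nm, " does not match the reference grid"))
    }
    out
  }
  lat <- g$lat_north - (seq_len(g$n_rows) - 1) * g$cell_deg
  lon <- g$lon_west + (seq_len(g$n_cols) - 1) * g$cell_deg
  px <- tibble(
    pixel = seq_len(g$n_rows * g$n_cols),
    row = rep(seq_len(g$n_rows), each = g$n_cols),
    col = rep(seq_len(g$n_cols), times = g$n_rows)
  ) %>%
    mutate(
      lat = lat[.data$row], lon = lon[.data$col],
      pixel_area_ha = pixel_area_ha(.data$lat, g$cell_deg)
    )
  for (nm in world_layer_names()) {
    px[[nm]] <- as.vector(t(get_layer(nm, "numeric")))
  }
  px$country_id <- as.vector(t(get_layer("country_id", "integer")))
  px$climate_zone <- as.vector(t(get_layer("climate_zone", "character")))
  # aggregation of exact fractions can drift at machine precision; renormalize
  cf <- as.matrix(px[cover_cols()])
  px[cover_cols()] <- cf / rowSums(cf)
  crop_tbl <- purrr::map_dfr(crops, function(cp) {
    tibble(
      pixel = px$pixel, crop = cp,
      suitability = as.vector(t(get_layer(paste0("suitability_", cp), "integer"))),
      attainable_yield = as.vector(t(get_layer(paste0("yield_", cp), "numeric")))
    )
  })
  carbon <- readr::read_csv(
    file.path(dir, "country_carbon.csv"),
    col_types = readr::cols(
      country_id = readr::col_integer(),
      c_density_mgc_ha = readr::col_double()
    ), progress = FALSE
  )
  new_world(px, crop_tbl, carbon, g$n_rows, g$n_cols, g$cell_deg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
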