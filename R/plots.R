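# Plot methods ----------------------------------------------------------------

#' Plot a world layer
#'
#' Raster map of any per-pixel column of the landscape table (a cover
#' fraction, peat, suitability of a crop via `crop =`, ...).
#'
#' @param world An `oilscape_world`.
#' @param layer Column of `world$pixels` to map (default `"cover_forest"`),
#'   or `"suitability"` / `"attainable_yield"` together with `crop`.
#' @param crop Crop whose layer to map when `layer` is a crop layer.
#' @return A ggplot object.
#' @export
plot_world <- function(world, layer = "cover_forest", crop = NULL) {
  if (layer %in% c("suitability", "attainable_yield")) {
    if (is.null(crop)) abort("give `crop` to map a crop layer")
    crop_label <- crop
    df <- world$crops %>%
      filter(.data$crop == crop_label) %>%
      left_join(world$pixels %>% select("pixel", "lon", "lat"), by = "pixel") %>%
      rename(value = all_of(layer))
  } else {
    if (!layer %in% names(world$pixels)) {
      abort(paste0("unknown layer: ", layer))
    }
    df <- world$pixels %>% select("lon", "lat", value = all_of(layer))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = layer) +
    ggplot2::theme_minimal()
}

#' Autoplot methods
#'
#' `autoplot()` for the package's result objects: demand scenarios as
#' stacked bars, an allocation as a map of selected pixels, an emissions
#' ledger as per-crop mechanism bars.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @name autoplot-oilscape
NULL

#' @rdname autoplot-oilscape
#' @param world World the allocation was computed on (required).
#' @method autoplot oilscape_allocation
#' @export
autoplot.oilscape_allocation <- function(object, world = NULL, ...) {
  if (is.null(world)) abort("pass the world the allocation was computed on")
  df <- world$pixels %>%
    select("pixel", "lon", "lat") %>%
    left_join(object$selected %>% select("pixel", "priority"), by = "pixel")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$priority)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", direction = -1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0(object$crop, " (", object$mode, " mode)"),
                  fill = "priority") +
    ggplot2::theme_minimal()
}
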