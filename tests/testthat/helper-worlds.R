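# Convenience constructor for hand-set single-row test worlds.
# `covers` is a list of named cover-fraction vectors (one per pixel); crops a
# tibble with pixel/crop/suitability/attainable_yield.

tiny_world <- function(covers, crops, area_ha = 100, zone = "temperate",
                       peat = 0, palm_share = 0, country = 1L,
                       carbon = tibble::tibble(country_id = 1L, c_density_mgc_ha = 100),
                       staples = NULL) {
  n <- length(covers)
  px <- tibble::tibble(
    pixel = seq_len(n), row = 1L, col = seq_len(n),
    lat = 0, lon = 0, pixel_area_ha = area_ha
  )
  for (nm in paste0("cover_", cover_classes)) px[[nm]] <- 0
  for (i in seq_len(n)) {
    for (k in names(covers[[i]])) px[[paste0("cover_", k)]][i] <- covers[[i]][[k]]
  }
  px$peat_fraction <- peat
  px$country_id <- country
  px$climate_zone <- zone
  px$existing_palm_share <- palm_share
  for (nm in paste0("staple_", staple_crops)) px[[nm]] <- 0
  if (!is.null(staples)) {
    for (i in seq_len(n)) {
      for (k in names(staples[[i]])) px[[paste0("staple_", k)]][i] <- staples[[i]][[k]]
    }
  }
  new_world(px, crops, carbon, 1, n)
}
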