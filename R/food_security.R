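# Staple-crop displacement -----------------------------------------------------

#' Staple-crop displacement by allocated oil crops
#'
#' Measures how much currently harvested staple area (wheat, maize, rice,
#' legumes, tubers) coincides with the annual-cropland slice consumed by each
#' allocation. Within a pixel the consumed annual-crop area is apportioned to
#' staples by their share of the pixel's annual-crop area, so per pixel the
#' overlap never exceeds either the consumed annual area or the staple's own
#' harvested area.
#'
#' @param results An `oilscape_allocation` or a list of them.
#' @param world The world they were computed on.
#' @param cover_order,trim_overshoot See [cover_breakdown()].
#' @return Tibble with `crop` (oil crop), `staple`, `overlap_ha`,
#'   `overlap_mha`, one row per combination.
#' @export
staple_displacement <- function(results, world,
                                cover_order = "proportional",
                                trim_overshoot = FALSE) {
  if (inherits(results, "oilscape_allocation")) results <- list(results)
  st_cols <- staple_cols()
  px <- world$pixels %>%
    mutate(annual_area_ha = .data$pixel_area_ha *
             (.data$cover_annual_crop_rainfed + .data$cover_annual_crop_irrigated)) %>%
    select("pixel", "annual_area_ha", all_of(st_cols))
  purrr::map_dfr(results, function(res) {
    consumed_annual <- consumption_detail(res, world, cover_order, trim_overshoot) %>%
      filter(.data$cover %in% annual_covers) %>%
      group_by(.data$pixel) %>%
      summarise(consumed_ha = sum(.data$area_ha), .groups = "drop")
    base <- tibble(crop = res$crop, staple = staple_crops, overlap_ha = 0)
    if (!nrow(consumed_annual)) {
      return(base %>% mutate(overlap_mha = 0))
    }
    d <- consumed_annual %>% left_join(px, by = "pixel")
    staple_total <- rowSums(as.matrix(d[st_cols]))
    denom <- pmax(d$annual_area_ha, staple_total)
    overlaps <- vapply(st_cols, function(s) {
      sum(ifelse(denom > 0, d$consumed_ha * d[[s]] / denom, 0))
    }, numeric(1))
    tibble(
      crop = res$crop,
      staple = staple_crops,
      overlap_ha = unname(overlaps)
    ) %>%
      mutate(overlap_mha = .data$overlap_ha / 1e6)
  })
}
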