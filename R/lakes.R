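#' Study-lake morphometry and fish-community table
#'
#' Lake-level covariates for the seven study lakes near Toolik Field Station,
#' Alaska: four closed "Fog" lakes and three surface-connected "LTER" lakes.
#' Columns cover lake morphometry (surface area, volume, depths, proportion of
#' area/volume shallower than 3 m), Secchi depth (an inverse proxy for primary
#' productivity), the fish community (AC = arctic char, AG = arctic grayling,
#' BT = burbot, LT = lake trout, SS = slimy sculpin), mark--recapture char
#' abundance with its 95% interval, and the published char density in
#' fish per hectare.
#'
#' @return A data.frame with one row per lake.
#' @seealso [char_density()] for how `density_fish_ha` derives from
#'   `abundance` and `surface_area_ha`.
#' @export
study_lakes <- function() {
  data.frame(
    group = c("Fog", "Fog", "Fog", "Fog", "LTER", "LTER", "LTER"),
    lake = c("Fog1", "Fog2", "Fog3", "Fog5", "LTER345", "LTER347", "LTER348"),
    latitude = c(68.684, 68.679, 68.673, 68.678, 68.623, 68.625, 68.641),
    longitude = c(149.082, 149.091, 149.088, 149.065, 149.151, 149.139, 149.127),
    surface_area_ha = c(3.5, 5.9, 3.9, 0.7, 30.7, 13.5, 5.7),
    volume_1e5m3 = c(2.9, 4.4, 3.1, 0.3, 38.2, 7.6, 1.9),
    max_depth_m = c(19.7, 19.8, 21.0, 9.9, 28.6, 17.6, 9.6),
    mean_depth_m = c(8.4, 7.8, 7.6, 3.5, 12.3, 5.6, 3.2),
    prop_area_lt3m = c(0.33, 0.21, 0.30, 0.52, 0.16, 0.28, 0.56),
    prop_vol_lt3m = c(0.29, 0.34, 0.31, 0.61, 0.22, 0.45, 0.70),
    secchi_depth_m = c(4.9, 7.1, 6.0, 5.0, 1.5, 1.8, 3.7),
    community = c("AC,SS", "AC,SS", "AC,SS", "AC,SS",
                  "AC,AG,LT,SS", "AC,AG,LT,SS", "AC,BT,SS"),
    abundance = c(448L, 163L, 666L, 75L, 277L, 73L, 331L),
    abundance_lo = c(290L, 105L, 477L, 55L, 177L, 40L, 227L),
    abundance_hi = c(693L, 288L, 1073L, 119L, 540L, 196L, 563L),
    density_fish_ha = c(128L, 27L, 170L, 107L, 9L, 5L, 58L),
    stringsAsFactors = FALSE
  )
}
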