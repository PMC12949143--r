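#' Mean tissue-plus-blood layer thickness over the alveolar surface
#'
#' Spreading the lung tissue and pulmonary capillary blood volumes as a
#' uniform layer over the alveolar surface gives a mean thickness
#' h = (V_tissue + V_blood) / A. In the units used at this boundary the
#' conversion is the identity: 1 mL / m^2 = 1e-6 m^3 / m^2 = 1 um.
#'
#' @param tissue_volume lung tissue volume, mL.
#' @param blood_volume pulmonary capillary blood volume, mL.
#' @param surface_area alveolar surface area, m^2.
#' @return layer thickness h in micrometres.
#' @export
layer_thickness <- function(tissue_volume, blood_volume, surface_area) {
  stopifnot(all(tissue_volume > 0), all(blood_volume > 0), all(surface_area > 0))
  (tissue_volume + blood_volume) / surface_area
}

#' Volume ratio of a sphere to the same sphere with a surface layer
#'
#' Representing the gas volume (FRC) by a single average alveolus -- a
#' sphere of the given radius -- and the CO2-equilibrating volume (ELV) by
#' the same sphere covered with a layer of thickness h, the ratio of the two
#' volumes is r^3 / (r + h)^3. This is the geometric consistency check for
#' the FRC/ELV proportionality constant.
#'
#' @param radius alveolus radius, um (> 0).
#' @param layer layer thickness h, um (>= 0).
#' @return the dimensionless volume ratio in (0, 1].
#' @export
sphere_volume_ratio <- function(radius, layer) {
  stopifnot(all(radius > 0), all(layer >= 0))
  (radius / (radius + layer))^3
}

#' Alveolar-geometry consistency table for the FRC/ELV constant
#'
#' Evaluates the layer thickness and sphere volume ratio over a range of
#' tissue volumes, with typical-adult defaults: alveolar surface area
#' 90 m^2, capillary blood volume 100 mL, tissue volume 500-700 mL and
#' alveolus radius 125 um.
#'
#' @param tissue_volume tissue volumes to tabulate, mL.
#' @param blood_volume capillary blood volume, mL.
#' @param surface_area alveolar surface area, m^2.
#' @param radius alveolus radius, um.
#' @return data frame with columns `tissue_volume_ml`, `h_um`, `frc_elv_ratio`.
#' @export
alveolar_consistency <- function(tissue_volume = c(500, 700),
                                 blood_volume = 100, surface_area = 90,
                                 radius = 125) {
  h <- layer_thickness(tissue_volume, blood_volume, surface_area)
  data.frame(tissue_volume_ml = tissue_volume, h_um = h,
             frc_elv_ratio = sphere_volume_ratio(radius, h))
}
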