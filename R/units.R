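#' Gravimetric to volumetric soil water content
#'
#' Multiplies the gravimetric (mass) water fraction by the soil bulk density
#' (water density taken as 1 g/cm3).
#'
#' @param theta_g Gravimetric water content (mass fraction, in (0, 1)).
#' @param bulk_density Soil bulk density (g/cm3).
#' @return Volumetric water content (fraction), vectorized.
#' @export
gravimetric_to_volumetric <- function(theta_g, bulk_density) {
  if (any(theta_g <= 0) || any(theta_g >= 1))
    stop("theta_g must lie in (0, 1)", call. = FALSE)
  if (any(bulk_density <= 0))
    stop("bulk_density must be > 0", call. = FALSE)
  out <- theta_g * bulk_density
  if (any(out >= 1))
    stop("inconsistent soil data: volumetric water content >= 1",
         call. = FALSE)
  out
}

#' Anthesis date from an observed heading date
#'
#' Station records usually report heading rather than anthesis; anthesis is
#' taken as heading plus seven calendar days.
#'
#' @param heading_date `Date` (or ISO string), vectorized.
#' @return Anthesis date(s).
#' @export
anthesis_from_heading <- function(heading_date) {
  as.Date(heading_date) + 7L
}

#' Fresh yield to dry matter
#'
#' Converts statistical (fresh-basis) grain yield to dry matter using the
#' standard grain moisture content of 12.5%.
#'
#' @param fresh_yield Yield on fresh basis (kg/ha), vectorized.
#' @return Dry-matter yield (kg/ha).
#' @export
yield_to_dry_matter <- function(fresh_yield) {
  if (any(fresh_yield < 0)) stop("yield must be >= 0", call. = FALSE)
  fresh_yield * (1 - 0.125)
}

#' Aboveground biomass from dry yield via a harvest index
#'
#' @param dry_yield Dry-matter grain yield (kg/ha).
#' @param HI Harvest index (dry yield / dry AGB at maturity, in (0, 1]).
#' @return AGB at maturity (kg/ha), vectorized.
#' @export
agb_from_yield <- function(dry_yield, HI) {
  if (any(HI <= 0) || any(HI > 1))
    stop("harvest index must lie in (0, 1]", call. = FALSE)
  dry_yield / HI
}

#' Total biomass and NPP from aboveground biomass
#'
#' Total (above plus below ground) biomass is AGB x (1 + root-shoot ratio);
#' net primary production is approximated as 0.45 x total biomass.
#'
#' @param agb Aboveground biomass (kg/ha).
#' @param root_shoot_ratio Root to shoot mass ratio (dimensionless, >= 0).
#' @return List with `total_biomass` and `npp` (kg/ha), vectorized.
#' @export
biomass_conversions <- function(agb, root_shoot_ratio) {
  if (any(agb < 0) || any(root_shoot_ratio < 0))
    stop("inputs must be >= 0", call. = FALSE)
  total <- agb * (1 + root_shoot_ratio)
  list(total_biomass = total, npp = 0.45 * total)
}

# Round half away from zero (R's round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)
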