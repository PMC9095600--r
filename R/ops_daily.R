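#' Daily thermal-time increment
#'
#' The effective temperature sum added on one day:
#' max(0, (tmin + tmax)/2 - tbase) degC d.
#'
#' @param tmin,tmax Daily minimum and maximum temperature (degC).
#' @param tbase Base temperature (degC).
#' @return Thermal-time increment (degC d), vectorized.
#' @export
thermal_increment <- function(tmin, tmax, tbase = 0) {
  if (!all(is.finite(tmin)) || !all(is.finite(tmax)) || !all(is.finite(tbase)))
    stop("invalid weather: non-finite temperature input", call. = FALSE)
  if (any(tmin > tmax)) stop("invalid weather: tmin > tmax", call. = FALSE)
  pmax(0, 0.5 * (tmin + tmax) - tbase)
}

#' Development stage from accumulated thermal time
#'
#' DVS runs linearly from 0 at emergence to 1 at anthesis (tsum = TSUM1) and
#' on to 2 at maturity (tsum = TSUM1 + TSUM2), where it is capped.
#'
#' @param tsum_accum Accumulated thermal time before the increment (degC d).
#' @param increment Thermal time added this day (degC d).
#' @param TSUM1 Emergence-to-anthesis thermal time requirement (degC d).
#' @param TSUM2 Anthesis-to-maturity thermal time requirement (degC d).
#' @return Development stage in [0, 2], vectorized over `tsum_accum`.
#' @export
update_phenology <- function(tsum_accum, increment = 0, TSUM1, TSUM2) {
  if (TSUM1 <= 0 || TSUM2 <= 0)
    stop("TSUM1 and TSUM2 must be > 0", call. = FALSE)
  if (any(tsum_accum < 0)) stop("tsum_accum must be >= 0", call. = FALSE)
  tsum <- tsum_accum + increment
  dvs <- ifelse(tsum <= TSUM1, tsum / TSUM1, 1 + (tsum - TSUM1) / TSUM2)
  pmin(dvs, 2)
}

#' One day of the root-zone soil water balance
#'
#' In order: an irrigation event of `policy$V` cm is applied if the policy is
#' enabled and the start-of-day moisture is strictly below `policy$SMc`
#' (raising moisture by V/root_depth); precipitation is added; actual
#' evapotranspiration et0 x min(1, cover) x stress is removed, with cover =
#' 1 - exp(-k_ext LAI); excess above saturation drains away and moisture is
#' floored at half the wilting point. The returned stress factor is
#' clamp((SM - sm_wilt)/(sm_crit - sm_wilt), 0, 1) with sm_crit = sm_wilt +
#' sm_crit_frac (sm_fc - sm_wilt), evaluated after irrigation and rain.
#'
#' @param SM Start-of-day volumetric soil moisture.
#' @param precip Precipitation (mm).
#' @param et0 Reference evapotranspiration (mm).
#' @param lai Leaf area index (m2/m2).
#' @param soil A [soil_params()] object.
#' @param policy An [irrigation_policy()] object.
#' @param k_ext Light extinction coefficient used for ground cover.
#' @return List with `SM` (end-of-day moisture), `irrigation_cm` and `stress`.
#' @export
soil_water_step <- function(SM, precip, et0, lai, soil, policy, k_ext = 0.6) {
  irr <- 0
  if (policy$enabled && SM < policy$SMc) {
    irr <- policy$V
    SM <- SM + policy$V / soil$root_depth
  }
  SM <- SM + precip / (10 * soil$root_depth)
  sm_crit <- soil$sm_wilt + soil$sm_crit_frac * (soil$sm_fc - soil$sm_wilt)
  stress <- min(1, max(0, (SM - soil$sm_wilt) / (sm_crit - soil$sm_wilt)))
  cover <- 1 - exp(-k_ext * lai)
  SM <- SM - et0 * min(1, cover) * stress / (10 * soil$root_depth)
  SM <- min(SM, soil$sm_sat)
  SM <- max(SM, 0.5 * soil$sm_wilt)
  list(SM = SM, irrigation_cm = irr, stress = stress)
}

#' One day of biomass growth
#'
#' Gross assimilation follows a light-use-efficiency rule on intercepted PAR,
#' A = eps_lue x 0.5 radiation x (1 - exp(-k_ext LAI)) x stress; maintenance
#' respiration is a Q10 function of mean temperature summed over living
#' organs and capped at A, and the non-negative net growth is split over
#' leaf/stem/storage/root by the DVS-dependent partitioning table. Leaf-area
#' growth is source-limited (SLA x leaf increment) except in the juvenile
#' phase (DVS < dvs_juvenile), where it is additionally capped by the
#' exponential rule LAI x (exp(RGRLAI dtsum) - 1).
#'
#' @param state List with `lai`, `leaf` (living leaf mass), `stem`,
#'   `storage`, `root` (kg/ha).
#' @param weather_day List with `radiation`, `tmin`, `tmax`.
#' @param crop A [crop_params()] object.
#' @param stress Water-stress factor in [0, 1].
#' @param dvs Development stage used for partitioning.
#' @param dtsum Thermal-time increment of the day (degC d), used by the
#'   juvenile LAI rule.
#' @return List with `assimilation`, `respiration`, `net`, and increments
#'   `d_leaf`, `d_stem`, `d_storage`, `d_root`, `d_lai`.
#' @export
daily_growth <- function(state, weather_day, crop, stress, dvs, dtsum) {
  tmean <- 0.5 * (weather_day$tmin + weather_day$tmax)
  A <- crop$eps_lue * 0.5 * weather_day$radiation *
    (1 - exp(-crop$k_ext * state$lai)) * stress
  rm <- (crop$rm_leaf * state$leaf + crop$rm_stem * state$stem +
           crop$rm_storage * state$storage + crop$rm_root * state$root) *
    crop$q10^((tmean - 25) / 10)
  rm <- min(rm, A)
  net <- A - rm
  fl <- part_fraction(crop, "leaf", dvs)
  fs <- part_fraction(crop, "stem", dvs)
  fo <- part_fraction(crop, "storage", dvs)
  fr <- part_fraction(crop, "root", dvs)
  d_leaf <- net * fl
  d_lai <- if (dvs < crop$dvs_juvenile)
    min(state$lai * (exp(crop$rgrlai * dtsum) - 1), crop$sla * d_leaf)
  else crop$sla * d_leaf
  list(assimilation = A, respiration = rm, net = net,
       d_leaf = d_leaf, d_stem = net * fs, d_storage = net * fo,
       d_root = net * fr, d_lai = d_lai)
}

# Partitioning fraction for one organ at a given DVS (linear interpolation,
# constant beyond the end nodes).
part_fraction <- function(crop, organ, dvs) {
  y <- crop[[paste0("part_", organ)]]
  x <- crop$part_dvs
  stats::approx(x, y, xout = min(max(dvs, x[1]), x[length(x)]),
                rule = 2)$y
}

#' Age and senesce leaf cohorts
#'
#' Each cohort's physiological age grows by max(0, tmean)/35 per day; a
#' cohort whose age exceeds `SPAN` dies, its mass moving to the dead-leaf
#' pool (which remains part of AGB) and its area leaving the canopy.
#'
#' @param cohorts data.frame with columns `mass`, `area`, `age`.
#' @param tmean Daily mean temperature (degC).
#' @param SPAN Leaf life span at 35 degC (d).
#' @return List with `cohorts` (survivors, aged), `dead_mass` (mass that died
#'   today) and `lai_loss` (area that died today).
#' @export
senesce_leaves <- function(cohorts, tmean, SPAN) {
  if (nrow(cohorts) == 0)
    return(list(cohorts = cohorts, dead_mass = 0, lai_loss = 0))
  cohorts$age <- cohorts$age + max(0, tmean) / 35
  dead <- cohorts$age > SPAN
  list(cohorts = cohorts[!dead, , drop = FALSE],
       dead_mass = sum(cohorts$mass[dead]),
       lai_loss = sum(cohorts$area[dead]))
}
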