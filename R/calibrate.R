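#' Assemble the calibration inputs of one Thiessen zone
#'
#' A zone bundles everything the three-step calibration needs: the station's
#' soil parameters, the zonal crop-parameter start (with phenology-fit TSUM1
#' and TSUM2), the weather series spanning the study years, per-year
#' emergence dates, the member counties' yield statistics, and the
#' province harvest-index table.
#'
#' @param station_id Station (zone) identifier.
#' @param soil A [soil_params()] object.
#' @param crop_start A [crop_params()] start point.
#' @param weather Weather data.frame covering all seasons.
#' @param emergence_by_year Named vector/list of emergence `Date`s, names =
#'   harvest years.
#' @param counties data.frame with columns `county`, `province`, `year`,
#'   `yield` (fresh kg/ha; NA allowed).
#' @param hi_table data.frame with columns `province`, `hi`.
#' @param years Harvest years to calibrate jointly (default: all present,
#'   taken in consecutive non-overlapping triples anchored at the first).
#' @return An object of class `wheat_zone`.
#' @export
wheat_zone <- function(station_id, soil, crop_start, weather,
                       emergence_by_year, counties, hi_table,
                       years = sort(unique(counties$year))) {
  stopifnot(inherits(soil, "soil_params"), inherits(crop_start, "crop_params"))
  validate_weather(weather)
  if (any(!is.na(counties$yield) & counties$yield <= 0))
    stop("county yields must be > 0 where present", call. = FALSE)
  structure(list(station_id = station_id, soil = soil,
                 crop_start = crop_start, weather = weather,
                 emergence_by_year = emergence_by_year,
                 counties = counties, hi_table = hi_table, years = years),
            class = "wheat_zone")
}

# Per-year weather matrices from a zone, starting at each emergence date.
zone_weather_matrices <- function(zone, max_days = 330) {
  out <- list()
  for (y in zone$years) {
    em <- as.Date(zone$emergence_by_year[[as.character(y)]])
    i0 <- match(em, zone$weather$date)
    if (is.na(i0))
      stop("weather does not cover emergence of year ", y, call. = FALSE)
    i1 <- min(i0 + max_days - 1, nrow(zone$weather))
    out[[as.character(y)]] <-
      weather_matrix(zone$weather[seq.int(i0, i1), , drop = FALSE])
  }
  out
}

# Annual simulator outputs entering the likelihood: max LAI, final TWSO and
# final AGB per year, for a given crop/policy configuration.
annual_outputs <- function(wms, crop, soil, policies, sm_init) {
  t(vapply(names(wms), function(y) {
    run <- season_core(wms[[y]], crop, soil, policies[[y]], sm_init)
    n <- length(run$agb)
    c(max_lai = max(run$lai), twso = run$twso[n], agb = run$agb[n])
  }, c(max_lai = 0, twso = 0, agb = 0)))
}

# Observation side of the likelihood for one representative county.
calibration_observations <- function(zone, rep_county, lai_mean = 6.5,
                                     lai_sd = 1.5, sd_frac = 0.10) {
  cc <- zone$counties[zone$counties$county == rep_county, , drop = FALSE]
  prov <- cc$province[1]
  hi <- zone$hi_table$hi[match(prov, zone$hi_table$province)]
  if (is.na(hi)) stop("no harvest index for province ", prov, call. = FALSE)
  yields <- cc$yield[match(zone$years, cc$year)]
  keep <- !is.na(yields)
  if (!any(keep))
    stop("representative county has no yields in the calibration window",
         call. = FALSE)
  twso_mu <- yield_to_dry_matter(yields[keep])
  list(years = zone$years[keep], d = sum(keep),
       dropped_years = zone$years[!keep],
       lai_mu = rep(lai_mean, sum(keep)), lai_sd = rep(lai_sd, sum(keep)),
       twso_mu = twso_mu, agb_mu = agb_from_yield(twso_mu, hi),
       sd_frac = sd_frac, hi = hi)
}

# Total log-likelihood of a crop/irrigation configuration against the
# observation block of one representative county.
calibration_loglik <- function(wms, crop, soil, policies, obs,
                               sm_init) {
  keep <- as.character(obs$years)
  sim <- annual_outputs(wms[keep], crop, soil, policies[keep], sm_init)
  total_log_likelihood(
    likelihood_spec(sim[, "max_lai"], obs$lai_mu, obs$lai_sd^2),
    likelihood_spec(sim[, "twso"], obs$twso_mu, (obs$sd_frac * obs$twso_mu)^2),
    likelihood_spec(sim[, "agb"], obs$agb_mu, (obs$sd_frac * obs$agb_mu)^2))
}

#' Default box bounds for the free crop parameters
#'
#' @param crop A [crop_params()] start point (bounds are centred on it for
#'   TSUM1/TSUM2 only; the biological parameters use absolute ranges).
#' @return Named list of c(lower, upper) ranges.
#' @export
default_calibration_bounds <- function(crop) {
  list(TDWI = c(50, 600), SPAN = c(15, 45), SLA = c(0.0012, 0.0040),
       eps_lue = c(15, 45), RGRLAI = c(0.004, 0.014),
       TSUM1 = crop$tsum1 * c(0.85, 1.15), TSUM2 = crop$tsum2 * c(0.85, 1.15))
}

#' Step 1/3: maximum-likelihood fit of crop parameters
#'
#' Maximizes the combined LAI/TWSO/AGB log-likelihood over a configurable
#' subset of crop parameters, holding irrigation fixed, by bounded
#' derivative-free search.
#'
#' @param zone A [wheat_zone()].
#' @param rep_county Representative county id providing the yield
#'   statistics.
#' @param crop Crop-parameter start point.
#' @param free_params Character vector of parameter names to optimize
#'   (empty returns `crop` unchanged). The default {SPAN, eps_lue} covers
#'   the leaf-dynamics and yield-scale degrees of freedom that the annual
#'   (max LAI, TWSO, AGB) observations actually constrain.
#' @param policies Named list (by year) of fixed [irrigation_policy()]s.
#' @param bounds Named list of ranges, see [default_calibration_bounds()].
#' @param maxeval Objective evaluation budget.
#' @param wms Precomputed weather matrices (internal reuse).
#' @return List with `crop` (fitted), `logLik`, `evals`.
#' @export
calibrate_crop_params <- function(zone, rep_county, crop,
                                  free_params = c("SPAN", "eps_lue"),
                                  policies = NULL,
                                  bounds = default_calibration_bounds(crop),
                                  maxeval = 500, wms = NULL) {
  if (is.null(wms)) wms <- zone_weather_matrices(zone)
  if (is.null(policies)) policies <- rainfed_policies(zone$years)
  obs <- calibration_observations(zone, rep_county)
  if (length(free_params) == 0) {
    ll <- calibration_loglik(wms, crop, zone$soil, policies, obs,
                             zone$soil$sm_fc)
    return(list(crop = crop, logLik = ll, evals = 1))
  }
  start <- vapply(free_params, function(nm) get_crop_param(crop, nm), 0)
  lo <- vapply(free_params, function(nm) bounds[[nm]][1], 0)
  hi <- vapply(free_params, function(nm) bounds[[nm]][2], 0)
  negll <- function(p) {
    cand <- tryCatch(set_crop_params(crop, stats::setNames(p, free_params)),
                     error = function(e) NULL)
    if (is.null(cand)) return(1e10)
    ll <- tryCatch(calibration_loglik(wms, cand, zone$soil, policies, obs,
                                      zone$soil$sm_fc),
                   error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)  # simulator failure -> reject candidate
    -ll
  }
  fit <- bounded_minimize(start, negll, lo, hi, maxeval = maxeval)
  list(crop = set_crop_params(crop, stats::setNames(fit$par, free_params)),
       logLik = -fit$value, evals = fit$counts)
}

rainfed_policies <- function(years) {
  p <- irrigation_policy(enabled = FALSE, SMc = 0, V = 0)
  stats::setNames(rep(list(p), length(years)), as.character(years))
}

#' Step 2/3: maximum-likelihood fit of per-year irrigation
#'
#' With crop parameters held fixed, maximizes the same log-likelihood over
#' the 2 d irrigation parameters (SMc_y, V_y for each jointly calibrated
#' year). SMc is bounded in [sm_wilt, sm_fc] and V in [0, v_max]; V = 0
#' reproduces the rainfed run, so the step can only improve the objective.
#'
#' @param zone A [wheat_zone()].
#' @param rep_county Representative county id.
#' @param crop Fixed crop parameters.
#' @param v_max Upper bound of the per-event application depth (cm).
#' @param maxeval Objective evaluation budget.
#' @param wms Precomputed weather matrices (internal reuse).
#' @return List with `policies` (named list by year), `logLik`, `evals`.
#' @export
calibrate_irrigation <- function(zone, rep_county, crop, v_max = 10,
                                 maxeval = 700, wms = NULL) {
  if (is.null(wms)) wms <- zone_weather_matrices(zone)
  obs <- calibration_observations(zone, rep_county)
  d <- obs$d
  soil <- zone$soil
  mk <- function(p) {
    pol <- lapply(seq_len(d), function(i)
      irrigation_policy(SMc = p[2 * i - 1], V = p[2 * i], enabled = TRUE))
    stats::setNames(pol, as.character(obs$years))
  }
  negll <- function(p) {
    ll <- tryCatch(calibration_loglik(wms, crop, soil, mk(p), obs,
                                      soil$sm_fc),
                   error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  start <- rep(c(soil$sm_wilt + 0.5 * (soil$sm_fc - soil$sm_wilt), 0), d)
  lo <- rep(c(soil$sm_wilt, 0), d)
  hi <- rep(c(soil$sm_fc, v_max), d)
  fit <- bounded_minimize(start, negll, lo, hi, maxeval = maxeval)
  pols <- mk(fit$par)
  full <- rainfed_policies(zone$years)
  full[names(pols)] <- pols
  list(policies = full, logLik = -fit$value, evals = fit$counts)
}

#' Three-step zonal calibration
#'
#' For each yield-level group of the zone's counties (high/medium/low by the
#' 33%/67% quantiles of mean yield, represented by the 17%/50%/83% quantile
#' counties): (1) fit the free crop parameters under rainfed conditions,
#' (2) fit per-year irrigation (SMc, V) with the crop fixed, (3) re-fit the
#' crop parameters with the optimized irrigation fixed. Each step restarts
#' from the previous optimum, so the objective sequence is non-decreasing up
#' to optimizer tolerance.
#'
#' @param zone A [wheat_zone()].
#' @param free_params Crop parameters optimized in steps 1 and 3.
#' @param bounds See [default_calibration_bounds()].
#' @param v_max Irrigation depth upper bound (cm).
#' @param maxeval Per-step evaluation budget.
#' @return An object of class `zone_calibration`: per level a list with
#'   `crop`, `policies`, `objectives` (the three step log-likelihoods),
#'   `rep_county`; plus the grouping and the phenology start point.
#' @export
three_step_calibration <- function(zone,
                                   free_params = c("SPAN", "eps_lue"),
                                   bounds = default_calibration_bounds(
                                     zone$crop_start),
                                   v_max = 10, maxeval = 800) {
  means <- stats::aggregate(yield ~ county, data = zone$counties,
                            FUN = mean, na.rm = TRUE)
  names(means) <- c("county", "mean_yield")
  grouping <- group_counties_by_yield(means)
  wms <- zone_weather_matrices(zone)
  levels <- lapply(names(grouping$representatives), function(lv) {
    rep_c <- grouping$representatives[[lv]]
    s1 <- calibrate_crop_params(zone, rep_c, zone$crop_start,
                                free_params = free_params,
                                bounds = bounds, maxeval = maxeval,
                                wms = wms)
    s2 <- calibrate_irrigation(zone, rep_c, s1$crop, v_max = v_max,
                               maxeval = maxeval, wms = wms)
    if (s2$logLik < s1$logLik) {
      # irrigation cannot beat the rainfed optimum here; keep rainfed
      s2 <- list(policies = rainfed_policies(zone$years),
                 logLik = s1$logLik, evals = s2$evals)
    }
    s3 <- calibrate_crop_params(zone, rep_c, s1$crop,
                                free_params = free_params,
                                policies = s2$policies, bounds = bounds,
                                maxeval = maxeval, wms = wms)
    list(crop = s3$crop, policies = s2$policies,
         objectives = c(step1 = s1$logLik, step2 = s2$logLik,
                        step3 = s3$logLik),
         rep_county = rep_c)
  })
  names(levels) <- names(grouping$representatives)
  structure(list(station_id = zone$station_id, levels = levels,
                 grouping = grouping, free_params = free_params,
                 crop_start = zone$crop_start, zone = zone),
            class = "zone_calibration")
}

#' @export
print.zone_calibration <- function(x, ...) {
  cat("Zonal three-step calibration (station ", x$station_id, ")\n",
      sep = "")
  for (lv in names(x$levels)) {
    l <- x$levels[[lv]]
    cat(sprintf("  %-7s rep county %-6s logLik %8.3f -> %8.3f -> %8.3f\n",
                lv, as.character(l$rep_county), l$objectives[1],
                l$objectives[2], l$objectives[3]))
  }
  cat("  free parameters:", paste(x$free_params, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.zone_calibration <- function(object, ...) {
  t(vapply(object$levels, function(l)
    vapply(object$free_params, function(nm) get_crop_param(l$crop, nm), 0),
    stats::setNames(numeric(length(object$free_params)),
                    object$free_params)))
}

#' @export
summary.zone_calibration <- function(object, ...) {
  co <- coef(object)
  obj <- t(vapply(object$levels, function(l) l$objectives, numeric(3)))
  irr <- vapply(object$levels, function(l)
    sum(vapply(l$policies, function(p) p$V * p$enabled, 0)), 0)
  out <- list(station_id = object$station_id, coef = co, objectives = obj,
              total_v = irr, grouping = object$grouping)
  class(out) <- "summary.zone_calibration"
  out
}

#' @export
print.summary.zone_calibration <- function(x, ...) {
  cat("Calibrated parameter sets (station ", x$station_id, ")\n", sep = "")
  print(round(x$coef, 4))
  cat("Step log-likelihoods:\n")
  print(round(x$objectives, 3))
  invisible(x)
}

#' Write a zone calibration to a structured text file
#'
#' One YAML document per zone holding the three parameter sets, the per-year
#' irrigation policies and the achieved step objectives.
#'
#' @param cal A `zone_calibration`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_zone_calibration <- function(cal, path) {
  doc <- list(station = cal$station_id,
              free_params = as.list(cal$free_params),
              levels = lapply(cal$levels, function(l) list(
                rep_county = as.character(l$rep_county),
                objectives = as.list(l$objectives),
                crop = lapply(cal$free_params, function(nm)
                  get_crop_param(l$crop, nm)) |>
                  stats::setNames(cal$free_params),
                tsum1 = l$crop$tsum1, tsum2 = l$crop$tsum2,
                policies = lapply(l$policies, function(p)
                  list(SMc = p$SMc, V = p$V, enabled = p$enabled)))))
  yaml::write_yaml(doc, path)
  invisible(path)
}
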