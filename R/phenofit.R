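#' Continuous anthesis and maturity crossing days
#'
#' From a weather series starting at emergence, returns the (fractionally
#' interpolated) day-after-emergence at which accumulated thermal time
#' crosses `TSUM1` (anthesis) and `TSUM1 + TSUM2` (maturity). The
#' interpolation makes the phenology-fit objective continuous in the thermal
#' time requirements.
#'
#' @param weather Weather data.frame starting at the emergence date.
#' @param TSUM1,TSUM2 Thermal-time requirements (degC d).
#' @param tbase Base temperature (degC).
#' @return List with `anthesis` and `maturity` (days after emergence, day 1
#'   being the emergence day; NA if the series ends before the crossing).
#' @export
simulate_phenology_dates <- function(weather, TSUM1, TSUM2, tbase = 0) {
  cum <- cumsum(thermal_increment(weather$tmin, weather$tmax, tbase))
  list(anthesis = crossing_day(cum, TSUM1),
       maturity = crossing_day(cum, TSUM1 + TSUM2))
}

crossing_day <- function(cum, target) {
  i <- match(TRUE, cum >= target)
  if (is.na(i)) return(NA_real_)
  prev <- if (i == 1) 0 else cum[i - 1]
  if (cum[i] == prev) return(as.numeric(i))
  (i - 1) + (target - prev) / (cum[i] - prev)
}

#' Fit zonal thermal-time requirements from station phenology
#'
#' Estimates (TSUM1, TSUM2) by minimizing the summed squared differences
#' between simulated and observed anthesis and maturity days over the
#' available seasons, with the simulation started at each season's observed
#' emergence. The search is a bounded derivative-free simplex refinement of
#' the closed-form start (the mean accumulated thermal time at the observed
#' dates).
#'
#' @param phenology data.frame with one row per season: columns `emergence`,
#'   `anthesis`, `maturity` (Dates).
#' @param weather Weather data.frame covering all seasons.
#' @param tbase Base temperature (degC).
#' @param bounds Named list with `TSUM1` and `TSUM2` ranges.
#' @return List with `TSUM1`, `TSUM2`, `sse` (day^2) and `n_seasons`.
#' @export
fit_phenology_params <- function(phenology, weather, tbase = 0,
                                 bounds = list(TSUM1 = c(400, 2200),
                                               TSUM2 = c(200, 1600))) {
  ph <- phenology[stats::complete.cases(
    phenology[, c("emergence", "anthesis", "maturity")]), , drop = FALSE]
  if (nrow(ph) == 0)
    stop("no season with complete emergence/anthesis/maturity dates",
         call. = FALSE)
  if (any(as.Date(ph$anthesis) >= as.Date(ph$maturity)) ||
      any(as.Date(ph$emergence) >= as.Date(ph$anthesis)))
    stop("degenerate phenology: require emergence < anthesis < maturity",
         call. = FALSE)
  seasons <- lapply(seq_len(nrow(ph)), function(i) {
    em <- as.Date(ph$emergence[i]); mt <- as.Date(ph$maturity[i])
    i0 <- match(em, weather$date)
    i1 <- match(mt + 60L, weather$date)
    if (is.na(i1)) i1 <- nrow(weather)
    if (is.na(i0) || weather$date[nrow(weather)] < mt)
      stop("weather does not cover a phenology season", call. = FALSE)
    w <- weather[seq.int(i0, i1), , drop = FALSE]
    cum <- cumsum(thermal_increment(w$tmin, w$tmax, tbase))
    list(cum = cum,
         obs_anth = as.numeric(em - em) + as.numeric(as.Date(ph$anthesis[i]) - em) + 1,
         obs_mat = as.numeric(mt - em) + 1)
  })
  # closed-form start: mean accumulated thermal time at the observed days
  t1_0 <- mean(vapply(seasons, function(s) s$cum[s$obs_anth], 0))
  t2_0 <- mean(vapply(seasons, function(s) s$cum[s$obs_mat], 0)) - t1_0
  sse <- function(p) {
    s2 <- 0
    for (s in seasons) {
      a <- crossing_day(s$cum, p[1])
      m <- crossing_day(s$cum, p[1] + p[2])
      if (is.na(a) || is.na(m)) return(1e10)
      s2 <- s2 + (a - s$obs_anth)^2 + (m - s$obs_mat)^2
    }
    s2
  }
  start <- c(min(max(t1_0, bounds$TSUM1[1]), bounds$TSUM1[2]),
             min(max(t2_0, bounds$TSUM2[1]), bounds$TSUM2[2]))
  fit <- bounded_minimize(start, sse,
                          lower = c(bounds$TSUM1[1], bounds$TSUM2[1]),
                          upper = c(bounds$TSUM1[2], bounds$TSUM2[2]),
                          maxeval = 600)
  list(TSUM1 = fit$par[1], TSUM2 = fit$par[2], sse = fit$value,
       n_seasons = length(seasons))
}
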