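# Named RNG substreams derived from one root seed, so each synthetic
# component can be regenerated independently and deterministically.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) %% 97651L) * 21841L + (h %% 21841L)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Seasonal climate profile of the synthetic weather generator
#'
#' A smooth sinusoidal annual temperature and radiation cycle with seeded
#' daily noise and a two-state (wet/dry) precipitation occurrence chain,
#' shaped like a semi-arid temperate winter-wheat region where spring
#' irrigation matters.
#'
#' @param tmean_annual Annual mean temperature (degC).
#' @param tmean_amplitude Half-range of the annual temperature cycle (degC).
#' @param tmean_peak_doy Day of year of the temperature maximum.
#' @param diurnal_half_range Half of the mean diurnal temperature range
#'   (degC).
#' @param rad_mean,rad_amplitude,rad_peak_doy Radiation cycle (MJ/m2/d).
#' @param temp_noise_sd,rad_noise_sd Daily noise SDs.
#' @param p_wet_dry,p_wet_wet Wet-day probabilities after a dry / wet day.
#' @param rain_mean Mean wet-day precipitation (mm, exponential).
#' @return List of class `climate_profile`.
#' @export
climate_profile <- function(tmean_annual = 13, tmean_amplitude = 14,
                            tmean_peak_doy = 200, diurnal_half_range = 4.5,
                            rad_mean = 15.5, rad_amplitude = 8.5,
                            rad_peak_doy = 172, temp_noise_sd = 1.5,
                            rad_noise_sd = 2.5, p_wet_dry = 0.10,
                            p_wet_wet = 0.45, rain_mean = 4.5) {
  structure(as.list(environment()), class = "climate_profile")
}

#' Generate a synthetic daily weather series
#'
#' Deterministic per seed. Daily mean temperature follows the profile's
#' sinusoid plus Gaussian noise; tmin/tmax bracket it by a (noisy) diurnal
#' half-range, so tmin <= tmax by construction. Radiation co-varies with day
#' length (its own sinusoid), is reduced on wet days and floored at 0.5.
#' Precipitation occurrence follows a two-state Markov chain with
#' exponential wet-day amounts. Vapour pressure is 75% of saturation at the
#' daily mean; wind is a positive perturbation around 2 m/s.
#'
#' @param seed Integer seed of this series.
#' @param start_date First day (`Date` or ISO string).
#' @param n_days Number of days (>= 1).
#' @param profile A [climate_profile()].
#' @return Weather data.frame (columns date, radiation, tmin, tmax, vap,
#'   wind, precip).
#' @export
generate_weather <- function(seed, start_date, n_days,
                             profile = climate_profile()) {
  stopifnot(n_days >= 1)
  p <- profile
  dates <- as.Date(start_date) + seq_len(n_days) - 1L
  doy <- as.integer(format(dates, "%j"))
  with_seed(seed, {
    tmean <- p$tmean_annual + p$tmean_amplitude *
      cos(2 * pi * (doy - p$tmean_peak_doy) / 365.25) +
      stats::rnorm(n_days, 0, p$temp_noise_sd)
    half <- pmax(0.5, p$diurnal_half_range + stats::rnorm(n_days, 0, 0.8))
    wet <- logical(n_days)
    u <- stats::runif(n_days)
    wet[1] <- u[1] < p$p_wet_dry
    for (i in 2:max(2, n_days)) {
      if (i > n_days) break
      wet[i] <- u[i] < (if (wet[i - 1]) p$p_wet_wet else p$p_wet_dry)
    }
    precip <- ifelse(wet, stats::rexp(n_days, 1 / p$rain_mean), 0)
    rad <- p$rad_mean + p$rad_amplitude *
      cos(2 * pi * (doy - p$rad_peak_doy) / 365.25) +
      stats::rnorm(n_days, 0, p$rad_noise_sd)
    rad <- pmax(0.5, rad * ifelse(wet, 0.7, 1))
    es <- 6.11 * exp(17.27 * tmean / (237.3 + tmean))
    wind <- 2 + abs(stats::rnorm(n_days, 0, 1))
    data.frame(date = dates, radiation = rad, tmin = tmean - half,
               tmax = tmean + half, vap = 0.75 * es, wind = wind,
               precip = precip)
  })
}

#' Define a synthetic study scenario
#'
#' Fixes every knob of the synthetic region: grid and station layout,
#' counties per zone, study years, the truth parameter distribution (zonal
#' jitter plus yield-level light-use-efficiency offsets and per-pixel
#' phenology/leaf perturbations), and the observation noise model (county
#' yield SD fraction 0.10; satellite LAI multiplicative bias 0.7 with
#' additive noise and a 3-point moving-average smoothing; station max-LAI
#' prior N(6.5, 1.5^2)). One root seed drives named substreams so the whole
#' scenario is reproducible.
#'
#' @param seed Root seed.
#' @param grid_dim c(rows, cols) of the 1 km pixel grid.
#' @param cell_size Cell size (km, nominal).
#' @param n_stations Number of agrometeorological stations (= zones).
#' @param counties_per_zone Counties carved out of each zone.
#' @param years Harvest years.
#' @param mask_fraction Fraction of cells inside the winter-wheat mask.
#' @param yield_noise_sd County yield noise SD as a fraction of the value.
#' @param lai_bias Multiplicative bias of satellite LAI vs true LAI.
#' @param lai_noise_sd Additive satellite LAI noise SD.
#' @param lai_smooth Apply the 3-point moving average to the LAI stacks.
#' @param pixel_idem_range,pixel_span_range Per-pixel truth perturbation
#'   ranges (uniform, days) of emergence offset and SPAN.
#' @param pixel_tsum1_frac Per-pixel TSUM1 perturbation range (fractional).
#' @param level_eps Named multiplicative light-use-efficiency offsets of the
#'   high/medium/low yield levels.
#' @param zone_jitter Apply random zonal jitter to the truth parameters.
#' @param irrigation Truth runs use threshold-triggered irrigation.
#' @param maxlai_mean,maxlai_sd Station max-LAI observation prior.
#' @param climate A [climate_profile()].
#' @return List of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1, grid_dim = c(6, 6), cell_size = 1,
                               n_stations = 1, counties_per_zone = 9,
                               years = 2007:2009, mask_fraction = 1,
                               yield_noise_sd = 0.10, lai_bias = 0.7,
                               lai_noise_sd = 0.10, lai_smooth = TRUE,
                               pixel_idem_range = c(-6, 6),
                               pixel_span_range = c(-4, 4),
                               pixel_tsum1_frac = c(-0.08, 0.08),
                               level_eps = c(high = 1.07, medium = 1,
                                             low = 0.93),
                               zone_jitter = TRUE, irrigation = TRUE,
                               maxlai_mean = 6.5, maxlai_sd = 1.5,
                               climate = climate_profile()) {
  stopifnot(lai_bias > 0, lai_bias <= 1, yield_noise_sd >= 0,
            lai_noise_sd >= 0)
  structure(as.list(environment()), class = "synthetic_scenario")
}

#' Generate the synthetic study region
#'
#' Lays out the pixel grid, stations (jittered lattice), Thiessen zones,
#' counties (contiguous chunks of each zone, one province per zone, yield
#' levels assigned in rotation), the winter-wheat mask, per-zone weather
#' series spanning all study years, and the truth parameters: per-zone
#' jittered crop/soil/irrigation constants, per-level light-use-efficiency
#' offsets and per-pixel (IDEM, SPAN, TSUM1) perturbations.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List of class `synthetic_region` with `cells`, `stations`,
#'   `counties`, `truth` (per zone), `weather` (per zone), `emergence` (per
#'   zone x year) and the scenario.
#' @export
generate_region <- function(scenario) {
  sc <- scenario
  nr <- sc$grid_dim[1]; nc <- sc$grid_dim[2]
  n <- nr * nc
  cells <- data.frame(pixel = seq_len(n),
                      row = rep(seq_len(nr), each = nc),
                      col = rep(seq_len(nc), times = nr))
  cells$x <- (cells$col - 0.5) * sc$cell_size
  cells$y <- (cells$row - 0.5) * sc$cell_size

  k <- sc$n_stations
  ks <- ceiling(sqrt(k))
  sx <- ((rep(seq_len(ks), times = ks) - 0.5) / ks) * nc * sc$cell_size
  sy <- ((rep(seq_len(ks), each = ks) - 0.5) / ks) * nr * sc$cell_size
  stations <- with_seed(substream_seed(sc$seed, "region"), {
    jx <- stats::runif(ks * ks, -0.2, 0.2) * nc * sc$cell_size / ks
    jy <- stats::runif(ks * ks, -0.2, 0.2) * nr * sc$cell_size / ks
    data.frame(id = seq_len(k), x = (sx + jx)[seq_len(k)],
               y = (sy + jy)[seq_len(k)])
  })
  cells$zone <- build_thiessen_zones(stations, cells)

  # counties: contiguous chunks of each zone's cells, levels in rotation
  cells$county <- NA_integer_
  county_rows <- list()
  lv_names <- c("high", "medium", "low")
  for (z in stations$id) {
    in_z <- which(cells$zone == z)
    in_z <- in_z[order(cells$row[in_z], cells$col[in_z])]
    ncty <- min(sc$counties_per_zone, length(in_z))
    chunk <- if (ncty == 1) rep(1L, length(in_z))
      else cut(seq_along(in_z), ncty, labels = FALSE)
    for (j in seq_len(ncty)) {
      cid <- z * 1000L + j
      cells$county[in_z[chunk == j]] <- cid
      county_rows[[length(county_rows) + 1]] <-
        data.frame(county = cid, province = z, zone = z,
                   level = lv_names[(j - 1) %% 3 + 1])
    }
  }
  counties <- do.call(rbind, county_rows)

  cells$masked <- with_seed(substream_seed(sc$seed, "mask"),
                            stats::runif(n) < sc$mask_fraction)
  cells$level <- counties$level[match(cells$county, counties$county)]

  # truth parameters
  truth <- with_seed(substream_seed(sc$seed, "truth"), {
    lapply(stations$id, function(z) {
      base <- crop_params()
      soil <- soil_params()
      if (sc$zone_jitter) {
        base <- set_crop_params(base, list(
          TSUM1 = base$tsum1 * stats::runif(1, 0.97, 1.03),
          TSUM2 = base$tsum2 * stats::runif(1, 0.97, 1.03),
          SPAN = base$span + stats::runif(1, -1.5, 1.5),
          eps_lue = base$eps_lue * stats::runif(1, 0.97, 1.03)))
        soil <- soil_params(
          sm_wilt = stats::runif(1, 0.10, 0.14),
          sm_fc = stats::runif(1, 0.26, 0.32),
          sm_sat = 0.45, root_depth = 100)
      }
      crop_by_level <- lapply(sc$level_eps, function(f)
        set_crop_params(base, list(eps_lue = base$eps_lue * f)))
      names(crop_by_level) <- names(sc$level_eps)
      policy <- if (sc$irrigation) {
        smc <- min(max(stats::runif(1, 0.18, 0.22), soil$sm_wilt + 0.02),
                   soil$sm_fc - 0.02)
        irrigation_policy(SMc = smc, V = stats::runif(1, 3, 5),
                          enabled = TRUE, soil = soil)
      } else irrigation_policy(enabled = FALSE, SMc = 0, V = 0)
      list(crop = crop_by_level, soil = soil, policy = policy)
    })
  })
  names(truth) <- as.character(stations$id)

  # per-pixel truth perturbations (drawn for all cells; used where masked)
  pert <- with_seed(substream_seed(sc$seed, "pixel"), data.frame(
    pixel = cells$pixel,
    idem_off = round(stats::runif(n, sc$pixel_idem_range[1],
                                  sc$pixel_idem_range[2])),
    span_add = stats::runif(n, sc$pixel_span_range[1],
                            sc$pixel_span_range[2]),
    tsum1_frac = stats::runif(n, sc$pixel_tsum1_frac[1],
                              sc$pixel_tsum1_frac[2])))

  # zonal emergence dates and per-zone weather spanning all seasons
  emergence <- with_seed(substream_seed(sc$seed, "calendar"), {
    out <- list()
    for (z in stations$id) {
      zj <- round(stats::runif(1, -3, 3))
      out[[as.character(z)]] <- stats::setNames(
        as.Date(paste0(sc$years - 1, "-10-08")) + zj +
          round(stats::runif(length(sc$years), -2, 2)),
        as.character(sc$years))
    }
    out
  })
  w_start <- as.Date(paste0(min(sc$years) - 1, "-09-01"))
  w_end <- as.Date(paste0(max(sc$years), "-07-31"))
  weather <- lapply(stations$id, function(z)
    generate_weather(substream_seed(sc$seed, paste0("weather", z)),
                     w_start, as.integer(w_end - w_start) + 1L,
                     sc$climate))
  names(weather) <- as.character(stations$id)

  structure(list(scenario = sc, cells = cells, stations = stations,
                 counties = counties, truth = truth, pixel_pert = pert,
                 emergence = emergence, weather = weather),
            class = "synthetic_region")
}

#' Simulate the truth and derive all synthetic observations
#'
#' Runs the crop core with the truth parameters for every masked pixel and
#' year, then derives what the real-data pipeline would observe: station
#' phenology dates (from the zonal medium-level run at the station),
#' station max-LAI draws from the N(6.5, 1.5^2) prior, county fresh yields
#' (pixel-mean dry grain / (1 - 0.125), with multiplicative noise), the
#' province harvest-index table (mean simulated TWSO/AGB ratio), and
#' satellite-like 8-day LAI stacks (true daily LAI subsampled every 8 days
#' from the zonal emergence, scaled by the low bias, plus noise and optional
#' 3-point smoothing).
#'
#' @param region A [generate_region()] result.
#' @return List with `station_obs`, `station_maxlai`, `county_stats`,
#'   `hi_table`, `lai_obs` (long: pixel, year, date, lai), `pixel_truth`
#'   and `zonal_runs`.
#' @export
simulate_truth_and_observe <- function(region) {
  sc <- region$scenario
  cells <- region$cells
  years <- sc$years

  zonal_runs <- list()
  station_rows <- list()
  for (z in region$stations$id) {
    zc <- as.character(z)
    tz <- region$truth[[zc]]
    for (y in years) {
      em <- region$emergence[[zc]][[as.character(y)]]
      run <- suppressWarnings(run_season(
        region$weather[[zc]], tz$crop$medium, tz$soil, tz$policy,
        emergence_date = em))
      zonal_runs[[paste(zc, y)]] <- run
      station_rows[[paste(zc, y)]] <- data.frame(
        station = z, year = y, emergence = em,
        anthesis = run$anthesis_date, maturity = run$maturity_date)
    }
  }
  station_obs <- do.call(rbind, station_rows)

  station_maxlai <- draw_station_maxlai(sc, region$stations$id, years)

  # per-pixel truth runs
  truth_rows <- list()
  lai_daily <- list()
  masked <- cells[cells$masked, , drop = FALSE]
  for (i in seq_len(nrow(masked))) {
    px <- masked$pixel[i]
    zc <- as.character(masked$zone[i])
    tz <- region$truth[[zc]]
    pp <- region$pixel_pert[region$pixel_pert$pixel == px, ]
    crop <- tz$crop[[masked$level[i]]]
    crop <- set_crop_params(crop, list(
      SPAN = crop$span + pp$span_add,
      TSUM1 = crop$tsum1 * (1 + pp$tsum1_frac)))
    for (y in years) {
      em <- region$emergence[[zc]][[as.character(y)]] + pp$idem_off
      run <- suppressWarnings(run_season(
        region$weather[[zc]], crop, tz$soil, tz$policy,
        emergence_date = em))
      s <- run$series
      truth_rows[[paste(px, y)]] <- data.frame(
        pixel = px, year = y, county = masked$county[i],
        province = masked$zone[i], level = masked$level[i],
        max_lai = max(s$lai), twso = s$twso[nrow(s)],
        agb = s$agb[nrow(s)], idem_off = pp$idem_off,
        span = crop$span, tsum1 = crop$tsum1)
      lai_daily[[paste(px, y)]] <- list(pixel = px, year = y,
                                        dates = s$date, lai = s$lai)
    }
  }
  pixel_truth <- do.call(rbind, truth_rows)

  # county statistics (fresh basis, noisy aggregates of the truth)
  county_stats <- with_seed(substream_seed(sc$seed, "yield"), {
    agg <- stats::aggregate(twso ~ county + province + year,
                            data = pixel_truth, FUN = mean)
    noise <- 1 + stats::rnorm(nrow(agg), 0, sc$yield_noise_sd)
    data.frame(county = agg$county, province = agg$province,
               year = agg$year,
               yield = pmax(1, agg$twso / (1 - 0.125) * noise))
  })

  hi_agg <- stats::aggregate(cbind(twso, agb) ~ province,
                             data = pixel_truth, FUN = mean)
  hi_table <- data.frame(province = hi_agg$province,
                         hi = hi_agg$twso / hi_agg$agb)

  # 8-day satellite-like LAI stacks, anchored at the zonal emergence
  lai_obs <- with_seed(substream_seed(sc$seed, "lai"), {
    rows <- lapply(lai_daily, function(ld) {
      zc <- as.character(cells$zone[cells$pixel == ld$pixel])
      y <- ld$year
      anchor <- region$emergence[[zc]][[as.character(y)]]
      zr <- zonal_runs[[paste(zc, y)]]
      season_days <- nrow(zr$series)
      n_obs <- ceiling(season_days / 8)
      dates <- anchor + 8 * (seq_len(n_obs) - 1)
      v <- sample_series(ld$lai, ld$dates, dates)
      v <- v * sc$lai_bias + stats::rnorm(n_obs, 0, sc$lai_noise_sd)
      if (sc$lai_smooth && n_obs >= 3) v <- smooth_ma3(v)
      data.frame(pixel = ld$pixel, year = y, date = dates,
                 lai = pmax(0, v))
    })
    do.call(rbind, rows)
  })
  rownames(lai_obs) <- NULL

  list(station_obs = station_obs, station_maxlai = station_maxlai,
       county_stats = county_stats, hi_table = hi_table, lai_obs = lai_obs,
       pixel_truth = pixel_truth, zonal_runs = zonal_runs)
}

#' Draw station maximum-LAI observations from the scenario prior
#'
#' The synthetic stand-in for the field max-LAI records whose pooled
#' histogram the calibration summarizes as N(6.5, 1.5^2): one independent
#' normal draw per station and year, deterministic per scenario seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @param station_ids Station identifiers.
#' @param years Observation years.
#' @return data.frame with columns `station`, `year`, `max_lai`.
#' @export
draw_station_maxlai <- function(scenario, station_ids, years) {
  with_seed(substream_seed(scenario$seed, "maxlai"), {
    g <- expand.grid(station = station_ids, year = years)
    g$max_lai <- stats::rnorm(nrow(g), scenario$maxlai_mean,
                              scenario$maxlai_sd)
    g
  })
}

# 3-point moving average with untouched endpoints.
smooth_ma3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  out <- v
  out[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
  out
}

#' Build the calibration zone object of a synthetic region
#'
#' Convenience bridge from the synthetic module to the calibration module:
#' fits the zonal TSUM1/TSUM2 from the synthetic station phenology and
#' assembles the [wheat_zone()] with default (uncalibrated) crop constants
#' as the start point.
#'
#' @param region A [generate_region()] result.
#' @param obs A [simulate_truth_and_observe()] result.
#' @param zone_id Which zone (station id).
#' @return A [wheat_zone()].
#' @export
synthetic_zone <- function(region, obs, zone_id = region$stations$id[1]) {
  zc <- as.character(zone_id)
  ph <- obs$station_obs[obs$station_obs$station == zone_id, , drop = FALSE]
  fit <- fit_phenology_params(ph, region$weather[[zc]])
  crop_start <- set_crop_params(crop_params(),
                                list(TSUM1 = fit$TSUM1, TSUM2 = fit$TSUM2))
  counties <- obs$county_stats[
    obs$county_stats$county %in%
      region$counties$county[region$counties$zone == zone_id], ,
    drop = FALSE]
  wheat_zone(station_id = zone_id, soil = region$truth[[zc]]$soil,
             crop_start = crop_start, weather = region$weather[[zc]],
             emergence_by_year = region$emergence[[zc]],
             counties = counties, hi_table = obs$hi_table,
             years = region$scenario$years)
}
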