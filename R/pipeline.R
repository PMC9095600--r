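#' Map pixels to calibrated yield levels
#'
#' A pixel follows its county's calibrated yield-level group; pixels whose
#' county is absent from the statistics (hence from the grouping) fall back
#' to the zone's medium-level parameters.
#'
#' @param cal A `zone_calibration`.
#' @param cells data.frame with columns `pixel`, `county`.
#' @return Character vector of levels, one per row of `cells`.
#' @export
pixel_levels <- function(cal, cells) {
  g <- cal$grouping$groups
  lv <- rep("medium", nrow(cells))
  for (nm in names(g)) lv[cells$county %in% g[[nm]]] <- nm
  if (!"medium" %in% names(g) && "all" %in% names(g))
    lv[!cells$county %in% unlist(g)] <- "all"
  lv
}

#' Daily AGB series of a season mapped onto a product window
#'
#' Bands before emergence are 0, bands inside the simulated season carry the
#' simulated AGB, and bands after maturity hold the final value (standing
#' biomass until harvest).
#'
#' @param season A `wheat_season`.
#' @param window A [season_window()].
#' @return Numeric vector of length `window$n_bands`.
#' @export
season_to_window <- function(season, window) {
  s <- season$series
  out <- numeric(window$n_bands)
  idx <- as.integer(s$date - window$start) + 1L
  keep <- idx >= 1 & idx <= window$n_bands
  out[idx[keep]] <- s$agb[keep]
  last <- max(idx[keep])
  if (is.finite(last) && last < window$n_bands)
    out[(last + 1):window$n_bands] <- s$agb[nrow(s)]
  out
}

#' Run the full synthetic-study pipeline
#'
#' One call (or the bundled command-line script) drives every stage against
#' a synthetic study region: simulate-synthetic (region, truth and
#' observations), calibrate (zonal three-step fits), assimilate (per-pixel
#' LAI fits, one harvest year at a time), export (270-band daily AGB
#' rasters) and validate (county error reports). All randomness flows from
#' `seed`; outputs are CSV/YAML/TIFF(+JSON) files under `output_dir`.
#'
#' @param config Named list of [synthetic_scenario()] arguments, or a path
#'   to a YAML file of them, or NULL for the defaults.
#' @param seed Root seed (overrides the scenario's).
#' @param output_dir Output directory (created if needed).
#' @param stages Subset of c("simulate-synthetic", "calibrate",
#'   "assimilate", "export", "validate"); later stages imply the earlier
#'   computations in-memory.
#' @param assim_cfg An [assim_config()].
#' @param cal_maxeval Per-step evaluation budget of the zonal calibration.
#' @return Invisibly, a list with the region, observations, calibrations,
#'   assimilation diagnostics and validation reports.
#' @export
run_pipeline <- function(config = NULL, seed = 1, output_dir = "wheatagb_out",
                         stages = c("simulate-synthetic", "calibrate",
                                    "assimilate", "export", "validate"),
                         assim_cfg = assim_config(), cal_maxeval = 800) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  config$seed <- seed
  scenario <- do.call(synthetic_scenario, config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  region <- generate_region(scenario)
  obs <- simulate_truth_and_observe(region)
  out <- list(region = region, obs = obs)
  if ("simulate-synthetic" %in% stages) {
    utils::write.csv(region$cells, file.path(output_dir, "cells.csv"),
                     row.names = FALSE)
    utils::write.csv(region$stations, file.path(output_dir, "stations.csv"),
                     row.names = FALSE)
    utils::write.csv(obs$county_stats,
                     file.path(output_dir, "county_yields.csv"),
                     row.names = FALSE)
    utils::write.csv(obs$hi_table,
                     file.path(output_dir, "harvest_index.csv"),
                     row.names = FALSE)
    utils::write.csv(obs$lai_obs, file.path(output_dir, "lai_obs.csv"),
                     row.names = FALSE)
    utils::write.csv(obs$station_obs,
                     file.path(output_dir, "station_phenology.csv"),
                     row.names = FALSE)
    for (z in names(region$weather))
      utils::write.csv(region$weather[[z]],
                       file.path(output_dir, paste0("weather_zone", z,
                                                    ".csv")),
                       row.names = FALSE)
  }
  if (!any(c("calibrate", "assimilate", "export", "validate") %in% stages))
    return(invisible(out))

  cals <- lapply(region$stations$id, function(z) {
    cal <- three_step_calibration(synthetic_zone(region, obs, z),
                                  maxeval = cal_maxeval)
    write_zone_calibration(cal, file.path(output_dir,
                                          paste0("calibration_zone", z,
                                                 ".yaml")))
    cal
  })
  names(cals) <- as.character(region$stations$id)
  out$calibrations <- cals
  if (!any(c("assimilate", "export", "validate") %in% stages))
    return(invisible(out))

  years <- scenario$years
  cells <- region$cells
  assim <- list()
  for (y in years) {
    zone_params <- lapply(names(cals), function(zc) {
      cal <- cals[[zc]]
      list(crop = lapply(cal$levels, function(l) l$crop),
           policy = lapply(cal$levels, function(l)
             l$policies[[as.character(y)]]),
           soil = region$truth[[zc]]$soil,
           weather = region$weather[[zc]],
           emergence = region$emergence[[zc]][[as.character(y)]])
    })
    names(zone_params) <- names(cals)
    px <- cells[, c("pixel", "zone", "masked")]
    px$level <- NA_character_
    for (zc in names(cals))
      px$level[px$zone == as.integer(zc)] <-
        pixel_levels(cals[[zc]], cells[px$zone == as.integer(zc), ])
    lo <- obs$lai_obs[obs$lai_obs$year == y, , drop = FALSE]
    assim[[as.character(y)]] <- assimilate_grid(px, lo, zone_params,
                                                assim_cfg)
    utils::write.csv(assim[[as.character(y)]]$diagnostics,
                     file.path(output_dir,
                               paste0("assimilation_", y, ".csv")),
                     row.names = FALSE)
  }
  out$assimilation <- assim
  if (!any(c("export", "validate") %in% stages)) return(invisible(out))

  nr <- scenario$grid_dim[1]; nc <- scenario$grid_dim[2]
  reports <- list()
  for (y in years) {
    win <- season_window(y)
    arr <- array(NA_real_, c(nr, nc, win$n_bands))
    res <- assim[[as.character(y)]]$results
    agb_max <- numeric(0)
    for (px in names(res)) {
      r <- res[[px]]
      if (is.null(r$season)) next
      cell <- cells[cells$pixel == as.integer(px), ]
      arr[cell$row, cell$col, ] <- season_to_window(r$season, win)
      agb_max[px] <- max(r$season$series$agb)
    }
    if ("export" %in% stages)
      write_agb_stack(arr, win,
                      file.path(output_dir,
                                sprintf("synthetic_wheat_AGB_%d.tif", y)),
                      geo = list(origin_x = 0, origin_y = 0,
                                 cell_size = 0.01, crs = "EPSG:4326"))
    if ("validate" %in% stages && length(agb_max) >= 2) {
      pa <- data.frame(pixel = as.integer(names(agb_max)), agb = agb_max)
      reports[[as.character(y)]] <- county_error_map(
        pa, cells, obs$county_stats[obs$county_stats$year == y, ],
        obs$hi_table)
      utils::write.csv(as.data.frame(reports[[as.character(y)]]),
                       file.path(output_dir,
                                 paste0("county_errors_", y, ".csv")),
                       row.names = FALSE)
    }
  }
  out$validation <- reports
  invisible(out)
}
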