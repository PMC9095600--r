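#' Simulate one winter-wheat season
#'
#' Runs the reduced-form daily crop simulator from emergence to maturity
#' (DVS = 2) or until the weather series ends. The daily update order is
#' phenology, soil water balance, growth, leaf senescence. Aboveground
#' biomass (AGB) counts living and dead leaves, stems and storage organs;
#' roots are excluded. Initial organ masses split `TDWI` by the partitioning
#' fractions at DVS = 0 and the initial LAI is SLA times the initial leaf
#' mass; soil moisture starts at field capacity unless `sm_init` is given.
#'
#' @param weather Daily weather data.frame (see [read_weather()]) covering at
#'   least the emergence date.
#' @param crop A [crop_params()] object.
#' @param soil A [soil_params()] object.
#' @param policy An [irrigation_policy()]; the default is rainfed.
#' @param emergence_date Emergence date (`Date` or ISO string); defaults to
#'   the first weather day.
#' @param sm_init Initial volumetric soil moisture.
#' @return An object of class `wheat_season`: a list with `series` (one row
#'   per simulated day: date, dvs, tsum, lai, agb, twso, sm, irrigation,
#'   stress, organ pools), `anthesis_date`, `maturity_date`, `truncated`
#'   (TRUE if weather ended before maturity) and the inputs.
#' @export
run_season <- function(weather, crop, soil,
                       policy = irrigation_policy(enabled = FALSE),
                       emergence_date = weather$date[1],
                       sm_init = soil$sm_fc) {
  stopifnot(inherits(crop, "crop_params"), inherits(soil, "soil_params"),
            inherits(policy, "irrigation_policy"))
  validate_weather(weather)
  emergence_date <- as.Date(emergence_date)
  i0 <- match(emergence_date, weather$date)
  if (is.na(i0))
    stop("emergence_date not covered by the weather series", call. = FALSE)
  w <- weather[seq.int(i0, nrow(weather)), , drop = FALSE]
  out <- season_core(weather_matrix(w), crop, soil, policy, sm_init)
  n <- length(out$dvs)
  series <- data.frame(
    date = emergence_date + seq_len(n) - 1L,
    dvs = out$dvs, tsum = out$tsum, lai = out$lai, agb = out$agb,
    twso = out$twso, sm = out$sm, irrigation = out$irrigation,
    stress = out$stress, leaf_living = out$leaf_living,
    leaf_dead = out$leaf_dead, stem = out$stem, root = out$root)
  res <- structure(list(
    series = series,
    anthesis_date = if (is.na(out$anthesis_day)) as.Date(NA)
      else emergence_date + out$anthesis_day - 1L,
    maturity_date = if (is.na(out$maturity_day)) as.Date(NA)
      else emergence_date + out$maturity_day - 1L,
    truncated = isTRUE(out$truncated),
    emergence_date = emergence_date,
    crop = crop, soil = soil, policy = policy), class = "wheat_season")
  if (res$truncated)
    warning("weather series ended before crop maturity (truncated season)",
            call. = FALSE)
  res
}

# Thin wrapper around the compiled daily loop; used directly (with
# pre-built weather matrices) inside optimization loops.
season_core <- function(wm, crop, soil, policy, sm_init) {
  cpp_run_season(wm, unclass(crop), unclass(soil), unclass(policy), sm_init)
}

#' @export
print.wheat_season <- function(x, ...) {
  s <- x$series
  n <- nrow(s)
  cat("Winter-wheat season simulation\n")
  cat(sprintf("  emergence  %s\n", format(x$emergence_date)))
  cat(sprintf("  anthesis   %s\n", format(x$anthesis_date)))
  cat(sprintf("  maturity   %s%s\n", format(x$maturity_date),
              if (x$truncated) "  (truncated: weather ended first)" else ""))
  cat(sprintf("  %d simulated days; max LAI %.2f; final AGB %.0f kg/ha; final yield (TWSO) %.0f kg/ha\n",
              n, max(s$lai), s$agb[n], s$twso[n]))
  if (any(s$irrigation > 0))
    cat(sprintf("  %d irrigation events, %.1f cm applied in total\n",
                sum(s$irrigation > 0), sum(s$irrigation)))
  invisible(x)
}

#' @export
summary.wheat_season <- function(object, ...) {
  s <- object$series
  n <- nrow(s)
  out <- list(
    emergence_date = object$emergence_date,
    anthesis_date = object$anthesis_date,
    maturity_date = object$maturity_date,
    truncated = object$truncated,
    n_days = n,
    max_lai = max(s$lai),
    final_agb = s$agb[n],
    final_twso = s$twso[n],
    harvest_index = if (s$agb[n] > 0) s$twso[n] / s$agb[n] else NA_real_,
    total_irrigation_cm = sum(s$irrigation),
    n_irrigation_events = sum(s$irrigation > 0))
  class(out) <- "summary.wheat_season"
  out
}

#' @export
print.summary.wheat_season <- function(x, ...) {
  cat("Season summary\n")
  cat(sprintf("  emergence %s, anthesis %s, maturity %s (%d days)%s\n",
              format(x$emergence_date), format(x$anthesis_date),
              format(x$maturity_date), x$n_days,
              if (x$truncated) " [truncated]" else ""))
  cat(sprintf("  max LAI %.2f; final AGB %.0f kg/ha; yield %.0f kg/ha; HI %.3f\n",
              x$max_lai, x$final_agb, x$final_twso, x$harvest_index))
  cat(sprintf("  irrigation: %d events, %.1f cm\n",
              x$n_irrigation_events, x$total_irrigation_cm))
  invisible(x)
}

#' @export
as.data.frame.wheat_season <- function(x, ...) x$series

#' Plot a simulated season
#'
#' Draws the LAI, biomass (AGB and storage organs) and soil-moisture
#' trajectories against date.
#'
#' @param x A `wheat_season` object.
#' @param ... Passed on to the base plotting calls.
#' @export
plot.wheat_season <- function(x, ...) {
  s <- x$series
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(s$date, s$lai, type = "l", xlab = "", ylab = "LAI", ...)
  graphics::plot(s$date, s$agb, type = "l", xlab = "",
                 ylab = "biomass (kg/ha)", ...)
  graphics::lines(s$date, s$twso, lty = 2)
  graphics::legend("topleft", c("AGB", "TWSO"), lty = c(1, 2), bty = "n")
  graphics::plot(s$date, s$sm, type = "l", xlab = "",
                 ylab = "soil moisture", ...)
  graphics::abline(h = c(x$soil$sm_wilt, x$soil$sm_fc), lty = 3)
  invisible(x)
}
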