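#' Read a daily weather series from CSV
#'
#' The file must carry the header columns `date` (ISO-8601), `radiation`
#' (MJ/m2/d shortwave), `tmin`, `tmax` (degC), `vap` (hPa), `wind` (m/s) and
#' `precip` (mm/d).
#'
#' @param path Path to the CSV file.
#' @return A validated weather data.frame (one row per day).
#' @export
read_weather <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "radiation", "tmin", "tmax", "vap", "wind", "precip")
  miss <- setdiff(need, names(w))
  if (length(miss))
    stop("weather file misses column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  w$date <- as.Date(w$date)
  validate_weather(w)
}

#' Validate a daily weather series
#'
#' Checks the physical invariants (tmin <= tmax, non-negative radiation and
#' precipitation, finite values, consecutive dates) and returns the frame.
#'
#' @param w Weather data.frame as produced by [read_weather()] or
#'   [generate_weather()].
#' @return The validated data.frame, invisibly unchanged.
#' @export
validate_weather <- function(w) {
  num <- c("radiation", "tmin", "tmax", "precip")
  for (nm in num)
    if (!all(is.finite(w[[nm]])))
      stop("invalid weather: non-finite values in '", nm, "'", call. = FALSE)
  if (any(w$tmin > w$tmax))
    stop("invalid weather: tmin > tmax", call. = FALSE)
  if (any(w$radiation < 0) || any(w$precip < 0))
    stop("invalid weather: negative radiation or precipitation",
         call. = FALSE)
  if (nrow(w) > 1 && any(diff(as.integer(w$date)) != 1))
    stop("invalid weather: dates must be consecutive days", call. = FALSE)
  w
}

#' Reference evapotranspiration from radiation and temperature
#'
#' A radiation-based (Makkink-style) reference ET: 0.65 x (radiation / 2.45)
#' x f(Tmean) mm/d, with f(T) = clamp(0.42 + 0.013 T, 0, 1) a mild linear
#' temperature factor standing in for the slope term of the saturation
#' vapour-pressure curve. Only the relative soil-moisture dynamics matter for
#' irrigation calibration, so this deliberately simple form is used.
#'
#' @param radiation Shortwave radiation (MJ/m2/d).
#' @param tmean Daily mean air temperature (degC).
#' @return Reference ET (mm/d), vectorized.
#' @export
et0_reference <- function(radiation, tmean) {
  f <- pmin(1, pmax(0, 0.42 + 0.013 * tmean))
  0.65 * (radiation / 2.45) * f
}

# Convert a weather data.frame to the matrix layout the C++ core expects.
weather_matrix <- function(w) {
  tmean <- 0.5 * (w$tmin + w$tmax)
  cbind(radiation = w$radiation, tmin = w$tmin, tmax = w$tmax,
        precip = w$precip, et0 = et0_reference(w$radiation, tmean))
}
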