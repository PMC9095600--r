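#' Harvest-year product window
#'
#' The daily product of one harvest year spans the last 90 days of the
#' previous calendar year and the first 180 days of the harvest year:
#' exactly 270 daily bands. The window is defined by day counts, so leap
#' years shift the calendar endpoints (e.g. 2006-10-03..2007-06-29 but
#' 2011-10-03..2012-06-28) while the band count never changes.
#'
#' @param harvest_year The harvest (product) year.
#' @return List of class `season_window` with `harvest_year`, `start`,
#'   `end`, `dates` (length 270) and `n_bands`.
#' @export
season_window <- function(harvest_year) {
  start <- as.Date(paste0(harvest_year - 1, "-12-31")) - 89L
  end <- as.Date(paste0(harvest_year, "-01-01")) + 179L
  dates <- seq(start, end, by = "day")
  stopifnot(length(dates) == 270L)
  structure(list(harvest_year = harvest_year, start = start, end = end,
                 dates = dates, n_bands = 270L), class = "season_window")
}

#' @export
print.season_window <- function(x, ...) {
  cat(sprintf("Harvest-year %d window: %s .. %s (%d daily bands)\n",
              x$harvest_year, format(x$start), format(x$end), x$n_bands))
  invisible(x)
}

#' Write a 270-band daily AGB raster stack
#'
#' Writes one harvest-year product: a multiband TIFF (32-bit samples, one
#' band per day of the [season_window()]) in kg/ha, with a JSON sidecar
#' (`<path>.json`) carrying the georeferencing (origin, cell size, CRS),
#' the band-to-date mapping, the no-data convention and the linear value
#' scaling used to pack values into the TIFF's unit sample range. Masked-out
#' pixels (NA) are stored as the no-data code and read back as NA.
#'
#' @param x 3-D array `[rows, cols, 270]` of AGB (kg/ha), NA = no data.
#' @param window A [season_window()].
#' @param path Output TIFF path.
#' @param geo List with `origin_x`, `origin_y`, `cell_size` (degrees) and
#'   `crs`.
#' @param vmax Upper value of the packed range (kg/ha).
#' @return `path`, invisibly.
#' @export
write_agb_stack <- function(x, window, path,
                            geo = list(origin_x = 0, origin_y = 0,
                                       cell_size = 0.01,
                                       crs = "EPSG:4326"),
                            vmax = 50000) {
  if (length(dim(x)) != 3 || dim(x)[3] != window$n_bands)
    stop("format error: stack must have exactly ", window$n_bands,
         " daily bands", call. = FALSE)
  if (is.null(geo$cell_size))
    stop("format error: missing georeferencing", call. = FALSE)
  fin <- x[is.finite(x)]
  if (length(fin) && (min(fin) < 0 || max(fin) > vmax))
    stop("AGB values outside [0, vmax]", call. = FALSE)
  pack <- 0.5  # data packed into [0, 0.5]; 1.0 is the no-data code
  frames <- lapply(seq_len(window$n_bands), function(b) {
    m <- x[, , b] / vmax * pack
    m[!is.finite(m)] <- 1
    m
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  meta <- list(product = "winter_wheat_daily_agb", units = "kg/ha",
               harvest_year = window$harvest_year,
               band_dates = format(window$dates), n_bands = window$n_bands,
               nrow = dim(x)[1], ncol = dim(x)[2],
               origin_x = geo$origin_x, origin_y = geo$origin_y,
               cell_size = geo$cell_size, crs = geo$crs,
               nodata_code = 1.0, value_scale = vmax / pack)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a daily AGB raster stack
#'
#' Inverse of [write_agb_stack()]; restores the kg/ha values, NA at no-data
#' pixels, and the window/georeferencing metadata.
#'
#' @param path TIFF path written by [write_agb_stack()].
#' @return List with `agb` (3-D array), `window`, `geo` and `meta`.
#' @export
read_agb_stack <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("format error: missing georeferencing sidecar ", side,
         call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (length(frames) != meta$n_bands)
    stop("format error: expected ", meta$n_bands, " bands, found ",
         length(frames), call. = FALSE)
  x <- array(NA_real_, c(meta$nrow, meta$ncol, meta$n_bands))
  for (b in seq_along(frames)) {
    m <- frames[[b]]
    m[m >= 0.999] <- NA
    x[, , b] <- m * meta$value_scale
  }
  win <- season_window(meta$harvest_year)
  list(agb = x, window = win,
       geo = meta[c("origin_x", "origin_y", "cell_size", "crs")],
       meta = meta)
}

#' Validation metrics: R2, RMSE and MAPE
#'
#' R2 uses the 1 - SS_res/SS_tot definition, RMSE the root mean squared
#' error, and MAPE the mean absolute percentage error (so observations must
#' be nonzero).
#'
#' @param pred,obs Equal-length numeric vectors (length >= 2).
#' @return List with `r2`, `rmse` (same units as the inputs) and `mape`
#'   (percent).
#' @export
validation_metrics <- function(pred, obs) {
  if (length(pred) != length(obs) || length(obs) < 2)
    stop("pred and obs must have equal length >= 2", call. = FALSE)
  if (any(obs == 0))
    stop("metric error: zero observation makes MAPE undefined",
         call. = FALSE)
  res <- pred - obs
  list(r2 = 1 - sum(res^2) / sum((obs - mean(obs))^2),
       rmse = sqrt(mean(res^2)),
       mape = mean(abs(res) / abs(obs)) * 100)
}

#' County-level error report against yield statistics
#'
#' Compares the per-county mean simulated maximum AGB with the
#' statistics-derived AGB (fresh yield -> dry matter -> / harvest index) and
#' flags counties whose error magnitude strictly exceeds the threshold
#' (default 2000 kg/ha). Counties with no masked pixels are excluded.
#'
#' @param pixel_agb data.frame with columns `pixel`, `agb` (max simulated
#'   AGB, kg/ha).
#' @param cells data.frame with columns `pixel`, `county`; only pixels
#'   present in `pixel_agb` count.
#' @param county_stats data.frame with columns `county`, `province`,
#'   `yield` (fresh kg/ha; multiple years are averaged).
#' @param hi_table data.frame with columns `province`, `hi`.
#' @param threshold Flagging threshold (kg/ha, strict inequality).
#' @return Object of class `county_error_report`: a data.frame (county,
#'   n_pixels, sim_agb, stat_agb, error, flagged) with the
#'   [validation_metrics()] attached as attribute `metrics`.
#' @export
county_error_map <- function(pixel_agb, cells, county_stats, hi_table,
                             threshold = 2000) {
  m <- merge(pixel_agb, cells[, c("pixel", "county")], by = "pixel")
  sim <- stats::aggregate(agb ~ county, data = m, FUN = mean)
  names(sim) <- c("county", "sim_agb")
  np <- stats::aggregate(pixel ~ county, data = m, FUN = length)
  names(np) <- c("county", "n_pixels")
  st <- stats::aggregate(yield ~ county + province, data = county_stats,
                         FUN = mean, na.rm = TRUE)
  st$hi <- hi_table$hi[match(st$province, hi_table$province)]
  st$stat_agb <- agb_from_yield(yield_to_dry_matter(st$yield), st$hi)
  rep <- merge(merge(sim, np, by = "county"),
               st[, c("county", "stat_agb")], by = "county")
  rep$error <- rep$sim_agb - rep$stat_agb
  rep$flagged <- abs(rep$error) > threshold
  metrics <- if (nrow(rep) >= 2)
    validation_metrics(rep$sim_agb, rep$stat_agb) else NULL
  structure(rep, metrics = metrics, threshold = threshold,
            class = c("county_error_report", "data.frame"))
}

#' @export
print.county_error_report <- function(x, ...) {
  cat(sprintf("County error report: %d counties, %d flagged (|error| > %.0f kg/ha)\n",
              nrow(x), sum(x$flagged), attr(x, "threshold")))
  m <- attr(x, "metrics")
  if (!is.null(m))
    cat(sprintf("  R2 %.3f; RMSE %.0f kg/ha; MAPE %.1f%%\n",
                m$r2, m$rmse, m$mape))
  NextMethod()
}
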