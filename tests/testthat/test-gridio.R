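test_that("the harvest-year window spans 90 + 180 days in every calendar", {
  w07 <- season_window(2007)
  expect_equal(w07$start, as.Date("2006-10-03"))
  expect_equal(w07$end, as.Date("2007-06-29"))
  expect_equal(w07$n_bands, 270L)
  expect_equal(length(w07$dates), 270L)
  # leap harvest year ends a calendar day earlier, never changes the count
  w12 <- season_window(2012)
  expect_equal(w12$start, as.Date("2011-10-03"))
  expect_equal(w12$end, as.Date("2012-06-28"))
  expect_equal(w12$n_bands, 270L)
  # leap previous year still starts Oct 3 (90 days before its end)
  expect_equal(season_window(2009)$start, as.Date("2008-10-03"))
  # band of Jan 1 of the harvest year is 91 (90 previous-year bands first)
  expect_equal(match(as.Date("2007-01-01"), w07$dates), 91L)
  # the band->date mapping is bijective over the window
  expect_equal(anyDuplicated(w07$dates), 0L)
})

test_that("AGB stacks round-trip through the raster writer", {
  set.seed(31)
  win <- season_window(2007)
  x <- array(runif(10 * 10 * 270, 0, 20000), c(10, 10, 270))
  x[1, 1, ] <- NA  # masked-out pixel
  x[4, 7, ] <- NA
  path <- file.path(tempdir(), "agb_2007.tif")
  write_agb_stack(x, win, path)
  back <- read_agb_stack(path)
  expect_equal(dim(back$agb), dim(x))
  expect_true(all(is.na(back$agb[1, 1, ])))
  expect_true(all(is.na(back$agb[4, 7, ])))
  expect_equal(back$agb[!is.na(x)], x[!is.na(x)], tolerance = 1e-6)
  expect_equal(back$window$harvest_year, 2007)
  expect_equal(back$meta$n_bands, 270L)
  expect_equal(back$geo$cell_size, 0.01)
  unlink(c(path, paste0(path, ".json")))
})

test_that("the raster writer enforces the band count and georeferencing", {
  win <- season_window(2007)
  bad <- array(0, c(4, 4, 100))
  expect_error(write_agb_stack(bad, win, tempfile()), "270")
  ok <- array(0, c(4, 4, 270))
  expect_error(write_agb_stack(ok, win, tempfile(),
                               geo = list(origin_x = 0, origin_y = 0,
                                          cell_size = NULL, crs = "x")),
               "georeferencing")
  # reading without the sidecar is a format error
  p <- file.path(tempdir(), "solo.tif")
  write_agb_stack(ok, win, p)
  unlink(paste0(p, ".json"))
  expect_error(read_agb_stack(p), "sidecar")
  unlink(p)
})

test_that("validation metrics match their definitions and an oracle", {
  m <- validation_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$r2, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$mape, 0)
  m2 <- validation_metrics(c(110, 90), c(100, 100))
  expect_equal(m2$rmse, 10)
  expect_equal(m2$mape, 10)
  expect_error(validation_metrics(1:3, c(1, 0, 2)), "zero")
  expect_error(validation_metrics(1:3, 1:2), "equal length")
  set.seed(32)
  for (k in 1:100) {
    n <- sample(5:60, 1)
    obs <- runif(n, 50, 150)
    pred <- obs + rnorm(n, 0, 20)
    m <- validation_metrics(pred, obs)
    o <- oracle_metrics(pred, obs)
    expect_equal(m$r2, unname(o["r2"]), tolerance = 1e-10)
    expect_equal(m$rmse, unname(o["rmse"]), tolerance = 1e-10)
    expect_equal(m$mape, unname(o["mape"]), tolerance = 1e-10)
  }
})

test_that("county error maps flag only strict threshold exceedances", {
  cells <- data.frame(pixel = 1:6, county = rep(1:3, each = 2))
  hi <- data.frame(province = 1, hi = 0.5)
  # choose fresh yields so the statistics-derived AGB is exactly sim - err
  sim <- c(10000, 12000, 9000)
  err <- c(2000, -2500, 0)
  stat_agb <- sim - err
  yield <- stat_agb * hi$hi / 0.875
  stats <- data.frame(county = 1:3, province = 1, yield = yield)
  pa <- data.frame(pixel = 1:6, agb = rep(sim, each = 2))
  rep <- county_error_map(pa, cells, stats, hi)
  expect_equal(rep$error, err, tolerance = 1e-9)
  expect_equal(rep$flagged, c(FALSE, TRUE, FALSE))  # 2000 is not flagged
  expect_equal(rep$n_pixels, c(2, 2, 2))
  # brute-force recount
  for (i in 1:3) {
    expect_equal(rep$sim_agb[i], mean(pa$agb[cells$county == i]))
  }
  m <- attr(rep, "metrics")
  expect_equal(m$rmse, sqrt(mean(err^2)), tolerance = 1e-9)
})

test_that("biomass conversions apply the root-shoot and NPP coefficients", {
  b <- biomass_conversions(10000, 0)
  expect_equal(b$total_biomass, 10000)
  expect_equal(b$npp, 4500)
  expect_equal(biomass_conversions(8000, 0.25)$total_biomass, 10000)
  expect_equal(biomass_conversions(0, 0.3)$npp, 0)
  expect_error(biomass_conversions(-1, 0), ">= 0")
})

test_that("season series map onto product windows with hold-after-maturity", {
  w <- const_weather(250, tmean = 10, start = "2006-10-03")
  s <- run_season(w, crop_params(), soil_params(),
                  emergence_date = as.Date("2006-10-10"))
  win <- season_window(2007)
  v <- season_to_window(s, win)
  expect_equal(length(v), 270)
  expect_equal(v[1:7], rep(0, 7))  # window starts before emergence
  n <- nrow(s$series)
  final <- s$series$agb[n]
  expect_equal(v[270], final)      # held at the final value
  idx <- match(s$series$date[10], win$dates)
  expect_equal(v[idx], s$series$agb[10])
})
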