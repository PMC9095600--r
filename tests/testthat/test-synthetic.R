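test_that("synthetic weather is deterministic and physically consistent", {
  a <- generate_weather(101, "2006-09-01", 400)
  b <- generate_weather(101, "2006-09-01", 400)
  expect_identical(a, b)
  expect_true(all(a$tmin <= a$tmax))
  expect_true(all(a$radiation >= 0))
  expect_true(all(a$precip >= 0))
  expect_silent(validate_weather(a))
  # different seed, different draws
  expect_false(identical(a$precip,
                         generate_weather(102, "2006-09-01", 400)$precip))
})

test_that("zero temperature noise reproduces the seasonal sinusoid exactly", {
  prof <- climate_profile(temp_noise_sd = 0)
  w <- generate_weather(7, "2007-01-01", 365, prof)
  doy <- as.integer(format(w$date, "%j"))
  expected <- prof$tmean_annual + prof$tmean_amplitude *
    cos(2 * pi * (doy - prof$tmean_peak_doy) / 365.25)
  expect_equal(0.5 * (w$tmin + w$tmax), expected, tolerance = 1e-12)
})

test_that("the synthetic region is deterministic and Thiessen-consistent", {
  sc <- synthetic_scenario(seed = 42, grid_dim = c(6, 6), n_stations = 4,
                           counties_per_zone = 3, years = 2007)
  r1 <- generate_region(sc)
  r2 <- generate_region(sc)
  expect_identical(r1$cells, r2$cells)
  expect_identical(r1$stations, r2$stations)
  # cross-module check: the zone labels are the Thiessen assignment
  expect_equal(r1$cells$zone,
               build_thiessen_zones(r1$stations,
                                    r1$cells[, c("x", "y")]))
  expect_equal(r1$cells$zone, oracle_nearest(r1$stations, r1$cells))
  # every cell belongs to exactly one county of its own zone
  expect_true(all(!is.na(r1$cells$county)))
  cz <- r1$counties$zone[match(r1$cells$county, r1$counties$county)]
  expect_equal(cz, r1$cells$zone)
  # mask fraction limits
  sc0 <- synthetic_scenario(seed = 42, grid_dim = c(4, 4),
                            mask_fraction = 0, counties_per_zone = 1)
  expect_false(any(generate_region(sc0)$cells$masked))
  sc1 <- synthetic_scenario(seed = 42, grid_dim = c(4, 4),
                            mask_fraction = 1, counties_per_zone = 1)
  expect_true(all(generate_region(sc1)$cells$masked))
})

test_that("satellite-like stacks follow the 8-day cadence", {
  sc <- synthetic_scenario(seed = 9, grid_dim = c(2, 2), n_stations = 1,
                           counties_per_zone = 1, years = 2007:2008)
  reg <- generate_region(sc)
  obs <- simulate_truth_and_observe(reg)
  for (y in sc$years) {
    season_days <- nrow(obs$zonal_runs[[paste("1", y)]]$series)
    n_obs <- ceiling(season_days / 8)
    per_pixel <- table(obs$lai_obs$pixel[obs$lai_obs$year == y])
    expect_true(all(per_pixel == n_obs))
    d <- obs$lai_obs$date[obs$lai_obs$year == y &
                            obs$lai_obs$pixel == reg$cells$pixel[1]]
    expect_true(all(diff(as.integer(d)) == 8))
  }
  expect_true(all(obs$lai_obs$lai >= 0))
})

test_that("an exact 8-day subsample is returned when bias and noise are off", {
  sc <- synthetic_scenario(seed = 10, grid_dim = c(2, 2), n_stations = 1,
                           counties_per_zone = 1, years = 2007,
                           lai_bias = 1, lai_noise_sd = 0,
                           lai_smooth = FALSE,
                           level_eps = c(high = 1, medium = 1, low = 1),
                           pixel_idem_range = c(0, 0),
                           pixel_span_range = c(0, 0),
                           pixel_tsum1_frac = c(0, 0))
  reg <- generate_region(sc)
  obs <- simulate_truth_and_observe(reg)
  px <- reg$cells$pixel[reg$cells$masked][1]
  got <- obs$lai_obs[obs$lai_obs$pixel == px, ]
  zr <- obs$zonal_runs[["1 2007"]]
  expect_equal(got$lai,
               wheatagb:::sample_series(zr$series$lai, zr$series$date,
                                        got$date),
               tolerance = 1e-12)
})

test_that("the noise-free conversion chain round-trips county statistics", {
  # one county, homogeneous pixels: the province harvest index equals the
  # simulated TWSO/AGB ratio, so fresh yield x 0.875 / HI recovers AGB
  sc <- synthetic_scenario(seed = 14, grid_dim = c(3, 3), n_stations = 1,
                           counties_per_zone = 1, years = 2007,
                           yield_noise_sd = 0,
                           pixel_idem_range = c(0, 0),
                           pixel_span_range = c(0, 0),
                           pixel_tsum1_frac = c(0, 0))
  reg <- generate_region(sc)
  obs <- simulate_truth_and_observe(reg)
  stats_agb <- agb_from_yield(yield_to_dry_matter(obs$county_stats$yield),
                              obs$hi_table$hi[1])
  sim_agb <- mean(obs$pixel_truth$agb)
  expect_equal(stats_agb, sim_agb, tolerance = 1e-6)
})

test_that("station max-LAI draws follow the configured prior", {
  sc <- synthetic_scenario(seed = 77)
  draws <- draw_station_maxlai(sc, seq_len(25), 2001:2020)  # 500 draws
  expect_equal(nrow(draws), 500)
  expect_lt(abs(mean(draws$max_lai) - sc$maxlai_mean), 0.2)
  expect_lt(abs(sd(draws$max_lai) - sc$maxlai_sd), 0.3)
  expect_identical(draws, draw_station_maxlai(sc, seq_len(25), 2001:2020))
})
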