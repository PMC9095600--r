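test_that("unit conversions follow the stated constants", {
  expect_equal(gravimetric_to_volumetric(0.20, 1.4), 0.28)
  expect_equal(gravimetric_to_volumetric(0.20, 1.0), 0.20)
  expect_error(gravimetric_to_volumetric(0.8, 1.5), "inconsistent")
  expect_error(gravimetric_to_volumetric(0, 1.2), "theta_g")

  expect_equal(anthesis_from_heading(as.Date("2010-04-20")),
               as.Date("2010-04-27"))
  expect_equal(anthesis_from_heading(as.Date("2007-12-28")),
               as.Date("2008-01-04"))
  expect_equal(anthesis_from_heading(as.Date("2008-02-25")),
               as.Date("2008-03-03"))  # leap February

  expect_equal(yield_to_dry_matter(8000), 7000)
  expect_equal(yield_to_dry_matter(0), 0)
  expect_equal(yield_to_dry_matter(1000), 875)

  expect_equal(agb_from_yield(7000, 0.5), 14000)
  expect_equal(agb_from_yield(7000, 1), 7000)
  expect_error(agb_from_yield(7000, 0), "harvest index")
})

test_that("the Gaussian log-likelihood matches the analytic identity cases", {
  sp <- likelihood_spec(c(1, 2, 3), c(1, 2, 3), rep(1, 3))
  expect_equal(log_likelihood_term(sp), -1.5 * log(2 * pi),
               tolerance = 1e-12)
  sp1 <- likelihood_spec(c(2, 3, 4), c(1, 2, 3), rep(1, 3))
  expect_equal(log_likelihood_term(sp1), -1.5 * log(2 * pi) - 1.5,
               tolerance = 1e-12)
  # monotone decrease with distance under fixed diagonal covariance
  lls <- sapply(c(0, 0.5, 1, 2, 4), function(a)
    log_likelihood_term(likelihood_spec(c(1, 2, 3) + a, c(1, 2, 3),
                                        c(2, 3, 4))))
  expect_true(all(diff(lls) < 0))
  expect_error(log_likelihood_term(
    likelihood_spec(1:2, 1:2, matrix(c(1, 1, 1, 1), 2))), "positive definite")
})

test_that("log-likelihood agrees with a dense-matrix oracle on random SPD cases", {
  set.seed(11)
  for (k in 1:50) {
    d <- sample(2:5, 1)
    S <- random_spd(d)
    x <- rnorm(d, 5)
    mu <- rnorm(d, 5)
    expect_equal(log_likelihood_term(likelihood_spec(x, mu, S)),
                 oracle_loglik(x, mu, S), tolerance = 1e-10)
  }
})

test_that("the combined likelihood sums its three terms and checks d", {
  sp <- likelihood_spec(c(1, 2, 3), c(1, 2, 3), rep(1, 3))
  expect_equal(total_log_likelihood(sp, sp, sp), -4.5 * log(2 * pi),
               tolerance = 1e-12)
  sp2 <- likelihood_spec(c(1, 2), c(1, 2), rep(1, 2))
  expect_error(total_log_likelihood(sp, sp, sp2), "share d")
})

test_that("county grouping follows the descending-quantile convention", {
  counties <- data.frame(county = 1:9, mean_yield = 9:1 * 1000)
  g <- group_counties_by_yield(counties)
  expect_equal(unname(g$representatives), c(2, 5, 8))
  expect_equal(counties$mean_yield[match(g$representatives,
                                         counties$county)],
               c(8000, 5000, 2000))
  expect_equal(lengths(g$groups), c(high = 3, medium = 3, low = 3))
  expect_false(g$fallback)
  # three counties: each is its own group's representative
  g3 <- group_counties_by_yield(data.frame(county = c(7, 8, 9),
                                           mean_yield = c(5, 9, 2) * 1000))
  expect_equal(unname(g3$representatives), c(8, 7, 9))
  expect_equal(unname(lengths(g3$groups)), c(1, 1, 1))
  # fewer than three: single-group fallback on the median county
  # median position round(0.5 (n-1)) half-up on the descending list
  g1 <- group_counties_by_yield(data.frame(county = 1:2,
                                           mean_yield = c(4, 6) * 1000))
  expect_true(g1$fallback)
  expect_equal(unname(g1$representatives), 1)
})

test_that("county grouping matches a brute-force re-sort on random instances", {
  set.seed(12)
  for (k in 1:50) {
    n <- sample(3:40, 1)
    counties <- data.frame(county = sample(1000, n),
                           mean_yield = round(runif(n, 2000, 9000)))
    g <- group_counties_by_yield(counties)
    o <- oracle_grouping(counties)
    expect_equal(unname(g$representatives), o$reps)
    expect_equal(g$groups$high, o$high)
    expect_equal(g$groups$medium, o$medium)
    expect_equal(g$groups$low, o$low)
  }
})

test_that("Thiessen assignment is nearest-station with lowest-id tie-break", {
  st <- data.frame(id = 1:2, x = c(0, 10), y = c(0, 0))
  expect_equal(build_thiessen_zones(st, data.frame(x = 2, y = 0)), 1)
  expect_equal(build_thiessen_zones(st, data.frame(x = 5, y = 0)), 1)
  expect_equal(build_thiessen_zones(st, data.frame(x = 7, y = 0)), 2)
  expect_error(build_thiessen_zones(st[0, ], data.frame(x = 1, y = 1)),
               "no stations")
  set.seed(13)
  st <- data.frame(id = sample(50, 8), x = runif(8, 0, 100),
                   y = runif(8, 0, 100))
  cells <- data.frame(x = runif(100, 0, 100), y = runif(100, 0, 100))
  z <- build_thiessen_zones(st, cells)
  expect_equal(z, oracle_nearest(st, cells))
  expect_true(all(z %in% st$id))  # a partition: every cell in one zone
})

test_that("phenology fitting recovers thermal-time requirements", {
  # constant 10 degC: day 100 anthesis and day 180 maturity mean
  # TSUM1 = 1000 and TSUM2 = 800 in closed form
  w <- const_weather(400, tmean = 10, start = "2006-10-01")
  ph <- data.frame(emergence = w$date[1], anthesis = w$date[100],
                   maturity = w$date[180])
  f <- fit_phenology_params(ph, w)
  expect_equal(f$TSUM1, 1000, tolerance = 10 / 1000)
  expect_equal(f$TSUM2, 800, tolerance = 10 / 800)
  # self-consistency on variable weather over three seasons
  wv <- generate_weather(99, "2005-09-01", 4 * 365)
  rows <- list()
  for (y in 2006:2008) {
    em <- as.Date(paste0(y - 1, "-10-08"))
    pd <- simulate_phenology_dates(
      wv[wv$date >= em, ], TSUM1 = 1080, TSUM2 = 750)
    rows[[as.character(y)]] <- data.frame(
      emergence = em, anthesis = em + round(pd$anthesis) - 1,
      maturity = em + round(pd$maturity) - 1)
  }
  f2 <- fit_phenology_params(do.call(rbind, rows), wv)
  expect_equal(f2$TSUM1, 1080, tolerance = 0.02)
  expect_equal(f2$TSUM2, 750, tolerance = 0.02)
  # degenerate phenology rejected
  bad <- data.frame(emergence = w$date[1], anthesis = w$date[100],
                    maturity = w$date[100])
  expect_error(fit_phenology_params(bad, w), "degenerate")
})

test_that("crop-parameter calibration honours empty free sets and bounds", {
  sc <- synthetic_scenario(seed = 3, grid_dim = c(4, 4), n_stations = 1,
                           counties_per_zone = 3, years = 2007,
                           yield_noise_sd = 0,
                           pixel_idem_range = c(0, 0),
                           pixel_span_range = c(0, 0),
                           pixel_tsum1_frac = c(0, 0))
  reg <- generate_region(sc)
  obs <- simulate_truth_and_observe(reg)
  zone <- synthetic_zone(reg, obs)
  rep_c <- reg$counties$county[1]
  r0 <- calibrate_crop_params(zone, rep_c, zone$crop_start,
                              free_params = character(0))
  expect_identical(r0$crop, zone$crop_start)
  expect_equal(r0$evals, 1)
  r1 <- calibrate_crop_params(zone, rep_c, zone$crop_start, maxeval = 150)
  b <- default_calibration_bounds(zone$crop_start)
  expect_gte(r1$crop$span, b$SPAN[1])
  expect_lte(r1$crop$span, b$SPAN[2])
  expect_gte(r1$crop$eps_lue, b$eps_lue[1])
  expect_lte(r1$crop$eps_lue, b$eps_lue[2])
  expect_gte(r1$logLik, r0$logLik - 1e-9)
})

test_that("irrigation calibration stays rainfed when the truth is rainfed", {
  sc <- synthetic_scenario(seed = 5, grid_dim = c(4, 4), n_stations = 1,
                           counties_per_zone = 3, years = 2007:2009,
                           yield_noise_sd = 0, irrigation = FALSE,
                           pixel_idem_range = c(0, 0),
                           pixel_span_range = c(0, 0),
                           pixel_tsum1_frac = c(0, 0))
  reg <- generate_region(sc)
  obs <- simulate_truth_and_observe(reg)
  zone <- synthetic_zone(reg, obs)
  truth <- reg$truth[["1"]]$crop$medium
  r <- calibrate_irrigation(zone, reg$counties$county[1], truth,
                            maxeval = 250)
  tot_v <- sum(vapply(r$policies, function(p) p$V * p$enabled, 0))
  expect_lt(tot_v, 0.5)  # effectively no water added
  for (p in r$policies) {
    expect_gte(p$V, 0)
    expect_gte(p$SMc, zone$soil$sm_wilt - 1e-9)
    expect_lte(p$SMc, zone$soil$sm_fc + 1e-9)
  }
})
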