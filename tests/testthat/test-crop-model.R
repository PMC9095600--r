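test_that("thermal increment follows the mean-temperature kernel", {
  expect_equal(thermal_increment(5, 15, 0), 10)
  expect_equal(thermal_increment(-10, -2, 0), 0)
  expect_equal(thermal_increment(0, 0, 0), 0)
  expect_error(thermal_increment(NaN, 5), "invalid weather")
  expect_error(thermal_increment(10, 5), "tmin > tmax")
})

test_that("development stage is piecewise linear in thermal time", {
  expect_equal(update_phenology(1000, 0, 1000, 800), 1)
  expect_equal(update_phenology(1800, 0, 1000, 800), 2)
  expect_equal(update_phenology(500, 0, 1000, 800), 0.5)
  expect_equal(update_phenology(900, 100, 1000, 800), 1)
  expect_equal(update_phenology(5000, 0, 1000, 800), 2)  # capped
  expect_error(update_phenology(100, 0, -1, 800), "TSUM1")
  expect_error(update_phenology(-5, 0, 1000, 800), "tsum_accum")
})

test_that("soil water step triggers irrigation strictly below SMc", {
  soil <- soil_params(root_depth = 100)
  pol <- irrigation_policy(SMc = 0.25, V = 5, enabled = TRUE)
  # at or above the trigger: no event
  r <- soil_water_step(0.30, 0, 0, 0, soil, pol)
  expect_equal(r$irrigation_cm, 0)
  r <- soil_water_step(0.25, 0, 0, 0, soil, pol)
  expect_equal(r$irrigation_cm, 0)
  # below the trigger: one event of V cm spread over the root zone
  r <- soil_water_step(0.20, 0, 0, 0, soil, pol)
  expect_equal(r$irrigation_cm, 5)
  expect_equal(r$SM, 0.25)
  # drainage invariant under extreme rain
  r <- soil_water_step(0.30, 500, 0, 2, soil, pol)
  expect_lte(r$SM, soil$sm_sat)
  # stress is the clamped relative position between wilt and critical
  r <- soil_water_step(soil$sm_wilt, 0, 0, 0, soil,
                       irrigation_policy(enabled = FALSE, SMc = 0, V = 0))
  expect_equal(r$stress, 0)
})

test_that("daily growth vanishes without light or water and saturates with LAI", {
  crop <- crop_params()
  st <- list(lai = 3, leaf = 1500, stem = 2000, storage = 0, root = 800)
  g0 <- daily_growth(st, list(radiation = 0, tmin = 10, tmax = 20),
                     crop, stress = 1, dvs = 0.6, dtsum = 15)
  expect_equal(g0$assimilation, 0)
  expect_equal(g0$net, 0)   # respiration capped at assimilation
  expect_equal(g0$d_leaf, 0)
  gs <- daily_growth(st, list(radiation = 20, tmin = 10, tmax = 20),
                     crop, stress = 0, dvs = 0.6, dtsum = 15)
  expect_equal(gs$assimilation, 0)
  big <- daily_growth(list(lai = 500, leaf = 1500, stem = 0, storage = 0,
                           root = 0),
                      list(radiation = 20, tmin = 10, tmax = 20),
                      crop_params(rm_leaf = 0), stress = 0.8, dvs = 0.6,
                      dtsum = 15)
  expect_equal(big$assimilation, crop$eps_lue * 0.5 * 20 * 0.8,
               tolerance = 1e-10)
})

test_that("leaf cohorts die once physiological age exceeds SPAN", {
  coh <- data.frame(mass = 100, area = 0.2, age = 0)
  # at 35 degC a cohort ages one day per day: death right after SPAN days
  span <- 5
  for (d in 1:span) {
    s <- senesce_leaves(coh, 35, span)
    coh <- s$cohorts
    expect_equal(nrow(coh), 1)
  }
  s <- senesce_leaves(coh, 35, span)
  expect_equal(nrow(s$cohorts), 0)
  expect_equal(s$dead_mass, 100)
  # at half the reference temperature aging halves: 2 x SPAN days
  coh <- data.frame(mass = 50, area = 0.1, age = 0)
  for (d in 1:(2 * span)) coh <- senesce_leaves(coh, 17.5, span)$cohorts
  expect_equal(nrow(coh), 1)
  expect_equal(nrow(senesce_leaves(coh, 17.5, span)$cohorts), 0)
  # no aging at or below 0 degC
  coh <- data.frame(mass = 50, area = 0.1, age = span - 1e-9)
  expect_equal(senesce_leaves(coh, -5, span)$cohorts$age, span - 1e-9)
})

test_that("anthesis lands where thermal time says under constant temperature", {
  w <- const_weather(260, tmean = 10, precip = 3)
  crop <- crop_params(TSUM1 = 1000, TSUM2 = 800)
  s <- run_season(w, crop, soil_params(), emergence_date = w$date[1])
  expect_equal(as.numeric(s$anthesis_date - w$date[1]) + 1, 100)
  expect_equal(as.numeric(s$maturity_date - w$date[1]) + 1, 180)
})

test_that("a lightless season keeps the initial aboveground mass and zero yield", {
  w <- const_weather(250, tmean = 10, radiation = 0, precip = 3)
  crop <- crop_params()
  s <- run_season(w, crop, soil_params(), emergence_date = w$date[1])
  above0 <- crop$tdwi * (1 - wheatagb:::part_fraction(crop, "root", 0))
  expect_equal(tail(s$series$agb, 1), above0, tolerance = 1e-10)
  expect_equal(tail(s$series$twso, 1), 0)
})

test_that("simulated seasons satisfy the state invariants", {
  set.seed(401)
  for (k in 1:10) {
    cfg <- random_config()
    w <- generate_weather(1000 + k, "2006-09-20", 320)
    s <- suppressWarnings(run_season(w, cfg$crop, cfg$soil, cfg$policy,
                                     emergence_date = w$date[10]))$series
    expect_true(all(diff(s$agb) >= -1e-9))
    expect_true(all(diff(s$dvs) >= 0))
    expect_true(all(s$twso <= s$agb + 1e-9))
    expect_true(all(s$sm <= cfg$soil$sm_sat + 1e-12))
    expect_true(all(s$sm >= 0.5 * cfg$soil$sm_wilt - 1e-12))
  }
})

test_that("the simulator is deterministic", {
  w <- generate_weather(5, "2006-09-20", 300)
  cfg <- random_config()
  a <- run_season(w, cfg$crop, cfg$soil, cfg$policy,
                  emergence_date = w$date[5])
  b <- run_season(w, cfg$crop, cfg$soil, cfg$policy,
                  emergence_date = w$date[5])
  expect_identical(a$series, b$series)
})

test_that("the compiled season loop matches the R reference stepper", {
  set.seed(402)
  for (k in 1:3) {
    cfg <- random_config()
    w <- generate_weather(2000 + k, "2006-09-25", 300)
    s <- suppressWarnings(run_season(w, cfg$crop, cfg$soil, cfg$policy,
                                     emergence_date = w$date[1]))$series
    r <- reference_season(w, cfg$crop, cfg$soil, cfg$policy)
    expect_equal(nrow(s), nrow(r))
    expect_equal(s$dvs, r$dvs, tolerance = 1e-10)
    expect_equal(s$lai, r$lai, tolerance = 1e-8)
    expect_equal(s$agb, r$agb, tolerance = 1e-8)
    expect_equal(s$twso, r$twso, tolerance = 1e-8)
    expect_equal(s$sm, r$sm, tolerance = 1e-10)
    expect_equal(s$irrigation, r$irrigation, tolerance = 1e-10)
  }
})

test_that("assimilated mass is linear in light-use efficiency without respiration", {
  # saturated light interception (large initial canopy, strong extinction,
  # no senescence within the season) makes assimilation independent of the
  # LAI path, so doubling eps_lue doubles the accumulated mass
  w <- const_weather(260, tmean = 12, radiation = 18, precip = 5)
  mk <- function(eps) crop_params(
    eps_lue = eps, rm_leaf = 0, rm_stem = 0, rm_storage = 0, rm_root = 0,
    TDWI = 1000, k_ext = 30, SPAN = 300, TSUM1 = 1500, TSUM2 = 1500)
  tot <- function(crop) {
    s <- suppressWarnings(run_season(w, crop, soil_params(),
                                     emergence_date = w$date[1]))$series
    n <- nrow(s)
    (s$agb[n] + s$root[n]) - crop$tdwi
  }
  g1 <- tot(mk(12))
  g2 <- tot(mk(24))
  expect_gt(g1, 0)
  expect_equal(g2 / g1, 2, tolerance = 1e-6)
})

test_that("a weather series ending before maturity flags truncation", {
  w <- const_weather(40, tmean = 10)
  expect_warning(s <- run_season(w, crop_params(), soil_params(),
                                 emergence_date = w$date[1]),
                 "truncated")
  expect_true(s$truncated)
  expect_true(is.na(s$maturity_date))
})
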