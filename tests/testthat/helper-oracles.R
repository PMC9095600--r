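# Independent brute-force oracles and small fixture builders.

# Dense-matrix Gaussian log-likelihood, written independently of the
# Cholesky-based implementation under test.
oracle_loglik <- function(x, mu, Sigma) {
  d <- length(x)
  r <- x - mu
  -0.5 * (d * log(2 * pi) + log(det(Sigma)) +
            drop(t(r) %*% solve(Sigma) %*% r))
}

random_spd <- function(d) {
  a <- matrix(rnorm(d * d), d)
  crossprod(a) + diag(d) * 0.5
}

# Naive normalized least-squares cost between two paired series.
oracle_lai_cost <- function(obs_v, sim_v) {
  nrm <- function(v) (v - min(v)) / (max(v) - min(v))
  sum((nrm(obs_v) - nrm(sim_v))^2)
}

oracle_metrics <- function(pred, obs) {
  c(r2 = 1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2),
    rmse = sqrt(sum((pred - obs)^2) / length(obs)),
    mape = 100 * sum(abs((pred - obs) / obs)) / length(obs))
}

# Loop-based nearest-station search with lowest-id tie-break.
oracle_nearest <- function(stations, cells) {
  vapply(seq_len(nrow(cells)), function(i) {
    d2 <- (stations$x - cells$x[i])^2 + (stations$y - cells$y[i])^2
    cand <- stations$id[d2 == min(d2)]
    min(cand)
  }, numeric(1))
}

# Independent re-sort implementation of the yield grouping convention.
oracle_grouping <- function(counties) {
  o <- counties[order(-counties$mean_yield, counties$county), ]
  n <- nrow(o)
  pos <- floor(c(0.17, 0.50, 0.83) * (n - 1) + 0.5) + 1
  p0 <- seq_len(n) - 1
  list(reps = o$county[pos],
       high = o$county[p0 <= 0.33 * (n - 1)],
       medium = o$county[p0 > 0.33 * (n - 1) & p0 <= 0.67 * (n - 1)],
       low = o$county[p0 > 0.67 * (n - 1)])
}

# Constant-condition weather builder.
const_weather <- function(n, tmean = 10, radiation = 15, precip = 2,
                          start = "2006-10-01") {
  data.frame(date = as.Date(start) + seq_len(n) - 1L,
             radiation = radiation, tmin = tmean, tmax = tmean,
             vap = 8, wind = 2, precip = precip)
}

# Pure-R daily stepper built from the exported daily-step operations; the
# independent reference for the compiled season loop.
reference_season <- function(weather, crop, soil, policy,
                             sm_init = soil$sm_fc) {
  n <- nrow(weather)
  tmean <- 0.5 * (weather$tmin + weather$tmax)
  et0 <- et0_reference(weather$radiation, tmean)
  fl0 <- wheatagb:::part_fraction(crop, "leaf", 0)
  fs0 <- wheatagb:::part_fraction(crop, "stem", 0)
  fo0 <- wheatagb:::part_fraction(crop, "storage", 0)
  cohorts <- data.frame(mass = crop$tdwi * fl0,
                        area = crop$sla * crop$tdwi * fl0, age = 0)
  stem <- crop$tdwi * fs0
  storage <- crop$tdwi * fo0
  root <- crop$tdwi * (1 - fl0 - fs0 - fo0)
  dead <- 0
  lai <- crop$sla * crop$tdwi * fl0
  sm <- sm_init
  tsum <- 0
  out <- data.frame(dvs = numeric(0), lai = numeric(0), agb = numeric(0),
                    twso = numeric(0), sm = numeric(0),
                    irrigation = numeric(0))
  for (i in seq_len(n)) {
    dtsum <- thermal_increment(weather$tmin[i], weather$tmax[i],
                               crop$tbase_pheno)
    tsum <- tsum + dtsum
    dvs <- update_phenology(tsum, 0, crop$tsum1, crop$tsum2)
    sw <- soil_water_step(sm, weather$precip[i], et0[i], lai, soil, policy,
                          crop$k_ext)
    sm <- sw$SM
    g <- daily_growth(list(lai = lai, leaf = sum(cohorts$mass),
                           stem = stem, storage = storage, root = root),
                      list(radiation = weather$radiation[i],
                           tmin = weather$tmin[i], tmax = weather$tmax[i]),
                      crop, sw$stress, dvs, dtsum)
    stem <- stem + g$d_stem
    storage <- storage + g$d_storage
    root <- root + g$d_root
    if (g$d_leaf > 0 || g$d_lai > 0)
      cohorts <- rbind(cohorts,
                       data.frame(mass = g$d_leaf, area = g$d_lai, age = 0))
    sen <- senesce_leaves(cohorts, tmean[i], crop$span)
    cohorts <- sen$cohorts
    dead <- dead + sen$dead_mass
    lai <- sum(cohorts$area)
    out[i, ] <- c(dvs, lai, sum(cohorts$mass) + dead + stem + storage,
                  storage, sm, sw$irrigation_cm)
    if (dvs >= 2) break
  }
  out
}

# Randomized but valid crop/soil/policy configuration for property sweeps.
random_config <- function() {
  crop <- crop_params(
    TSUM1 = runif(1, 800, 1300), TSUM2 = runif(1, 600, 1000),
    TDWI = runif(1, 120, 350), SPAN = runif(1, 20, 40),
    SLA = runif(1, 0.0015, 0.0030), eps_lue = runif(1, 18, 32))
  soil <- soil_params(sm_wilt = runif(1, 0.08, 0.15),
                      sm_fc = runif(1, 0.25, 0.33),
                      sm_sat = runif(1, 0.40, 0.48))
  policy <- if (runif(1) < 0.5) {
    irrigation_policy(SMc = runif(1, soil$sm_wilt + 0.01, soil$sm_fc - 0.01),
                      V = runif(1, 1, 6), enabled = TRUE)
  } else irrigation_policy(enabled = FALSE, SMc = 0, V = 0)
  list(crop = crop, soil = soil, policy = policy)
}
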