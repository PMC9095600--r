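# wheatagb

Gridded daily aboveground biomass (AGB) for winter wheat, built from three
sparse information sources: county yield statistics, agrometeorological
station records, and 8-day satellite leaf-area index (LAI). The package
implements the full estimation chain as reusable, tested R code:

1. **Crop core** — a reduced-form WOFOST-style daily simulator
   (phenology by thermal time, light-use-efficiency growth, Q10
   maintenance respiration, DVS-dependent partitioning, leaf cohorts with
   a 35 °C-referenced life span, a bucket soil-water balance with
   threshold-triggered irrigation).
2. **Zonal calibration** — Thiessen-polygon zones around stations;
   per-zone thermal-time fitting from phenology dates; counties grouped
   into high/medium/low yield levels by the 33%/67% quantiles of mean
   yield (representatives at the 17%/50%/83% positions); and a three-step
   maximum-likelihood calibration (crop → irrigation → crop) of the
   objective

   log L = log L_LAI + log L_TWSO + log L_AGB,

   each term −½ [d·log 2π + log|Σ| + MD²(x; μ, Σ)] with d = 3 jointly
   calibrated years, an N(6.5, 1.5²) prior per year on simulated maximum
   LAI, and county yields (converted at 12.5% grain moisture, divided by
   a province harvest index for AGB) with SDs of 10% of the statistic.
3. **Per-pixel assimilation** — re-initialization of the emergence day
   (IDEM), leaf life span (SPAN) and emergence-to-anthesis thermal time
   (TSUM1) on each masked pixel by minimizing the normalized
   weak-constraint cost

   J = Σ_t [ norm(LAI_obs)_t − norm(LAI_sim)_t ]²,

   where norm() is min–max normalization per side — invariant to the
   satellite product's low bias — minimized by a bounded derivative-free
   simplex search from the zonal values.
4. **Products and validation** — 270-band daily rasters per harvest year
   (the last 90 days of the previous year plus the first 180 of the
   harvest year), R²/RMSE/MAPE validation and county error maps with a
   ±2000 kg/ha flagging threshold, plus total-biomass and NPP
   (0.45 × total) conversions.

A synthetic-data module (`synthetic_scenario()`, `generate_region()`,
`simulate_truth_and_observe()`) generates weather, stations, counties,
truth parameters and satellite-like LAI with the statistical structure the
analysis assumes, so the whole pipeline runs end to end without external
data. The methods vignette (`vignettes/methods.Rmd`) documents the model,
the calibration and assimilation objectives, all defaults and the known
limitations.

## A worked season

```r
library(wheatagb)
w    <- generate_weather(42, "2006-09-01", 320)   # synthetic daily weather
crop <- crop_params()                             # winter-wheat defaults
soil <- soil_params()
pol  <- irrigation_policy(SMc = 0.2, V = 4)       # irrigate 4 cm below SM 0.20
s    <- run_season(w, crop, soil, pol, emergence_date = "2006-10-08")
print(s)
#> Winter-wheat season simulation
#>   emergence  2006-10-08
#>   anthesis   2007-04-23
#>   maturity   2007-06-04
#>   240 simulated days; max LAI 6.41; final AGB 16604 kg/ha; final yield (TWSO) 5654 kg/ha
#>   4 irrigation events, 16.0 cm applied in total
```

Anthesis falls in late April and maturity in early June because thermal
time (TSUM1 = 1000 °C d to anthesis, TSUM2 = 800 °C d to maturity)
accumulates slowly through winter; the yield of 5654 kg/ha dry matter
corresponds to about 6.5 t/ha at the 12.5% standard moisture.

## A calibrated zone

```r
sc   <- synthetic_scenario(seed = 1, grid_dim = c(6, 6), n_stations = 1,
                           counties_per_zone = 9, years = 2007:2009,
                           yield_noise_sd = 0, pixel_idem_range = c(0, 0),
                           pixel_span_range = c(0, 0), pixel_tsum1_frac = c(0, 0))
reg  <- generate_region(sc)
obs  <- simulate_truth_and_observe(reg)
zone <- synthetic_zone(reg, obs)      # phenology-fit TSUM1/TSUM2 + county stats
cal  <- three_step_calibration(zone)
print(cal)
#> Zonal three-step calibration (station 1)
#>   high    rep county 1004   logLik  -96.596 ->  -52.121 ->  -52.057
#>   medium  rep county 1005   logLik  -90.375 ->  -51.847 ->  -51.823
#>   low     rep county 1006   logLik  -83.527 ->  -52.021 ->  -51.980
#>   free parameters: SPAN, eps_lue
coef(cal)
#>          SPAN eps_lue
#> high   29.981  25.439
#> medium 29.516  24.411
#> low    28.364  23.317
```

The three log-likelihoods rise monotonically across the steps (the large
step-1 → step-2 jump is irrigation being switched on), and the recovered
light-use efficiencies order the yield levels correctly: this noise-free
zone was generated with level offsets of ±7% around eps_lue ≈ 24.5, and
the fit recovers each within a few percent.

The same machinery runs from the shell via the bundled driver:

```sh
Rscript inst/cli/wheatagb.R all --seed 1 --output-dir out/
```

which writes the synthetic inputs (CSV), per-zone calibration files
(YAML), assimilation diagnostics (CSV), the 270-band AGB raster
(TIFF + JSON sidecar) and the county validation report.

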