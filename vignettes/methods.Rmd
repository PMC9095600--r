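---
title: "Methods: simulating, calibrating and assimilating winter-wheat biomass"
author: "wheatagb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, calibrating and assimilating winter-wheat biomass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatagb)
```

# The problem

County yield statistics describe winter wheat at coarse administrative
scale once a year; satellite leaf-area index (LAI) describes every 1 km
pixel every 8 days, but with a known low bias; agrometeorological stations
contribute phenology dates, soil water constants and maximum-LAI records at
a few dozen points. `wheatagb` combines the three through a daily crop
growth simulator: station data parameterize Thiessen zones, county
statistics calibrate crop and irrigation parameters per yield level via a
Gaussian log-likelihood, and the satellite LAI re-initializes three
parameters per pixel through a normalized weak-constraint cost. The product
is a daily aboveground-biomass (AGB) raster stack per harvest year.

Because the real inputs are large external archives, the package ships a
synthetic-data module that generates a full study region with the same
statistical structure, so every stage — and the pipeline end to end — runs
and is tested without downloads.

# The crop core

The simulator is a deliberately reduced daily model of the WOFOST family:
it keeps the state variables and parameters that the calibration and
assimilation layers act on (DVS, LAI, AGB, storage-organ biomass TWSO, soil
moisture; TSUM1, TSUM2, TDWI, SPAN, SMc, V, emergence day) and replaces the
full photosynthesis machinery with a light-use-efficiency core. The daily
update order is: phenology, soil water, growth, leaf senescence.

**Phenology.** Thermal time accrues as $\max(0, (T_{min}+T_{max})/2 -
T_{base})$ with $T_{base} = 0\,^\circ$C by default. The development stage
runs linearly from 0 (emergence) to 1 (anthesis) as the sum approaches
TSUM1, then to 2 (maturity) over TSUM2, where the run stops.

**Growth.** Gross assimilation is
$A = \varepsilon \cdot 0.5\,R_s \cdot (1 - e^{-k\,\mathrm{LAI}}) \cdot s$,
with $R_s$ the shortwave radiation (half of it PAR), $k = 0.6$ the
extinction coefficient, $s \in [0,1]$ the water-stress factor and
$\varepsilon$ the light-use efficiency in kg ha$^{-1}$ per MJ m$^{-2}$ PAR
(default 24, i.e. 2.4 g MJ$^{-1}$). Maintenance respiration is a $Q_{10}$
function of mean temperature over the living organ pools, capped at $A$;
the non-negative net growth is split over leaves, stems, storage organs and
roots by a piecewise-linear partitioning table in DVS. AGB counts living
and dead aboveground organs; roots are excluded.

**Leaf dynamics.** Leaf mass lives in daily cohorts. Leaf area grows at
SLA $\times$ leaf-mass increment, except in the juvenile phase
(DVS $< 0.3$) where it is additionally capped by the exponential rule
$\mathrm{LAI}\,(e^{\mathrm{RGRLAI}\,\Delta T} - 1)$. Cohorts age by
$\max(0, T_{mean})/35$ per day and die once their age exceeds SPAN — so
SPAN is the leaf life span at a constant 35 °C, and leaves live twice as
long at 17.5 °C. Dead leaf mass stays in AGB.

**Soil water.** A single bucket over the rooted depth (100 cm default).
Each day, if irrigation is enabled and the start-of-day moisture is
strictly below the trigger SMc, an event of V cm is applied
($\Delta SM = V / \mathrm{root\ depth}$). Rain is added, actual
evapotranspiration $ET_0 \cdot \min(1, \mathrm{cover}) \cdot s$ is removed
(cover $= 1 - e^{-k\,\mathrm{LAI}}$), excess above saturation drains, and
moisture is floored at half the wilting point. The stress factor is the
clamped position of moisture between the wilting point and a critical
level halfway to field capacity. $ET_0$ is a radiation-based
(Makkink-style) reference, $0.65\,(R_s/2.45)\,f(T)$ with
$f(T) = \mathrm{clamp}(0.42 + 0.013\,T,\,0,\,1)$: only relative
soil-moisture dynamics matter for calibrating SMc and V, so a simple,
documented form is preferred.

The daily loop is compiled (C++); a pure-R reference stepper assembled
from the exported daily-step functions lives in the test suite and the two
are held equal to within $10^{-8}$ on randomized configurations.

## Default parameters

Defaults describe a temperate winter wheat: TSUM1 1000 and TSUM2
800 °C d, TDWI 210 kg ha$^{-1}$, SPAN 30 d, SLA 0.0021 ha kg$^{-1}$,
RGRLAI 0.0082 (°C d)$^{-1}$, $\varepsilon$ 24 kg ha$^{-1}$(MJ m$^{-2}$)$^{-1}$.
They were chosen once so that an irrigated season under the default
synthetic climate shows a maximum LAI near 6.5, a fresh grain yield near
6 t ha$^{-1}$ and a final AGB near 15 t ha$^{-1}$ — the magnitudes a
North-China-Plain agronomist would call ordinary. Every value is
overridable through `crop_params()`, and the calibration layer treats a
configurable subset as free.

One visible simplification: assimilation has no direct temperature
limitation (only respiration and phenology respond to temperature), so the
model grows more in mid-winter than a dormant crop would. The calibration
absorbs this into its effective parameter values; it is a limitation to
keep in mind when reading absolute winter AGB levels.

# Zonal parameterization

Stations partition the region into Thiessen polygons: each cell joins its
nearest station (Euclidean distance, exact ties to the lowest station id),
so zones form a partition. Station soil constants convert from gravimetric
to volumetric water content by multiplying with bulk density; anthesis
dates missing from station records are reconstructed as heading + 7
calendar days. TSUM1 and TSUM2 are fitted per zone by minimizing the
summed squared day differences between simulated and observed anthesis and
maturity, with the thermal-time crossing day interpolated fractionally so
the objective is continuous; the search starts from the closed-form
estimate (mean accumulated thermal time at the observed dates).

# Calibration within a zone

Counties are ranked by mean statistical yield (descending) and split into
high/medium/low groups at the 33% and 67% quantile positions;
representative counties sit at the 17%, 50% and 83% positions, with
positions computed as round(q·(n−1)), half-up, on the descending list.
With fewer than three counties the zone falls back to a single group
represented by the median county.

The objective for a representative county joins three Gaussian
log-likelihood terms over $d = 3$ jointly calibrated years (consecutive,
non-overlapping), each of the form
$-\tfrac12 [d \log 2\pi + \log |\Sigma| + \mathrm{MD}^2]$ with
$\mathrm{MD}$ the Mahalanobis distance of the simulated vector from the
observation mean:

* annual maximum LAI against the station climatology prior, mean 6.5 and
  SD 1.5 per year;
* TWSO at maturity against the county yield converted to dry matter
  (12.5% standard grain moisture), SD 10% of the value;
* AGB at maturity against dry yield divided by the province harvest
  index, SD 10% of the value.

Covariances are diagonal (annual independence); a full symmetric
positive-definite matrix is accepted by the likelihood code but unused by
default. Years missing from a county's statistics are dropped from all
three terms with $d$ reduced accordingly.

**Three steps.** (1) Fit the free crop parameters under rainfed
conditions; (2) with the crop fixed, fit per-year irrigation (SMc, V) —
six parameters for three years, with SMc bounded in [wilting point, field
capacity] and V in [0, 10 cm]; since V = 0 reproduces the rainfed run,
this step can only improve the objective, and the code keeps the rainfed
configuration whenever the search does not; (3) re-fit the crop parameters
with the optimized irrigation fixed. Each step restarts from the previous
optimum, so the objective sequence is non-decreasing up to optimizer
tolerance.

**The free parameter set.** The default is {SPAN, eps_lue}. The annual
observation vector (max LAI, TWSO, AGB over three years) constrains a
leaf-dynamics direction and a yield-scale direction well, but it is nearly
flat in TDWI (a 10% change moves final AGB by roughly 2%, because faster
early growth only shifts canopy closure by days) and SLA trades off
against SPAN along a max-LAI ridge. Fitting all four therefore produces
bound-hugging, irreproducible estimates, while the two-parameter set is
recovered within a few percent on noise-free synthetic zones. TDWI, SLA,
RGRLAI, TSUM1 and TSUM2 can still be freed through the `free_params`
argument when richer observations justify it.

**Optimizer.** All fits use a bounded derivative-free simplex search in
the spirit of subspace-simplex (Subplex) methods: parameters map to an
unconstrained scale through a logistic transform of their box bounds,
Nelder–Mead runs there (relative tolerance $10^{-8}$), and the search
restarts from its own optimum with a fresh simplex until it stops
improving (at most 2–4 restarts). There is no random restart, so every
fit is reproducible.

# Per-pixel assimilation

Satellite LAI runs low relative to field LAI, so absolute values are not
trusted; the cost matches normalized shapes:
$$J = \sum_t \left( \frac{L^{obs}_t - L^{obs}_{min}}{L^{obs}_{max} -
L^{obs}_{min}} - \frac{L^{sim}_t - L^{sim}_{min}}{L^{sim}_{max} -
L^{sim}_{min}} \right)^2,$$
with min/max taken over the paired values of each side separately, per
season. $J$ is invariant under positive affine transforms of either side,
which is exactly what makes a 0.7 multiplicative bias harmless. Simulated
LAI is sampled on the observation dates (no compositing-window averaging);
dates outside the simulated season pair with LAI 0.

Three parameters are re-initialized per pixel within bounds: the emergence
day IDEM (zonal ± 10 d), SPAN ([15, 45] d) and TSUM1 (zonal ± 15%).
Fractional IDEM blends the simulated LAI of the two bracketing integer
emergence days, keeping $J$ continuous. Observation series with amplitude
below 0.2 LAI are skipped as degenerate and the zonal run is returned.

The cost surface needs care. Distinct (IDEM, SPAN) basins exist, and along
(IDEM, TSUM1) the surface has a curved, nearly flat valley: shifting
emergence by one day is almost interchangeable with ~20 °C d of TSUM1,
because normalization crushes the small early-season LAI values that would
separate the two. The fit therefore begins with a deterministic coarse
scan over (IDEM, SPAN) at the zonal TSUM1 — keeping TSUM1 anchored near
the zonal value, as a purely local search started from the zonal
parameters would — and then refines all three parameters with the bounded
simplex search. The final cost never exceeds the start cost: if the search
cannot improve on the zonal configuration, that configuration is kept.

A consequence worth knowing: when the zonal parameters come from the
three-step calibration, the calibrated (SPAN, eps_lue) pair has already
absorbed the county-mean effect of the pixels' phenology/leaf deviations.
Re-initializing SPAN per pixel on top of such parameters can then break
that compensation and leave AGB-at-maturity errors unchanged or slightly
worse even though the LAI shape fit improves markedly. Assimilation
reliably reduces AGB error relative to the zone-level parameter sets
themselves (the package's paired-improvement experiment measures exactly
this); improving on an already-calibrated zone requires observations that
constrain absolute biomass, which a normalized LAI shape deliberately does
not.

# The synthetic study region

`synthetic_scenario()` fixes every knob; one root seed drives named
substreams (weather, region, truth, mask, pixel, calendar, yield, lai,
maxlai) so components regenerate independently and the whole region is
bit-reproducible.

* **Weather** — sinusoidal annual temperature (mean 13 °C, amplitude
  14 °C) and radiation cycles with seeded daily noise, a two-state
  wet/dry precipitation chain with exponential wet-day amounts
  (semi-arid: ~300 mm yr$^{-1}$, so spring irrigation matters), tmin/tmax
  bracketing the mean by a noisy diurnal half-range (tmin ≤ tmax by
  construction).
* **Region** — stations on a jittered lattice, Thiessen zones, counties
  as contiguous chunks of each zone (one province per zone), a
  configurable winter-wheat mask fraction.
* **Truth** — per zone, jitters on TSUM1/TSUM2 (±3%), SPAN (±1.5 d) and
  eps_lue (±3%); yield levels offset eps_lue by ±7% (high/low); per
  pixel, uniform perturbations of emergence day (±6 d), SPAN (±4 d) and
  TSUM1 (±8%). TDWI and SLA are treated as regional variety constants.
  The truth distribution deliberately matches the structure the
  calibration assumes — station maximum LAI scattered around 6.5
  regardless of level — which also keeps recovery experiments well-posed:
  the varied parameters are the estimated ones.
* **Observations** — station phenology from the zonal medium-level run;
  station max-LAI drawn from N(6.5, 1.5²); county fresh yield = pixel-mean
  dry TWSO / 0.875 times (1 + noise), noise SD 10%; province harvest
  index = mean simulated TWSO/AGB ratio; satellite-like stacks = true
  daily LAI sampled every 8 days from the zonal emergence, times a 0.7
  bias, plus additive noise (SD 0.1) and a 3-point moving average standing
  in for the smoothing of real reprocessed products.

What the generator does **not** emulate: real compositing artefacts and
cloud gaps, spatially correlated weather fields, winter dormancy, multiple
crops per pixel, and counties straddling zones. Passing tests on this
world demonstrate the estimation machinery is correct and well-behaved,
not that the real-data products reach any particular accuracy.

# Products and validation

A harvest-year product spans the last 90 days of the previous calendar
year plus the first 180 days of the harvest year — 270 daily bands always,
with leap years shifting the calendar endpoints, never the count. Stacks
are written as multiband 32-bit TIFF with a JSON sidecar carrying the
georeferencing (origin, 0.01° cells, CRS), the band→date mapping, the
no-data code and the linear packing scale (the TIFF stores unit-range
samples; values round-trip to ~10$^{-5}$ kg ha$^{-1}$). Within the window,
bands before emergence are 0 and bands after maturity hold the final AGB.

Validation reports R² (as $1 - SS_{res}/SS_{tot}$, not squared
correlation), RMSE and MAPE, and a per-county error table comparing mean
simulated maximum AGB with statistics-derived AGB (fresh → dry → /HI);
counties are flagged when |error| strictly exceeds 2000 kg ha$^{-1}$.

# Numerical conventions and degenerate inputs

* Quantile positions: round(q·(n−1)) half-up on descending-sorted lists
  (R's own `round()` is round-half-even and is not used there).
* Ties in Thiessen assignment go to the lowest station id; ties in yield
  ranking to the lowest county id.
* Flat series (zero amplitude) are errors for normalization and skip the
  pixel in assimilation; singular covariances, non-positive harvest
  indices, gravimetric conversions reaching 1, and anthesis = maturity
  all raise informative errors.
* Weather ending before maturity yields a truncated season carrying a
  warning flag rather than an error.
* Simulator candidates that fail inside a calibration search are rejected
  with an effectively $-\infty$ objective instead of aborting the fit.

# Problem sizes used by the test suite

The packaged experiments run at desk scale, chosen as the smallest sizes
at which the statistical questions are meaningful: single-zone regions of
6×6 cells with 9 counties and 3 years for calibration recovery; one pixel
for the perturbed-truth assimilation experiment; 5×5 grids over 20 seeds
for the paired-improvement experiment; 200 randomized seasons for the
invariant sweep; 50–150 random instances per brute-force oracle
comparison.

# Known limitations

* No temperature limitation on assimilation and no vernalization or
  photoperiod response: the season must start at an observed emergence
  date, and winter growth is overestimated relative to a dormant crop.
* The simulated harvest index (~0.33) sits below modern field values
  (~0.45) because stem reserves are not remobilized to grain; the
  calibration chain is internally consistent, so this does not bias the
  synthetic experiments.
* The (IDEM, TSUM1) near-degeneracy of the normalized cost means those
  two parameters are only jointly determined by LAI shape; the reported
  per-pixel values are the ridge point nearest the zonal configuration.
* Assimilation on top of calibrated zone parameters improves LAI-shape
  fidelity and spatial detail but not necessarily AGB-at-maturity error
  (see the assimilation section).
* Counties are assigned to zones wholesale (by construction in the
  synthetic world; by centroid in any real-data use); sub-county zone
  splits are not supported.
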