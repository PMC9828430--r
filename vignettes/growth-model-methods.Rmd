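---
title: "Methods: genotype-specific switchgrass growth simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-specific switchgrass growth simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchgrow)
```

## The model

`switchgrow` simulates the growth of upland and lowland switchgrass
(*Panicum virgatum* L.) at a daily time step. The two ecotypes differ
systematically — lowland cultivars (Alamo, Kanlow) are taller, later-flowering
and adapted to warm, wet sites; upland cultivars (Cave-in-Rock and relatives)
are hardier and adapted to colder, drier sites — and the model captures this
genotype-by-environment interaction purely through ecotype-specific parameter
sets. Each simulated day runs, in order:

1. **Meteorology** — daily mean temperature `(Tmin + Tmax)/2`, degree-day
   increments above two bases (10 °C for the development clock, 0 °C for leaf
   expansion), astronomical day length, and potential evapotranspiration
   (FAO-56 Penman–Monteith when wind and humidity are available, Thornthwaite
   otherwise; the choice is recorded in the run metadata).
2. **Soil water** — a free-draining single-layer bucket over a configurable
   rooted depth (default 1000 mm). The Campbell retention curve
   `θ(ψ) = θs (ψ/ψe)^(-1/b)` is parameterised from texture via the Cosby
   sand/clay regressions, with porosity from bulk density and an
   organic-matter particle-density correction. Field capacity, wilt point and
   the extractable-water floor are the curve at −10 kPa, −2 MPa and −11 MPa.
   Actual evapotranspiration is `PET · C(LAI) · f_w(ψ)` with canopy cover
   factor `C = e_s + (1 − e_s)(1 − e^{−k·LAI})` and `f_w` the photosynthesis
   water-stress factor. Conservation is exact by construction:
   `precip − AET − drainage = ΔSWC` to machine precision.
3. **Phenology** — a six-stage "physiostat" state machine (0 dormant,
   1 shoot emergence, 2 leaf expansion, 3 leaf-area maximum / onset of leaf
   senescence, 4 plant senescence and repartition, 5 above-ground drying)
   advanced by cumulative DD10 thresholds with environmental triggers and
   brakes: emergence requires a moist seedbed (ψ ≥ −0.3 MPa) and a frost-free
   day; stage 3 can be brought forward by the canopy reaching its maximum
   LAI, a frost day, drought beyond the leaf-expansion stop, or (if enabled)
   short post-solstice day length; a killing frost forces stage 4.
4. **Canopy and dry matter** — LAI grows by `dd_lai_factor × DD0` per day
   under the leaf-expansion water factor, capped at `LAImax`, and declines
   linearly by `rate × peak LAI` per day from stage 3. Intercepted PAR
   follows Beer's law `1 − e^{−k·LAI}` with `k = 0.36` for both ecotypes.
   Daily dry matter is `RUEmax · TVF · f_w · fIPAR · PAR` (g m⁻², ×0.01 to
   Mg ha⁻¹), accumulated through stages 2–3; the seasonal peak is recorded at
   the stage-4 onset, after which standing dry matter declines linearly to
   the spring harvest.
5. **Kill events** — winter kill when the dormant-season (1 Nov → harvest)
   count of days with `Tmin` below the ecotype's absolute minimum (−23.3 °C
   lowland, −34.4 °C upland) reaches 60; an alternative chill-day rule
   (days below 0 °C) is selectable because the absolute rule understates
   observed lowland losses at cold continental sites. Drought gives shoot
   death (early stage 4) after 30 consecutive days below the wilt point and
   outright plant death at the −11 MPa necrosis floor. Sustained in-season
   soil frost (a damped air-temperature proxy at 10 cm) forces premature
   senescence.

Harvest is on 1 March; the harvested yield is `0.832 × peak DM` for both
ecotypes, the stand is reset (perennial cycle), and plant deaths trigger a
replant whose establishment season is flagged and yields zero.

## Ecotype parameters

| parameter | lowland (Alamo) | upland (CIR) | units |
|---|---|---|---|
| DD10 stage thresholds | 105/168/1174/1566/1694 | 80/125/1085/1395/1488 | °C·day |
| extinction coefficient k | 0.36 | 0.36 | – |
| maximum LAI | 12 | 7 | – |
| DD0 leaf-expansion factor | 0.004 | 0.006 | LAI per °C·day |
| LAI senescence rate | 0.03 | 0.049 | day⁻¹ (of peak) |
| maximum RUE | 5.05 | 3.19 | g DM MJ⁻¹ IPAR |
| optimum temperature | 28 | 23 | °C |
| absolute winter minimum | −23.3 | −34.4 | °C |
| harvest ratio | 0.832 | 0.832 | – |

Stress anchors shared by both ecotypes: full supply at −10 kPa; leaf
expansion stops at −1 MPa; photosynthesis stops at −2 MPa; emergence needs
≥ −0.3 MPa; necrosis at −11 MPa. All parameters live in a single validated
registry (`genotype_defaults()`) and can be overridden field-by-field with
`genotype_params()`, so further cultivars can be added without code changes.

## Design choices where the design was open

* **Temperature response (TVF).** The radiation-use efficiency modifier is a
  bivariate Gaussian in the daily temperature and the mean temperature over
  the leaf-formation period (a 30-day running window during stages 1–3),
  normalised to 1 at the optimum, with breadth σ = 8 °C. The functional form
  is smooth, symmetric and has the right qualitative behaviour (full
  efficiency at the optimum, steep decline a few degrees above it); σ is
  configurable for recalibration.
* **PAR fraction.** PAR is taken as 0.5 of global shortwave radiation — the
  common crop-model convention — and is configurable.
* **AET contract.** The water-stress factor applied to AET is the
  photosynthesis factor, so AET reaches zero at the −2 MPa stop. A
  consequence worth knowing: evapotranspiration alone can then never dry the
  bucket *past* the wilt point — the potential approaches −2 MPa
  asymptotically. In-simulation drought kills therefore arise only from dry
  initial conditions or user-supplied forcing; the drought-kill checks
  themselves (`check_drought_kill()`) operate on any potential series.
* **LAI senescence units.** The published decline rates (0.03/0.049 day⁻¹)
  are read as a fraction of the attained peak LAI per day (a linear decline);
  exponential decay is available via `senescence_mode = "exponential"`.
* **Upland stage-3 timing.** Because stage 3 *is* "leaf-area maximum", and
  the upland DD0 factor (0.006) with LAImax 7 accumulates leaf faster than
  the stage-2 DD10 span (125 → 1085) elapses, a stress-free upland season
  always reaches its maximum LAI before the DD10 threshold: the LAI brake,
  not the clock, starts upland leaf senescence. Lowland (0.004, LAImax 12)
  normally senesces on the clock. This is a genuine property of the
  published parameter set, not an implementation artefact.
* **Winter-kill counting.** The 60 qualifying days are counted (not required
  consecutive) within one dormant season, which is order-invariant; the
  absolute-threshold rule is the default, with `winterkill_mode = "chill"`
  as the documented alternative.
* **Kill-year policy in means.** `mean_annual_yield()` includes kill-year
  zeros and excludes replant establishment seasons; both behaviours are
  explicit arguments.
* **Season bookkeeping.** The annual reset coincides with the 1 March
  harvest. If a season reaches harvest while still in stages 1–3 (short cool
  summers), the standing dry matter at harvest is taken as the peak so that
  yield = 0.832 × peak holds for every record.
* **Day length.** Declination uses the standard cosine approximation
  `δ = −23.44° cos(2π(doy+10)/365)`; day length is exactly complementary
  across hemispheres on the same day, and complementary within ~0.3 h for
  the same hemisphere half a year apart.

## The synthetic weather generator

`generate_weather()` emulates the statistical shape of the forcing the model
is meant to consume, without any download: a sinusoidal seasonal temperature
cycle plus stationary AR(1) noise (ρ = 0.7, σ = 2 °C by default), a fixed
diurnal range, independent wet days with gamma amounts (shape 0.7) whose
scale reproduces the archetype's annual total in expectation, and global
radiation as top-of-atmosphere flux times a transmissivity that drops on wet
days. Three presets define the study conditions: a temperate semi-arid
continental climate (9 °C mean, 450 mm), a warm-humid climate (16 °C,
1100 mm) in which both ecotypes complete their cycle and lowland out-yields
upland, and a cold continental climate (−2 °C mean, 24 °C seasonal
amplitude) whose winters exceed 60 days below −24 °C, killing lowland while
upland survives. Everything is reproducible from an integer seed
(Mersenne-Twister), and the generator restores the caller's RNG state.

What the generator does *not* emulate — multi-day synoptic rain persistence,
heat waves decoupled from the seasonal cycle, humidity/wind fields (so
synthetic runs use Thornthwaite PET), interannual climate trends — bounds
what passing tests show: they validate the process implementation and its
qualitative genotype-by-environment behaviour, not predictive skill on any
real site.

## Spatial mapping

`generate_grid()` builds a small in-memory climate cube (per-cell weather
with optional north–south temperature/precipitation gradients, co-registered
soil, slope and availability masks); `run_grid()` simulates every cell and
returns a matrix-backed `yield_raster`, with cells outside the adaptation
zone (more plant-death events than allowed, default none) as NoData.
`optimal_map()` takes the cellwise maximum of the two ecotype rasters and
labels the winner (ties to upland, the wider-adapted ecotype);
`apply_mask()` removes unavailable cells and slopes strictly above 15°;
`aggregate_totals()` produces area-weighted totals (Tg), means (Mg ha⁻¹) and
areas (M ha), with geographic cell areas from the cosine rule. Raster I/O
uses the plain-text ESRI ASCII grid format (NoData −9999).

## Validation statistics

`fit_stats()` reports n, r² (squared Pearson correlation of modelled vs
measured, the regression-based definition), RMSE, bias, and the alternative
1 − SSE/SST model-efficiency statistic. The packaged fixture
(`table3_fixture()`) carries 61 measured/modelled yield pairs (33 upland,
28 lowland) from 14 multi-site field trials; one upland pair (Yangling 2010,
measured 30.2 vs modelled 8.9 Mg ha⁻¹) is a marked outlier, so the upland
statistics are always computed and reported under both inclusion policies.
A second fixture carries the 34-entry literature census of Beer's-law
extinction coefficients whose median magnitude fixes `k = 0.36`.

## Numerical choices and degenerate inputs

Stage thresholds are strict (`dd10 ≥ threshold`); transitions may cascade
within a day but never move backwards within a season. The retention curve
is clamped (and flagged) outside the physical content range. AET is capped
so the store never falls below the −11 MPa floor, keeping the balance exact.
The Thornthwaite heat index comes from the calendar-month climatology of the
supplied series (≥ 12 months required), months at or below 0 °C get zero
PET, and monthly means above 26.5 °C use the Willmott high-temperature
polynomial. Zero-variance inputs to `fit_stats()` are flagged rather than
returning a spurious r².

Test problem sizes are deliberately modest — multi-year single-site runs of
3–11 years, grids up to 3×3 cells for full simulations and 50×50 for the
map-algebra oracles — chosen so the whole suite re-runs in well under a
minute while still exercising every seasonal code path (a simulated year
takes on the order of 0.1–0.2 s).

## Known limitations

Single-layer hydrology (no layering, snow, runoff, irrigation or
groundwater); no nitrogen limitation; no moisture content at harvest; no
tillering or organ-level morphology; base temperature fixed at 10 °C; soil
temperature at 10 cm is a damped air-temperature proxy; the spatial module
works on in-memory grids and plain-text rasters rather than NetCDF/GeoTIFF
stacks. Regional totals for any real landscape require real gridded climate
and soil inputs, which are outside the package's scope.
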