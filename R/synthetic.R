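#' Climate archetype for the synthetic weather generator
#'
#' A parametric description of a daily climate: a sinusoidal seasonal
#' temperature cycle with AR(1) noise, a fixed diurnal range, Bernoulli
#' wet-day occurrence with gamma rainfall amounts, and clear-sky
#' transmissivity coupled to wet days. Three presets are shipped:
#' `"loess-semiarid"` (temperate continental, 9 C mean, 450 mm),
#' `"warm-humid"` (16 C mean, 1100 mm) and `"cold-continental"`
#' (-2 C mean with severe winters, 420 mm).
#'
#' @param preset Preset name, or `"custom"` with all fields supplied via
#'   `...`.
#' @param ... Field overrides: `mean_temp`, `amplitude`, `diurnal_range`
#'   (degrees C), `annual_precip` (mm), `wet_prob`, `rain_shape`,
#'   `transmissivity`, `cloud_factor`, `ar1_rho`, `noise_sd`, `solar_noise_sd`,
#'   `phase_doy`.
#' @return A `climate_archetype` list.
#' @export
climate_archetype <- function(preset = c("loess-semiarid", "warm-humid",
                                         "cold-continental", "custom"),
                              ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    "loess-semiarid" = list(mean_temp = 9, amplitude = 14, diurnal_range = 10,
                            annual_precip = 450, wet_prob = 0.25),
    "warm-humid" = list(mean_temp = 16, amplitude = 10, diurnal_range = 8,
                        annual_precip = 1100, wet_prob = 0.45,
                        transmissivity = 0.55),
    "cold-continental" = list(mean_temp = -2, amplitude = 24,
                              diurnal_range = 10,
                              annual_precip = 420, wet_prob = 0.25),
    "custom" = list())
  defaults <- list(mean_temp = 10, amplitude = 12, diurnal_range = 10,
                   annual_precip = 500, wet_prob = 0.3, rain_shape = 0.7,
                   transmissivity = 0.6, cloud_factor = 0.45,
                   ar1_rho = 0.7, noise_sd = 2, solar_noise_sd = 0.05,
                   phase_doy = 15)
  arch <- utils::modifyList(defaults, utils::modifyList(base, list(...)))
  stopifnot(arch$wet_prob >= 0, arch$wet_prob <= 1, arch$amplitude >= 0,
            arch$diurnal_range >= 0, arch$annual_precip >= 0,
            arch$rain_shape > 0, arch$transmissivity > 0,
            arch$transmissivity <= 0.8,
            abs(arch$ar1_rho) < 1)
  arch$preset <- preset
  structure(arch, class = "climate_archetype")
}

#' Generate a synthetic daily weather series
#'
#' Daily mean temperature is `mean_temp - amplitude * cos(2 pi (doy -
#' phase_doy) / 365.25)` plus stationary AR(1) noise; minima and maxima sit
#' at half the diurnal range either side. Wet days are drawn independently
#' at `wet_prob` with gamma-distributed amounts whose scale reproduces the
#' archetype's annual total in expectation. Global radiation is the
#' top-of-atmosphere flux times the archetype transmissivity, reduced by the
#' cloud factor on wet days; PAR is half of global radiation. Fully
#' reproducible from `seed` (R's default Mersenne-Twister generator).
#'
#' @param archetype A [climate_archetype()].
#' @param years Number of calendar years, `>= 1`.
#' @param site A [site_info()] (latitude drives the radiation cycle).
#' @param seed Integer seed.
#' @param start_year First calendar year, default 2001.
#' @return A [as_daily_weather()] series.
#' @export
generate_weather <- function(archetype, years, site, seed = 1L,
                             start_year = 2001L) {
  stopifnot(inherits(archetype, "climate_archetype"), years >= 1)
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + years - 1L)),
               by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  a <- archetype
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  seasonal <- a$mean_temp - a$amplitude * cos(2 * pi * (doy - a$phase_doy) / 365.25)
  noise <- numeric(n)
  if (a$noise_sd > 0) {
    z <- stats::rnorm(n, 0, a$noise_sd * sqrt(1 - a$ar1_rho^2))
    noise[1] <- stats::rnorm(1, 0, a$noise_sd)
    for (i in 2:n) noise[i] <- a$ar1_rho * noise[i - 1] + z[i]
  }
  tmean <- seasonal + noise
  tmin <- tmean - a$diurnal_range / 2
  tmax <- tmean + a$diurnal_range / 2

  wet <- stats::runif(n) < a$wet_prob
  precip <- numeric(n)
  if (any(wet) && a$annual_precip > 0) {
    mean_amount <- a$annual_precip / (365.25 * a$wet_prob)
    precip[wet] <- stats::rgamma(sum(wet), shape = a$rain_shape,
                                 scale = mean_amount / a$rain_shape)
  }

  ra <- extraterrestrial_radiation(site$latitude, doy)
  tau <- a$transmissivity * ifelse(wet, a$cloud_factor, 1)
  if (a$solar_noise_sd > 0) {
    tau <- tau * (1 + stats::rnorm(n, 0, a$solar_noise_sd))
  }
  tau <- pmin(pmax(tau, 0.03), 0.8)
  solar <- ra * tau

  as_daily_weather(data.frame(date = dates, tmin = tmin, tmax = tmax,
                              precip = precip, solar = solar))
}

#' Textbook synthetic soil profiles
#'
#' Deterministic texture archetypes with plausible organic carbon and bulk
#' density: loam (0.40/0.40/0.20), sandy (0.65/0.25/0.10) and clay
#' (0.20/0.30/0.50).
#'
#' @param archetype `"loam"`, `"sandy"` or `"clay"`.
#' @param depth Rooted depth (mm), default 1000.
#' @return A [soil_profile()].
#' @export
generate_soil <- function(archetype = c("loam", "sandy", "clay"),
                          depth = 1000) {
  archetype <- match.arg(archetype)
  switch(archetype,
         loam = soil_profile(0.40, 0.40, 0.20, soc = 0.015,
                             bulk_density = 1.30, depth = depth),
         sandy = soil_profile(0.65, 0.25, 0.10, soc = 0.008,
                              bulk_density = 1.50, depth = depth),
         clay = soil_profile(0.20, 0.30, 0.50, soc = 0.020,
                             bulk_density = 1.25, depth = depth))
}

#' Generate a synthetic climate grid
#'
#' A small gridded stand-in for a climate cube plus co-registered soil,
#' slope and mask layers. Row 1 is the northern edge; per-row temperature
#' and precipitation offsets build north-south gradients, each cell's
#' weather is generated with its own seed derived from `seed`, and latitude
#' follows the grid's geometry.
#'
#' @param nx,ny Grid dimensions (columns, rows), `>= 1`.
#' @param base A [climate_archetype()] for the grid centre.
#' @param years Simulated calendar years per cell.
#' @param site A [site_info()] for the northern edge (row 1).
#' @param seed Integer seed; cell `(r, c)` uses `seed + (r-1)*nx + (c-1)`.
#' @param temperature_gradient Degrees C added per row moving south.
#' @param precip_gradient mm of annual precipitation added per row moving
#'   south.
#' @param res Cell size in degrees, default 0.5.
#' @param slope Slope raster (degrees): a matrix, a single value, or `NULL`
#'   for flat terrain.
#' @param mask Logical availability mask matrix; default all available.
#' @return A `climate_cube` list with `cells` (row-major list of
#'   `weather`/`site`/`soil`), `slope`, `mask` and grid geometry.
#' @export
generate_grid <- function(nx, ny, base = climate_archetype("loess-semiarid"),
                          years = 3, site = site_info(36, 108), seed = 1L,
                          temperature_gradient = 0, precip_gradient = 0,
                          res = 0.5, slope = NULL, mask = NULL) {
  stopifnot(nx >= 1, ny >= 1)
  soil <- generate_soil("loam")
  cells <- vector("list", nx * ny)
  for (r in seq_len(ny)) {
    lat <- site$latitude - (r - 1) * res
    for (c in seq_len(nx)) {
      arch <- climate_archetype(
        "custom",
        mean_temp = base$mean_temp + temperature_gradient * (r - 1),
        amplitude = base$amplitude, diurnal_range = base$diurnal_range,
        annual_precip = max(0, base$annual_precip + precip_gradient * (r - 1)),
        wet_prob = base$wet_prob, rain_shape = base$rain_shape,
        transmissivity = base$transmissivity, cloud_factor = base$cloud_factor,
        ar1_rho = base$ar1_rho, noise_sd = base$noise_sd,
        solar_noise_sd = base$solar_noise_sd, phase_doy = base$phase_doy)
      cell_site <- site_info(lat, site$longitude + (c - 1) * res,
                             site$elevation)
      cell_seed <- as.integer(seed + (r - 1) * nx + (c - 1))
      cells[[(r - 1) * nx + c]] <- list(
        weather = generate_weather(arch, years, cell_site, cell_seed),
        site = cell_site, soil = soil)
    }
  }
  if (is.null(slope)) slope <- matrix(0, ny, nx)
  if (length(slope) == 1L) slope <- matrix(slope, ny, nx)
  if (is.null(mask)) mask <- matrix(TRUE, ny, nx)
  structure(list(nx = nx, ny = ny, years = years, res = res,
                 lat0 = site$latitude, lon0 = site$longitude,
                 cells = cells, slope = slope, mask = mask,
                 base = base, seed = seed),
            class = "climate_cube")
}
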