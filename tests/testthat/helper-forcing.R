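# Shared deterministic forcings for the simulator tests.

# A noise-free "ideal" growing climate: constant temperature (frost-free),
# daily rain keeping the bucket at field capacity, constant PAR.
constant_weather <- function(tmean = 28, years = 1, precip = 10, par = 8,
                             start = "2001-01-01", diurnal = 0) {
  dates <- seq(as.Date(start), by = "day",
               length.out = round(365.25 * years))
  as_daily_weather(data.frame(
    date = dates,
    tmin = tmean - diurnal / 2,
    tmax = tmean + diurnal / 2,
    precip = precip,
    solar = 2 * par,
    pet = 3))
}

# A monotone warming spring from 1 March onward: tmean ramps linearly so the
# DD10 clock is strictly increasing once above base.
warming_spring_weather <- function(t0 = 2, ramp = 0.15, years = 1,
                                   start = "2001-01-01") {
  dates <- seq(as.Date(start), by = "day",
               length.out = round(365.25 * years))
  mar1 <- as.Date(sub("-\\d{2}-\\d{2}$", "-03-01", start))
  days_since <- pmax(0, as.numeric(dates - mar1))
  tmean <- t0 + ramp * days_since
  as_daily_weather(data.frame(
    date = dates, tmin = tmean, tmax = tmean,
    precip = 8, solar = 16, pet = 3))
}

loam <- function() generate_soil("loam")
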