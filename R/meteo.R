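#' Daily mean temperature
#'
#' Standard convention: the arithmetic mean of the daily minimum and maximum
#' air temperature.
#'
#' @param tmin Daily minimum temperature (degrees C).
#' @param tmax Daily maximum temperature (degrees C). Must satisfy
#'   `tmin <= tmax` elementwise.
#' @return Daily mean temperature (degrees C), vectorised.
#' @export
#' @examples
#' daily_mean_temperature(0, 10)
#' daily_mean_temperature(8.2, 19.6)
daily_mean_temperature <- function(tmin, tmax) {
  if (length(tmin) != length(tmax)) {
    stop("tmin and tmax must have the same length")
  }
  bad <- which(tmin > tmax)
  if (length(bad)) {
    stop("tmin exceeds tmax at position(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }
  (tmin + tmax) / 2
}

#' Cumulative degree days above a base temperature
#'
#' Thermal time driving the phenology clock: element `i` of the result is
#' `sum_{j <= i} max(0, tmean_j - base)`, so the series is non-decreasing.
#'
#' @param tmean Daily mean temperature series (degrees C), non-empty.
#' @param base Base temperature (degrees C); 10 for the physiostat clock,
#'   0 for leaf-expansion thermal time.
#' @return Cumulative degree-day series (degrees C day), same length as `tmean`.
#' @export
#' @examples
#' degree_days(c(12, 8, 15), base = 10)
degree_days <- function(tmean, base = 10) {
  if (length(tmean) == 0L) stop("tmean series is empty")
  cumsum(pmax(0, tmean - base))
}

#' Astronomical day length
#'
#' Day length from standard solar-declination geometry. Declination uses the
#' cosine approximation `delta = -23.44 * cos(2*pi*(doy + 10)/365)` degrees and
#' the sunrise hour angle `cos(h) = -tan(phi) tan(delta)`, clamped for polar
#' day/night.
#'
#' @param latitude Latitude (degrees, -90..90).
#' @param doy Day of year (1..366), vectorised.
#' @return Day length in hours, in `[0, 24]`.
#' @export
day_length <- function(latitude, doy) {
  if (any(abs(latitude) > 90)) stop("latitude must be within [-90, 90]")
  decl <- -23.44 * pi / 180 * cos(2 * pi * (doy + 10) / 365)
  x <- -tan(latitude * pi / 180) * tan(decl)
  x <- pmin(1, pmax(-1, x))
  acos(x) * 24 / pi
}

#' Extraterrestrial solar radiation
#'
#' Top-of-atmosphere daily shortwave radiation (FAO-56 eq. 21), used by the
#' reference-evapotranspiration routine and the synthetic weather generator.
#'
#' @param latitude Latitude (degrees).
#' @param doy Day of year, vectorised.
#' @return Radiation in MJ m-2 day-1.
#' @export
extraterrestrial_radiation <- function(latitude, doy) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  decl <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(decl))))
  24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
}

#' Thornthwaite potential evapotranspiration
#'
#' Monthly Thornthwaite (1948) PET with the day-length/month-length
#' correction, distributed uniformly over each month's days. The annual heat
#' index is formed from the calendar-month temperature climatology of the
#' supplied series; months at or below 0 degrees C contribute nothing and
#' receive zero PET. Monthly means above 26.5 degrees C use the Willmott
#' high-temperature polynomial.
#'
#' @param tmean Daily mean temperature series (degrees C).
#' @param dates `Date` vector parallel to `tmean`, covering at least 12
#'   distinct calendar months.
#' @param latitude Latitude (degrees) for the day-length correction.
#' @return Daily PET series (mm day-1), same length as `tmean`.
#' @export
pet_thornthwaite <- function(tmean, dates, latitude) {
  if (length(tmean) != length(dates)) stop("tmean and dates must align")
  mon <- as.integer(format(dates, "%m"))
  if (length(unique(mon)) < 12L) {
    stop("pet_thornthwaite needs at least 12 calendar months of data")
  }
  ym <- format(dates, "%Y-%m")
  # calendar-month climatology -> annual heat index
  clim <- tapply(tmean, mon, mean)
  warm <- clim[clim > 0]
  heat_index <- if (length(warm)) sum((warm / 5)^1.514) else 0
  a <- 6.75e-7 * heat_index^3 - 7.71e-5 * heat_index^2 +
    1.792e-2 * heat_index + 0.49239

  pet <- numeric(length(tmean))
  for (g in unique(ym)) {
    idx <- which(ym == g)
    tm <- mean(tmean[idx])
    ndays <- length(idx)
    if (tm <= 0 || heat_index <= 0) {
      pet[idx] <- 0
      next
    }
    pet_month <- if (tm < 26.5) {
      16 * (10 * tm / heat_index)^a
    } else {
      -415.85 + 32.24 * tm - 0.43 * tm^2
    }
    doys <- as.integer(format(dates[idx], "%j"))
    daylen <- mean(day_length(latitude, doys))
    pet_month <- pet_month * (daylen / 12) * (ndays / 30)
    pet[idx] <- max(0, pet_month) / ndays
  }
  pet
}

#' FAO-56 Penman-Monteith reference evapotranspiration
#'
#' Daily reference evapotranspiration for a well-watered clipped-grass surface
#' (FAO Irrigation and Drainage Paper 56), with soil heat flux taken as zero
#' at the daily step. Actual vapour pressure can be supplied directly (`ea`,
#' kPa) or derived from mean relative humidity (`rh`, percent).
#'
#' @param tmin,tmax Daily minimum/maximum temperature (degrees C).
#' @param solar Incoming global shortwave radiation (MJ m-2 day-1).
#' @param wind Wind speed at 2 m (m s-1).
#' @param doy Day of year.
#' @param latitude Latitude (degrees).
#' @param elevation Site elevation (m), default 0.
#' @param ea Actual vapour pressure (kPa), optional.
#' @param rh Mean relative humidity (percent), used when `ea` is missing.
#' @return Reference evapotranspiration (mm day-1), non-negative, vectorised.
#'   Signals an error of class `switchgrow_insufficient_inputs` when wind or
#'   humidity information is absent so callers can fall back to Thornthwaite.
#' @export
pet_penman_monteith <- function(tmin, tmax, solar, wind, doy, latitude,
                                elevation = 0, ea = NULL, rh = NULL) {
  if (missing(wind) || is.null(wind) || all(is.na(wind)) ||
      ((is.null(ea) || all(is.na(ea))) && (is.null(rh) || all(is.na(rh))))) {
    stop(structure(
      class = c("switchgrow_insufficient_inputs", "error", "condition"),
      list(message = "Penman-Monteith needs wind speed and humidity (rh or ea)",
           call = sys.call())
    ))
  }
  tmean <- (tmin + tmax) / 2
  svp <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  es <- (svp(tmax) + svp(tmin)) / 2
  if (is.null(ea) || all(is.na(ea))) ea <- rh / 100 * es
  delta <- 4098 * svp(tmean) / (tmean + 237.3)^2
  p_atm <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
  gamma <- 0.000665 * p_atm

  ra <- extraterrestrial_radiation(latitude, doy)
  rso <- (0.75 + 2e-5 * elevation) * ra
  rns <- (1 - 0.23) * solar
  rel <- ifelse(rso > 0, pmin(solar / rso, 1), 0)
  rnl <- 4.903e-9 * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(pmax(ea, 0))) * (1.35 * rel - 0.35)
  rn <- rns - rnl

  et0 <- (0.408 * delta * rn + gamma * 900 / (tmean + 273) * wind * (es - ea)) /
    (delta + gamma * (1 + 0.34 * wind))
  pmax(0, et0)
}

#' Photosynthetically active radiation from global radiation
#'
#' PAR as a fixed fraction of global shortwave radiation. The fraction is the
#' common crop-model convention of 0.5 and is configurable.
#'
#' @param solar Global radiation (MJ m-2 day-1), non-negative.
#' @param f_par PAR fraction of global radiation, default 0.5.
#' @return PAR (MJ m-2 day-1).
#' @export
par_from_solar <- function(solar, f_par = 0.5) {
  if (any(solar < 0, na.rm = TRUE)) stop("solar radiation must be non-negative")
  f_par * solar
}

#' Read a daily weather table
#'
#' Reads delimited text with header columns
#' `date,tmin,tmax,precip,solar[,par][,pet][,wind][,rh]` (ISO-8601 dates),
#' derives `tmean` and `par` where absent, and validates the series.
#'
#' @param path Path to a delimited text file (comma-separated by default).
#' @param sep Field separator.
#' @return A validated `daily_weather` data frame.
#' @export
read_weather <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  as_daily_weather(df)
}

#' Construct and validate a daily weather series
#'
#' Enforces the forcing contract used by the simulator: contiguous daily
#' dates without duplicates, `tmin <= tmean <= tmax`, non-negative
#' precipitation, and `par <= solar` when both are present. `tmean` and `par`
#' are derived when absent.
#'
#' @param df Data frame with at least `date`, `tmin`, `tmax`, `precip`, and
#'   one of `solar` or `par`. Optional: `pet`, `wind`, `rh`.
#' @param f_par PAR fraction used when `par` must be derived from `solar`.
#' @return The data frame with derived columns, classed `daily_weather`.
#' @export
as_daily_weather <- function(df, f_par = 0.5) {
  need <- c("date", "tmin", "tmax", "precip")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("weather is missing column(s): ", paste(miss, collapse = ", "))
  if (!inherits(df$date, "Date")) df$date <- as.Date(df$date)
  if (anyDuplicated(df$date)) stop("weather has duplicate dates")
  if (is.unsorted(df$date)) df <- df[order(df$date), , drop = FALSE]
  gaps <- diff(as.integer(df$date))
  if (any(gaps != 1L)) stop("weather series is not contiguous daily")
  if (!("solar" %in% names(df)) && !("par" %in% names(df))) {
    stop("weather needs a 'solar' or 'par' column")
  }
  if (is.null(df$tmean)) df$tmean <- daily_mean_temperature(df$tmin, df$tmax)
  if (any(df$tmin > df$tmean + 1e-9) || any(df$tmean > df$tmax + 1e-9)) {
    stop("tmin <= tmean <= tmax violated")
  }
  if (any(df$precip < 0)) stop("precipitation must be non-negative")
  if (is.null(df$par)) df$par <- par_from_solar(df$solar, f_par)
  if (!is.null(df$solar) && any(df$par > df$solar + 1e-9)) {
    stop("par must not exceed global radiation")
  }
  class(df) <- c("daily_weather", "data.frame")
  df
}

#' Site metadata
#'
#' @param latitude Latitude in degrees (-90..90).
#' @param longitude Longitude in degrees.
#' @param elevation Elevation in metres (optional).
#' @return A `site_info` list.
#' @export
site_info <- function(latitude, longitude = 0, elevation = 0) {
  if (abs(latitude) > 90) stop("latitude must be within [-90, 90]")
  structure(list(latitude = latitude, longitude = longitude,
                 elevation = elevation),
            class = "site_info")
}
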