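test_that("daily mean temperature is the tmin/tmax midpoint and rejects inversions", {
  expect_equal(daily_mean_temperature(0, 10), 5)
  expect_equal(daily_mean_temperature(-5, -5), -5)
  expect_equal(daily_mean_temperature(8.2, 19.6), 13.9)
  expect_error(daily_mean_temperature(10, 0), "tmin exceeds tmax")
})

test_that("degree days accumulate clamped excess over the base", {
  expect_equal(degree_days(c(12, 8, 15), base = 10), c(2, 2, 7))
  expect_equal(degree_days(c(12, 8, 15), base = 0), c(12, 20, 35))
  expect_equal(degree_days(c(5, 9, 10), base = 10), c(0, 0, 0))
  expect_error(degree_days(numeric(0)), "empty")
})

test_that("degree days are non-decreasing and additive over splits", {
  set.seed(42)
  tm <- rnorm(200, 12, 8)
  dd <- degree_days(tm, 10)
  expect_true(all(diff(dd) >= 0))
  for (cut in c(1, 57, 199)) {
    dd_a <- degree_days(tm[1:cut], 10)
    dd_b <- degree_days(tm[(cut + 1):200], 10)
    expect_equal(dd_a[cut] + dd_b[200 - cut], dd[200])
  }
})

test_that("day length follows sunrise-angle geometry", {
  # equator: about 12 h year-round
  expect_true(all(abs(day_length(0, 1:365) - 12) < 0.2))
  # 40 N at the June solstice: independent evaluation of
  # cos(h) = -tan(phi) tan(delta), delta = -23.44 cos(2 pi (172+10)/365)
  delta <- -23.44 * pi / 180 * cos(2 * pi * 182 / 365)
  expected <- acos(-tan(40 * pi / 180) * tan(delta)) * 24 / pi
  expect_equal(day_length(40, 172), expected, tolerance = 1e-12)
  expect_equal(day_length(40, 172), 14.9, tolerance = 0.01)
  # polar day and night
  expect_equal(day_length(70, 172), 24)
  expect_equal(day_length(70, 355), 0)
  expect_error(day_length(95, 100), "latitude")
})

test_that("day length is hemispherically and seasonally antisymmetric", {
  for (phi in c(10, 35, 55)) {
    for (d in c(20, 100, 200, 300)) {
      # opposite hemisphere, same day: exactly complementary
      expect_equal(day_length(phi, d) + day_length(-phi, d), 24,
                   tolerance = 1e-9)
      # same hemisphere, half a year later: complementary within the
      # declination approximation
      expect_lt(abs(day_length(phi, d) +
                    day_length(phi, (d + 182) %% 365) - 24), 0.3)
    }
  }
})

test_that("Thornthwaite PET matches a hand evaluation and clamps cold months", {
  dates <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), 1)
  # all-frozen year
  expect_equal(pet_thornthwaite(rep(-3, length(dates)), dates, 45),
               rep(0, length(dates)))
  # one warm month among cold: closed-form check of I, a, monthly PET
  tm <- ifelse(format(dates, "%m") == "07", 20, -5)
  pet <- pet_thornthwaite(tm, dates, 0)
  july <- format(dates, "%m") == "07"
  expect_true(all(pet[!july] == 0))
  I <- (20 / 5)^1.514
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  L <- mean(day_length(0, as.integer(format(dates[july], "%j"))))
  expected_month <- 16 * (10 * 20 / I)^a * (L / 12) * (31 / 30)
  expect_equal(sum(pet[july]), expected_month, tolerance = 1e-9)
  # constant warm tropics: equal monthly rates
  pet2 <- pet_thornthwaite(rep(20, length(dates)), dates, 0)
  daily_rates <- tapply(pet2, format(dates, "%m"), unique)
  expect_true(all(unlist(daily_rates) > 0))
  expect_lt(diff(range(unlist(daily_rates))) /
            mean(unlist(daily_rates)), 0.12)  # month length + day length only
  expect_error(pet_thornthwaite(rep(10, 100), dates[1:100], 0), "12 calendar months")
})

test_that("Penman-Monteith reproduces the published reference-day value", {
  # mid-latitude summer day: Tmax 21.5, Tmin 12.3, Rs 22.07 MJ, u2 2.78 m/s,
  # ea 1.409 kPa, 50.8 N at 100 m -> about 3.9 mm reference ET
  et0 <- pet_penman_monteith(12.3, 21.5, 22.07, 2.78, 187, 50.80, 100,
                             ea = 1.409)
  expect_equal(et0, 3.9, tolerance = 0.03)
  # no driving gradient: saturated still air, no shortwave; only the small
  # clear-sky longwave artifact remains
  calm <- pet_penman_monteith(15, 15, 0, 0, 100, 40, 0, rh = 100)
  expect_lt(calm, 0.5)
  # purity
  expect_identical(
    pet_penman_monteith(12.3, 21.5, 22.07, 2.78, 187, 50.80, 100, ea = 1.409),
    et0)
  expect_error(pet_penman_monteith(12.3, 21.5, 22.07, wind = NULL, doy = 187,
                                   latitude = 50.8),
               class = "switchgrow_insufficient_inputs")
})

test_that("both PET methods are non-negative over random forcing", {
  set.seed(11)
  dates <- seq(as.Date("2001-01-01"), as.Date("2002-12-31"), 1)
  doy <- as.integer(format(dates, "%j"))
  tm <- 10 - 14 * cos(2 * pi * (doy - 15) / 365) + rnorm(length(dates), 0, 3)
  expect_true(all(pet_thornthwaite(tm, dates, 40) >= 0))
  et0 <- pet_penman_monteith(tm - 5, tm + 5, pmax(0, rnorm(length(dates), 15, 5)),
                             runif(length(dates), 0.5, 6), doy, 40, 200,
                             rh = runif(length(dates), 30, 95))
  expect_true(all(et0 >= 0))
})

test_that("PAR scales from global radiation by the configured fraction", {
  expect_equal(par_from_solar(0), 0)
  expect_equal(par_from_solar(20), 10)
  expect_equal(par_from_solar(20, f_par = 0.45), 9)
  expect_error(par_from_solar(-1), "non-negative")
})

test_that("weather reader derives columns and enforces the series contract", {
  df <- data.frame(date = seq(as.Date("2001-01-01"), by = "day", length.out = 10),
                   tmin = 5, tmax = 15, precip = 1, solar = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  w <- read_weather(path)
  expect_s3_class(w, "daily_weather")
  expect_equal(w$tmean, rep(10, 10))
  expect_equal(w$par, rep(10, 10))

  gap <- df[-5, ]
  expect_error(as_daily_weather(gap), "contiguous")
  dup <- rbind(df, df[1, ])
  expect_error(as_daily_weather(dup), "duplicate")
  neg <- df; neg$precip[2] <- -1
  expect_error(as_daily_weather(neg), "non-negative")
  toohigh <- df; toohigh$par <- 25
  expect_error(as_daily_weather(toohigh), "exceed")
})
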