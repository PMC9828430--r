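test_that("genotype defaults carry the ecotype parameter registry", {
  low <- genotype_defaults("lowland")
  up <- genotype_defaults("upland")
  expect_equal(low$dd_stage, c(105, 168, 1174, 1566, 1694))
  expect_equal(up$dd_stage, c(80, 125, 1085, 1395, 1488))
  expect_equal(low$lai_max, 12)
  expect_equal(low$rue_max, 5.05)
  expect_equal(low$t_opt, 28)
  expect_equal(low$t_kill, -23.3)
  expect_equal(up$lai_max, 7)
  expect_equal(up$rue_max, 3.19)
  expect_equal(up$t_opt, 23)
  expect_equal(up$t_kill, -34.4)
  expect_equal(low$k, 0.36)
  expect_equal(up$k, 0.36)
  expect_equal(low$harvest_ratio, 0.832)
  expect_error(genotype_defaults("alpine"))
  # overrides validate
  expect_equal(genotype_params(low, rue_max = 4.7)$rue_max, 4.7)
  expect_error(genotype_params(low, nonsense = 1), "unknown")
  expect_error(genotype_params(low, psi_stop_lai = -5000), "anchors")
})

test_that("a no-stress constant season matches an independent re-accumulation", {
  g <- genotype_defaults("lowland")
  w <- constant_weather(tmean = 28, years = 2, precip = 10, par = 8)
  sim <- run_site(w, site_info(35), loam(), g)
  expect_equal(nrow(sim$annual), 1L)

  # straight-line oracle: replay the daily rules with plain arithmetic
  dd10 <- 0; lai <- 0; peak_lai <- 0; stage <- 0L; dm <- 0; peak <- NA
  for (j in 1:365) {
    dd10 <- dd10 + 18          # 28 C -> 18 degree days over base 10
    repeat {
      if (stage == 0L && dd10 >= 105) stage <- 1L
      else if (stage == 1L && dd10 >= 168) stage <- 2L
      else if (stage == 2L && (dd10 >= 1174 || lai >= 12)) stage <- 3L
      else if (stage == 3L && dd10 >= 1566) { stage <- 4L; peak <- dm }
      else if (stage == 4L && dd10 >= 1694) stage <- 5L
      else break
    }
    if (stage %in% 1:2) {
      lai <- min(12, lai + 0.004 * 28)
      peak_lai <- max(peak_lai, lai)
    } else if (stage %in% 3:4) {
      lai <- max(0, lai - 0.03 * peak_lai)
    } else lai <- 0
    if (stage %in% 2:3) dm <- dm + 5.05 * (1 - exp(-0.36 * lai)) * 8 * 0.01
  }
  expect_equal(sim$annual$peak_dm, peak, tolerance = 1e-9)
  expect_equal(sim$annual$yield, 0.832 * peak, tolerance = 1e-9)

  # daily trajectory reaches the same peak
  expect_equal(max(sim$daily$dm), peak, tolerance = 1e-9)
})

test_that("identical runs are bit-identical and cold climates stay dormant", {
  g <- genotype_defaults("lowland")
  w <- constant_weather(tmean = 28, years = 1)
  a <- run_site(w, site_info(35), loam(), g)
  b <- run_site(w, site_info(35), loam(), g)
  expect_identical(a$daily, b$daily)
  expect_identical(a$annual, b$annual)

  w5 <- constant_weather(tmean = 5, years = 2)
  cold <- run_site(w5, site_info(35), loam(), g)
  expect_true(all(cold$daily$stage == 0))
  expect_equal(cold$annual$yield, 0)
})

test_that("every unkilled season harvests the repartition ratio of its peak", {
  g <- genotype_defaults("lowland")
  w <- generate_weather(climate_archetype("warm-humid"), 6, site_info(34),
                        seed = 19)
  sim <- run_site(w, site_info(34), loam(), g)
  clean <- sim$annual[sim$annual$kill == "none" & !sim$annual$replant, ]
  expect_gt(nrow(clean), 2)
  expect_equal(clean$yield, 0.832 * clean$peak_dm, tolerance = 1e-12)
  expect_true(all(sim$annual$yield <= sim$annual$peak_dm + 1e-12))
})

test_that("water balance closes to machine precision over a multi-year run", {
  g <- genotype_defaults("lowland")
  s <- site_info(36, 108)
  w <- generate_weather(climate_archetype("loess-semiarid"), 3, s, seed = 4)
  sim <- run_site(w, s, loam(), g)
  d <- sim$daily
  resid <- sum(as.data.frame(w)$precip) - sum(d$aet) - sum(d$drainage) -
    (d$swc[nrow(d)] - sim$meta$init_swc)
  expect_lt(abs(resid), 1e-9)
  expect_true(all(d$aet <= d$pet + 1e-12))
})

test_that("warm-wet climates favour lowland; lethal winters kill only lowland", {
  s <- site_info(34, 108)
  warm <- generate_weather(climate_archetype("warm-humid"), 4, s, seed = 7)
  low <- run_site(warm, s, loam(), genotype_defaults("lowland"))
  up <- run_site(warm, s, loam(), genotype_defaults("upland"))
  expect_gt(mean_annual_yield(low), mean_annual_yield(up))

  sc <- site_info(41, 108)
  coldw <- generate_weather(climate_archetype("cold-continental"), 3, sc,
                            seed = 3)
  # the synthetic winters exceed 60 days below -24 C
  wd <- as.data.frame(coldw)
  mth <- as.integer(format(wd$date, "%m"))
  yrs <- as.integer(format(wd$date, "%Y"))
  first_winter <- (yrs == 2001 & mth %in% c(11, 12)) | (yrs == 2002 & mth %in% 1:2)
  expect_gt(sum(wd$tmin[first_winter] < -24), 60)

  low_c <- run_site(coldw, sc, loam(), genotype_defaults("lowland"))
  up_c <- run_site(coldw, sc, loam(), genotype_defaults("upland"))
  expect_true(all(low_c$annual$kill == "winter_kill"))
  expect_equal(mean_annual_yield(low_c), 0)
  expect_true(all(up_c$annual$kill == "none"))
  expect_gt(mean_annual_yield(up_c), 0)
})

test_that("mean annual yield applies the documented kill and replant policy", {
  fake <- structure(list(annual = data.frame(
    year = 2001:2004,
    peak_dm = c(12, 0, 10, 16),
    yield = c(10, 0, 0, 14),
    kill = c("none", "winter_kill", "none", "none"),
    establishment = c(TRUE, FALSE, TRUE, FALSE),
    replant = c(FALSE, FALSE, TRUE, FALSE))),
    class = "site_simulation")
  # kill-year zero included; replant establishment year excluded
  expect_equal(mean_annual_yield(fake), mean(c(10, 0, 14)))
  expect_equal(mean_annual_yield(fake, period = 2001:2002), 5)
  expect_equal(mean_annual_yield(fake, include_establishment = FALSE),
               mean(c(0, 14)))
  expect_error(mean_annual_yield(fake, period = 2050), "no seasons")
})

test_that("PET method selection follows column availability", {
  s <- site_info(40, 0)
  base <- as.data.frame(constant_weather(tmean = 15, years = 1))
  base$pet <- NULL
  th <- run_site(as_daily_weather(base), s, loam(), genotype_defaults("upland"))
  expect_equal(th$meta$pet_method, "thornthwaite")
  pm <- base
  pm$wind <- 2; pm$rh <- 60
  got <- run_site(as_daily_weather(pm), s, loam(), genotype_defaults("upland"))
  expect_equal(got$meta$pet_method, "penman_monteith")
  supplied <- run_site(constant_weather(tmean = 15, years = 1), s, loam(),
                       genotype_defaults("upland"))
  expect_equal(supplied$meta$pet_method, "supplied")
})

test_that("a ten-year single-site run completes quickly", {
  g <- genotype_defaults("lowland")
  s <- site_info(36, 108)
  w <- generate_weather(climate_archetype("loess-semiarid"), 10, s, seed = 12)
  elapsed <- system.time(run_site(w, s, loam(), g))[["elapsed"]]
  expect_lt(elapsed, 5)
})
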