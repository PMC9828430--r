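test_that("optimal map equals a brute-force per-cell maximum", {
  set.seed(21)
  mkmat <- function() {
    m <- matrix(runif(2500, 0, 25), 50, 50)
    m[runif(2500) < 0.15] <- NA
    m
  }
  u <- yield_raster(mkmat()); l <- yield_raster(mkmat())
  opt <- optimal_map(u, l)

  # brute-force oracle loop
  ref <- matrix(NA_real_, 50, 50); lab <- matrix(NA_real_, 50, 50)
  for (r in 1:50) for (c in 1:50) {
    uv <- u$values[r, c]; lv <- l$values[r, c]
    if (is.na(uv) && is.na(lv)) next
    if (is.na(lv) || (!is.na(uv) && uv >= lv)) {   # ties -> upland
      ref[r, c] <- uv; lab[r, c] <- 0
    } else {
      ref[r, c] <- lv; lab[r, c] <- 1
    }
  }
  expect_equal(opt$values, ref)
  expect_equal(opt$ecotype, lab)

  # cellwise max dominates each ecotype's total
  tot <- function(x) aggregate_totals(x, 100)$total_Tg
  expect_gte(tot(opt), tot(u))
  expect_gte(tot(opt), tot(l))
})

test_that("optimal map handles NoData passthrough and ties", {
  u <- yield_raster(matrix(c(5, NA), 1, 2))
  l <- yield_raster(matrix(c(20, 10), 1, 2))
  opt <- optimal_map(u, l)
  expect_equal(opt$values, matrix(c(20, 10), 1, 2))
  expect_equal(opt$ecotype, matrix(c(1, 1), 1, 2))
  tie <- optimal_map(yield_raster(matrix(7)), yield_raster(matrix(7)))
  expect_equal(tie$ecotype, matrix(0))            # tie -> upland
  both_na <- optimal_map(yield_raster(matrix(NA_real_)),
                         yield_raster(matrix(NA_real_)))
  expect_true(is.na(both_na$values))
  expect_error(optimal_map(u, yield_raster(matrix(1, 2, 2))), "match")
})

test_that("slope masking is strict at the limit and mask composes", {
  v <- yield_raster(matrix(10, 2, 2))
  slope <- matrix(c(15.0, 15.1, 0, 30), 2, 2)
  out <- apply_mask(v, matrix(TRUE, 2, 2), slope)
  expect_equal(is.na(out$values), matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
  # empty mask wipes everything; full mask over flat terrain is identity
  expect_true(all(is.na(apply_mask(v, matrix(FALSE, 2, 2))$values)))
  expect_equal(apply_mask(v, matrix(TRUE, 2, 2), matrix(0, 2, 2))$values,
               v$values)
  # masking never increases the total
  set.seed(9)
  y <- yield_raster(matrix(runif(100, 0, 20), 10, 10))
  m <- matrix(runif(100) < 0.5, 10, 10)
  expect_lte(aggregate_totals(apply_mask(y, m), 50)$total_Tg,
             aggregate_totals(y, 50)$total_Tg)
})

test_that("aggregation matches brute-force summation and handles empties", {
  one <- aggregate_totals(yield_raster(matrix(20)), 100)
  expect_equal(one$total_Tg, 0.002)
  expect_equal(one$weighted_mean, 20)
  empty <- aggregate_totals(yield_raster(matrix(NA_real_, 2, 2)), 100)
  expect_equal(empty$total_Tg, 0)
  expect_equal(empty$area_Mha, 0)
  expect_true(is.na(empty$weighted_mean))
  set.seed(33)
  v <- matrix(runif(400, 0, 30), 20, 20); v[runif(400) < 0.2] <- NA
  a <- matrix(runif(400, 50, 150), 20, 20)
  got <- aggregate_totals(yield_raster(v), a)
  # brute force
  tot <- 0; ar <- 0
  for (i in seq_along(v)) if (!is.na(v[i])) {
    tot <- tot + v[i] * a[i]; ar <- ar + a[i]
  }
  expect_equal(got$total_Tg, tot * 1e-6)
  expect_equal(got$weighted_mean, tot / ar)
  expect_equal(got$area_Mha, ar / 1e6)
  # permutation invariance
  p <- sample(400)
  expect_equal(aggregate_totals(yield_raster(matrix(v[p], 20, 20)),
                                matrix(a[p], 20, 20))$total_Tg,
               got$total_Tg)
})

test_that("geographic cell areas follow the cosine rule", {
  # hand-computed: 0.5 deg cell at the equator
  expect_equal(geographic_cell_area(0, 0.5), (111320 * 0.5)^2 / 1e4)
  expect_equal(geographic_cell_area(60, 0.5),
               (111320 * 0.5)^2 * cos(pi / 3) / 1e4)
  expect_lt(geographic_cell_area(60, 0.5), geographic_cell_area(0, 0.5))
})

test_that("uniform grids reproduce the single-site result; gradients order yields", {
  s <- site_info(36, 108)
  arch <- climate_archetype("warm-humid")
  cube <- generate_grid(2, 2, base = arch, years = 2, site = s, seed = 5,
                        res = 0)         # res 0: identical latitude per row
  g <- genotype_defaults("lowland")
  yr <- run_grid(cube, g)
  # same seed per cell would differ; cells share climate statistics but not
  # noise, so compare against per-cell single-site runs instead
  for (r in 1:2) for (c in 1:2) {
    cell <- cube$cells[[(r - 1) * 2 + c]]
    expect_equal(yr$values[r, c],
                 mean_annual_yield(run_site(cell$weather, cell$site,
                                            cell$soil, g)))
  }
})

test_that("cells with lethal winters become NoData for lowland only", {
  s <- site_info(41, 108)
  cube <- generate_grid(1, 2, base = climate_archetype("cold-continental"),
                        years = 2, site = s, seed = 3,
                        temperature_gradient = 20)
  # row 1 keeps the severe winters; row 2 is 20 C warmer and benign
  low <- run_grid(cube, genotype_defaults("lowland"))
  up <- run_grid(cube, genotype_defaults("upland"))
  expect_true(is.na(low$values[1, 1]))
  expect_false(is.na(low$values[2, 1]))
  expect_true(all(!is.na(up$values)))
})

test_that("ASCII grid round-trips values, NoData and geometry", {
  set.seed(14)
  v <- matrix(runif(12, 0, 20), 3, 4); v[2, 2] <- NA
  y <- yield_raster(v, lat0 = 38, lon0 = 106, res = 0.5)
  path <- withr::local_tempfile(fileext = ".asc")
  write_yield_raster(y, path)
  back <- read_yield_raster(path)
  expect_equal(back$values, v, tolerance = 1e-6)
  expect_equal(back$lat0, 38)
  expect_equal(back$lon0, 106)
  expect_equal(back$res, 0.5)
})
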