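make_cells <- function(n = 30, lapse = -0.006, warm = 1.2, noise = 0,
                       seed = 1, t0 = 22) {
  generate_climate(climate_scenario(n_cells = n, lapse_C_per_m = lapse,
                                    warming_C = warm, noise_sd_C = noise,
                                    seed = seed, t0_C = t0))
}

test_that("decadal means average the years present and flag gaps", {
  s <- data.frame(cell_id = "c1", year = 2001:2010, t_mean_C = 1:10)
  expect_equal(decadal_mean(s, c(2001, 2010))$t_mean_C, 5.5)
  s2 <- data.frame(cell_id = "c1", year = 2001:2010, t_mean_C = 7)
  expect_equal(decadal_mean(s2, c(2001, 2010))$t_mean_C, 7)
  # 3 of 10 years missing: mean over the 7 present, flagged
  s3 <- s[s$year <= 2007, ]
  out <- decadal_mean(s3, c(2001, 2010))
  expect_equal(out$t_mean_C, 4)
  expect_equal(out$n_years, 7L)
  # cell entirely outside the decade is excluded with a report
  s4 <- rbind(s, data.frame(cell_id = "c2", year = 1950, t_mean_C = 1))
  expect_warning(out4 <- decadal_mean(s4, c(2001, 2010)), "excluded")
  expect_equal(attr(out4, "excluded_cells"), "c2")
})

test_that("paired period test: uniform offset, df = cells - 1, one-sample identity", {
  cells <- make_cells(n = 356, warm = 1.2, noise = 0)
  res <- paired_period_test(cells, "mean")
  expect_equal(res$mean_diff_C, 1.2, tolerance = 1e-12)
  expect_equal(res$df, 355)
  expect_true(res$p_value < 1e-100 || !is.finite(res$statistic))
  # with noise: agreement with the one-sample t on differences to 1e-12
  cells <- make_cells(n = 80, warm = 2.1, noise = 0.3, seed = 4)
  res <- paired_period_test(cells, "mean")
  h <- cells[cells$period == "historical", ]
  m <- cells[cells$period == "modern", ]
  tt <- t.test(m$t_mean_C[match(h$cell_id, m$cell_id)] - h$t_mean_C)
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  # unmatched cells are named
  expect_error(paired_period_test(cells[-1, ], "mean"), "c0001")
})

test_that("warming trend: exact slope on a line, total change over the span", {
  s <- data.frame(year = 1900:2006, value = 5 + 0.02 * (1900:2006 - 1900))
  res <- warming_trend(s)
  expect_equal(res$slope_C_per_year, 0.02, tolerance = 1e-12)
  expect_equal(res$total_change_C, 0.02 * 106, tolerance = 1e-9)
  expect_error(warming_trend(data.frame(year = 1:5, value = 1:5)), "10")
  # white noise: slope centred on zero
  set.seed(11)
  sl <- replicate(300, warming_trend(
    data.frame(year = 1950:2000, value = rnorm(51)))$slope_C_per_year)
  expect_lt(abs(mean(sl)), 3 * sd(sl) / sqrt(300))
})

test_that("displacement: noiseless grid gives delta-T over lapse exactly", {
  cells <- make_cells(n = 50, lapse = -0.006, warm = 1.2, noise = 0)
  res <- equivalent_elevation(cells, "mean")
  expect_equal(res$displacement_mean_m, 200, tolerance = 1e-9)
  expect_equal(res$displacement_sd_m, 0, tolerance = 1e-9)
  expect_equal(res$lapse_C_per_m, -0.006, tolerance = 1e-9)
  # isotherm-matching reconstruction agrees on the noiseless grid
  res2 <- equivalent_elevation(cells, "mean", method = "isotherm_match")
  expect_equal(res2$displacement_mean_m, 200, tolerance = 1e-9)
  # invariant to adding a constant to all temperatures
  shifted <- cells
  shifted[c("t_min_C", "t_mean_C", "t_max_C")] <-
    shifted[c("t_min_C", "t_mean_C", "t_max_C")] + 7
  res3 <- equivalent_elevation(shifted, "mean")
  expect_equal(res3$displacement_mean_m, res$displacement_mean_m,
               tolerance = 1e-9)
  # no gradient is an error
  flat <- cells
  flat$t_mean_C <- 10 + 1.2 * (flat$period == "modern")
  expect_error(equivalent_elevation(flat, "mean"), "gradient")
})

test_that("displacement under noise stays within the delta-method tolerance", {
  cells <- make_cells(n = 400, lapse = -0.006, warm = 1.2, noise = 0.2,
                      seed = 31)
  res <- equivalent_elevation(cells, "mean")
  # SE of the mean displacement, propagating lapse-slope and mean-dT noise
  m <- cells[cells$period == "modern", ]
  fit <- summary(lm(t_mean_C ~ elevation_m, data = m))
  b <- fit$coefficients["elevation_m", "Estimate"]
  se_b <- fit$coefficients["elevation_m", "Std. Error"]
  se_dt <- sqrt(2) * 0.2 / sqrt(400)
  se_disp <- sqrt((se_dt / abs(b))^2 + (1.2 * se_b / b^2)^2)
  expect_lt(abs(res$displacement_mean_m - 200), 3 * se_disp)
})

test_that("occupied climate ranges: identical samples accept, separated samples reject", {
  cells <- make_cells(n = 60, warm = 0, noise = 0)
  occ <- rbind(make_records("a", "historical", seq(1400, 1850, 50)),
               make_records("a", "modern", seq(1400, 1850, 50)))
  res <- occupied_climate_test(occ, cells)
  expect_lt(res$statistic, 0.05)
  expect_gt(res$p_value, 0.9)
  expect_equal(res$mean_diff_C, 0, tolerance = 1e-9)
  # 3 degree warming with no overlap: p < 0.001 at n = 10 per period
  cells <- make_cells(n = 60, warm = 3, noise = 0)
  res <- occupied_climate_test(occ, cells)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$mean_diff_C, 3, tolerance = 1e-9)
  expect_equal(res$n_hist, 10)
  # nearest-cell mode warns outside the grid's elevation hull
  occ2 <- rbind(make_records("a", "historical", c(2900, 2950)),
                make_records("a", "modern", c(2900, 2950)))
  w <- capture_warnings(occupied_climate_test(occ2, cells, mode = "nearest"))
  expect_match(w, "hull", all = TRUE)
  expect_length(w, 2)  # one per period
})

test_that("land-use change: hand-computed chi-square and period symmetry", {
  grid <- data.frame(
    cell_id = sprintf("g%02d", 1:60), elevation_m = 1200,
    period = rep(c("historical", "modern"), each = 30),
    landuse_class = c(rep("forest", 20), rep("grass", 10),
                      rep("forest", 10), rep("grass", 20)))
  res <- landuse_change_test(grid, list(c(1000, 1400)))
  expect_equal(res$chi2, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1)
  # symmetric under period exchange
  swapped <- grid
  swapped$period <- ifelse(grid$period == "historical", "modern", "historical")
  expect_equal(landuse_change_test(swapped, list(c(1000, 1400)))$chi2,
               res$chi2, tolerance = 1e-12)
  # identical counts: chi-square exactly 0
  same <- grid
  same$landuse_class <- rep(c(rep("forest", 20), rep("grass", 10)), 2)
  expect_equal(landuse_change_test(same, list(c(1000, 1400)))$chi2, 0)
  # df drops classes absent from both periods; zone with one period errors
  expect_error(landuse_change_test(grid[grid$period == "modern", ],
                                   list(c(1000, 1400))), "only one period")
  # three zones, three classes: df = 2 per zone
  zones <- list(c(1000, 1400), c(1400, 1800), c(1800, 2200))
  props <- lapply(1:3, function(z)
    list(historical = c(forest = 0.2, grassland = 0.6, other = 0.2),
         modern = c(forest = 0.5, grassland = 0.4, other = 0.1)))
  g <- generate_landuse(zones, props, 80, seed = 5)
  res3 <- landuse_change_test(g, zones)
  expect_equal(nrow(res3), 3L)
  expect_equal(res3$df, rep(2, 3))
})
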