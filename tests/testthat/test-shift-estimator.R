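test_that("equal per-bin counts are kept in full, with no randomness", {
  occ <- rbind(
    make_records("a", "historical", c(1010, 1050, 1090, 1130, 1170)),
    make_records("a", "modern", c(1020, 1060, 1100, 1140, 1180)))
  sch <- bin_scheme(1000, 1200, 200)
  bal <- balanced_replicate(occ, sch)
  expect_equal(nrow(bal), 10L)
  expect_identical(sort(bal$record_id), sort(occ$record_id))
})

test_that("a bin present in only one period contributes nothing", {
  occ <- rbind(
    make_records("a", "historical", c(1050, 1150, 1250)),
    make_records("a", "modern", c(1100)))
  sch <- bin_scheme(1000, 1400, 200)
  set.seed(1)
  bal <- balanced_replicate(occ, sch)
  expect_false(1250 %in% bal$elevation_m)   # bin 2 has no modern records
  expect_equal(sum(bal$period == "historical"), 1L)
  expect_equal(sum(bal$period == "modern"), 1L)
})

test_that("balancing conservation: equal period counts in every bin of every replicate", {
  occ <- generate_resurvey(recovery_scenario(2, n_species = 4,
                                             n_per_period = 60))
  sch <- bin_scheme(1000, 3000, 200)
  set.seed(42)
  for (r in 1:20) {
    bal <- balanced_replicate(occ, sch)
    tab <- table(assign_bin(bal$elevation_m, sch), bal$period)
    expect_true(all(tab[, "historical"] == tab[, "modern"]))
  }
})

test_that("two-record bin: each historical record kept with probability 1/2", {
  occ <- rbind(make_records("a", "historical", c(1050, 1150)),
               make_records("a", "modern", 1100))
  sch <- bin_scheme(1000, 1200, 200)
  set.seed(7)
  kept <- replicate(2000, balanced_replicate(occ, sch)$elevation_m[1])
  expect_true(all(kept %in% c(1050, 1150)))
  expect_lt(abs(mean(kept == 1050) - 0.5), 0.05)
  # and the estimator's average difference converges to 0 (+/-50 with equal
  # probability): binomial tail puts |mean| < 5 m for virtually all seeds
  est <- estimate_shifts(occ, sch, taxa = "a", n_replicates = 1000, seed = 3,
                         min_per_period = 1)
  expect_lt(abs(est$shift_m), 5)
  expect_equal(est$n_replicates_used, 1000L)
})

test_that("identical period record sets give exactly zero shift and zero spread", {
  elev <- c(1025, 1100, 1340, 1600, 1610, 1980, 2150)
  occ <- rbind(make_records(c("a", "a", "a", "b", "b", "b", "b"),
                            "historical", elev),
               make_records(c("a", "a", "a", "b", "b", "b", "b"),
                            "modern", elev))
  est <- estimate_shifts(occ, bin_scheme(1000, 2200), n_replicates = 50,
                         seed = 1)
  expect_identical(est$shift_m, c(0, 0))
  expect_identical(est$replicate_sd, c(0, 0))
  expect_equal(est$mean_hist, est$mean_mod)
})

test_that("estimates are reproducible to the last bit under a fixed seed", {
  occ <- generate_resurvey(recovery_scenario(6, n_species = 5,
                                             n_per_period = 50))
  sch <- bin_scheme(1000, 3000, 200)
  a <- estimate_shifts(occ, sch, n_replicates = 100, seed = 99)
  b <- estimate_shifts(occ, sch, n_replicates = 100, seed = 99)
  expect_identical(a, b)
})

test_that("species absent from a period is undefined, not silently zero", {
  occ <- rbind(make_records("a", "historical", c(1050, 1100)),
               make_records("a", "modern", c(1060, 1120)),
               make_records("z", "historical", c(2150, 2180)))
  sch <- bin_scheme(1000, 2200, 200)
  expect_warning(
    est <- estimate_shifts(occ, sch, taxa = c("a", "z"), n_replicates = 20,
                           seed = 2),
    "undefined")
  expect_true(is.na(est$shift_m[est$taxon == "z"]))
  expect_equal(est$n_replicates_skipped[est$taxon == "z"], 20L)
  expect_false(is.na(est$shift_m[est$taxon == "a"]))
})

test_that("estimator matches exhaustive enumeration on small instances", {
  # every bin's larger period has <= 4 records: enumerate all balanced
  # subsets and compare the Monte-Carlo mean within 3 MC standard errors
  set.seed(12)
  occ <- rbind(
    make_records(sample(c("a", "b"), 7, TRUE), "historical",
                 runif(7, 1000, 1399)),
    make_records(sample(c("a", "b"), 6, TRUE), "modern",
                 runif(6, 1000, 1399)))
  sch <- bin_scheme(1000, 1400, 200)
  taxa <- filter_shared_species(occ, 1)
  exact <- enum_balanced_expectation(occ, sch, taxa)
  est <- estimate_shifts(occ, sch, taxa = taxa, n_replicates = 4000, seed = 5,
                         min_per_period = 1)
  for (tx in taxa) {
    i <- which(est$taxon == tx)
    mc_se <- est$replicate_sd[i] / sqrt(est$n_replicates_used[i])
    expect_lt(abs(est$shift_m[i] - exact[tx]), 3 * mc_se + 1e-9)
  }
})

test_that("estimator is consistent on interior species as n grows", {
  # community whose joint support covers every species in both periods
  for (n in c(50, 500)) {
    set.seed(n)
    sp <- data.frame(name = sprintf("s%d", 1:6), group = "bee",
                     true_mean_hist_m = seq(1600, 2100, length.out = 6),
                     true_shift_m = runif(6, -60, 60), niche_sd_m = 100,
                     abundance_weight = n)
    occ <- generate_resurvey(resurvey_scenario(sp, bin_scheme(1000, 3000),
                                               seed = n + 1))
    est <- estimate_shifts(occ, bin_scheme(1000, 3000),
                           n_replicates = 400, seed = 1)
    err <- est$shift_m - sp$true_shift_m[match(est$taxon, sp$name)]
    tol <- 3 * sqrt(raw_diff_se(occ, est$taxon)^2 + est$replicate_sd^2) + 5
    expect_true(all(abs(err) < tol),
                info = sprintf("n = %d, max err %.1f", n, max(abs(err))))
  }
})

test_that("overall test: normal shifts use t with df = n - 1 and a CI bracketing the mean", {
  set.seed(8)
  est <- data.frame(shift_m = rnorm(12, 120, 80))
  res <- overall_shift_test(est)
  expect_equal(res$test_used, "t_one_sample")
  expect_equal(res$df, 11)
  expect_gte(res$normality_p, 0.05)
  expect_true(res$ci95[1] <= res$mean_shift_m &&
                res$mean_shift_m <= res$ci95[2])
  tt <- t.test(est$shift_m)
  expect_equal(res$statistic, unname(tt$statistic))
  expect_equal(res$p_value, tt$p.value)
})

test_that("overall test: skewed shifts fall back to the signed-rank branch", {
  set.seed(3)
  x <- c(rexp(12, 1 / 50), 900, 1200, 1500)   # heavy right tail
  res <- overall_shift_test(data.frame(shift_m = x))
  expect_equal(res$test_used, "wilcoxon_signed_rank")
  expect_lt(res$normality_p, 0.05)
  wt <- suppressWarnings(wilcox.test(x, mu = 0, conf.int = TRUE))
  expect_equal(res$statistic, unname(wt$statistic))
})

test_that("overall test: degenerate and undersized inputs are handled", {
  res <- overall_shift_test(data.frame(shift_m = rep(100, 5)))
  expect_equal(res$mean_shift_m, 100)
  expect_equal(res$ci95, c(100, 100))
  expect_true(res$p_floor)
  expect_error(overall_shift_test(data.frame(shift_m = c(1, 2))),
               "at least 3")
})
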