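test_that("bundled datasets parse with the documented record counts", {
  d1 <- load_dataset("dataset1")
  expect_length(d1$time, 121)
  expect_equal(sum(d1$status == 0L), 53)   # starred entries as printed
  g1 <- load_dataset("dataset2_group1")
  expect_length(g1$time, 51)
  expect_equal(sum(g1$status == 0L), 9)
  g2 <- load_dataset("dataset2_group2")
  expect_length(g2$time, 45)
  expect_equal(sum(g2$status == 0L), 15)
  pooled <- load_dataset("dataset2")
  expect_length(pooled$time, 96)
  expect_equal(sum(pooled$status == 0L), 24)
  expect_error(load_dataset("nope"))
})

test_that("descriptive statistics reproduce the published summaries", {
  s1 <- descriptive_stats(load_dataset("dataset1"))
  expect_equal(s1$mean, 32.30, tolerance = 0.005)
  expect_equal(s1$median, 22.05, tolerance = 0.005)
  expect_equal(s1$variance, 772.21, tolerance = 0.01)
  expect_equal(s1$sd, 27.79, tolerance = 0.005)
  expect_equal(s1$skewness, 1.68, tolerance = 0.005)
  expect_equal(s1$kurtosis, 5.66, tolerance = 0.005)
  g1 <- descriptive_stats(load_dataset("dataset2_group1"))
  expect_equal(g1$mean, 280.17, tolerance = 0.005)
  expect_equal(g1$median, 160.00, tolerance = 0.005)
  g2 <- descriptive_stats(load_dataset("dataset2_group2"))
  expect_equal(g2$mean, 304.90, tolerance = 0.005)
  expect_equal(g2$median, 176.00, tolerance = 0.005)
  expect_equal(g2$skewness, 2.94, tolerance = 0.005)
})

test_that("a single uncensored value yields missing dispersion statistics", {
  ds <- censored_sample(time = c(7, 9), status = c(1, 0))
  st <- descriptive_stats(ds)
  expect_equal(st$mean, 7)
  expect_equal(st$median, 7)
  expect_true(is.na(st$variance))
})

test_that("the shape-flexible mixture never fits worse than its exponential special case", {
  g2 <- load_dataset("dataset2_group2")
  f_ged <- fit_mixged_unlabeled(g2, "2cmged")
  f_ed <- fit_mixged_unlabeled(g2, "2cmed")
  expect_gte(f_ged$loglik, f_ed$loglik - 1e-6)
  expect_equal(f_ged$k, 5)
  expect_equal(f_ed$k, 3)
  # label-switching convention
  expect_lte(f_ged$par$theta1, f_ged$par$theta2)
})

test_that("goodness-of-fit report obeys the information-criterion identities", {
  g2 <- load_dataset("dataset2_group2")
  rep_ <- fit_and_score(g2, "2cmed")
  expect_equal(rep_$AIC, 2 * rep_$k - 2 * rep_$loglik)
  expect_equal(rep_$n, 30)   # default convention fits the uncensored records
  expect_equal(rep_$BIC, rep_$k * log(30) - 2 * rep_$loglik)
  expect_true(rep_$KS >= 0 && rep_$KS <= 1)
  expect_true(rep_$KS_pvalue >= 0 && rep_$KS_pvalue <= 1)
  # the censored-likelihood convention uses every record and never fits
  # better than the richer model under the same convention
  full_ed <- fit_and_score(g2, "2cmed", censored = "likelihood")
  full_ged <- fit_and_score(g2, "2cmged", censored = "likelihood")
  expect_equal(full_ed$n, 45)
  expect_gte(full_ged$loglik, full_ed$loglik - 1e-6)
})

test_that("EDF statistics match textbook formulas on a known sample", {
  u <- c(0.1, 0.3, 0.4, 0.7, 0.9)
  st <- gedmix:::edf_stats(u)
  i <- 1:5
  expect_equal(st$KS, max(i / 5 - u, u - (i - 1) / 5))
  expect_equal(st$CM, 1 / 60 + sum((u - (2 * i - 1) / 10)^2))
  expect_equal(st$AD,
               -5 - mean((2 * i - 1) * (log(u) + log(1 - rev(u)))))
})

test_that("model selection prefers the exponential mixture on its own data", {
  wins <- 0L
  n_rep <- 12
  for (r in seq_len(n_rep)) {
    set.seed(300 + r)
    lab <- rmixged(150, mixged_par(1, 1.0, 1, 3.0, 0.5))
    ds <- censored_sample(lab$time)
    a_ed <- fit_and_score(ds, "2cmed")
    a_ged <- fit_and_score(ds, "2cmged")
    if (a_ed$AIC <= a_ged$AIC) wins <- wins + 1L
  }
  expect_gt(wins, n_rep / 2)
})
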