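test_that("draws are reproducible given a seed", {
  s <- censored_ref(50, seed = 71)
  d1 <- is_draws(s, m = 500, seed = 5)
  d2 <- is_draws(s, m = 500, seed = 5)
  expect_identical(d1$draws, d2$draws)
  expect_identical(d1$log_weights, d2$log_weights)
})

test_that("mixing-weight proposal marginal is the stated Beta law", {
  s <- censored_ref(50, seed = 73)
  r1 <- sum(s$status == 1L & s$label == 1L)
  r2 <- sum(s$status == 1L & s$label == 2L)
  d <- is_draws(s, m = 20000, seed = 7)
  ks <- ks.test(d$draws[, "pi1"], function(q) pbeta(q, r1 + 1, r2 + 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("normalised weights sum to one and ESS is reported", {
  s <- censored_ref(50, seed = 75)
  d <- is_draws(s, m = 2000, seed = 9)
  expect_equal(sum(d$weights), 1, tolerance = 1e-12)
  expect_equal(d$ess, 1 / sum(d$weights^2), tolerance = 1e-12)
})

test_that("complete samples contribute no survival factor to the weight", {
  s <- censor_conventional(labelled_sample(30, seed = 77), 0)
  p <- gedmix:::sample_pieces(s)
  v <- c(0.7, 1.1, 1.2, 1.6, 0.4)
  chi1 <- -sum(log1p(-exp(-v[3] * p$x1)))
  chi2 <- -sum(log1p(-exp(-v[4] * p$x2)))
  direct <- chi1 - (p$r1 + 1) * log(chi1) + chi2 - (p$r2 + 1) * log(chi2)
  expect_equal(h14_log_weight(v, s), direct, tolerance = 1e-12)
})

test_that("weights are invariant to reordering the sample", {
  s <- censored_ref(40, seed = 79)
  set.seed(2)
  perm <- sample(40)
  s2 <- censored_sample(s$time[perm], s$status[perm], s$label[perm],
                        t_anchor = s$t_anchor)
  v <- c(0.7, 1.1, 1.2, 1.6, 0.4)
  expect_equal(h14_log_weight(v, s), h14_log_weight(v, s2))
})

test_that("residual weight times proposals is pointwise proportional to the posterior", {
  om <- omega_ref()
  set.seed(81)
  s <- censor_conventional(rmixged(12, om), 0.25)
  set.seed(83)
  consts <- replicate(20, {
    v <- c(runif(2, 0.3, 2), runif(2, 0.5, 2.5), runif(1, 0.2, 0.8))
    # flat prior: the posterior kernel is the likelihood itself
    loglik_mixged(s, gedmix:::vec_par(v)) -
      proposal_logdens(v, s) - h14_log_weight(v, s)
  })
  expect_lt(max(consts) - min(consts), 1e-8)
})

test_that("the informative-prior factorisation also matches its posterior", {
  om <- omega_ref()
  ip <- prior_ip_default(om)
  set.seed(85)
  s <- censor_conventional(rmixged(12, om), 0.25)
  set.seed(87)
  consts <- replicate(20, {
    v <- c(runif(2, 0.3, 2), runif(2, 0.5, 2.5), runif(1, 0.2, 0.8))
    omv <- gedmix:::vec_par(v)
    loglik_mixged(s, omv) + prior_logdens(omv, ip) -
      proposal_logdens(v, s, a1 = ip$a1, b1 = ip$b1,
                       a1u = c(ip$a11, ip$a12), b1u = c(ip$b11, ip$b12),
                       a2u = c(ip$a21, ip$a22), b2u = c(ip$b21, ip$b22)) -
      h14_log_weight(v, s, ip)
  })
  expect_lt(max(consts) - min(consts), 1e-8)
})

test_that("Jensen orderings hold exactly on the weighted draws", {
  s <- censored_ref(100, seed = 89)
  d <- is_draws(s, m = 4000, seed = 11)
  self <- bayes_is(s, draws = d, loss = "SELF")$estimate
  plf <- bayes_is(s, draws = d, loss = "PLF")$estimate
  elf <- bayes_is(s, draws = d, loss = "ELF")$estimate
  llf <- bayes_is(s, draws = d, loss = "LLF")$estimate
  expect_true(all(plf >= self - 1e-12))
  expect_true(all(self >= llf - 1e-12))
  expect_true(all(self >= elf - 1e-12))
})

test_that("IS posterior means match the collapsed quadrature oracle on a toy sample", {
  # three observations, informative prior (the flat-prior toy posterior is
  # improper for a single-failure component)
  s <- censored_sample(time = c(0.4, 1.1, 0.8), label = c(1, 1, 2))
  ip <- prior_ip_default(omega_ref())
  d <- is_draws(s, prior = ip, m = 200000, seed = 13)
  est <- colSums(d$draws * d$weights)
  o1 <- component_posterior_oracle(c(0.4, 1.1), a1 = ip$a11, b1 = ip$b11,
                                   a2 = ip$a21, b2 = ip$b21,
                                   theta_max = 40)
  o2 <- component_posterior_oracle(0.8, a1 = ip$a12, b1 = ip$b12,
                                   a2 = ip$a22, b2 = ip$b22,
                                   theta_max = 40)
  expect_equal(est[["theta1"]], o1$E_theta, tolerance = 0.01)
  expect_equal(est[["lambda1"]], o1$E_lambda, tolerance = 0.01)
  expect_equal(est[["theta2"]], o2$E_theta, tolerance = 0.01)
  expect_equal(est[["lambda2"]], o2$E_lambda, tolerance = 0.01)
  expect_equal(est[["pi1"]], (2 + ip$a1) / (3 + ip$a1 + ip$b1),
               tolerance = 0.01)
})

test_that("low effective sample size is flagged", {
  s <- censored_ref(200, seed = 91)
  d <- is_draws(s, m = 1000, seed = 15)
  res <- bayes_is(s, draws = d, loss = "SELF")
  if (d$ess < 50) expect_true(all(res$flag == "effective sample size < 50"))
  expect_s3_class(res, "mixged_bayes")
})
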