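test_that("complete-sample log-likelihood is the labelled product form", {
  s <- censored_sample(time = c(0.4, 1.1, 0.8, 2.0),
                       label = c(1, 1, 2, 2))
  om <- mixged_par(0.6, 1.4, 1.2, 0.9, 0.35)
  manual <- 2 * log(0.35) + 2 * log(0.65) +
    sum(dged(c(0.4, 1.1), 0.6, 1.4, log = TRUE)) +
    sum(dged(c(0.8, 2.0), 1.2, 0.9, log = TRUE))
  expect_equal(loglik_mixged(s, om), manual, tolerance = 1e-12)
})

test_that("single labelled observation matches the hand computation", {
  s <- censored_sample(time = 1, label = 1)
  om <- mixged_par(1, 2, 1, 2, 0.5)
  expect_equal(loglik_mixged(s, om), log(0.5) + log(2) - 2)
})

test_that("exponentiated log-likelihood equals the censored product form", {
  s <- censored_sample(time = c(0.3, 0.9, 1.4, 2.2, 2.5),
                       status = c(1, 1, 1, 0, 0),
                       label = c(1, 2, 1, NA, NA))
  om <- mixged_par(0.7, 1.1, 1.3, 0.8, 0.4)
  t <- s$t_anchor
  prod_form <- 0.4 * dged(0.3, 0.7, 1.1) * 0.4 * dged(1.4, 0.7, 1.1) *
    0.6 * dged(0.9, 1.3, 0.8) *
    (1 - 0.4 * pged(t, 0.7, 1.1) - 0.6 * pged(t, 1.3, 0.8))^2
  expect_equal(exp(loglik_mixged(s, om)), prod_form, tolerance = 1e-10)
})

test_that("log-likelihood returns -Inf when the survival factor is non-positive", {
  s <- censored_sample(time = c(5, 6, 7, 8), status = c(1, 1, 1, 0),
                       label = c(1, 2, 1, NA))
  # huge rates push F(t) to 1 and the bracket to 0
  expect_identical(loglik_mixged(s, mixged_par(5, 50, 5, 50, 0.5)), -Inf)
})

test_that("score matches finite differences of the log-likelihood", {
  set.seed(17)
  for (i in 1:8) {
    s <- censor_conventional(rmixged(12, omega_ref()), 0.25)
    v <- c(runif(2, 0.3, 2), runif(2, 0.4, 2.2), runif(1, 0.2, 0.8))
    om <- mixged_par(v[1], v[3], v[2], v[4], v[5])
    sc <- score_mixged(s, om)
    vv <- c(v[1], v[2], v[3], v[4], v[5])   # canonical order
    fd <- vapply(1:5, function(j) {
      h <- 1e-6 * max(abs(vv[j]), 1)
      vp <- vv; vm <- vv
      vp[j] <- vv[j] + h; vm[j] <- vv[j] - h
      (loglik_mixged(s, gedmix:::vec_par(vp)) -
         loglik_mixged(s, gedmix:::vec_par(vm))) / (2 * h)
    }, numeric(1))
    expect_equal(unname(sc), fd, tolerance = 1e-5)
  }
})

test_that("mixing-weight score has the closed complete-data form", {
  s <- censored_sample(time = c(0.4, 1.1, 0.8), label = c(1, 1, 2))
  om <- mixged_par(1, 1, 1, 1, 0.3)
  sc <- score_mixged(s, om)
  expect_equal(sc[["pi1"]], 2 / 0.3 - 1 / 0.7)
  # stationary at pi1 = r1 / r
  sc2 <- score_mixged(s, mixged_par(1, 1, 1, 1, 2 / 3))
  expect_equal(sc2[["pi1"]], 0, tolerance = 1e-12)
})

test_that("numerical Hessian agrees with a Richardson-extrapolated oracle", {
  s <- censored_ref(60, seed = 23)
  v <- c(0.6, 0.9, 1.1, 1.6, 0.42)
  p <- gedmix:::sample_pieces(s)
  H <- gedmix:::hessian_pieces(p, v)
  Hr <- pracma::hessian(function(w) gedmix:::loglik_pieces(p, w), v)
  expect_equal(H, (Hr + t(Hr)) / 2, tolerance = 1e-5)
})

test_that("third-derivative array is symmetric and matches a direct check", {
  s <- censored_ref(60, seed = 23)
  p <- gedmix:::sample_pieces(s)
  v <- c(0.6, 0.9, 1.1, 1.6, 0.42)
  L <- gedmix:::third_derivs_pieces(p, v)
  expect_equal(L[1, 3, 5], L[5, 3, 1])
  expect_equal(L[2, 2, 4], L[4, 2, 2])
  # d^3/dpi1^3 of the complete part alone: 2 r1/pi^3 - 2 r2/(1-pi)^3 plus
  # the survival-factor contribution; check against finite differences of
  # the analytic score instead of re-deriving it
  h <- 1e-4
  vp <- v; vm <- v; vp[5] <- v[5] + h; vm[5] <- v[5] - h
  fd <- (gedmix:::score_pieces(p, vp)[5] - 2 * gedmix:::score_pieces(p, v)[5] +
           gedmix:::score_pieces(p, vm)[5]) / h^2
  expect_equal(L[5, 5, 5], unname(fd), tolerance = 1e-3)
})

test_that("maximum-likelihood fit recovers the truth on large complete samples", {
  om <- omega_ref()
  s <- censor_conventional(labelled_sample(2000, seed = 31), 0)
  fit <- fit_mixged(s)
  expect_true(fit$converged)
  expect_lt(fit$score_norm, 1e-5)
  se <- sqrt(diag(fit$sigma))
  expect_true(all(abs(fit$par_vec - c(0.5, 0.75, 1.2, 1.5, 0.45)) < 3 * se))
  # optimality relative to the generating values
  expect_gte(fit$loglik, loglik_mixged(s, om))
})

test_that("complete labelled fits give the closed-form mixing weight", {
  s <- censor_conventional(labelled_sample(300, seed = 37), 0)
  fit <- fit_mixged(s)
  r1 <- sum(s$label == 1L)
  expect_equal(fit$par$pi1, r1 / 300, tolerance = 1e-6)
})

test_that("log-likelihood is invariant to sample permutation", {
  s <- censored_ref(40, seed = 41)
  om <- mixged_par(0.6, 1.3, 0.9, 1.7, 0.5)
  set.seed(1)
  perm <- sample(40)
  s2 <- censored_sample(s$time[perm], s$status[perm], s$label[perm],
                        t_anchor = s$t_anchor)
  expect_equal(loglik_mixged(s, om), loglik_mixged(s2, om))
})

test_that("unlabelled likelihood is label-swap symmetric and reduces correctly", {
  s <- censored_ref(40, seed = 43)
  om <- mixged_par(0.6, 1.3, 0.9, 1.7, 0.35)
  sw <- mixged_par(0.9, 1.7, 0.6, 1.3, 0.65)
  expect_equal(loglik_mixged_unlabeled(s, om),
               loglik_mixged_unlabeled(s, sw), tolerance = 1e-12)
  # shape-1, complete data: exponential-mixture log-likelihood
  sc <- censored_sample(c(0.5, 1.2, 2.0))
  om_e <- mixged_par(1, 1.1, 1, 2.3, 0.4)
  expect_equal(loglik_mixged_unlabeled(sc, om_e),
               sum(log(0.4 * dexp(sc$time, 1.1) +
                         0.6 * dexp(sc$time, 2.3))))
  # near-degenerate weight: single-GED censored log-likelihood
  om_d <- mixged_par(0.8, 1.4, 1, 1, 1 - 1e-12)
  s5 <- censored_sample(c(0.3, 0.9, 1.4, 2.2, 2.5),
                        status = c(1, 1, 1, 0, 0))
  single <- sum(dged(c(0.3, 0.9, 1.4), 0.8, 1.4, log = TRUE)) +
    sum(log(1 - pged(c(2.2, 2.5), 0.8, 1.4)))
  expect_equal(loglik_mixged_unlabeled(s5, om_d), single, tolerance = 1e-8)
})

test_that("unlabelled toy sample matches term-by-term evaluation", {
  s <- censored_sample(c(0.3, 0.9, 1.4, 2.2, 2.5),
                       status = c(1, 1, 1, 0, 0))
  om <- mixged_par(0.7, 1.1, 1.3, 0.8, 0.4)
  manual <- sum(log(dmixged(c(0.3, 0.9, 1.4), om))) +
    sum(log(1 - pmixged(c(2.2, 2.5), om)))
  expect_equal(loglik_mixged_unlabeled(s, om), manual, tolerance = 1e-10)
})

test_that("parameter errors shrink with sample size", {
  om <- omega_ref()
  err <- sapply(c(50, 200, 1000), function(n) {
    e <- sapply(1:8, function(r) {
      s <- censor_conventional(labelled_sample(n, seed = 100 * n + r), 0)
      f <- tryCatch(fit_mixged(s), error = function(e) NULL)
      if (is.null(f)) return(rep(NA, 5))
      abs(f$par_vec - c(0.5, 0.75, 1.2, 1.5, 0.45))
    })
    rowMeans(e, na.rm = TRUE)
  })
  # mean absolute error decreases from n=50 to n=1000 for every parameter
  expect_true(all(err[, 3] < err[, 1]))
})
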