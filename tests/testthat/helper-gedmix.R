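# Shared fixtures: the reference parameter set used throughout the
# simulation checks, and small seeded samples.

omega_ref <- function() mixged_par(0.50, 1.20, 0.75, 1.50, 0.45)

labelled_sample <- function(n, omega = omega_ref(), seed = 1) {
  set.seed(seed)
  rmixged(n, omega)
}

censored_ref <- function(n, rate = 0.2, omega = omega_ref(), seed = 1) {
  censor_conventional(labelled_sample(n, omega, seed), rate)
}

# Collapsed 1-D quadrature oracle for a single complete-data component
# block under a Gamma(a1, b1) prior on lambda and Gamma(a2, b2) on theta
# (flat prior: a1 = a2 = 1, b1 = b2 = 0). Integrating lambda analytically,
# the theta marginal is
#   p(theta) propto theta^{r + a2 - 1} e^{-theta (kappa + b2)}
#             e^{chi(theta)} (chi(theta) + b1)^{-(r + a1)},
# with chi(theta) = -sum log(1 - e^{-theta x}), and
# E[lambda | theta] = (r + a1) / (chi(theta) + b1).
# Posterior means are computed by log-space trapezoid quadrature on a wide
# theta grid; independent of the package's estimation code paths.
component_posterior_oracle <- function(x, a1 = 1, b1 = 0, a2 = 1, b2 = 0,
                                       theta_max = 60, n_grid = 20000) {
  r <- length(x)
  kappa <- sum(x)
  th <- seq(theta_max / n_grid, theta_max, length.out = n_grid)
  chi <- vapply(th, function(t) -sum(log1p(-exp(-t * x))), numeric(1))
  logk <- (r + a2 - 1) * log(th) - th * (kappa + b2) + chi -
    (r + a1) * log(chi + b1)
  w <- exp(logk - max(logk))
  w <- w / sum(w)
  list(E_theta = sum(w * th),
       E_lambda = sum(w * (r + a1) / (chi + b1)))
}

# log density of the Beta/Gamma importance proposals at a parameter point
# (independent re-derivation used by the posterior-identity check)
proposal_logdens <- function(v, sample, a1 = 1, b1 = 1,
                             a1u = c(1, 1), b1u = c(0, 0),
                             a2u = c(1, 1), b2u = c(0, 0)) {
  obs <- sample$status == 1L
  x1 <- sample$time[obs & sample$label == 1L]
  x2 <- sample$time[obs & sample$label == 2L]
  r1 <- length(x1); r2 <- length(x2)
  chi1 <- -sum(log1p(-exp(-v[3] * x1)))
  chi2 <- -sum(log1p(-exp(-v[4] * x2)))
  stats::dbeta(v[5], r1 + a1, r2 + b1, log = TRUE) +
    stats::dgamma(v[3], r1 + a2u[1], rate = sum(x1) + b2u[1], log = TRUE) +
    stats::dgamma(v[4], r2 + a2u[2], rate = sum(x2) + b2u[2], log = TRUE) +
    stats::dgamma(v[1], r1 + a1u[1], rate = chi1 + b1u[1], log = TRUE) +
    stats::dgamma(v[2], r2 + a1u[2], rate = chi2 + b1u[2], log = TRUE)
}

# synthetic Lindley workspace with prescribed curvature and no
# third-derivative or prior terms (an exactly quadratic log-posterior)
quadratic_workspace <- function(v, sigma) {
  structure(list(mle = NULL, prior = prior_nip(), v = v, sigma = sigma,
                 Lijk = array(0, c(5, 5, 5)), A = rep(0, 5),
                 P = rep(0, 5), d = rep(0, 5)),
            class = "lindley_ws")
}
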