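#' Log-likelihood of a labelled right-censored mixture sample
#'
#' Evaluates the censored 2CMGED log-likelihood in which observed failures
#' carry known component labels and the `n - r` censored items contribute
#' a pooled survival factor at the anchor time `t`:
#' \deqn{\ell = r_1\log\pi_1 + r_2\log(1-\pi_1) + \sum_j \big[r_j\log\lambda_j
#'   + r_j\log\theta_j - \theta_j\sum_i x_{ji}
#'   + (\lambda_j-1)\sum_i \log(1-e^{-\theta_j x_{ji}})\big]
#'   + (n-r)\log G,}
#' with \eqn{G = 1 - \pi_1(1-e^{-\theta_1 t})^{\lambda_1}
#'   - (1-\pi_1)(1-e^{-\theta_2 t})^{\lambda_2}}.
#' When the survival factor `G` is non-positive at the supplied parameters
#' the function returns `-Inf` rather than raising an error.
#'
#' @param sample a [censored_sample()] with component labels on all
#'   observed failures.
#' @param omega a [mixged_par()] or numeric 5-vector
#'   `(lambda1, theta1, lambda2, theta2, pi1)`.
#' @return a single number (possibly `-Inf`).
#' @export
loglik_mixged <- function(sample, omega) {
  omega <- as_mixged_par(omega)
  p <- sample_pieces(sample)
  loglik_pieces(p, par_vec(omega))
}

# internal: pre-extracted sufficient pieces of a labelled censored sample
sample_pieces <- function(sample) {
  if (!inherits(sample, "censored_sample"))
    stop("'sample' must be a censored_sample", call. = FALSE)
  obs <- sample$status == 1L
  if (is.null(sample$label) || anyNA(sample$label[obs]))
    stop("observed failures must carry component labels", call. = FALSE)
  x1 <- sample$time[obs & sample$label == 1L]
  x2 <- sample$time[obs & sample$label == 2L]
  list(x1 = x1, x2 = x2, r1 = length(x1), r2 = length(x2),
       n = length(sample$time), t = sample$t_anchor)
}

# v = (lambda1, lambda2, theta1, theta2, pi1)
loglik_pieces <- function(p, v) {
  l1 <- v[[1]]; l2 <- v[[2]]; t1 <- v[[3]]; t2 <- v[[4]]; pi1 <- v[[5]]
  if (l1 <= 0 || l2 <= 0 || t1 <= 0 || t2 <= 0 || pi1 <= 0 || pi1 >= 1)
    return(-Inf)
  r <- p$r1 + p$r2
  ll <- p$r1 * log(pi1) + p$r2 * log1p(-pi1) +
    p$r1 * (log(l1) + log(t1)) + p$r2 * (log(l2) + log(t2)) -
    t1 * sum(p$x1) - t2 * sum(p$x2) +
    (l1 - 1) * sum(log1p(-exp(-t1 * p$x1))) +
    (l2 - 1) * sum(log1p(-exp(-t2 * p$x2)))
  if (p$n > r) {
    G <- 1 - pi1 * exp(l1 * log1p(-exp(-t1 * p$t))) -
      (1 - pi1) * exp(l2 * log1p(-exp(-t2 * p$t)))
    if (!is.finite(G) || G <= 0) return(-Inf)
    ll <- ll + (p$n - r) * log(G)
  }
  ll
}

#' Score vector of the labelled censored mixture log-likelihood
#'
#' Analytic partial derivatives of [loglik_mixged()] with respect to the
#' parameters, in the order `(lambda1, lambda2, theta1, theta2, pi1)`.
#'
#' @inheritParams loglik_mixged
#' @return a named numeric 5-vector.
#' @export
score_mixged <- function(sample, omega) {
  omega <- as_mixged_par(omega)
  score_pieces(sample_pieces(sample), par_vec(omega))
}

score_pieces <- function(p, v) {
  l1 <- v[[1]]; l2 <- v[[2]]; t1 <- v[[3]]; t2 <- v[[4]]; pi1 <- v[[5]]
  e1 <- exp(-t1 * p$x1); e2 <- exp(-t2 * p$x2)
  d_l1 <- p$r1 / l1 + sum(log1p(-e1))
  d_l2 <- p$r2 / l2 + sum(log1p(-e2))
  d_t1 <- p$r1 / t1 - sum(p$x1) + (l1 - 1) * sum(p$x1 * e1 / (1 - e1))
  d_t2 <- p$r2 / t2 - sum(p$x2) + (l2 - 1) * sum(p$x2 * e2 / (1 - e2))
  d_p1 <- p$r1 / pi1 - p$r2 / (1 - pi1)
  r <- p$r1 + p$r2
  if (p$n > r) {
    # survival-factor contributions at the anchor t
    u1 <- -expm1(-t1 * p$t)           # 1 - e^{-theta1 t}
    u2 <- -expm1(-t2 * p$t)
    A1 <- u1^l1; A2 <- u2^l2
    G <- 1 - pi1 * A1 - (1 - pi1) * A2
    m <- p$n - r
    d_l1 <- d_l1 - m * pi1 * A1 * log(u1) / G
    d_l2 <- d_l2 - m * (1 - pi1) * A2 * log(u2) / G
    d_t1 <- d_t1 - m * pi1 * l1 * u1^(l1 - 1) * p$t * exp(-t1 * p$t) / G
    d_t2 <- d_t2 - m * (1 - pi1) * l2 * u2^(l2 - 1) * p$t * exp(-t2 * p$t) / G
    d_p1 <- d_p1 + m * (A2 - A1) / G
  }
  c(lambda1 = d_l1, lambda2 = d_l2, theta1 = d_t1, theta2 = d_t2,
    pi1 = d_p1)
}

# central-difference Hessian of the log-likelihood via the analytic score;
# steps scale with parameter magnitude
hessian_pieces <- function(p, v) {
  h <- .Machine$double.eps^(1 / 3) * pmax(abs(v), 0.1)
  H <- matrix(0, 5, 5)
  for (i in 1:5) {
    vp <- v; vm <- v
    vp[i] <- v[i] + h[i]; vm[i] <- v[i] - h[i]
    H[i, ] <- (score_pieces(p, vp) - score_pieces(p, vm)) / (2 * h[i])
  }
  (H + t(H)) / 2
}

# third-derivative array L[i, j, k] = d^3 logL / dv_i dv_j dv_k by central
# second differences of the analytic score (k is the score component)
third_derivs_pieces <- function(p, v) {
  h <- .Machine$double.eps^(1 / 4) * pmax(abs(v), 0.1)
  L <- array(0, c(5, 5, 5))
  s0 <- score_pieces(p, v)
  for (i in 1:5) {
    vp <- v; vm <- v
    vp[i] <- v[i] + h[i]; vm[i] <- v[i] - h[i]
    L[i, i, ] <- (score_pieces(p, vp) - 2 * s0 + score_pieces(p, vm)) / h[i]^2
    for (j in seq_len(i - 1L)) {
      vpp <- v; vpm <- v; vmp <- v; vmm <- v
      vpp[c(i, j)] <- v[c(i, j)] + h[c(i, j)]
      vpm[i] <- v[i] + h[i]; vpm[j] <- v[j] - h[j]
      vmp[i] <- v[i] - h[i]; vmp[j] <- v[j] + h[j]
      vmm[c(i, j)] <- v[c(i, j)] - h[c(i, j)]
      mix <- (score_pieces(p, vpp) - score_pieces(p, vpm) -
                score_pieces(p, vmp) + score_pieces(p, vmm)) /
        (4 * h[i] * h[j])
      L[i, j, ] <- mix
      L[j, i, ] <- mix
    }
  }
  # enforce full symmetry over index permutations
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    if (i <= j && j <= k) {
      m <- mean(c(L[i, j, k], L[i, k, j], L[j, i, k],
                  L[j, k, i], L[k, i, j], L[k, j, i]))
      L[i, j, k] <- L[i, k, j] <- L[j, i, k] <- m
      L[j, k, i] <- L[k, i, j] <- L[k, j, i] <- m
    }
  }
  L
}

# unconstrained parameterisation: eta = (log lambdas, log thetas, logit pi1)
eta_to_v <- function(eta) c(exp(eta[1:4]), stats::plogis(eta[5]))
v_to_eta <- function(v) c(log(v[1:4]), stats::qlogis(v[5]))

#' Maximum-likelihood fit of the labelled censored mixture model
#'
#' Maximises [loglik_mixged()] by quasi-Newton iteration on transformed
#' parameters (log for shapes and rates, logit for the mixing weight),
#' using the analytic score, followed by Newton polishing of the gradient.
#' The observed-information matrix is computed by central differences of
#' the analytic score at the optimum, and `sigma` is the inverse of the
#' negative Hessian (the posterior-curvature covariance used by Lindley's
#' approximation).
#'
#' @inheritParams loglik_mixged
#' @param init `"auto"` (per-component method-of-moments on the labelled
#'   failures, with the mixing weight initialised at `r1/r`) or a
#'   [mixged_par()].
#' @param tol convergence tolerance on the transformed-scale gradient
#'   norm.
#' @param max_restarts deterministic perturbed restarts attempted on
#'   failure.
#' @return an object of class `"mixged_mle"`: list with elements `par`
#'   (a [mixged_par()]), `par_vec`, `loglik`, `score`, `score_norm`,
#'   `hessian`, `sigma`, `converged`, `n_iter`.
#' @examples
#' om <- mixged_par(0.5, 1.2, 0.75, 1.5, 0.45)
#' set.seed(1)
#' s <- censor_conventional(rmixged(200, om), 0.2)
#' fit_mixged(s)
#' @export
fit_mixged <- function(sample, init = "auto", tol = 1e-8,
                       max_restarts = 5) {
  p <- sample_pieces(sample)
  if (p$r1 < 2 || p$r2 < 2)
    stop("need at least 2 observed failures per component", call. = FALSE)
  v0 <- if (identical(init, "auto")) mom_init(p) else par_vec(as_mixged_par(init))

  nll <- function(eta) {
    v <- eta_to_v(eta)
    -loglik_pieces(p, v)
  }
  ngr <- function(eta) {
    v <- eta_to_v(eta)
    jac <- c(v[1:4], v[5] * (1 - v[5]))   # d v / d eta
    -score_pieces(p, v) * jac
  }

  best <- NULL
  scales <- list(c(1, 1, 1, 1, 1), c(1.5, 1, 1, 1.5, 1),
                 c(0.7, 1.3, 1.2, 0.8, 1), c(2, 0.5, 0.8, 1.4, 1),
                 c(0.5, 2, 1.5, 0.6, 1), c(1.2, 1.2, 0.6, 0.6, 1))
  n_iter <- 0L
  for (attempt in seq_len(max_restarts + 1L)) {
    vstart <- v0 * scales[[((attempt - 1L) %% length(scales)) + 1L]]
    vstart[5] <- min(max(vstart[5], 0.02), 0.98)
    eta <- v_to_eta(vstart)
    opt <- try(stats::optim(eta, nll, ngr, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-14)),
               silent = TRUE)
    if (inherits(opt, "try-error") || !is.finite(opt$value)) next
    eta <- opt$par
    n_iter <- n_iter + opt$counts[["function"]]
    # Newton polish on the transformed-scale gradient
    for (k in 1:20) {
      g <- ngr(eta)
      if (max(abs(g)) <= tol) break
      he <- .Machine$double.eps^(1 / 3) * pmax(abs(eta), 0.1)
      Heta <- matrix(0, 5, 5)
      for (i in 1:5) {
        ep <- eta; em <- eta
        ep[i] <- eta[i] + he[i]; em[i] <- eta[i] - he[i]
        Heta[i, ] <- (ngr(ep) - ngr(em)) / (2 * he[i])
      }
      Heta <- (Heta + t(Heta)) / 2
      step <- try(solve(Heta, g), silent = TRUE)
      if (inherits(step, "try-error") || !all(is.finite(step))) break
      # damped step, keep the likelihood from degrading
      lam <- 1
      f0 <- nll(eta)
      repeat {
        cand <- eta - lam * step
        if (is.finite(nll(cand)) && nll(cand) <= f0 + 1e-10) break
        lam <- lam / 2
        if (lam < 1e-6) { cand <- eta; break }
      }
      if (identical(cand, eta)) break
      eta <- cand
      n_iter <- n_iter + 1L
    }
    g <- ngr(eta)
    cand <- list(eta = eta, value = nll(eta), gnorm = max(abs(g)))
    if (is.null(best) || cand$value < best$value - 1e-10 ||
        (abs(cand$value - best$value) <= 1e-10 && cand$gnorm < best$gnorm))
      best <- cand
    if (!is.null(best) && best$gnorm <= max(tol, 1e-6)) break
  }
  if (is.null(best))
    stop("maximum-likelihood fit failed from every starting point",
         call. = FALSE)

  v_hat <- eta_to_v(best$eta)
  sc <- score_pieces(p, v_hat)
  H <- hessian_pieces(p, v_hat)
  sigma <- try(solve(-H), silent = TRUE)
  ok_sigma <- !inherits(sigma, "try-error") && all(is.finite(sigma)) &&
    all(diag(sigma) > 0)
  if (!ok_sigma) sigma <- matrix(NA_real_, 5, 5)
  sigma <- (sigma + t(sigma)) / 2
  converged <- best$gnorm <= max(tol, 1e-6) && ok_sigma
  structure(list(par = vec_par(v_hat), par_vec = v_hat,
                 loglik = loglik_pieces(p, v_hat),
                 score = sc, score_norm = max(abs(sc)),
                 hessian = H, sigma = sigma,
                 converged = converged, n_iter = n_iter,
                 pieces = p),
            class = "mixged_mle")
}

#' @export
print.mixged_mle <- function(x, ...) {
  cat("Censored 2CMGED maximum-likelihood fit\n")
  print(x$par)
  cat(sprintf("  log-likelihood %.4f; converged: %s (max |score| = %.2e)\n",
              x$loglik, x$converged, x$score_norm))
  invisible(x)
}

# method-of-moments starting values on the labelled failures:
# for a GED, mean = (psi(lambda+1) - psi(1)) / theta and
# var = (psi'(1) - psi'(lambda+1)) / theta^2, so the squared
# coefficient of variation identifies lambda alone.
mom_init <- function(p) {
  one <- function(x) {
    m <- mean(x); s2 <- stats::var(x)
    if (!is.finite(s2) || s2 <= 0) return(c(1, 1 / max(m, 1e-8)))
    cv2 <- s2 / m^2
    f <- function(loglam) {
      lam <- exp(loglam)
      (trigamma(1) - trigamma(lam + 1)) /
        (digamma(lam + 1) - digamma(1))^2 - cv2
    }
    lam <- tryCatch(exp(stats::uniroot(f, c(log(1e-3), log(1e3)))$root),
                    error = function(e) 1)
    th <- (digamma(lam + 1) - digamma(1)) / m
    c(lam, th)
  }
  c1 <- one(p$x1); c2 <- one(p$x2)
  r <- p$r1 + p$r2
  c(c1[1], c2[1], c1[2], c2[2], min(max(p$r1 / r, 0.02), 0.98))
}

#' Log-likelihood of an unlabelled right-censored mixture sample
#'
#' The standard right-censored mixture likelihood for samples without
#' component labels: observed failures contribute `log f(x)` and censored
#' items `log(1 - F(x))`, each at the mixture (not component) law. Used
#' for fitting the real datasets, where subpopulation membership is
#' unobserved.
#'
#' @param sample a [censored_sample()] (labels, if present, are ignored).
#' @inheritParams loglik_mixged
#' @return a single number (possibly `-Inf`).
#' @export
loglik_mixged_unlabeled <- function(sample, omega) {
  omega <- as_mixged_par(omega)
  obs <- sample$status == 1L
  f <- dmixged(sample$time[obs], omega)
  s <- 1 - pmixged(sample$time[!obs], omega)
  if (any(f <= 0) || any(s <= 0)) return(-Inf)
  sum(log(f)) + sum(log(s))
}

#' Fit a mixture model to an unlabelled censored sample
#'
#' Maximises [loglik_mixged_unlabeled()] for either the full 2CMGED
#' (5 parameters) or the exponential-mixture special case 2CMED
#' (3 parameters, both shapes fixed at 1) by quasi-Newton iteration on
#' transformed parameters from several deterministic starting points.
#' Component labels being unobserved, fits are reported with the
#' convention `theta1 <= theta2` to resolve label switching.
#'
#' @inheritParams loglik_mixged_unlabeled
#' @param model `"2cmged"` or `"2cmed"`.
#' @return list with `par` (a [mixged_par()]), `loglik`, `k` (number of
#'   free parameters), `converged`.
#' @export
fit_mixged_unlabeled <- function(sample, model = c("2cmged", "2cmed")) {
  model <- match.arg(model)
  x <- sample$time
  # data-driven rate scales: fast-failing and slow-failing halves
  lo <- x[x <= stats::median(x)]; hi <- x[x > stats::median(x)]
  th_lo <- 1 / max(mean(hi), 1e-12); th_hi <- 1 / max(mean(lo), 1e-12)
  starts <- list()
  for (lam in if (model == "2cmged") c(0.5, 1, 2) else 1)
    for (p1 in c(0.3, 0.5, 0.7))
      starts[[length(starts) + 1L]] <-
        c(lam, lam, th_hi, th_lo, p1)
  starts[[length(starts) + 1L]] <-
    c(if (model == "2cmged") c(1.5, 0.7) else c(1, 1),
      1 / mean(x), 2 / mean(x), 0.5)

  free <- if (model == "2cmged") 1:5 else 3:5
  nll <- function(eta_free, base) {
    eta <- base; eta[free] <- eta_free
    v <- eta_to_v(eta)
    -loglik_mixged_unlabeled(sample, vec_par(v))
  }
  best <- NULL
  for (st in starts) {
    eta0 <- v_to_eta(st)
    opt <- try(stats::optim(eta0[free], nll, base = eta0, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(opt, "try-error") || !is.finite(opt$value)) next
    # Nelder-Mead polish guards against BFGS stalling on a ridge
    opt2 <- try(stats::optim(opt$par, nll, base = eta0,
                             control = list(maxit = 2000,
                                            reltol = 1e-12)),
                silent = TRUE)
    if (!inherits(opt2, "try-error") && is.finite(opt2$value) &&
        opt2$value < opt$value) opt <- opt2
    if (is.null(best) || opt$value < best$value) {
      best <- opt; best$base <- eta0
    }
  }
  if (is.null(best))
    stop("unlabelled fit failed from every starting point", call. = FALSE)
  eta <- best$base; eta[free] <- best$par
  v <- eta_to_v(eta)
  # label-switching convention: theta1 <= theta2
  if (v[3] > v[4]) v <- c(v[2], v[1], v[4], v[3], 1 - v[5])
  list(par = vec_par(v), loglik = -best$value,
       k = length(free), converged = best$convergence == 0)
}
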