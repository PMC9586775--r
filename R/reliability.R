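#' Reliability characteristics of the 2CMGED
#'
#' Evaluates, at a time `t > 0`, the survival function
#' `R(t) = 1 - F(t)`, the hazard rate `HR(t) = f(t) / R(t)` and the
#' reversed hazard rate `RHR(t) = f(t) / F(t)` of the mixture.
#'
#' @param omega a [mixged_par()] or numeric 5-vector
#'   `(lambda1, theta1, lambda2, theta2, pi1)`.
#' @param t evaluation time, `> 0`.
#' @return an object of class `"reliability_chars"`: list with fields
#'   `t`, `R`, `HR`, `RHR`.
#' @examples
#' reliability_chars(mixged_par(0.50, 1.20, 0.75, 1.50, 0.45), 1.00)
#' @export
reliability_chars <- function(omega, t) {
  omega <- as_mixged_par(omega)
  if (!is.finite(t) || t <= 0)
    stop("'t' must be a positive time", call. = FALSE)
  f <- dmixged(t, omega)
  Fv <- pmixged(t, omega)
  R <- 1 - Fv
  if (R <= 0) stop("survival is zero at 't'; hazard rate undefined",
                   call. = FALSE)
  if (Fv <= 0) stop("CDF is zero at 't'; reversed hazard rate undefined",
                    call. = FALSE)
  structure(list(t = t, R = R, HR = f / R, RHR = f / Fv),
            class = "reliability_chars")
}

#' @export
print.reliability_chars <- function(x, ...) {
  cat(sprintf("Reliability characteristics at t = %.4g:\n", x$t))
  cat(sprintf("  R(t) = %.4f   HR(t) = %.4f   RHR(t) = %.4f\n",
              x$R, x$HR, x$RHR))
  invisible(x)
}

# the three reliability functionals as functions of the canonical
# parameter 5-vector (lambda1, lambda2, theta1, theta2, pi1)
rc_functionals <- function(t) {
  om <- function(v) vec_par(v)
  list(R = function(v) 1 - pmixged(t, om(v)),
       HR = function(v) {
         o <- om(v); dmixged(t, o) / (1 - pmixged(t, o))
       },
       RHR = function(v) {
         o <- om(v); dmixged(t, o) / pmixged(t, o)
       })
}

#' Bayes estimation of the reliability characteristics
#'
#' Estimates `R(t)`, `HR(t)` and `RHR(t)` under a loss function by either
#' Lindley's approximation (posterior expectations of the reliability
#' functionals, with numerically differentiated gradients and Hessians)
#' or importance sampling (weighted ratio estimators of the functionals
#' over the posterior draws). Loss transformations and posterior-risk
#' definitions are identical to the parameter case.
#'
#' @inheritParams bayes_la
#' @param method `"LA"` or `"IS"`.
#' @param t evaluation time, `> 0`.
#' @param m,seed importance-sampling draw count and seed (IS only).
#' @param ws optional precomputed [lindley_workspace()] (LA only).
#' @param draws optional precomputed [is_draws()] object (IS only).
#' @return a `data.frame` with one row per characteristic (`quantity`,
#'   `estimate`, `posterior_risk`, `flag`).
#' @examples
#' om <- mixged_par(0.5, 1.2, 0.75, 1.5, 0.45)
#' set.seed(1)
#' s <- censor_conventional(rmixged(300, om), 0.2)
#' bayes_rc(s, t = 1, method = "LA")
#' @export
bayes_rc <- function(sample, prior = prior_nip(), loss = "SELF",
                     method = c("LA", "IS"), t = 1, linex_a = 1,
                     m = 10000, seed = NULL, ws = NULL, draws = NULL) {
  method <- match.arg(method)
  loss <- match.arg(toupper(loss), loss_names)
  fns <- rc_functionals(t)
  if (method == "LA") {
    if (is.null(ws)) ws <- lindley_workspace(sample, prior)
    rows <- lapply(fns, function(fn) {
      mom <- la_functional_moments(ws, fn, linex_a)
      loss_estimate(mom, loss, linex_a)
    })
  } else {
    if (is.null(draws)) draws <- is_draws(sample, prior, m, seed)
    w <- draws$weights
    rows <- lapply(fns, function(fn) {
      val <- apply(draws$draws, 1, fn)
      mom <- list(m1 = sum(w * val), m2 = sum(w * val^2),
                  minv = sum(w / val), mlog = sum(w * log(val)),
                  mexp = sum(w * exp(-linex_a * val)))
      loss_estimate(mom, loss, linex_a)
    })
  }
  out <- data.frame(quantity = names(fns),
                    estimate = vapply(rows, `[[`, numeric(1), "estimate"),
                    posterior_risk = vapply(rows, `[[`, numeric(1),
                                            "posterior_risk"),
                    flag = vapply(rows, `[[`, character(1), "flag"))
  structure(out, method = method, prior = prior$kind, loss = loss,
            t = t, class = c("mixged_bayes", "data.frame"))
}

# Lindley moments of an arbitrary scalar functional: the transforms
# needed by the losses are expectations of elementary functions of w, so
# each gets its own numerically differentiated Lindley pass
la_functional_moments <- function(ws, fn, linex_a = 1) {
  ex <- function(g) {
    lindley_expectation(ws, function(v) g(fn(v)))
  }
  list(m1 = ex(identity), m2 = ex(function(x) x^2),
       minv = ex(function(x) 1 / x), mlog = ex(log),
       mexp = ex(function(x) exp(-linex_a * x)))
}
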