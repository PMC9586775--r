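#' Prior specifications for the censored mixture model
#'
#' Two families of joint priors on `(lambda1, lambda2, theta1, theta2,
#' pi1)` are supported:
#' * `prior_nip()` — the noninformative flat prior (constant density over
#'   the parameter space, zero gradient);
#' * `prior_ip()` — the informative conjugate-style product prior:
#'   `pi1 ~ Beta(a1, b1)`, `lambda_u ~ Gamma(a1u, b1u)` and
#'   `theta_u ~ Gamma(a2u, b2u)` (shape/rate), all hyperparameters
#'   positive.
#'
#' `prior_ip_default()` builds a mildly informative prior by prior-mean
#' matching: every Gamma component has shape 2 and rate `2 / m` so its
#' mean equals the anticipated parameter value `m`, and the mixing weight
#' gets a `Beta(2, 2)` centred at 1/2.
#'
#' @param a1,b1 Beta hyperparameters for `pi1`.
#' @param a11,b11,a12,b12 Gamma shape/rate for `lambda1`, `lambda2`.
#' @param a21,b21,a22,b22 Gamma shape/rate for `theta1`, `theta2`.
#' @param anticipated a [mixged_par()] of anticipated parameter values.
#' @param shape common Gamma shape used by `prior_ip_default`.
#' @return an object of class `"mixged_prior"`.
#' @examples
#' prior_nip()
#' prior_ip_default(mixged_par(0.5, 1.2, 0.75, 1.5, 0.45))
#' @name priors
NULL

#' @rdname priors
#' @export
prior_nip <- function() {
  structure(list(kind = "NIP"), class = "mixged_prior")
}

#' @rdname priors
#' @export
prior_ip <- function(a1, b1, a11, b11, a12, b12, a21, b21, a22, b22) {
  h <- c(a1 = a1, b1 = b1, a11 = a11, b11 = b11, a12 = a12, b12 = b12,
         a21 = a21, b21 = b21, a22 = a22, b22 = b22)
  if (any(!is.finite(h)) || any(h <= 0))
    stop("all hyperparameters must be positive", call. = FALSE)
  structure(c(list(kind = "IP"), as.list(h)), class = "mixged_prior")
}

#' @rdname priors
#' @export
prior_ip_default <- function(anticipated, shape = 2) {
  a <- as_mixged_par(anticipated)
  prior_ip(a1 = 2, b1 = 2,
           a11 = shape, b11 = shape / a$lambda1,
           a12 = shape, b12 = shape / a$lambda2,
           a21 = shape, b21 = shape / a$theta1,
           a22 = shape, b22 = shape / a$theta2)
}

#' @export
print.mixged_prior <- function(x, ...) {
  if (x$kind == "NIP") {
    cat("Noninformative (flat) prior on (lambda1, lambda2, theta1, theta2, pi1)\n")
  } else {
    cat("Informative Beta-Gamma prior:\n")
    cat(sprintf("  pi1     ~ Beta(%.3g, %.3g)\n", x$a1, x$b1))
    cat(sprintf("  lambda1 ~ Gamma(%.3g, %.3g)   lambda2 ~ Gamma(%.3g, %.3g)\n",
                x$a11, x$b11, x$a12, x$b12))
    cat(sprintf("  theta1  ~ Gamma(%.3g, %.3g)   theta2  ~ Gamma(%.3g, %.3g)\n",
                x$a21, x$b21, x$a22, x$b22))
  }
  invisible(x)
}

#' Log prior density and its gradient
#'
#' Evaluates the joint log prior density at an interior parameter point,
#' and (for `prior_grad`) its analytic gradient in the canonical order
#' `(lambda1, lambda2, theta1, theta2, pi1)`. Under the flat prior both
#' are constant zero.
#'
#' @param omega a [mixged_par()] interior to the parameter space.
#' @param prior a [prior_nip()] or [prior_ip()].
#' @return `prior_logdens` a single number; `prior_grad` a numeric
#'   5-vector.
#' @export
prior_logdens <- function(omega, prior) {
  omega <- as_mixged_par(omega)
  check_prior(prior)
  if (prior$kind == "NIP") return(0)
  stats::dbeta(omega$pi1, prior$a1, prior$b1, log = TRUE) +
    stats::dgamma(omega$lambda1, prior$a11, rate = prior$b11, log = TRUE) +
    stats::dgamma(omega$lambda2, prior$a12, rate = prior$b12, log = TRUE) +
    stats::dgamma(omega$theta1, prior$a21, rate = prior$b21, log = TRUE) +
    stats::dgamma(omega$theta2, prior$a22, rate = prior$b22, log = TRUE)
}

#' @rdname prior_logdens
#' @export
prior_grad <- function(omega, prior) {
  omega <- as_mixged_par(omega)
  check_prior(prior)
  if (prior$kind == "NIP")
    return(c(lambda1 = 0, lambda2 = 0, theta1 = 0, theta2 = 0, pi1 = 0))
  c(lambda1 = (prior$a11 - 1) / omega$lambda1 - prior$b11,
    lambda2 = (prior$a12 - 1) / omega$lambda2 - prior$b12,
    theta1 = (prior$a21 - 1) / omega$theta1 - prior$b21,
    theta2 = (prior$a22 - 1) / omega$theta2 - prior$b22,
    pi1 = (prior$a1 - 1) / omega$pi1 - (prior$b1 - 1) / (1 - omega$pi1))
}

check_prior <- function(prior) {
  if (!inherits(prior, "mixged_prior"))
    stop("'prior' must be built by prior_nip() or prior_ip()",
         call. = FALSE)
  invisible(TRUE)
}
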