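#' Parameter set of a two-component generalized exponential mixture
#'
#' Bundles the five parameters of the 2CMGED: shapes `lambda1`, `lambda2`,
#' rates `theta1`, `theta2` and the first mixing weight `pi1` (the second
#' weight is implied as `1 - pi1` and never stored). Validation rejects
#' non-positive shapes/rates and weights outside the open interval (0, 1).
#'
#' @param lambda1,theta1 shape and rate of component 1 (both `> 0`).
#' @param lambda2,theta2 shape and rate of component 2 (both `> 0`).
#' @param pi1 mixing weight of component 1, in (0, 1).
#' @return an object of class `"mixged_par"`: a named list with the five
#'   fields above.
#' @examples
#' mixged_par(0.50, 1.20, 0.75, 1.50, 0.45)
#' @export
mixged_par <- function(lambda1, theta1, lambda2, theta2, pi1) {
  check_ged_par(lambda1, theta1)
  check_ged_par(lambda2, theta2)
  if (!is.finite(pi1) || pi1 <= 0 || pi1 >= 1)
    stop("'pi1' must lie strictly between 0 and 1", call. = FALSE)
  structure(list(lambda1 = lambda1, theta1 = theta1,
                 lambda2 = lambda2, theta2 = theta2, pi1 = pi1),
            class = "mixged_par")
}

#' @export
print.mixged_par <- function(x, ...) {
  cat("Two-component generalized exponential mixture parameters\n")
  cat(sprintf("  component 1: lambda = %.4g, theta = %.4g  (weight %.4g)\n",
              x$lambda1, x$theta1, x$pi1))
  cat(sprintf("  component 2: lambda = %.4g, theta = %.4g  (weight %.4g)\n",
              x$lambda2, x$theta2, 1 - x$pi1))
  invisible(x)
}

# internal: parameter vector in the canonical order used throughout
# (lambda1, lambda2, theta1, theta2, pi1)
par_vec <- function(omega) {
  c(lambda1 = omega$lambda1, lambda2 = omega$lambda2,
    theta1 = omega$theta1, theta2 = omega$theta2, pi1 = omega$pi1)
}

vec_par <- function(v) {
  mixged_par(lambda1 = v[[1]], theta1 = v[[3]],
             lambda2 = v[[2]], theta2 = v[[4]], pi1 = v[[5]])
}

as_mixged_par <- function(omega) {
  if (inherits(omega, "mixged_par")) return(omega)
  if (is.numeric(omega) && length(omega) == 5) {
    # accept (lambda1, theta1, lambda2, theta2, pi1) as printed in tables
    return(mixged_par(omega[[1]], omega[[2]], omega[[3]], omega[[4]],
                      omega[[5]]))
  }
  stop("'omega' must be a 'mixged_par' or a numeric 5-vector ",
       "(lambda1, theta1, lambda2, theta2, pi1)", call. = FALSE)
}

#' The two-component generalized exponential mixture (2CMGED)
#'
#' Density, distribution function and labelled random generation for the
#' mixture \eqn{f(x) = \pi_1 f_1(x) + (1-\pi_1) f_2(x)} of two GEDs. With
#' both shapes equal to 1 the model reduces to the two-component
#' exponential mixture (2CMED).
#'
#' `rmixged` draws each observation by first drawing a uniform `u` and
#' assigning component 1 iff `u <= pi1`, then inverting the component CDF;
#' it returns the component labels alongside the times, as needed by the
#' labelled censored likelihood.
#'
#' @param x,q vector of non-negative quantiles.
#' @param n number of draws.
#' @param omega a [mixged_par()] (or numeric 5-vector
#'   `(lambda1, theta1, lambda2, theta2, pi1)`).
#' @param log,log.p logical; return log values.
#' @return `dmixged`/`pmixged` numeric vectors; `rmixged` a `data.frame`
#'   with columns `time` and `label` (1 or 2).
#' @examples
#' om <- mixged_par(0.50, 1.20, 0.75, 1.50, 0.45)
#' dmixged(1, om)
#' pmixged(1, om)           # 1 - R(1) = 0.8313
#' rmixged(5, om)
#' @name mixged
NULL

#' @rdname mixged
#' @export
dmixged <- function(x, omega, log = FALSE) {
  omega <- as_mixged_par(omega)
  d <- omega$pi1 * dged(x, omega$lambda1, omega$theta1) +
    (1 - omega$pi1) * dged(x, omega$lambda2, omega$theta2)
  if (log) log(d) else d
}

#' @rdname mixged
#' @export
pmixged <- function(q, omega, log.p = FALSE) {
  omega <- as_mixged_par(omega)
  p <- omega$pi1 * pged(q, omega$lambda1, omega$theta1) +
    (1 - omega$pi1) * pged(q, omega$lambda2, omega$theta2)
  if (log.p) log(p) else p
}

#' @rdname mixged
#' @export
rmixged <- function(n, omega) {
  omega <- as_mixged_par(omega)
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  u <- stats::runif(n)
  label <- ifelse(u <= omega$pi1, 1L, 2L)
  v <- stats::runif(n)
  lam <- ifelse(label == 1L, omega$lambda1, omega$lambda2)
  th <- ifelse(label == 1L, omega$theta1, omega$theta2)
  time <- -log1p(-v^(1 / lam)) / th
  data.frame(time = time, label = label)
}
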