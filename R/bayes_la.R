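#' Workspace for Lindley's approximation
#'
#' Precomputes every sample-level quantity that Lindley's expansion of a
#' posterior expectation needs: the maximum-likelihood fit, the curvature
#' matrix `sigma` (inverse negative Hessian of the log-likelihood at the
#' MLE), the 5x5x5 array of third log-likelihood derivatives `L_ijk`, the
#' contracted vector `A_i = sum_jk sigma_jk L_jki`, the prior gradient
#' `P`, and the prior shift `d = sigma P`. Building the workspace once
#' lets many functionals be approximated at negligible extra cost.
#'
#' @param sample a labelled [censored_sample()].
#' @param prior a [prior_nip()] or [prior_ip()].
#' @param mle optional precomputed [fit_mixged()] result.
#' @return an object of class `"lindley_ws"`.
#' @export
lindley_workspace <- function(sample, prior = prior_nip(), mle = NULL) {
  check_prior(prior)
  if (is.null(mle)) mle <- fit_mixged(sample)
  if (!isTRUE(mle$converged))
    stop("Lindley's approximation requires a converged MLE", call. = FALSE)
  v <- mle$par_vec
  p <- mle$pieces
  if (is.null(p)) p <- sample_pieces(sample)
  Lijk <- third_derivs_pieces(p, v)
  sigma <- mle$sigma
  A <- vapply(1:5, function(i) sum(sigma * Lijk[, , i]), numeric(1))
  P <- prior_grad(mle$par, prior)
  structure(list(mle = mle, prior = prior, v = v, sigma = sigma,
                 Lijk = Lijk, A = A, P = P,
                 d = as.numeric(sigma %*% P)),
            class = "lindley_ws")
}

#' Lindley approximation to a posterior expectation
#'
#' Approximates `E[w(Omega) | data]` by the large-sample expansion around
#' the MLE:
#' \deqn{E[w] \approx w(\hat\Omega) + \sum_i g_i d_i
#'   + \tfrac12\sum_{ij} g_{ij}\sigma_{ij}
#'   + \tfrac12\sum_i A_i B_i,}
#' where `g` and `g_ij` are the gradient and Hessian of `w`,
#' `d = sigma P` carries the prior gradient (zero under the flat prior),
#' `B = sigma g`, and `A_i` contracts the third log-likelihood
#' derivatives with `sigma`. The gradient and Hessian of `w` may be
#' supplied analytically; if omitted they are computed by central finite
#' differences.
#'
#' @param ws a [lindley_workspace()].
#' @param w function of the parameter 5-vector
#'   `(lambda1, lambda2, theta1, theta2, pi1)`, or a precomputed value.
#' @param grad,hess optional gradient 5-vector and 5x5 Hessian of `w` at
#'   the MLE; computed numerically from `w` when `NULL`.
#' @return the approximate posterior expectation, a single number.
#' @examples
#' om <- mixged_par(0.5, 1.2, 0.75, 1.5, 0.45)
#' set.seed(1)
#' s <- censor_conventional(rmixged(300, om), 0.2)
#' ws <- lindley_workspace(s)
#' lindley_expectation(ws, function(v) v[3])   # E[theta1 | data]
#' @export
lindley_expectation <- function(ws, w, grad = NULL, hess = NULL) {
  stopifnot(inherits(ws, "lindley_ws"))
  v <- ws$v
  if (is.function(w)) {
    w0 <- w(v)
    if (is.null(grad)) grad <- pracma::grad(w, v)
    if (is.null(hess)) hess <- pracma::hessian(w, v)
  } else {
    w0 <- w
    if (is.null(grad) || is.null(hess))
      stop("'grad' and 'hess' are required when 'w' is not a function",
           call. = FALSE)
  }
  B <- as.numeric(ws$sigma %*% grad)
  w0 + sum(grad * ws$d) + 0.5 * sum(hess * ws$sigma) +
    0.5 * sum(ws$A * B)
}

# expectation of a function of a single coordinate c, with analytic first
# and second derivatives w1, w2 at the MLE value
lindley_coord <- function(ws, c, w0, w1, w2) {
  w0 + w1 * ws$d[c] + 0.5 * w2 * ws$sigma[c, c] +
    0.5 * w1 * sum(ws$A * ws$sigma[, c])
}

# posterior moments of coordinate c needed by the four losses:
# E[x], E[x^2], E[1/x], E[log x], E[e^{-a x}]
la_coord_moments <- function(ws, c, linex_a = 1) {
  x <- ws$v[c]
  list(m1 = lindley_coord(ws, c, x, 1, 0),
       m2 = lindley_coord(ws, c, x^2, 2 * x, 2),
       minv = lindley_coord(ws, c, 1 / x, -1 / x^2, 2 / x^3),
       mlog = lindley_coord(ws, c, log(x), 1 / x, -1 / x^2),
       mexp = lindley_coord(ws, c, exp(-linex_a * x),
                            -linex_a * exp(-linex_a * x),
                            linex_a^2 * exp(-linex_a * x)))
}

# Bayes estimate and posterior risk from the five posterior moments of a
# scalar quantity, for one loss function. Risks are the posterior
# expected losses at the Bayes estimate:
#   SELF: E[x^2] - E[x]^2          PLF: 2(sqrt(E[x^2]) - E[x])
#   ELF:  log E[1/x] + E[log x]    LLF (shape a): a (E[x] - estimate)
# Approximation error can push a risk slightly negative; risks are
# floored at zero. An estimate outside its admissible range is flagged.
loss_estimate <- function(mom, loss, linex_a = 1) {
  est <- NA_real_; risk <- NA_real_; flag <- NA_character_
  if (loss == "SELF") {
    est <- mom$m1
    risk <- mom$m2 - mom$m1^2
  } else if (loss == "PLF") {
    if (mom$m2 <= 0) flag <- "E[x^2] <= 0" else {
      est <- sqrt(mom$m2)
      risk <- 2 * (sqrt(mom$m2) - mom$m1)
    }
  } else if (loss == "ELF") {
    if (mom$minv <= 0) flag <- "E[1/x] <= 0" else {
      est <- 1 / mom$minv
      risk <- log(mom$minv) + mom$mlog
    }
  } else if (loss == "LLF") {
    if (mom$mexp <= 0) flag <- "E[exp(-a x)] <= 0" else {
      est <- -log(mom$mexp) / linex_a
      risk <- linex_a * (mom$m1 - est)
    }
  } else stop("unknown loss '", loss, "'", call. = FALSE)
  if (!is.na(risk)) risk <- max(risk, 0)
  list(estimate = est, posterior_risk = risk, flag = flag)
}

par_names <- c("lambda1", "lambda2", "theta1", "theta2", "pi1")
loss_names <- c("SELF", "PLF", "ELF", "LLF")

#' Bayes estimates of the mixture parameters by Lindley's approximation
#'
#' Computes, for each of the five parameters, the Bayes estimate and the
#' posterior risk under the requested loss function:
#' squared error (`SELF`, posterior mean), precautionary (`PLF`,
#' `sqrt(E[x^2])`), entropy (`ELF`, `1/E[1/x]`) and LINEX (`LLF`,
#' `-log(E[exp(-a x)])/a`, shape `a = 1` by default). All posterior
#' expectations come from [lindley_expectation()] with analytic
#' derivative bundles for the elementary transforms.
#'
#' @inheritParams lindley_workspace
#' @param loss one of `"SELF"`, `"PLF"`, `"ELF"`, `"LLF"`.
#' @param linex_a LINEX shape constant.
#' @param ws optional precomputed [lindley_workspace()] (overrides
#'   `sample`/`prior`/`mle`).
#' @return an object of class `"mixged_bayes"`: a `data.frame` with one
#'   row per parameter (`parameter`, `estimate`, `posterior_risk`,
#'   `flag`) and metadata attributes `method`, `prior`, `loss`.
#' @examples
#' om <- mixged_par(0.5, 1.2, 0.75, 1.5, 0.45)
#' set.seed(1)
#' s <- censor_conventional(rmixged(300, om), 0.2)
#' bayes_la(s, prior_nip(), "SELF")
#' @export
bayes_la <- function(sample, prior = prior_nip(), loss = "SELF",
                     linex_a = 1, mle = NULL, ws = NULL) {
  loss <- match.arg(toupper(loss), loss_names)
  if (is.null(ws)) ws <- lindley_workspace(sample, prior, mle)
  rows <- lapply(1:5, function(c) {
    mom <- la_coord_moments(ws, c, linex_a)
    loss_estimate(mom, loss, linex_a)
  })
  bayes_result(rows, method = "LA", prior = ws$prior$kind, loss = loss)
}

bayes_result <- function(rows, method, prior, loss) {
  out <- data.frame(parameter = par_names,
                    estimate = vapply(rows, `[[`, numeric(1), "estimate"),
                    posterior_risk = vapply(rows, `[[`, numeric(1),
                                            "posterior_risk"),
                    flag = vapply(rows, `[[`, character(1), "flag"))
  structure(out, method = method, prior = prior, loss = loss,
            class = c("mixged_bayes", "data.frame"))
}

#' @export
print.mixged_bayes <- function(x, ...) {
  cat(sprintf("Bayes estimates (%s, %s prior, %s loss)\n",
              attr(x, "method"), attr(x, "prior"), attr(x, "loss")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
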