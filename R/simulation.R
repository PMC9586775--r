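#' Configuration of a Monte-Carlo censoring study
#'
#' Bundles the study conditions: sample size, censoring rate, replication
#' count, seed, censoring scheme and true parameter values. The number of
#' censored items per replication is `round(n * censor_rate)`
#' (half-up rounding).
#'
#' @param n sample size per replication.
#' @param censor_rate fraction censored, in `[0, 1)`.
#' @param reps number of replications, `>= 1`.
#' @param seed integer seed; the whole study is reproducible from it.
#' @param scheme `"conventional"` (censored items enter through the
#'   pooled survival factor at the largest observed failure) or `"ce"`
#'   (censored items replaced by conditional expectations and the
#'   completed sample analysed with the complete-data likelihood).
#' @param true_params a [mixged_par()] of generating values.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(n, censor_rate = 0.20, reps, seed,
                       scheme = c("conventional", "ce"),
                       true_params = mixged_par(0.50, 1.20, 0.75, 1.50,
                                                0.45)) {
  scheme <- match.arg(scheme)
  if (reps < 1) stop("'reps' must be at least 1", call. = FALSE)
  if (n < 2) stop("'n' must be at least 2", call. = FALSE)
  structure(list(n = as.integer(n), censor_rate = censor_rate,
                 reps = as.integer(reps), seed = as.integer(seed),
                 scheme = scheme,
                 true_params = as_mixged_par(true_params)),
            class = "sim_config")
}

#' Monte-Carlo study of the censored-mixture Bayes estimators
#'
#' Repeats, `reps` times: draw a labelled mixture sample of size `n`,
#' censor it under the configured scheme, fit the MLE, and compute Bayes
#' estimates with posterior risks for every requested (method, prior,
#' loss) combination — sharing the MLE, the third-derivative workspace
#' and the importance-sampling draws across combinations within a
#' replication. Reported estimates and risks are the replication
#' averages. Replications whose MLE fails to converge are skipped and
#' counted; the study aborts if more than `max_fail_frac` of the
#' replications fail.
#'
#' @param config a [sim_config()].
#' @param methods subset of `c("LA", "IS")`.
#' @param priors subset of `c("NIP", "IP")`.
#' @param losses subset of `c("SELF", "PLF", "ELF", "LLF")`.
#' @param m_is importance-sampling draws per replication.
#' @param linex_a LINEX shape constant.
#' @param ip informative prior; defaults to
#'   `prior_ip_default(config$true_params)` (prior means matched to the
#'   generating values).
#' @param max_fail_frac abort threshold for the replication failure rate.
#' @return a tidy `data.frame` with columns `method`, `prior`, `loss`,
#'   `n`, `censor_rate`, `scheme`, `parameter`, `estimate`,
#'   `posterior_risk`, `reps`, `seed`, plus attributes `n_failed` and
#'   `n_flagged`.
#' @examples
#' cfg <- sim_config(n = 50, reps = 5, seed = 1)
#' run_simulation_study(cfg, methods = "LA", priors = "NIP",
#'                      losses = "SELF", m_is = 500)
#' @export
run_simulation_study <- function(config,
                                 methods = c("LA", "IS"),
                                 priors = c("NIP", "IP"),
                                 losses = loss_names,
                                 m_is = 2000, linex_a = 1, ip = NULL,
                                 max_fail_frac = 0.10) {
  stopifnot(inherits(config, "sim_config"))
  methods <- match.arg(methods, c("LA", "IS"), several.ok = TRUE)
  priors <- match.arg(priors, c("NIP", "IP"), several.ok = TRUE)
  losses <- match.arg(toupper(losses), loss_names, several.ok = TRUE)
  if ("IP" %in% priors && is.null(ip))
    ip <- prior_ip_default(config$true_params)
  prior_obj <- list(NIP = prior_nip(), IP = ip)

  dims <- c(length(methods), length(priors), length(losses), 5L)
  est_sum <- array(0, dims); risk_sum <- array(0, dims)
  cnt <- array(0L, dims)
  n_failed <- 0L; n_flagged <- 0L

  set.seed(config$seed)
  for (rep in seq_len(config$reps)) {
    lab <- rmixged(config$n, config$true_params)
    cs <- if (config$scheme == "conventional")
      censor_conventional(lab, config$censor_rate)
    else censor_ce(lab, config$censor_rate, config$true_params)

    mle <- tryCatch(fit_mixged(cs), error = function(e) NULL)
    if (is.null(mle) || !mle$converged) { n_failed <- n_failed + 1L; next }

    ws0 <- if ("LA" %in% methods)
      tryCatch(lindley_workspace(cs, prior_nip(), mle),
               error = function(e) NULL) else NULL
    if ("LA" %in% methods && is.null(ws0)) { n_failed <- n_failed + 1L; next }

    for (pi in seq_along(priors)) {
      pr <- prior_obj[[priors[pi]]]
      ws <- NULL; dr <- NULL
      if ("LA" %in% methods) {
        ws <- ws0
        if (priors[pi] == "IP") {   # only the prior-gradient terms change
          ws$prior <- pr
          ws$P <- prior_grad(mle$par, pr)
          ws$d <- as.numeric(ws$sigma %*% ws$P)
        }
      }
      if ("IS" %in% methods) dr <- is_draws(cs, pr, m = m_is)
      for (mi in seq_along(methods)) {
        for (li in seq_along(losses)) {
          res <- if (methods[mi] == "LA")
            bayes_la(cs, ws = ws, loss = losses[li], linex_a = linex_a)
          else
            bayes_is(cs, draws = dr, loss = losses[li], linex_a = linex_a)
          ok <- is.finite(res$estimate) & is.finite(res$posterior_risk)
          n_flagged <- n_flagged + sum(!ok)
          est_sum[mi, pi, li, ok] <- est_sum[mi, pi, li, ok] +
            res$estimate[ok]
          risk_sum[mi, pi, li, ok] <- risk_sum[mi, pi, li, ok] +
            res$posterior_risk[ok]
          cnt[mi, pi, li, ok] <- cnt[mi, pi, li, ok] + 1L
        }
      }
    }
  }
  if (n_failed > max_fail_frac * config$reps)
    stop(sprintf(paste("simulation aborted: %d of %d replications failed",
                       "to produce a converged fit"),
                 n_failed, config$reps), call. = FALSE)

  grid <- expand.grid(parameter = par_names, loss = losses,
                      prior = priors, method = methods,
                      stringsAsFactors = FALSE)
  idx <- cbind(match(grid$method, methods), match(grid$prior, priors),
               match(grid$loss, losses), match(grid$parameter, par_names))
  out <- data.frame(method = grid$method, prior = grid$prior,
                    loss = grid$loss, n = config$n,
                    censor_rate = config$censor_rate,
                    scheme = config$scheme, parameter = grid$parameter,
                    estimate = est_sum[idx] / pmax(cnt[idx], 1L),
                    posterior_risk = risk_sum[idx] / pmax(cnt[idx], 1L),
                    reps = cnt[idx], seed = config$seed)
  structure(out, n_failed = n_failed, n_flagged = n_flagged)
}

#' Write simulation results as tidy CSV
#'
#' @param results a data frame from [run_simulation_study()] (or several
#'   row-bound together).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
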