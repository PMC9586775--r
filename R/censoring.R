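#' Right-censored sample container
#'
#' Holds lifetimes with event-status flags (1 = observed failure,
#' 0 = right censored), optional component labels, and the censoring
#' anchor `t_anchor` — the time `t` entering the survival factor
#' `[1 - F(t)]^{n-r}` of the censored mixture likelihood. When a sample is
#' produced by the conventional largest-order-statistic scheme, `t_anchor`
#' is the largest observed failure time `x_r`.
#'
#' @param time numeric vector of non-negative lifetimes.
#' @param status integer vector, 1 = observed failure, 0 = censored.
#'   Defaults to all observed.
#' @param label optional integer vector of component indices (1 or 2) for
#'   the observed failures; may be `NA` for censored entries.
#' @param t_anchor censoring anchor; defaults to the largest observed
#'   failure time.
#' @return an object of class `"censored_sample"`.
#' @examples
#' censored_sample(c(1, 2, 3, 4), status = c(1, 1, 1, 0),
#'                 label = c(1, 2, 1, NA))
#' @export
censored_sample <- function(time, status = rep(1L, length(time)),
                            label = NULL, t_anchor = NULL) {
  if (length(time) == 0L) stop("'time' must be nonempty", call. = FALSE)
  if (length(status) != length(time))
    stop("'time' and 'status' must have equal length", call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0))
    stop("'time' must be finite and non-negative", call. = FALSE)
  status <- as.integer(status)
  if (!all(status %in% c(0L, 1L)))
    stop("'status' must be 0 (censored) or 1 (observed)", call. = FALSE)
  if (!any(status == 1L))
    stop("sample must contain at least one observed failure", call. = FALSE)
  if (!is.null(label)) {
    if (length(label) != length(time))
      stop("'label' must match 'time' in length", call. = FALSE)
    label <- as.integer(label)
    if (!all(label[!is.na(label)] %in% c(1L, 2L)))
      stop("'label' entries must be 1 or 2 (or NA)", call. = FALSE)
  }
  if (is.null(t_anchor)) t_anchor <- max(time[status == 1L])
  structure(list(time = time, status = status, label = label,
                 t_anchor = t_anchor),
            class = "censored_sample")
}

#' @export
print.censored_sample <- function(x, ...) {
  n <- length(x$time); r <- sum(x$status == 1L)
  cat(sprintf("Right-censored sample: n = %d, observed = %d, censored = %d\n",
              n, r, n - r))
  cat(sprintf("  censoring anchor t = %.6g\n", x$t_anchor))
  if (!is.null(x$label)) {
    r1 <- sum(x$status == 1L & x$label == 1L, na.rm = TRUE)
    r2 <- sum(x$status == 1L & x$label == 2L, na.rm = TRUE)
    cat(sprintf("  observed failures per component: r1 = %d, r2 = %d\n",
                r1, r2))
  }
  invisible(x)
}

# round-half-up, so censored counts are deterministic across platforms
round_half_up <- function(x) floor(x + 0.5)

#' Conventional right censoring of a labelled sample
#'
#' Implements the largest-order-statistic (type-II style) scheme: given a
#' complete labelled sample, the smallest `n - round(n * censor_rate)`
#' times are marked observed and the largest `round(n * censor_rate)` are
#' marked censored. The censoring anchor is set to the largest observed
#' failure `x_r`.
#'
#' @param sample a `data.frame` with columns `time` and `label`, as
#'   returned by [rmixged()].
#' @param censor_rate fraction censored, in `[0, 1)`.
#' @param t_anchor optional override for the anchor time for users who
#'   have a true study-termination time; defaults to `x_r`.
#' @return a [censored_sample()] retaining all labels (the likelihood only
#'   uses labels of observed failures).
#' @examples
#' s <- rmixged(20, mixged_par(0.5, 1.2, 0.75, 1.5, 0.45))
#' censor_conventional(s, 0.2)
#' @export
censor_conventional <- function(sample, censor_rate, t_anchor = NULL) {
  if (!is.finite(censor_rate) || censor_rate < 0 || censor_rate >= 1)
    stop("'censor_rate' must lie in [0, 1)", call. = FALSE)
  n <- nrow(sample)
  k <- round_half_up(n * censor_rate)
  if (n - k < 1L)
    stop("censoring rate leaves no observed items", call. = FALSE)
  ord <- order(sample$time)
  status <- integer(n)
  status[ord[seq_len(n - k)]] <- 1L
  censored_sample(time = sample$time, status = status,
                  label = sample$label, t_anchor = t_anchor)
}

#' Conditional-expectation censoring of a labelled sample
#'
#' Selects the censored set exactly as [censor_conventional()] (so with a
#' common random sample the two schemes censor the identical indices), but
#' instead of leaving the censored items at the anchor it replaces each
#' one by the conditional expectation `E[X | X > x_r]` of its component's
#' lifetime beyond the largest observed failure. The completed sample is
#' flagged all-observed, and downstream estimation uses the complete-data
#' likelihood.
#'
#' The component parameters feeding the conditional expectation are
#' supplied through `omega`: the true values in simulation studies, or
#' plug-in estimates in real-data use.
#'
#' @inheritParams censor_conventional
#' @param omega a [mixged_par()] supplying the per-component GED
#'   parameters used in the conditional expectation.
#' @return a completed [censored_sample()] with all `status = 1`.
#' @examples
#' om <- mixged_par(0.5, 1.2, 0.75, 1.5, 0.45)
#' s <- rmixged(20, om)
#' censor_ce(s, 0.2, om)
#' @export
censor_ce <- function(sample, censor_rate, omega) {
  omega <- as_mixged_par(omega)
  conv <- censor_conventional(sample, censor_rate)
  cens <- which(conv$status == 0L)
  if (length(cens)) {
    x_r <- conv$t_anchor
    ce1 <- ged_cexp(omega$lambda1, omega$theta1, x_r)
    ce2 <- ged_cexp(omega$lambda2, omega$theta2, x_r)
    conv$time[cens] <- ifelse(conv$label[cens] == 1L, ce1, ce2)
  }
  censored_sample(time = conv$time, status = rep(1L, length(conv$time)),
                  label = conv$label)
}

#' Read and write censored samples as delimited text
#'
#' `read_censored_sample` accepts two-column (`time`, `status`) or
#' three-column (`time`, `status`, `label`) CSV files; `status` is 1 for
#' an observed event and 0 for a censored one.
#'
#' @param path file path.
#' @param x a [censored_sample()].
#' @return `read_censored_sample` a [censored_sample()];
#'   `write_censored_sample` the path, invisibly.
#' @export
read_censored_sample <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time", "status") %in% names(d)))
    stop("file must have columns 'time' and 'status'", call. = FALSE)
  censored_sample(time = d$time, status = d$status,
                  label = if ("label" %in% names(d)) d$label else NULL)
}

#' @rdname read_censored_sample
#' @export
write_censored_sample <- function(x, path) {
  d <- data.frame(time = x$time, status = x$status)
  if (!is.null(x$label)) d$label <- x$label
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
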