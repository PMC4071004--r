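# Session filtering and condition-wise psychometric / chronometric fits.

#' Filter a session for analysis
#'
#' Removes the first trial and any stimulus trial whose reaction time
#' exceeds `rt_cutoff` (trials without an RT are kept). Null trials are
#' retained as prior-context markers. A `prior_response` column is added
#' before filtering: the response on the preceding trial, provided that
#' trial was a stimulus trial with a valid (unfiltered) response —
#' otherwise `NA`. The presented `prior_label` is kept regardless of
#' filtering, since the prior stimulus was seen even if its response was
#' discarded.
#'
#' @param session a `tc_session` (or compatible data.frame).
#' @param rt_cutoff reaction-time cutoff in ms (default 1000).
#' @return the filtered session; attribute `filter_log` records counts
#'   removed at each step.
#' @export
filter_trials <- function(session, rt_cutoff = 1000) {
  if (nrow(session) == 0) stop("session is empty")
  s <- as.data.frame(session)
  n <- nrow(s)
  is_stim <- !is.na(s$duration_ms)
  rt_bad <- is_stim & !is.na(s$rt_ms) & s$rt_ms > rt_cutoff
  resp_ok <- is_stim & !rt_bad & !is.na(s$response) &
    s$response %in% c("short", "long")
  s$prior_response <- c(NA_character_,
                        ifelse(resp_ok[-n], s$response[-n], NA_character_))
  if (is.null(s$prior_label))
    s$prior_label <- c(NA_character_, s$label[-n])
  keep <- rep(TRUE, n)
  keep[1] <- FALSE
  keep[rt_bad] <- FALSE
  out <- s[keep, , drop = FALSE]
  log <- list(n_input = n, n_first_removed = 1L,
              n_rt_removed = sum(rt_bad & seq_len(n) > 1L),
              n_output = nrow(out), rt_cutoff = rt_cutoff)
  structure(new_session(out, params = attr(session, "params"),
                        seed = attr(session, "seed"),
                        duration_set = attr(session, "duration_set")),
            filter_log = log)
}

#' Aggregate binary responses by duration level
#'
#' @param trials data.frame with `duration_ms` and `response`
#'   (`"short"`/`"long"`); null/unanswered trials are dropped.
#' @return data.frame with `duration_ms`, `n`, `n_long`, `p_long`.
#' @export
aggregate_responses <- function(trials) {
  ok <- !is.na(trials$duration_ms) & !is.na(trials$response) &
    trials$response %in% c("short", "long")
  t <- trials[ok, , drop = FALSE]
  if (nrow(t) == 0)
    return(data.frame(duration_ms = numeric(0), n = integer(0),
                      n_long = integer(0), p_long = numeric(0)))
  d <- sort(unique(t$duration_ms))
  n <- as.integer(table(factor(t$duration_ms, levels = d)))
  nl <- as.integer(tapply(t$response == "long",
                          factor(t$duration_ms, levels = d), sum))
  data.frame(duration_ms = d, n = n, n_long = nl, p_long = nl / n)
}

#' Fit a two-parameter logistic psychometric function
#'
#' Binomial maximum-likelihood fit of
#' `P(long | t) = 1 / (1 + exp(-(t - mu) / s))` in linear duration
#' space (no lapse or guess rate). Returns the bisection point
#' (`bp = mu`, the 50% point), the 25% and 75% thresholds
#' (`t25/t75 = mu -/+ s log 3`), the difference limen
#' (`dl = (t75 - t25)/2`) and the coefficient of variation
#' (`cv = dl/bp`).
#'
#' @param x raw trials (data.frame with `duration_ms`, `response`), or
#'   aggregated counts (`duration_ms`, `n`, `n_long`), or proportions
#'   (`duration_ms`, `n`, `p_long`); proportions may be non-integer
#'   (used for closed-form recovery checks).
#' @param min_per_level duration levels with fewer trials are dropped
#'   before fitting (condition cells depleted by RT filtering).
#' @param n_boot bootstrap replicates for threshold CIs (0 = none); see
#'   [bootstrap_thresholds()].
#' @param seed seed for the bootstrap.
#' @return an object of class `psychometric_fit`: list with `bp`, `dl`,
#'   `cv`, `t25`, `t75`, `mu`, `s`, `slope` (= 1/s per ms),
#'   `n_per_level`, `converged`, `data`, and (when bootstrapped)
#'   `ci_t25`, `ci_t75`.
#' @export
fit_psychometric <- function(x, min_per_level = 1, n_boot = 0,
                             seed = NULL) {
  agg <- if (all(c("duration_ms", "n") %in% names(x)) &&
             (("n_long" %in% names(x)) || ("p_long" %in% names(x)))) {
    a <- as.data.frame(x)
    if (is.null(a$p_long)) a$p_long <- a$n_long / a$n
    if (is.null(a$n_long)) a$n_long <- a$p_long * a$n
    a[order(a$duration_ms), , drop = FALSE]
  } else aggregate_responses(x)
  agg <- agg[agg$n >= min_per_level & agg$n > 0, , drop = FALSE]

  fit <- list(bp = NA_real_, dl = NA_real_, cv = NA_real_,
              t25 = NA_real_, t75 = NA_real_, mu = NA_real_,
              s = NA_real_, slope = NA_real_,
              n_per_level = stats::setNames(agg$n,
                                            round(agg$duration_ms)),
              converged = FALSE, data = agg)
  class(fit) <- "psychometric_fit"
  if (nrow(agg) < 2) return(fit)
  if (all(agg$p_long <= 0) || all(agg$p_long >= 1)) return(fit)

  g <- tryCatch(
    suppressWarnings(glm(p_long ~ duration_ms, family = binomial(),
                         weights = agg$n, data = agg,
                         control = list(epsilon = 1e-10, maxit = 100))),
    error = function(e) NULL)
  if (is.null(g)) return(fit)
  b <- unname(coef(g))
  if (any(!is.finite(b)) || b[2] <= 0) return(fit)
  mu <- -b[1] / b[2]
  s <- 1 / b[2]
  fit$mu <- fit$bp <- unname(mu)
  fit$s <- unname(s)
  fit$slope <- unname(b[2])
  fit$t25 <- fit$bp - s * log(3)
  fit$t75 <- fit$bp + s * log(3)
  fit$dl <- (fit$t75 - fit$t25) / 2
  fit$cv <- fit$dl / fit$bp
  fit$converged <- isTRUE(g$converged) && is.finite(fit$bp) && fit$bp > 0
  if (n_boot > 0 && fit$converged) {
    ci <- bootstrap_thresholds(fit, n_boot = n_boot, seed = seed)
    fit$ci_t25 <- ci$ci_t25
    fit$ci_t75 <- ci$ci_t75
  }
  fit
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<psychometric_fit> not converged (",
        sum(x$n_per_level), " trials)\n", sep = "")
  } else {
    cat(sprintf(
      "<psychometric_fit> BP=%.1f ms, DL=%.1f ms, CV=%.3f (n=%d)\n",
      x$bp, x$dl, x$cv, sum(x$n_per_level)))
  }
  invisible(x)
}

#' Bias-corrected bootstrap intervals for psychometric thresholds
#'
#' Parametric bootstrap: responses at each duration level are resampled
#' from the fitted curve (binomial with the observed level counts), the
#' logistic is refit, and bias-corrected percentile intervals are formed
#' for the 25% and 75% thresholds. Non-converged replicates are dropped;
#' an error is raised if fewer than 90% survive.
#'
#' @param fit a converged `psychometric_fit`.
#' @param n_boot number of replicates (default 1999).
#' @param level confidence level.
#' @param seed integer seed.
#' @return list with `ci_t25`, `ci_t75` (length-2 vectors), `n_used`.
#' @export
bootstrap_thresholds <- function(fit, n_boot = 1999, level = 0.95,
                                 seed = NULL) {
  if (!inherits(fit, "psychometric_fit") || !fit$converged)
    stop("`fit` must be a converged psychometric_fit")
  if (n_boot <= 0)
    return(list(ci_t25 = c(fit$t25, fit$t25),
                ci_t75 = c(fit$t75, fit$t75), n_used = 0L))
  agg <- fit$data
  p_hat <- 1 / (1 + exp(-(agg$duration_ms - fit$mu) / fit$s))
  n <- round(agg$n)
  res <- with_seed(seed, {
    t25 <- t75 <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      nl <- rbinom(length(n), n, p_hat)
      f <- fit_psychometric(data.frame(duration_ms = agg$duration_ms,
                                       n = n, n_long = nl))
      if (f$converged) { t25[b] <- f$t25; t75[b] <- f$t75 }
    }
    list(t25 = t25, t75 = t75)
  })
  ok <- !is.na(res$t25) & !is.na(res$t75)
  if (mean(ok) < 0.9)
    stop("bootstrap failed: fewer than 90% of replicates converged")
  bc_ci <- function(boot, est) {
    z0 <- qnorm(pmin(pmax(mean(boot < est), 1 / length(boot)),
                     1 - 1 / length(boot)))
    za <- qnorm(c((1 - level) / 2, 1 - (1 - level) / 2))
    unname(quantile(boot, pnorm(2 * z0 + za), names = FALSE))
  }
  list(ci_t25 = bc_ci(res$t25[ok], fit$t25),
       ci_t75 = bc_ci(res$t75[ok], fit$t75),
       n_used = sum(ok))
}

#' Chronometric function: mean reaction time per duration
#'
#' @param trials data.frame with `duration_ms` and `rt_ms`.
#' @param levels duration levels to report (default: observed levels);
#'   levels without trials are flagged with `n = 0` and `NA` means.
#' @return data.frame with `duration_ms`, `mean_rt`, `se_rt`, `n`.
#' @export
chronometric <- function(trials, levels = NULL) {
  ok <- !is.na(trials$duration_ms) & !is.na(trials$rt_ms)
  t <- trials[ok, , drop = FALSE]
  if (is.null(levels)) levels <- sort(unique(t$duration_ms))
  f <- factor(t$duration_ms, levels = levels)
  n <- as.integer(table(f))
  m <- as.numeric(tapply(t$rt_ms, f, mean))
  se <- as.numeric(tapply(t$rt_ms, f, function(x)
    if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_))
  data.frame(duration_ms = levels, mean_rt = m, se_rt = se, n = n)
}

#' Session-level exclusion rule
#'
#' A session is excluded when its full-session psychometric fit failed
#' to converge or its coefficient of variation is 1 or greater.
#'
#' @param fit the full-session `psychometric_fit`.
#' @return logical: `TRUE` if the session should be excluded.
#' @export
exclude_session <- function(fit) {
  !isTRUE(fit$converged) || !is.finite(fit$cv) || fit$cv >= 1
}
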