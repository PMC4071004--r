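# Carryover analysis: condition splits by prior response / prior
# duration, the two carryover indices, RT matrices, and cohort-level
# correlations.

session_duration_set <- function(session) {
  ds <- attr(session, "duration_set")
  if (is.null(ds)) stop("session carries no duration_set attribute")
  ds
}

#' Split trials by the previous trial's response
#'
#' Stimulus trials are assigned to the prior-"long" or prior-"short"
#' subset according to the response given on the preceding trial.
#' Trials whose prior trial was null, unanswered, or removed by the RT
#' filter belong to neither subset.
#'
#' @param session a filtered session (see [filter_trials()]).
#' @return list with `long`, `short` (data.frames) and `n_excluded`.
#' @export
split_by_prior_response <- function(session) {
  if (is.null(session$prior_response))
    stop("session lacks `prior_response`; run filter_trials() first")
  stim <- session[!is.na(session$duration_ms), , drop = FALSE]
  long <- stim[!is.na(stim$prior_response) & stim$prior_response == "long", ,
               drop = FALSE]
  short <- stim[!is.na(stim$prior_response) & stim$prior_response == "short", ,
                drop = FALSE]
  list(long = long, short = short,
       n_excluded = nrow(stim) - nrow(long) - nrow(short))
}

#' Split trials by the previous trial's presented duration
#'
#' Stimulus trials are assigned by the label presented on the preceding
#' trial (one of the duration labels or null). Assignment uses the
#' presented sequence: a prior stimulus was perceived even when its
#' response was later RT-filtered.
#'
#' @param session a filtered session.
#' @return named list of data.frames, one per prior label (null first).
#' @export
split_by_prior_duration <- function(session) {
  ds <- session_duration_set(session)
  labs <- c(ds$null_label, ds$labels)
  stim <- session[!is.na(session$duration_ms), , drop = FALSE]
  out <- lapply(labs, function(l)
    stim[!is.na(stim$prior_label) & stim$prior_label == l, , drop = FALSE])
  names(out) <- labs
  out
}

#' Full carryover profile of one session
#'
#' Fits the eleven condition psychometric curves (full session, two
#' prior-response conditions, eight prior-label conditions), computes
#' the decision-bias index and the perceptual-carryover slope, and the
#' RT matrices when reaction times are present.
#'
#' @param session a `tc_session`; filtered automatically (default RT
#'   cutoff) if `prior_response` is missing.
#' @param min_per_level minimum trials per duration level within a
#'   condition cell (default 4); sparser levels are dropped from that
#'   condition's fit.
#' @param rt_cutoff cutoff used if the session still needs filtering.
#' @return an object of class `carryover_profile`: list with `fit_full`,
#'   `fit_prior_long`, `fit_prior_short`, `fits_prior_duration` (named
#'   list, null first), `decision_bias` (ms, negative = assimilative),
#'   `perceptual_slope` (dimensionless, positive = contrastive),
#'   `session_cv`, `rt` (see [rt_analyses()]) or `NULL`, `n_curves`,
#'   `excluded` (session-level exclusion flag) and `flagged` (indices
#'   unavailable).
#' @export
carryover_profile <- function(session, min_per_level = 4,
                              rt_cutoff = 1000) {
  if (is.null(session$prior_response))
    session <- filter_trials(session, rt_cutoff = rt_cutoff)
  ds <- session_duration_set(session)
  stim <- session[!is.na(session$duration_ms), , drop = FALSE]

  fit_full <- fit_psychometric(stim, min_per_level = 1)
  by_resp <- split_by_prior_response(session)
  fit_long <- fit_psychometric(by_resp$long, min_per_level = min_per_level)
  fit_short <- fit_psychometric(by_resp$short, min_per_level = min_per_level)
  by_dur <- split_by_prior_duration(session)
  fits_dur <- lapply(by_dur, fit_psychometric,
                     min_per_level = min_per_level)

  bias <- if (fit_long$converged && fit_short$converged)
    fit_long$bp - fit_short$bp else NA_real_

  prior_ms <- ds$durations
  bps <- vapply(fits_dur[ds$labels], function(f)
    if (f$converged) f$bp else NA_real_, numeric(1))
  usable <- is.finite(bps)
  slope <- if (sum(usable) >= 5)
    unname(coef(lm(bps[usable] ~ prior_ms[usable]))[2]) else NA_real_

  rt <- if (any(!is.na(stim$rt_ms))) rt_analyses(session) else NULL

  structure(
    list(fit_full = fit_full, fit_prior_long = fit_long,
         fit_prior_short = fit_short, fits_prior_duration = fits_dur,
         decision_bias = bias, perceptual_slope = slope,
         session_cv = fit_full$cv, rt = rt,
         n_curves = 2L + 1L + length(fits_dur),
         excluded = exclude_session(fit_full),
         flagged = !is.finite(bias) || !is.finite(slope)),
    class = "carryover_profile")
}

#' @export
print.carryover_profile <- function(x, ...) {
  cat(sprintf(
    "<carryover_profile> bias=%s ms, slope=%s, session CV=%s%s\n",
    fmt_num(x$decision_bias), fmt_num(x$perceptual_slope, 4),
    fmt_num(x$session_cv, 3),
    if (x$excluded) " [excluded]" else if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

fmt_num <- function(x, digits = 1) {
  if (!is.finite(x)) "NA" else formatC(x, digits = digits, format = "f")
}

#' Decision-bias index
#'
#' Signed difference between the bisection points of the prior-response
#' conditions, `BP(prior long) - BP(prior short)`. Negative values mean
#' the current response is assimilated toward the previous response.
#'
#' @param profile a `carryover_profile`.
#' @return index in ms (`NA` if either condition fit failed).
#' @export
decision_bias_index <- function(profile) profile$decision_bias

#' Perceptual-carryover slope
#'
#' OLS slope of the condition bisection points against the prior
#' stimulus duration (linear ms scale) over the seven duration priors
#' (the null prior is excluded). Positive values indicate contrast
#' (perception pushed away from the prior duration), negative values
#' assimilation. Requires at least 5 of the 7 condition fits.
#'
#' @param profile a `carryover_profile`.
#' @return dimensionless slope (`NA` if undefined).
#' @export
perceptual_slope <- function(profile) profile$perceptual_slope

#' Reaction-time carryover analyses
#'
#' Cell means of RT for every (prior label x current duration) pairing,
#' marginal mean RT per prior label, and the OLS slope of RT against the
#' prior duration (duration priors only).
#'
#' @param session a filtered session with RTs.
#' @return list with `rt_matrix` (8 x 7, prior label x current
#'   duration, `NA` for empty cells), `rt_by_prior` (data.frame), and
#'   `prior_slope` (ms RT per ms prior duration).
#' @export
rt_analyses <- function(session) {
  ds <- session_duration_set(session)
  labs <- c(ds$null_label, ds$labels)
  stim <- session[!is.na(session$duration_ms) & !is.na(session$rt_ms) &
                    !is.na(session$prior_label), , drop = FALSE]
  pf <- factor(stim$prior_label, levels = labs)
  cf <- factor(stim$label, levels = ds$labels)
  mat <- tapply(stim$rt_ms, list(pf, cf), mean)
  dimnames(mat) <- list(prior = labs, current = round(ds$durations))
  marg <- tapply(stim$rt_ms, pf, mean)
  nn <- as.integer(table(pf))
  by_prior <- data.frame(prior_label = labs,
                         prior_ms = c(NA, ds$durations),
                         mean_rt = as.numeric(marg), n = nn)
  use <- is.finite(by_prior$prior_ms) & is.finite(by_prior$mean_rt)
  slope <- if (sum(use) >= 3)
    unname(coef(lm(mean_rt ~ prior_ms, data = by_prior[use, ]))[2])
  else NA_real_
  list(rt_matrix = mat, rt_by_prior = by_prior, prior_slope = slope)
}

#' Cohort-level correlations between carryover indices
#'
#' Pearson correlations across sessions between the decision-bias index
#' and (a) the perceptual-carryover slope, (b) the full-session CV.
#'
#' @param profiles list of `carryover_profile` objects.
#' @param drop_excluded drop session-level exclusions (CV >= 1 or
#'   non-converged) before correlating (default `TRUE`).
#' @return list with `r_bias_slope`, `r_bias_cv`, `n` (profiles used),
#'   `flagged` (`TRUE` when undefined, e.g. zero variance).
#' @export
cohort_correlations <- function(profiles, drop_excluded = TRUE) {
  bias <- vapply(profiles, function(p) p$decision_bias, numeric(1))
  slope <- vapply(profiles, function(p) p$perceptual_slope, numeric(1))
  cv <- vapply(profiles, function(p) p$session_cv, numeric(1))
  excl <- vapply(profiles, function(p) isTRUE(p$excluded), logical(1))
  ok <- is.finite(bias) & is.finite(slope) & is.finite(cv)
  if (drop_excluded) ok <- ok & !excl
  if (sum(ok) < 3)
    return(list(r_bias_slope = NA_real_, r_bias_cv = NA_real_,
                n = sum(ok), flagged = TRUE))
  if (sd(bias[ok]) == 0 || sd(slope[ok]) == 0 || sd(cv[ok]) == 0)
    return(list(r_bias_slope = NA_real_, r_bias_cv = NA_real_,
                n = sum(ok), flagged = TRUE))
  list(r_bias_slope = cor(bias[ok], slope[ok]),
       r_bias_cv = cor(bias[ok], cv[ok]),
       n = sum(ok), flagged = FALSE)
}

#' Repetition vs null-prior bisection comparison
#'
#' For each session, fits the psychometric function on trials whose
#' prior stimulus repeated the current duration and on trials whose
#' prior trial was null, and reports the paired BP difference. Under the
#' observer model (no repetition-suppression mechanism) the mean
#' difference is near zero.
#'
#' @param sessions list of (filtered or raw) `tc_session` objects.
#' @param min_per_level minimum trials per level within each condition.
#' @return list with `per_session` (data.frame of `bp_repeat`,
#'   `bp_null`, `diff`), `mean_diff`, `n_used`, `flagged`.
#' @export
repetition_check <- function(sessions, min_per_level = 4) {
  rows <- lapply(sessions, function(s) {
    if (is.null(s$prior_response)) s <- filter_trials(s)
    ds <- session_duration_set(s)
    stim <- s[!is.na(s$duration_ms), , drop = FALSE]
    rep_tr <- stim[!is.na(stim$prior_label) &
                     stim$prior_label == stim$label, , drop = FALSE]
    null_tr <- stim[!is.na(stim$prior_label) &
                      stim$prior_label == ds$null_label, , drop = FALSE]
    f_rep <- fit_psychometric(rep_tr, min_per_level = min_per_level)
    f_null <- fit_psychometric(null_tr, min_per_level = min_per_level)
    data.frame(
      bp_repeat = if (f_rep$converged) f_rep$bp else NA_real_,
      bp_null = if (f_null$converged) f_null$bp else NA_real_)
  })
  per <- do.call(rbind, rows)
  per$diff <- per$bp_repeat - per$bp_null
  ok <- is.finite(per$diff)
  list(per_session = per,
       mean_diff = if (any(ok)) mean(per$diff[ok]) else NA_real_,
       n_used = sum(ok), flagged = !any(ok))
}
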