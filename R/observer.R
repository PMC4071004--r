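# Ideal observer for temporal bisection with a leaky memory prior.
#
# On each stimulus trial the observer (i) perceives the duration as a
# Gaussian draw whose sd scales with the duration (scalar timing),
# (ii) forms a criterion as the exponentially weighted geometric mean of
# the last M perceived durations, (iii) draws a per-trial uncertainty
# threshold with half-normal scale theta, and (iv) responds "long" or
# "short" when the percept-criterion difference exceeds the threshold,
# otherwise repeats the previous response.

OBSERVER_VARIANTS <- c("full", "unlimited_prior", "zero_uncertainty",
                       "zero_weighting", "memory_based_uncertainty")

#' Observer model parameters
#'
#' @param M memory window in trials (integer >= 1).
#' @param theta uncertainty threshold scale in ms (>= 0).
#' @param cv perceptual coefficient of variation (0 <= cv < 1); the
#'   sensory sd on a trial of duration `t` is `cv * t`.
#' @param variant one of `"full"`, `"unlimited_prior"`,
#'   `"zero_uncertainty"`, `"zero_weighting"`,
#'   `"memory_based_uncertainty"`.
#' @param seed integer seed for the simulation.
#' @return an object of class `observer_params`.
#' @export
observer_params <- function(M = 13, theta = 49, cv = 0.16,
                            variant = "full", seed = NULL) {
  variant <- match.arg(variant, OBSERVER_VARIANTS)
  if (M < 1 || M != round(M)) stop("`M` must be a positive integer")
  if (theta < 0) stop("`theta` must be non-negative")
  if (cv < 0 || cv >= 1) stop("`cv` must be in [0, 1)")
  structure(list(M = as.integer(M), theta = theta, cv = cv,
                 variant = variant, seed = seed),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params> M=", x$M, " theta=", x$theta, " ms, cv=", x$cv,
      ", variant=", x$variant, "\n", sep = "")
  invisible(x)
}

#' Noisy perception of a duration
#'
#' Draws perceived durations from `Normal(t, cv * t)`, truncated below
#' at 1 ms. The proportional sd implements the scalar property of
#' interval timing.
#'
#' @param t veridical duration(s) in ms (> 0).
#' @param cv coefficient of variation.
#' @param n draws per element of `t` (used when `t` is scalar).
#' @return perceived duration(s) in ms.
#' @export
perceive <- function(t, cv, n = length(t)) {
  if (any(t <= 0)) stop("`t` must be positive")
  tt <- if (length(t) == 1L) rep(t, n) else t
  pmax(rnorm(length(tt), mean = tt, sd = cv * tt), 1)
}

#' Exponential-decay memory weights
#'
#' Weights for the remembered durations, most recent first:
#' `w_j` proportional to `exp(-j / M)` for lag `j = 0..M-1`, normalized
#' to sum to one. Larger windows decay more slowly, so remote trials
#' retain more influence.
#'
#' @param M window length in trials (>= 1).
#' @param constant if `TRUE`, return uniform weights (the zero-weighting
#'   variant).
#' @return numeric weight vector of length `M` summing to 1.
#' @export
decay_weights <- function(M, constant = FALSE) {
  if (M < 1) stop("`M` must be at least 1")
  M <- as.integer(M)
  if (constant) return(rep(1 / M, M))
  w <- exp(-(seq_len(M) - 1L) / M)
  w / sum(w)
}

#' Weighted geometric-mean memory prior
#'
#' The criterion for the short/long judgment: `exp(sum(w * log(t)))`
#' over the remembered perceived durations. Always lies between the
#' smallest and largest remembered value.
#'
#' @param memory perceived durations in ms, most recent first.
#' @param weights weight vector of the same length (normalized
#'   internally).
#' @return prior mean in ms.
#' @export
prior_mean <- function(memory, weights) {
  if (length(memory) == 0) stop("memory is empty")
  if (length(weights) != length(memory))
    stop("`weights` must match `memory` in length")
  w <- weights / sum(weights)
  exp(sum(w * log(memory)))
}

#' Per-trial uncertainty threshold
#'
#' The threshold is the absolute value of a zero-mean Gaussian draw with
#' sd `theta` (equivalently: a Gaussian centred on the criterion with sd
#' `theta`, minus the criterion, in absolute value). Half-normal with
#' mean `theta * sqrt(2/pi)`.
#'
#' @param theta threshold scale in ms (>= 0).
#' @param n number of draws.
#' @return non-negative threshold(s) in ms.
#' @export
draw_threshold <- function(theta, n = 1) {
  if (theta < 0) stop("`theta` must be non-negative")
  abs(rnorm(n, 0, theta))
}

#' Decision rule
#'
#' Respond "long" if the percept exceeds the criterion by more than the
#' threshold, "short" if it falls below by more than the threshold;
#' otherwise repeat the previous response (guess fairly if there is
#' none).
#'
#' @param perceived perceived duration, ms.
#' @param tbar criterion (memory prior mean), ms.
#' @param threshold uncertainty threshold, ms (>= 0).
#' @param prev_response `"short"`, `"long"`, or `NA`/`"none"`.
#' @return `"short"` or `"long"`.
#' @export
decide <- function(perceived, tbar, threshold, prev_response = NA) {
  if (threshold < 0) stop("`threshold` must be non-negative")
  d <- perceived - tbar
  if (d > threshold) return("long")
  if (-d > threshold) return("short")
  if (is.na(prev_response) || prev_response == "none")
    return(c("short", "long")[1 + rbinom(1, 1, 0.5)])
  prev_response
}

#' Simulate an observer session over a trial sequence
#'
#' Runs the ideal observer through a counterbalanced sequence. The
#' memory buffer is seeded with three entries at the geometric mean of
#' the stimulus range (mirroring the example stimuli shown before a
#' session). Null trials contribute no percept, leave the memory
#' untouched, and carry the previous response forward.
#'
#' Variants: `unlimited_prior` lets the buffer (and the decay constant)
#' grow with the number of trials seen; `zero_uncertainty` forces
#' `theta = 0`; `zero_weighting` uses uniform memory weights;
#' `memory_based_uncertainty` replaces `theta` on each trial with the
#' standard deviation of the remembered durations (uncertainty tracks
#' the dispersion of the memory prior).
#'
#' @param seq a `trial_sequence` built over a `duration_set`.
#' @param params an `observer_params`.
#' @param seed optional seed overriding `params$seed`.
#' @return an object of class `tc_session`: a data.frame with columns
#'   `trial_index`, `label`, `duration_ms`, `perceived_ms`, `tbar_ms`,
#'   `threshold_ms`, `response`, `rt_ms`, `prior_label`, carrying the
#'   parameters and seed as attributes.
#' @export
simulate_session <- function(seq, params, seed = NULL) {
  if (!inherits(seq, "trial_sequence")) stop("`seq` must be a trial_sequence")
  if (!inherits(params, "observer_params"))
    stop("`params` must be observer_params")
  ds <- seq$duration_set
  if (is.null(ds)) stop("sequence has no duration_set; cannot simulate")
  if (is.null(seed)) seed <- params$seed
  labs <- seq$labels
  n <- length(labs)
  dur <- label_duration(ds, labs)
  is_null <- labs == ds$null_label
  variant <- params$variant
  theta0 <- if (variant == "zero_uncertainty") 0 else params$theta

  gm <- sqrt(ds$t_min * ds$t_max)
  perceived <- rep(NA_real_, n)
  tbar <- rep(NA_real_, n)
  thr <- rep(NA_real_, n)
  resp <- rep(NA_character_, n)

  # weight tables are reused across trials with equal buffer length
  wcache <- new.env(parent = emptyenv())
  get_w <- function(len, M) {
    key <- paste0(len, ".", M)
    w <- wcache[[key]]
    if (is.null(w)) {
      w <- if (variant == "zero_weighting") rep(1 / len, len)
      else {
        ww <- exp(-(seq_len(len) - 1L) / M)
        ww / sum(ww)
      }
      wcache[[key]] <- w
    }
    w
  }

  with_seed(seed, {
    memory <- rep(gm, 3) # most recent first
    if (variant != "unlimited_prior" && length(memory) > params$M)
      memory <- memory[seq_len(params$M)]
    prev <- NA_character_
    for (i in seq_len(n)) {
      if (is_null[i]) next
      p <- perceive(dur[i], params$cv, 1)
      len <- length(memory)
      M_eff <- if (variant == "unlimited_prior") len else params$M
      w <- get_w(len, M_eff)
      tb <- prior_mean(memory, w)
      th <- if (variant == "memory_based_uncertainty") {
        # threshold scale tied to the dispersion of remembered intervals
        draw_threshold(if (len > 1) sd(memory) else 0, 1)
      } else if (theta0 == 0) 0 else draw_threshold(theta0, 1)
      r <- decide(p, tb, th, prev)
      perceived[i] <- p
      tbar[i] <- tb
      thr[i] <- th
      resp[i] <- r
      prev <- r
      memory <- c(p, memory)
      if (variant != "unlimited_prior" && length(memory) > params$M)
        memory <- memory[seq_len(params$M)]
    }
  })

  out <- data.frame(
    trial_index = seq_len(n), label = labs, duration_ms = dur,
    perceived_ms = perceived, tbar_ms = tbar, threshold_ms = thr,
    response = resp, rt_ms = NA_real_,
    prior_label = c(NA_character_, labs[-n]),
    stringsAsFactors = FALSE)
  new_session(out, params = params, seed = seed, duration_set = ds)
}

new_session <- function(df, params = NULL, seed = NULL,
                        duration_set = NULL) {
  structure(df, params = params, seed = seed,
            duration_set = duration_set,
            class = c("tc_session", "data.frame"))
}

#' @export
print.tc_session <- function(x, ...) {
  n_null <- sum(is.na(x$duration_ms))
  cat("<tc_session> ", nrow(x), " trials (", nrow(x) - n_null,
      " stimulus, ", n_null, " null)\n", sep = "")
  p <- attr(x, "params")
  if (!is.null(p)) print(p)
  invisible(x)
}

#' Criterion trajectory of a simulated session
#'
#' @param session a simulated `tc_session` with recorded criterion
#'   values.
#' @return numeric vector of the memory-prior mean on each stimulus
#'   trial, in presentation order.
#' @export
prior_trajectory <- function(session) {
  tb <- session$tbar_ms[!is.na(session$tbar_ms)]
  if (length(tb) == 0) stop("session has no recorded criterion values")
  tb
}

#' Log-log spectral slope of a time series
#'
#' Welch-style averaged periodogram (Hann-windowed segments, 50%
#' overlap) followed by a least-squares fit of log10 power against
#' log10 frequency. A slope near -1 indicates 1/f (pink) structure; a
#' flat spectrum of white noise gives a slope near 0.
#'
#' @param x numeric series (length >= 64).
#' @param segment segment length (power of two recommended).
#' @return list with `slope`, `freq`, `power`, and `degenerate` (`TRUE`
#'   when the series has no variance).
#' @export
spectrum_slope <- function(x, segment = 128) {
  n <- length(x)
  if (n < 64) stop("series too short for a spectral estimate (need >= 64)")
  segment <- min(segment, n)
  if (sd(x) == 0 || !is.finite(sd(x)))
    return(list(slope = NA_real_, freq = numeric(0), power = numeric(0),
                degenerate = TRUE))
  x <- x - mean(x)
  step <- max(1L, floor(segment / 2))
  starts <- seq(1L, n - segment + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(segment) / (segment + 1)) # Hann
  acc <- numeric(floor(segment / 2))
  for (s in starts) {
    seg <- x[s:(s + segment - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- Mod(fft(seg))^2 / segment
    acc <- acc + sp[2:(floor(segment / 2) + 1L)]
  }
  pw <- acc / length(starts)
  fr <- (1:floor(segment / 2)) / segment
  keep <- pw > 0
  fit <- lm(log10(pw[keep]) ~ log10(fr[keep]))
  list(slope = unname(coef(fit)[2]), freq = fr, power = pw,
       degenerate = FALSE)
}

#' Central-tendency diagnostic for a simulated session
#'
#' For a binary-response task an "estimate" of each duration is not
#' observable; the minimal model-consistent construction used here takes
#' the percept when it exceeded the uncertainty threshold and the
#' criterion otherwise. Regression of these estimates toward the mean of
#' the stimulus set is the classic central-tendency signature.
#'
#' @param session a simulated `tc_session`.
#' @return data.frame with `duration_ms`, `mean_estimate_ms`, `n`; the
#'   regression slope of estimate on duration is attached as attribute
#'   `slope` (< 1 indicates central tendency).
#' @export
central_tendency <- function(session) {
  ok <- !is.na(session$perceived_ms)
  s <- session[ok, , drop = FALSE]
  est <- ifelse(abs(s$perceived_ms - s$tbar_ms) > s$threshold_ms,
                s$perceived_ms, s$tbar_ms)
  agg <- aggregate(est, list(duration_ms = s$duration_ms), mean)
  names(agg)[2] <- "mean_estimate_ms"
  agg$n <- as.integer(table(s$duration_ms)[as.character(agg$duration_ms)])
  sl <- unname(coef(lm(est ~ s$duration_ms))[2])
  structure(agg, slope = sl)
}
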