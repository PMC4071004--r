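# Synthetic participants: observer-model responses plus a parametric
# reaction-time model, so the full analysis pipeline (including RT
# filtering and chronometric analyses) is testable without human data.

#' Cohort presets for synthetic participants
#'
#' Group-level parameter distributions mirroring the fitted observer
#' values for the two task modalities: a shared memory window around 13
#' trials, an uncertainty threshold around 49 ms (auditory) or 84 ms
#' (visual), and fixed perceptual variability `cv = 0.16`. Per-subject
#' `M` and `theta` are Gaussian draws around these means (sd 4 trials
#' and 15 ms), clipped to `M` in \[1, 30\] and `theta` in \[1, 150\].
#'
#' The RT model is a package invention (only qualitative RT patterns
#' are being emulated): `rt = base - b_dur * log(duration) - drop *
#' 1[duration > geometric mean] + b_prior * prior_duration + noise`,
#' floored at 150 ms — RT declines with duration, drops once the
#' boundary has elapsed, and grows linearly with the prior duration.
#'
#' @param modality `"auditory"` or `"visual"`.
#' @param M_mean,theta_mean group means for the observer parameters.
#' @param M_sd,theta_sd between-subject standard deviations.
#' @param cv perceptual coefficient of variation.
#' @param rt_params list with `base` (ms), `b_dur` (ms per log-ms),
#'   `drop` (ms), `b_prior` (ms per ms), `noise_sd` (ms).
#' @return an object of class `cohort_preset`.
#' @export
cohort_preset <- function(modality = c("auditory", "visual"),
                          M_mean = 13,
                          theta_mean = NULL,
                          M_sd = 4, theta_sd = 15, cv = 0.16,
                          rt_params = list(base = 1250, b_dur = 120,
                                           drop = 50, b_prior = 0.1,
                                           noise_sd = 80)) {
  modality <- match.arg(modality)
  if (is.null(theta_mean))
    theta_mean <- if (modality == "auditory") 49 else 84
  stopifnot(M_sd >= 0, theta_sd >= 0,
            all(c("base", "b_dur", "drop", "b_prior", "noise_sd") %in%
                  names(rt_params)),
            rt_params$noise_sd >= 0)
  structure(list(modality = modality, M_mean = M_mean,
                 theta_mean = theta_mean, M_sd = M_sd,
                 theta_sd = theta_sd, cv = cv, rt_params = rt_params),
            class = "cohort_preset")
}

#' @export
print.cohort_preset <- function(x, ...) {
  cat("<cohort_preset> ", x$modality, ": M ~ N(", x$M_mean, ", ",
      x$M_sd, "), theta ~ N(", x$theta_mean, ", ", x$theta_sd,
      ") ms, cv=", x$cv, "\n", sep = "")
  invisible(x)
}

#' Simulate one synthetic participant
#'
#' Draws subject-level observer parameters from the preset, simulates
#' responses with the ideal observer on a fresh (or supplied)
#' counterbalanced sequence, and attaches model reaction times.
#'
#' @param preset a `cohort_preset`.
#' @param seed integer seed (drives parameter draw, sequence, observer
#'   noise and RT noise through derived substreams).
#' @param sequence optional `trial_sequence` to reuse.
#' @param duration_set stimulus set (default 300-900 ms, 7 levels).
#' @param multiplicity sequence multiplicity (default 8).
#' @return a `tc_session` with `rt_ms` filled in; the true subject
#'   parameters are attached as attribute `truth` (list with `M`,
#'   `theta`, `cv`, `rt_params`).
#' @export
synth_participant <- function(preset, seed = NULL, sequence = NULL,
                              duration_set = make_duration_set(),
                              multiplicity = 8) {
  stopifnot(inherits(preset, "cohort_preset"))
  ms <- if (is.null(seed)) NULL else seed
  par <- with_seed(if (is.null(ms)) NULL else derive_seed(ms, "subject"), {
    M <- round(rnorm(1, preset$M_mean, preset$M_sd))
    th <- rnorm(1, preset$theta_mean, preset$theta_sd)
    list(M = min(max(M, 1), 30), theta = min(max(th, 1), 150))
  })
  if (is.null(sequence))
    sequence <- generate_sequence(duration_set, multiplicity,
                                  seed = if (is.null(ms)) NULL else
                                    derive_seed(ms, "sequence"))
  op <- observer_params(M = par$M, theta = par$theta, cv = preset$cv,
                        variant = "full",
                        seed = if (is.null(ms)) NULL else
                          derive_seed(ms, "observer"))
  ses <- simulate_session(sequence, op)
  ds <- attr(ses, "duration_set")
  gm <- sqrt(ds$t_min * ds$t_max) # BP proxy for the post-boundary drop
  rp <- preset$rt_params
  prior_ms <- label_duration(ds, ses$prior_label)
  prior_ms[is.na(prior_ms)] <- 0
  stim <- !is.na(ses$duration_ms)
  rt <- with_seed(if (is.null(ms)) NULL else derive_seed(ms, "rt"), {
    mu <- rp$base - rp$b_dur * log(ses$duration_ms[stim]) -
      rp$drop * (ses$duration_ms[stim] > gm) +
      rp$b_prior * prior_ms[stim]
    pmax(mu + rnorm(sum(stim), 0, rp$noise_sd), 150)
  })
  ses$rt_ms[stim] <- rt
  attr(ses, "truth") <- list(M = par$M, theta = par$theta,
                             cv = preset$cv, rt_params = rp,
                             modality = preset$modality)
  ses
}

#' Simulate a synthetic cohort
#'
#' Generates `n` independent synthetic participants, each on a freshly
#' generated counterbalanced sequence, together with a manifest of the
#' true per-subject parameters for recovery scoring.
#'
#' @param n number of participants (default 40, one modality group).
#' @param preset a `cohort_preset`.
#' @param master_seed integer master seed; subject seeds are derived
#'   from it.
#' @param ... passed to [synth_participant()].
#' @return list with `sessions` (list of `tc_session`) and `manifest`
#'   (data.frame: subject, seed, M, theta, cv, modality and RT
#'   parameters).
#' @export
synth_cohort <- function(n = 40, preset = cohort_preset("auditory"),
                         master_seed = NULL, ...) {
  stopifnot(n >= 1)
  seeds <- vapply(seq_len(n), function(i)
    derive_seed(if (is.null(master_seed)) i else master_seed, i),
    integer(1))
  sessions <- lapply(seeds, function(s)
    synth_participant(preset, seed = s, ...))
  manifest <- do.call(rbind, lapply(seq_len(n), function(i) {
    tr <- attr(sessions[[i]], "truth")
    data.frame(subject = i, seed = seeds[i], M = tr$M,
               theta = tr$theta, cv = tr$cv, modality = tr$modality,
               rt_base = tr$rt_params$base, rt_b_dur = tr$rt_params$b_dur,
               rt_drop = tr$rt_params$drop,
               rt_b_prior = tr$rt_params$b_prior,
               rt_noise_sd = tr$rt_params$noise_sd)
  }))
  list(sessions = sessions, manifest = manifest)
}
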