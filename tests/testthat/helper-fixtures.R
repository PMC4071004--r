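# Shared fixtures, memoized so expensive objects (the 512-trial
# sequence, the 500-permutation Monte Carlo grid) are built once per
# test run and reused across files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

tc_ds <- function() memo("ds", make_duration_set(300, 900, 7))

# canonical 512-trial counterbalanced sequence
tc_seq <- function() memo("seq", generate_sequence(tc_ds(), 8, seed = 101))

# the full-model Monte Carlo grid shared by acceptance and property
# tests (500 permutations, M ~ U{1..30}, theta ~ U{1..150}, cv 0.16)
tc_grid <- function() memo("grid500",
                           run_grid(n_perm = 500, sequence = tc_seq(),
                                    seed = 11))

# one default full-model session + filtered version + profile
tc_session <- function() memo("session", {
  simulate_session(tc_seq(), observer_params(13, 49, 0.16, seed = 202))
})
tc_profile <- function() memo("profile",
                              carryover_profile(tc_session()))

# simulate a cohort of carryover profiles, one fresh sequence each
tc_cohort_indices <- function(variant, n, seedbase, Ms = NULL,
                              ths = NULL) {
  with_seed(seedbase, {
    if (is.null(Ms)) Ms <- sample(1:30, n, replace = TRUE)
    if (is.null(ths)) ths <- sample(1:150, n, replace = TRUE)
  })
  t(vapply(seq_len(n), function(i) {
    sq <- generate_sequence(tc_ds(), 8, seed = seedbase + i)
    p <- observer_params(M = Ms[i], theta = ths[i], cv = 0.16,
                         variant = variant, seed = seedbase * 2L + i)
    pr <- carryover_profile(simulate_session(sq, p))
    c(bias = pr$decision_bias, slope = pr$perceptual_slope,
      cv = pr$session_cv)
  }, numeric(3)))
}

# exact logistic response proportions at the stimulus durations
logistic_props <- function(mu, s, n = 1e4, ds = tc_ds()) {
  data.frame(duration_ms = ds$durations,
             n = rep(n, ds$n_levels),
             p_long = 1 / (1 + exp(-(ds$durations - mu) / s)))
}
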