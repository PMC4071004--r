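# Filtering and psychometric / chronometric fitting.

test_that("filtering removes the first trial and slow trials, keeps nulls", {
  ses <- tc_session()
  f0 <- filter_trials(ses)
  expect_equal(nrow(f0), 511) # no RTs recorded: only first-trial removal
  expect_equal(attr(f0, "filter_log")$n_rt_removed, 0)

  ses2 <- ses
  slow <- which(!is.na(ses2$duration_ms))[2:11]
  ses2$rt_ms[!is.na(ses2$duration_ms)] <- 500
  ses2$rt_ms[slow] <- 1200
  f <- filter_trials(ses2, rt_cutoff = 1000)
  expect_false(any(f$trial_index %in% slow))
  expect_equal(attr(f, "filter_log")$n_rt_removed, 10)
  # nulls retained (minus the removed first trial if it was null)
  expect_equal(sum(is.na(f$duration_ms)),
               sum(is.na(ses2$duration_ms[-1])))
  # prior_response is NA after nulls and after filtered trials
  after_null <- which(f$prior_label == "null")
  expect_true(all(is.na(f$prior_response[after_null])))
  after_slow <- which(f$trial_index %in% (slow + 1))
  expect_true(all(is.na(f$prior_response[after_slow])))
  # but the presented prior label is kept regardless
  expect_true(all(!is.na(f$prior_label)))
})

test_that("logistic fit recovers generating parameters from exact proportions", {
  # closed form: t75 - t25 = 2 s log 3, cv = s log 3 / mu
  d <- logistic_props(mu = 520, s = 60)
  fit <- fit_psychometric(d)
  expect_true(fit$converged)
  expect_equal(fit$bp, 520, tolerance = 1e-6)
  expect_equal(fit$s, 60, tolerance = 1e-6)
  expect_equal(fit$dl, 60 * log(3), tolerance = 1e-6)
  expect_equal(fit$cv, 60 * log(3) / 520, tolerance = 1e-6)
  expect_lt(fit$t25, fit$bp)
  expect_gt(fit$t75, fit$bp)
})

test_that("step data give a boundary BP and a vanishing DL", {
  ds <- tc_ds()
  d <- data.frame(duration_ms = ds$durations, n = 64,
                  n_long = ifelse(ds$durations >= 519, 64, 0))
  fit <- fit_psychometric(d)
  expect_gt(fit$bp, ds$durations[3])
  expect_lt(fit$bp, ds$durations[4])
  expect_lt(fit$dl, 10)
})

test_that("fits are scale-equivariant and degenerate data are flagged", {
  d <- logistic_props(mu = 520, s = 60)
  f1 <- fit_psychometric(d)
  d2 <- d
  d2$duration_ms <- d2$duration_ms * 3
  f2 <- fit_psychometric(d2)
  expect_equal(f2$bp, 3 * f1$bp, tolerance = 1e-6)
  expect_equal(f2$dl, 3 * f1$dl, tolerance = 1e-6)
  expect_equal(f2$cv, f1$cv, tolerance = 1e-8)
  # all-long responses cannot be fit
  dd <- data.frame(duration_ms = tc_ds()$durations, n = 10, n_long = 10)
  expect_false(fit_psychometric(dd)$converged)
  # fewer than two levels cannot be fit
  expect_false(fit_psychometric(
    data.frame(duration_ms = 500, n = 10, n_long = 5))$converged)
})

test_that("session exclusion triggers on CV >= 1 or failed convergence", {
  good <- fit_psychometric(logistic_props(520, 60))
  expect_false(exclude_session(good))
  # cv exactly 1 is excluded (boundary inclusive)
  borderline <- good
  borderline$cv <- 1
  expect_true(exclude_session(borderline))
  bad <- good
  bad$converged <- FALSE
  expect_true(exclude_session(bad))
})

test_that("bootstrap threshold intervals are deterministic and shrink with n", {
  with_seed(12, {
    p <- 1 / (1 + exp(-(tc_ds()$durations - 520) / 60))
    mk <- function(n) data.frame(duration_ms = tc_ds()$durations, n = n,
                                 n_long = rbinom(7, n, p))
    small <- fit_psychometric(mk(50))
    big <- fit_psychometric(mk(450))
    ci_s <- bootstrap_thresholds(small, n_boot = 400, seed = 1)
    ci_s2 <- bootstrap_thresholds(small, n_boot = 400, seed = 1)
    expect_identical(ci_s, ci_s2)
    ci_b <- bootstrap_thresholds(big, n_boot = 400, seed = 1)
    w_small <- diff(ci_s$ci_t75)
    w_big <- diff(ci_b$ci_t75)
    # 9x the data: width should shrink roughly 3x
    expect_gt(w_small / w_big, 1.8)
    expect_lt(w_small / w_big, 5)
  })
  # n_boot = 0 returns point estimates
  f <- fit_psychometric(logistic_props(520, 60))
  z <- bootstrap_thresholds(f, n_boot = 0)
  expect_equal(z$ci_t25, c(f$t25, f$t25))
})

test_that("chronometric means are per-level with missing levels flagged", {
  tr <- data.frame(duration_ms = rep(c(300, 520, 900), each = 5),
                   rt_ms = 500)
  ch <- chronometric(tr, levels = c(300, 520, 624, 900))
  expect_equal(ch$mean_rt[ch$duration_ms == 300], 500)
  expect_equal(ch$n[ch$duration_ms == 624], 0)
  expect_true(is.na(ch$mean_rt[ch$duration_ms == 624]))
})

test_that("synthetic RT model yields a declining chronometric curve", {
  preset <- cohort_preset("auditory")
  ses <- synth_participant(preset, seed = 77)
  f <- filter_trials(ses)
  ch <- chronometric(f[!is.na(f$duration_ms), ],
                     levels = tc_ds()$durations)
  # monotone decreasing on average: regression slope negative
  expect_lt(coef(lm(mean_rt ~ duration_ms, ch))[2], 0)
})
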