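# Ideal observer primitives and session simulation.

test_that("perception is unbiased, scalar, and exact at zero noise", {
  expect_identical(with_seed(1, perceive(600, 0)), 600)
  with_seed(2, {
    x <- perceive(600, 0.16, n = 1e5)
    expect_lt(abs(mean(x) - 600), 1)       # mean within 600 +/- 1
    expect_lt(abs(sd(x) - 96), 2)          # sd within 0.16*600 +/- 2
    # scalar property: sd proportional to t
    y <- perceive(300, 0.16, n = 1e5)
    z <- perceive(900, 0.16, n = 1e5)
    expect_equal(sd(z) / sd(y), 3, tolerance = 0.05)
  })
  expect_error(perceive(0, 0.16), "positive")
})

test_that("decay weights are normalized exponentials with ratio exp(-1/M)", {
  expect_identical(decay_weights(1), 1)
  w <- decay_weights(5)
  expect_equal(sum(w), 1)
  expect_equal(w[-1] / w[-5], rep(exp(-1 / 5), 4), tolerance = 1e-12)
  expect_true(all(diff(w) < 0))
  expect_equal(decay_weights(4, constant = TRUE), rep(0.25, 4))
  expect_error(decay_weights(0), "at least 1")
})

test_that("memory prior is the weighted geometric mean, bounded by memory", {
  expect_equal(prior_mean(rep(500, 4), decay_weights(4)), 500)
  expect_equal(prior_mean(c(300, 900), c(0.5, 0.5)), sqrt(300 * 900))
  expect_equal(prior_mean(c(400, 800), c(1, 0)), 400)
  with_seed(3, {
    for (i in 1:25) {
      mem <- runif(7, 200, 1000)
      tb <- prior_mean(mem, decay_weights(7))
      expect_gte(tb, min(mem))
      expect_lte(tb, max(mem))
    }
  })
  expect_error(prior_mean(numeric(0), numeric(0)), "empty")
  expect_error(prior_mean(c(1, 2), 1), "length")
})

test_that("uncertainty threshold is half-normal with mean theta*sqrt(2/pi)", {
  expect_identical(with_seed(1, draw_threshold(0)), 0)
  with_seed(4, {
    x <- draw_threshold(50, n = 1e5)
    expect_true(all(x >= 0))
    se <- 50 * sqrt(1 - 2 / pi) / sqrt(1e5)
    expect_lt(abs(mean(x) - 50 * sqrt(2 / pi)), 4 * se)
  })
})

test_that("decision rule: ideal beyond threshold, repeat within", {
  expect_identical(decide(600, 500, 0, "short"), "long")
  expect_identical(decide(510, 500, 50, "short"), "short")
  expect_identical(decide(400, 500, 50, "long"), "short")
  expect_true(with_seed(5, decide(500, 500, 50, NA)) %in%
                c("short", "long"))
})

test_that("session simulation is deterministic with the design counts", {
  ses <- tc_session()
  expect_equal(nrow(ses), 512)
  expect_equal(sum(!is.na(ses$response)), 448)
  expect_equal(sum(is.na(ses$duration_ms)), 64)
  # responses only on stimulus trials; prior_label bookkeeping
  expect_true(all(is.na(ses$response[is.na(ses$duration_ms)])))
  expect_identical(ses$prior_label[-1], ses$label[-512])
  ses2 <- simulate_session(tc_seq(), observer_params(13, 49, 0.16,
                                                     seed = 202))
  expect_identical(as.data.frame(ses), as.data.frame(ses2))
  # criterion stays within the perceivable range
  tb <- ses$tbar_ms[!is.na(ses$tbar_ms)]
  expect_true(all(tb > 0 & tb < 2000))
})

test_that("noiseless zero-threshold observer is the veridical comparator", {
  p <- observer_params(13, 0, 0, variant = "full", seed = 6)
  ses <- simulate_session(tc_seq(), p)
  ok <- !is.na(ses$response) &
    ses$perceived_ms != ses$tbar_ms # exact ties fall back on repeats
  expect_identical(ses$response[ok],
                   ifelse(ses$perceived_ms[ok] > ses$tbar_ms[ok],
                          "long", "short"))
  expect_identical(ses$perceived_ms[ok], ses$duration_ms[ok])
})

test_that("variant mechanics differ from the full model as specified", {
  sq <- tc_seq()
  z <- simulate_session(sq, observer_params(13, 84, 0.16,
                                            variant = "zero_uncertainty",
                                            seed = 7))
  expect_true(all(z$threshold_ms[!is.na(z$threshold_ms)] == 0))
  f <- simulate_session(sq, observer_params(13, 84, 0.16, seed = 7))
  expect_gt(mean(f$threshold_ms, na.rm = TRUE), 0)
  # zero-weighting and full differ only through the weighting
  w <- simulate_session(sq, observer_params(13, 84, 0.16,
                                            variant = "zero_weighting",
                                            seed = 7))
  expect_false(identical(w$tbar_ms, f$tbar_ms))
})

test_that("spectral slope separates white noise from smoothed series", {
  with_seed(8, {
    slopes <- vapply(1:10, function(i)
      spectrum_slope(rnorm(448))$slope, numeric(1))
    expect_lt(abs(mean(slopes)), 0.3) # flat spectrum of iid noise
  })
  expect_error(spectrum_slope(rnorm(10)), "too short")
  expect_true(spectrum_slope(rep(1, 100))$degenerate)
})

test_that("larger memory windows yield steeper (more 1/f) criterion spectra", {
  diffs <- vapply(1:20, function(i) {
    sq <- generate_sequence(tc_ds(), 8, seed = 300 + i)
    s30 <- simulate_session(sq, observer_params(30, 1, 0.16, seed = i))
    s2 <- simulate_session(sq, observer_params(2, 1, 0.16, seed = i))
    spectrum_slope(prior_trajectory(s30))$slope -
      spectrum_slope(prior_trajectory(s2))$slope
  }, numeric(1))
  expect_lt(mean(diffs), 0)
})

test_that("central tendency: estimates regress weakly toward the mean", {
  ct <- central_tendency(tc_session())
  expect_equal(nrow(ct), 7)
  expect_true(is.finite(attr(ct, "slope")))
  # the regression effect is weak per session; average it out at the
  # visual-preset uncertainty where criterion substitution is frequent
  sl <- vapply(1:15, function(i) {
    s <- simulate_session(tc_seq(), observer_params(13, 84, 0.16,
                                                    seed = 400 + i))
    attr(central_tendency(s), "slope")
  }, numeric(1))
  expect_lt(mean(sl), 1)
  expect_gt(mean(sl), 0)
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(observer_params(0, 49, 0.16), "M")
  expect_error(observer_params(13, -1, 0.16), "theta")
  expect_error(observer_params(13, 49, 1.2), "cv")
  expect_error(observer_params(13, 49, 0.16, variant = "bogus"))
})
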