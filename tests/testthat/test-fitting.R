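# Monte Carlo grid and RMSE parameter matching.

test_that("grid runs are reproducible and respect degenerate ranges", {
  g1 <- run_grid(n_perm = 3, sequence = tc_seq(), seed = 99)
  g2 <- run_grid(n_perm = 3, sequence = tc_seq(), seed = 99)
  expect_identical(g1$entries, g2$entries)
  expect_true(all(g1$entries$M >= 1 & g1$entries$M <= 30))
  expect_true(all(g1$entries$theta >= 1 & g1$entries$theta <= 150))
  expect_true(all(g1$entries$n_curves == 11L))

  gd <- run_grid(n_perm = 4, M_range = c(5, 5), theta_range = c(50, 50),
                 sequence = tc_seq(), seed = 100)
  expect_true(all(gd$entries$M == 5) && all(gd$entries$theta == 50))
  # index spread at fixed parameters reflects only simulation noise
  expect_gt(sd(gd$entries$decision_bias), 0)
})

test_that("exhaustive mode sweeps the full integer grid", {
  g <- run_grid(M_range = c(2, 3), theta_range = c(40, 41),
                sequence = tc_seq(), exhaustive = TRUE, seed = 4)
  expect_equal(nrow(g$entries), 4)
  expect_setequal(paste(g$entries$M, g$entries$theta),
                  c("2 40", "3 40", "2 41", "3 41"))
})

test_that("fit_session returns the exact grid minimum with parsimony ties", {
  grid <- tc_grid()
  e <- grid$entries[!grid$entries$flagged, ]
  target <- structure(list(decision_bias = e$decision_bias[17],
                           perceptual_slope = e$perceptual_slope[17],
                           session_cv = e$session_cv[17],
                           excluded = FALSE),
                      class = "carryover_profile")
  f <- fit_session(target, grid)
  expect_equal(f$rmse, 0)
  expect_equal(f$best_M, e$M[17])
  expect_equal(f$best_theta, e$theta[17])
  # brute-force oracle: scan the standardized RMSE surface directly
  sc <- list(sd_bias = sd(e$decision_bias),
             sd_slope = sd(e$perceptual_slope))
  rmse <- sqrt((((target$decision_bias - e$decision_bias) / sc$sd_bias)^2 +
                ((target$perceptual_slope - e$perceptual_slope) /
                   sc$sd_slope)^2) / 2)
  expect_equal(f$rmse, min(rmse))
  expect_gte(f$runner_up_gap, 0)
})

test_that("single-entry grids and tie-breaking behave as documented", {
  one <- structure(list(entries = data.frame(
    M = 7, theta = 30, seed = 1, decision_bias = -50,
    perceptual_slope = 0.2, session_cv = 0.2, n_curves = 11L,
    flagged = FALSE), variant = "full", cv = 0.16), class = "grid_result")
  prof <- structure(list(decision_bias = -10, perceptual_slope = 0.1,
                         excluded = FALSE), class = "carryover_profile")
  f <- fit_session(prof, one, scale = list(sd_bias = 1, sd_slope = 1))
  expect_equal(f$best_M, 7)
  # equal-RMSE entries resolve toward smaller theta, then smaller M
  tie <- one
  tie$entries <- data.frame(
    M = c(9, 3, 3), theta = c(20, 40, 20),
    seed = 1:3, decision_bias = -50, perceptual_slope = 0.2,
    session_cv = 0.2, n_curves = 11L, flagged = FALSE)
  ft <- fit_session(prof, tie, scale = list(sd_bias = 1, sd_slope = 1))
  expect_equal(ft$best_theta, 20)
  expect_equal(ft$best_M, 3)
  # flagged-only grids are an error
  allflag <- one
  allflag$entries$flagged <- TRUE
  expect_error(fit_session(prof, allflag), "usable")
  expect_error(fit_session(structure(list(decision_bias = NA_real_,
                                          perceptual_slope = 0.1),
                                     class = "carryover_profile"), one),
               "flagged")
})

test_that("recovered theta increases with generating theta", {
  grid <- tc_grid()
  med_theta <- vapply(c(10, 50, 100), function(th) {
    fits <- vapply(1:30, function(i) {
      p <- observer_params(13, th, 0.16, seed = th * 100 + i)
      pr <- carryover_profile(simulate_session(tc_seq(), p))
      if (pr$flagged || pr$excluded) return(NA_real_)
      fit_session(pr, grid)$best_theta
    }, numeric(1))
    median(fits, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_theta) > 0))
})

test_that("compare_variants is consistent under identical grids", {
  grid <- tc_grid()
  profs <- lapply(1:5, function(i) {
    p <- observer_params(10, 60, 0.16, seed = 9000 + i)
    carryover_profile(simulate_session(tc_seq(), p))
  })
  cv <- compare_variants(profs, list(full = grid, alt = grid))
  expect_equal(cv$summary$mean_rmse[1], cv$summary$mean_rmse[2])
  expect_equal(unname(cv$rmse[, "full"]), unname(cv$rmse[, "alt"]))
  expect_error(compare_variants(profs, list(alt = grid)), "reference")
})
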