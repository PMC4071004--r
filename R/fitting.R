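# Monte Carlo exploration of the (M, theta) parameter space and RMSE
# matching of observer parameters to session carryover profiles.

#' Monte Carlo grid over the observer parameter space
#'
#' Runs `n_perm` observer simulations with the memory window `M` and
#' uncertainty threshold `theta` drawn uniformly (integer steps: M in
#' 1-trial steps, theta in 1-ms steps) from their ranges, analyzes each
#' session (11 condition psychometric curves, bootstrap disabled), and
#' records the carryover indices. Sensory variability is held fixed
#' (default `cv = 0.16`).
#'
#' @param n_perm number of permutations (default 500).
#' @param M_range integer range for `M` (default `c(1, 30)`).
#' @param theta_range range for `theta` in ms (default `c(1, 150)`).
#' @param cv fixed perceptual coefficient of variation.
#' @param variant observer variant simulated.
#' @param sequence a `trial_sequence` shared by all permutations;
#'   generated from `duration_set` when `NULL`.
#' @param duration_set stimulus set used when generating a sequence.
#' @param multiplicity sequence multiplicity (default 8, 512 trials).
#' @param exhaustive if `TRUE`, sweep the full integer grid instead of
#'   random draws (`n_perm` is ignored).
#' @param min_per_level per-level floor for condition fits.
#' @param seed master seed; permutation seeds are derived from it.
#' @return an object of class `grid_result`: list with `entries` (one
#'   row per permutation: `M`, `theta`, `seed`, `decision_bias`,
#'   `perceptual_slope`, `session_cv`, `n_curves`, `flagged`),
#'   `variant`, `cv`.
#' @export
run_grid <- function(n_perm = 500, M_range = c(1, 30),
                     theta_range = c(1, 150), cv = 0.16,
                     variant = "full", sequence = NULL,
                     duration_set = make_duration_set(),
                     multiplicity = 8, exhaustive = FALSE,
                     min_per_level = 4, seed = NULL) {
  variant <- match.arg(variant, OBSERVER_VARIANTS)
  if (M_range[1] < 1 || M_range[2] < M_range[1])
    stop("invalid `M_range`")
  if (theta_range[1] < 0 || theta_range[2] < theta_range[1])
    stop("invalid `theta_range`")
  if (is.null(sequence))
    sequence <- generate_sequence(duration_set, multiplicity,
                                  seed = derive_seed(
                                    if (is.null(seed)) 0 else seed,
                                    "sequence"))
  pars <- if (exhaustive) {
    expand.grid(M = M_range[1]:M_range[2],
                theta = theta_range[1]:theta_range[2])
  } else {
    with_seed(if (is.null(seed)) NULL else derive_seed(seed, "draws"), {
      draw <- function(lo, hi, n) # safe for collapsed ranges
        if (lo == hi) rep(as.integer(lo), n) else
          sample(lo:hi, n, replace = TRUE)
      data.frame(M = draw(M_range[1], M_range[2], n_perm),
                 theta = draw(theta_range[1], theta_range[2], n_perm))
    })
  }
  n <- nrow(pars)
  entries <- data.frame(
    M = pars$M, theta = pars$theta,
    seed = vapply(seq_len(n), function(i)
      derive_seed(if (is.null(seed)) i else seed, i), integer(1)),
    decision_bias = NA_real_, perceptual_slope = NA_real_,
    session_cv = NA_real_, n_curves = 0L, flagged = FALSE)
  for (i in seq_len(n)) {
    p <- observer_params(M = entries$M[i], theta = entries$theta[i],
                         cv = cv, variant = variant,
                         seed = entries$seed[i])
    ses <- simulate_session(sequence, p)
    prof <- carryover_profile(ses, min_per_level = min_per_level)
    entries$decision_bias[i] <- prof$decision_bias
    entries$perceptual_slope[i] <- prof$perceptual_slope
    entries$session_cv[i] <- prof$session_cv
    entries$n_curves[i] <- prof$n_curves
    entries$flagged[i] <- prof$excluded || prof$flagged
  }
  structure(list(entries = entries, variant = variant, cv = cv,
                 M_range = M_range, theta_range = theta_range,
                 seed = seed),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("<grid_result> ", nrow(x$entries), " permutations (",
      x$variant, "), ", sum(x$entries$flagged), " flagged\n", sep = "")
  invisible(x)
}

grid_scale <- function(grid) {
  e <- grid$entries[!grid$entries$flagged, , drop = FALSE]
  if (nrow(e) == 0) stop("grid has no usable (non-flagged) entries")
  list(sd_bias = max(sd(e$decision_bias), .Machine$double.eps),
       sd_slope = max(sd(e$perceptual_slope), .Machine$double.eps))
}

#' Fit observer parameters to a session profile by grid RMSE
#'
#' Finds the grid permutation whose (decision bias, perceptual slope)
#' pair best matches the profile's, by root mean-squared error over the
#' two indices. The two components are incommensurate (ms vs
#' dimensionless), so each is standardized by the grid's own spread
#' before the RMSE (override with `scale` to compare across grids).
#' Ties are broken toward smaller `theta`, then smaller `M`.
#'
#' @param profile a non-flagged `carryover_profile`.
#' @param grid a `grid_result`.
#' @param scale optional list with `sd_bias`, `sd_slope` used for
#'   standardization (default: this grid's spread).
#' @return an object of class `fit_result`: list with `best_M`,
#'   `best_theta`, `rmse`, `runner_up_gap`, `index`.
#' @export
fit_session <- function(profile, grid, scale = NULL) {
  if (!is.finite(profile$decision_bias) ||
      !is.finite(profile$perceptual_slope))
    stop("profile is flagged: carryover indices unavailable")
  e <- grid$entries
  ok <- !e$flagged & is.finite(e$decision_bias) &
    is.finite(e$perceptual_slope)
  if (!any(ok)) stop("grid has no usable entries")
  if (is.null(scale)) scale <- grid_scale(grid)
  zb <- (profile$decision_bias - e$decision_bias[ok]) / scale$sd_bias
  zs <- (profile$perceptual_slope - e$perceptual_slope[ok]) / scale$sd_slope
  rmse <- sqrt((zb^2 + zs^2) / 2)
  idx <- which(ok)
  ord <- order(rmse, e$theta[ok], e$M[ok])
  best <- ord[1]
  gap <- if (length(ord) > 1) rmse[ord[2]] - rmse[best] else NA_real_
  structure(list(best_M = e$M[idx[best]], best_theta = e$theta[idx[best]],
                 rmse = rmse[best], runner_up_gap = gap,
                 index = idx[best]),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> M=%d, theta=%d ms (RMSE %.4f)\n",
              as.integer(x$best_M), as.integer(x$best_theta), x$rmse))
  invisible(x)
}

#' Compare observer variants by fit quality
#'
#' Fits every profile against each variant's grid and summarizes mean
#' RMSE (reported as `1 - RMSE`, larger = better) plus paired
#' differences against the reference variant. All grids are
#' standardized with the reference grid's spread so RMSE values are
#' commensurable across variants.
#'
#' @param profiles list of non-flagged `carryover_profile` objects.
#' @param grids named list of `grid_result` objects, one per variant.
#' @param reference name of the reference grid (default `"full"`).
#' @return list with `summary` (data.frame: variant, mean_rmse,
#'   mean_score = mean(1 - RMSE), wins_vs_reference), and `rmse`
#'   (profiles x variants matrix).
#' @export
compare_variants <- function(profiles, grids, reference = "full") {
  if (!reference %in% names(grids))
    stop("`grids` must contain the reference variant '", reference, "'")
  scale <- grid_scale(grids[[reference]])
  rmse <- sapply(names(grids), function(v)
    vapply(profiles, function(p)
      fit_session(p, grids[[v]], scale = scale)$rmse, numeric(1)))
  rmse <- matrix(rmse, nrow = length(profiles),
                 dimnames = list(NULL, names(grids)))
  ref <- rmse[, reference]
  summary <- data.frame(
    variant = colnames(rmse),
    mean_rmse = colMeans(rmse),
    mean_score = colMeans(1 - rmse),
    wins_vs_reference = colSums(rmse > ref),
    row.names = NULL)
  list(summary = summary, rmse = rmse)
}
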