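# Configuration, session CSV round-tripping, JSON artifact export and
# the end-to-end pipeline.

SESSION_COLUMNS <- c("trial_index", "label", "duration_ms",
                     "perceived_ms", "response", "rt_ms", "prior_label")

#' Pipeline run configuration
#'
#' Bundles all tunable settings with defaults matching the task design:
#' durations 300-900 ms in 7 log-spaced levels with multiplicity 8
#' (512 trials), RT cutoff 1000 ms, 1999 bootstrap replicates,
#' exclusion at CV >= 1, and fitting ranges M in 1-30 trials, theta in
#' 1-150 ms.
#'
#' @param t_min,t_max,n_levels,multiplicity stimulus design.
#' @param M,theta,cv,variant observer parameters.
#' @param rt_cutoff,n_boot,exclude_cv,min_per_level analysis settings.
#' @param M_range,theta_range,n_perm fitting settings.
#' @param n_subjects number of simulated subjects in [run_pipeline()].
#' @param seed master seed.
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(t_min = 300, t_max = 900, n_levels = 7,
                       multiplicity = 8,
                       M = 13, theta = 49, cv = 0.16, variant = "full",
                       rt_cutoff = 1000, n_boot = 1999, exclude_cv = 1,
                       min_per_level = 4,
                       M_range = c(1, 30), theta_range = c(1, 150),
                       n_perm = 500, n_subjects = 1, seed = 1) {
  cfg <- list(
    stimulus = list(t_min = t_min, t_max = t_max, n_levels = n_levels,
                    multiplicity = multiplicity),
    observer = list(M = M, theta = theta, cv = cv, variant = variant),
    analysis = list(rt_cutoff = rt_cutoff, n_boot = n_boot,
                    exclude_cv = exclude_cv,
                    min_per_level = min_per_level),
    fitting = list(M_range = M_range, theta_range = theta_range,
                   n_perm = n_perm),
    n_subjects = n_subjects, seed = seed)
  observer_params(M, theta, cv, variant) # validate
  stopifnot(rt_cutoff > 0, n_boot >= 0, exclude_cv > 0, n_perm >= 1,
            n_subjects >= 1)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file; fields mirror [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Write a session to CSV
#'
#' One row per trial with empty fields on null trials; session metadata
#' (observer parameters, seed, stimulus set) is stored in `#`-prefixed
#' header comments so the file round-trips losslessly through
#' [read_session()].
#'
#' @param session a `tc_session`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  df <- as.data.frame(session)
  extra <- intersect(c("tbar_ms", "threshold_ms"), names(df))
  df <- df[, c(SESSION_COLUMNS, extra), drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- ifelse(
    is.na(df[[j]]), "", formatC(df[[j]], digits = 12, format = "g"))
  meta <- character(0)
  ds <- attr(session, "duration_set")
  if (!is.null(ds))
    meta <- c(meta, paste0("# duration_set: ", jsonlite::toJSON(
      ds[c("t_min", "t_max", "n_levels", "null_label")],
      auto_unbox = TRUE)))
  p <- attr(session, "params")
  if (!is.null(p))
    meta <- c(meta, paste0("# params: ", jsonlite::toJSON(
      unclass(p)[!vapply(unclass(p), is.null, logical(1))],
      auto_unbox = TRUE)))
  if (!is.null(attr(session, "seed")))
    meta <- c(meta, paste0("# seed: ", attr(session, "seed")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a session from CSV
#'
#' Validates the required columns and numeric fields; malformed rows
#' are rejected with their line numbers.
#'
#' @param path CSV file written by [write_session()] (or any file with
#'   the required columns).
#' @return a `tc_session`.
#' @export
read_session <- function(path) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- lines[meta_idx]
  body <- if (length(meta_idx)) lines[-meta_idx] else lines
  df <- read.csv(text = body, stringsAsFactors = FALSE,
                 colClasses = "character", na.strings = "")
  missing <- setdiff(SESSION_COLUMNS, names(df))
  if (length(missing))
    stop("session file is missing column(s): ",
         paste(missing, collapse = ", "))
  num_cols <- intersect(c("trial_index", "duration_ms", "perceived_ms",
                          "rt_ms", "tbar_ms", "threshold_ms"), names(df))
  header_off <- length(meta_idx) + 1L
  for (cl in num_cols) {
    v <- df[[cl]]
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad))
      stop("non-numeric value in column `", cl, "` at line ",
           paste(bad + header_off, collapse = ", "))
    df[[cl]] <- parsed
  }
  df$trial_index <- as.integer(df$trial_index)
  ds <- params <- seed <- NULL
  pick <- function(key) {
    m <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, ": "), "", m[1]) else NULL
  }
  if (!is.null(j <- pick("duration_set"))) {
    d <- jsonlite::fromJSON(j)
    ds <- make_duration_set(d$t_min, d$t_max, d$n_levels, d$null_label)
  }
  if (!is.null(j <- pick("params"))) {
    p <- jsonlite::fromJSON(j)
    params <- observer_params(p$M, p$theta, p$cv, p$variant,
                              seed = p$seed)
  }
  if (!is.null(j <- pick("seed"))) seed <- as.integer(j)
  new_session(df, params = params, seed = seed, duration_set = ds)
}

#' Export a trial sequence to CSV
#'
#' Columns `trial_index`, `label`, `duration_ms` (empty on null
#' trials).
#'
#' @param seq a `trial_sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  ds <- seq$duration_set
  dur <- if (is.null(ds)) rep(NA_real_, length(seq$labels)) else
    label_duration(ds, seq$labels)
  df <- data.frame(trial_index = seq_along(seq$labels),
                   label = seq$labels,
                   duration_ms = ifelse(is.na(dur), "",
                                        formatC(dur, digits = 12,
                                                format = "g")))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

profile_json <- function(profile) {
  fit_rec <- function(f) list(bp = f$bp, dl = f$dl, cv = f$cv,
                              t25 = f$t25, t75 = f$t75,
                              converged = f$converged,
                              n = sum(f$n_per_level))
  list(decision_bias = profile$decision_bias,
       perceptual_slope = profile$perceptual_slope,
       session_cv = profile$session_cv,
       excluded = profile$excluded, flagged = profile$flagged,
       fit_full = fit_rec(profile$fit_full),
       fit_prior_long = fit_rec(profile$fit_prior_long),
       fit_prior_short = fit_rec(profile$fit_prior_short),
       fits_prior_duration = lapply(profile$fits_prior_duration,
                                    fit_rec),
       rt_by_prior = if (!is.null(profile$rt))
         profile$rt$rt_by_prior else NULL,
       rt_prior_slope = if (!is.null(profile$rt))
         profile$rt$prior_slope else NULL,
       rt_matrix = if (!is.null(profile$rt))
         profile$rt$rt_matrix else NULL)
}

#' Write grid results to JSON
#' @param grid a `grid_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  jsonlite::write_json(list(entries = grid$entries,
                            variant = grid$variant, cv = grid$cv,
                            M_range = grid$M_range,
                            theta_range = grid$theta_range),
                       path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read grid results from JSON
#' @param path file written by [write_grid()].
#' @return a `grid_result`.
#' @export
read_grid <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(entries = as.data.frame(x$entries),
                 variant = x$variant, cv = x$cv,
                 M_range = x$M_range, theta_range = x$theta_range,
                 seed = NULL),
            class = "grid_result")
}

#' Run the end-to-end pipeline
#'
#' Generates the counterbalanced sequence, simulates `n_subjects`
#' observer sessions, filters and profiles each, runs the Monte Carlo
#' grid, fits every profile, and writes all artifacts (sequence CSV,
#' session CSVs, profile/grid/fit JSON) under `outdir`. Deterministic
#' under the config's master seed. Per-stage filter and exclusion
#' counts are reported via `message()`.
#'
#' @param config a `run_config`.
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `paths` (artifact files) and the
#'   in-memory `profiles`, `grid` and `fits`.
#' @export
run_pipeline <- function(config = run_config(), outdir = tempfile("run"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  st <- config$stimulus
  ds <- make_duration_set(st$t_min, st$t_max, st$n_levels)
  seqc <- generate_sequence(ds, st$multiplicity,
                            seed = derive_seed(config$seed, "sequence"))
  paths <- list(sequence = file.path(outdir, "sequence.csv"))
  write_sequence(seqc, paths$sequence)
  say("sequence: ", length(seqc$labels), " trials")

  ob <- config$observer
  an <- config$analysis
  profiles <- list()
  paths$sessions <- character(0)
  for (i in seq_len(config$n_subjects)) {
    p <- observer_params(ob$M, ob$theta, ob$cv, ob$variant,
                         seed = derive_seed(config$seed, 1000 + i))
    ses <- simulate_session(seqc, p)
    sp <- file.path(outdir, sprintf("session_%03d.csv", i))
    write_session(ses, sp)
    paths$sessions <- c(paths$sessions, sp)
    filt <- filter_trials(ses, rt_cutoff = an$rt_cutoff)
    lg <- attr(filt, "filter_log")
    say("subject ", i, ": removed ", lg$n_first_removed, " first + ",
        lg$n_rt_removed, " RT trials; ", lg$n_output, " kept")
    profiles[[i]] <- carryover_profile(filt,
                                       min_per_level = an$min_per_level)
    say("subject ", i, ": ", profiles[[i]]$n_curves, " curves, CV=",
        fmt_num(profiles[[i]]$session_cv, 3),
        if (profiles[[i]]$excluded) " [excluded]" else "")
  }
  paths$profiles <- file.path(outdir, "profiles.json")
  jsonlite::write_json(lapply(profiles, profile_json), paths$profiles,
                       auto_unbox = TRUE, digits = NA, na = "null")

  ft <- config$fitting
  grid <- run_grid(n_perm = ft$n_perm, M_range = ft$M_range,
                   theta_range = ft$theta_range, cv = ob$cv,
                   sequence = seqc, min_per_level = an$min_per_level,
                   seed = derive_seed(config$seed, "grid"))
  paths$grid <- file.path(outdir, "grid.json")
  write_grid(grid, paths$grid)
  say("grid: ", nrow(grid$entries), " permutations, ",
      sum(grid$entries$flagged), " flagged")

  fits <- lapply(profiles, function(pr)
    if (pr$flagged || pr$excluded) NULL else fit_session(pr, grid))
  paths$fits <- file.path(outdir, "fits.json")
  jsonlite::write_json(
    lapply(fits, function(f) if (is.null(f)) NULL else unclass(f)),
    paths$fits, auto_unbox = TRUE, digits = NA, na = "null")
  say("fits written to ", paths$fits)
  invisible(list(paths = paths, profiles = profiles, grid = grid,
                 fits = fits))
}
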