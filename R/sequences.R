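# Design generation: log-spaced duration grid and path-guided,
# first-order counterbalanced de Bruijn trial sequences.

#' Log-spaced duration stimulus set
#'
#' Builds the set of `n_levels` durations spaced at a constant ratio
#' between `t_min` and `t_max`, plus a sentinel label for null (blank)
#' trials. With an odd number of levels the middle duration sits at the
#' geometric mean `sqrt(t_min * t_max)`.
#'
#' @param t_min shortest duration in ms (> 0).
#' @param t_max longest duration in ms (> `t_min`).
#' @param n_levels number of duration levels (>= 2).
#' @param null_label label used for null trials.
#' @return an object of class `duration_set`: list with `t_min`, `t_max`,
#'   `n_levels`, `durations` (full precision, ms), `labels`
#'   (`"d1"`..`"d<n>"`) and `null_label`.
#' @examples
#' ds <- make_duration_set(300, 900, 7)
#' round(ds$durations) # 300 360 433 520 624 749 900
#' @export
make_duration_set <- function(t_min = 300, t_max = 900, n_levels = 7,
                              null_label = "null") {
  if (!is.numeric(t_min) || t_min <= 0) stop("`t_min` must be positive")
  if (!is.numeric(t_max) || t_max <= t_min)
    stop("`t_max` must exceed `t_min`")
  if (n_levels < 2) stop("`n_levels` must be at least 2")
  d <- exp(seq(log(t_min), log(t_max), length.out = n_levels))
  structure(
    list(t_min = t_min, t_max = t_max, n_levels = as.integer(n_levels),
         durations = d, labels = paste0("d", seq_len(n_levels)),
         null_label = null_label),
    class = "duration_set")
}

#' @export
print.duration_set <- function(x, ...) {
  cat("<duration_set> ", x$n_levels, " levels, ",
      round(x$t_min), "-", round(x$t_max), " ms: ",
      paste(round(x$durations), collapse = " "),
      " (+ '", x$null_label, "')\n", sep = "")
  invisible(x)
}

#' Map labels to durations
#'
#' @param ds a `duration_set`.
#' @param labels character vector of labels (`"d1"`.. or the null label).
#' @return numeric durations in ms, `NA` for null labels.
#' @export
label_duration <- function(ds, labels) {
  idx <- match(labels, ds$labels)
  ds$durations[idx]
}

#' Sinusoidal guide function for path-guided sequences
#'
#' Sum of `n_sinusoids` sinusoids with periods drawn uniformly in
#' `period_range` (in sequence elements) and uniform random phases.
#' The guide shapes the local ordering of a counterbalanced sequence so
#' that stimulus magnitude drifts smoothly rather than jumping.
#'
#' @param length number of elements (> 0).
#' @param n_sinusoids number of summed sinusoids.
#' @param period_range length-2 numeric, periods in elements, within
#'   `[2, length]`.
#' @param seed integer seed (`NULL` = use current RNG stream).
#' @return numeric vector of length `length`.
#' @export
make_guide <- function(length, n_sinusoids = 2, period_range = c(20, 40),
                       seed = NULL) {
  if (length <= 0) stop("`length` must be positive")
  if (!is.numeric(period_range) || length(period_range) != 2 ||
      any(!is.finite(period_range)) || period_range[2] < period_range[1])
    stop("`period_range` must be a valid (lo, hi) pair")
  if (period_range[1] < 2 || period_range[2] > length)
    stop("`period_range` must lie within [2, length]")
  with_seed(seed, {
    t <- seq_len(length)
    g <- numeric(length)
    for (i in seq_len(n_sinusoids)) {
      p <- runif(1, period_range[1], period_range[2])
      phase <- runif(1, 0, 2 * pi)
      g <- g + sin(2 * pi * t / p + phase)
    }
    g
  })
}

seq_labels <- function(x) {
  if (inherits(x, "duration_set")) c(x$null_label, x$labels)
  else if (is.character(x)) c("null", x)
  else stop("`x` must be a duration_set or a character vector of labels")
}

#' Generate a path-guided first-order counterbalanced sequence
#'
#' Constructs an Eulerian circuit on the complete directed multigraph
#' over the stimulus labels plus the null label, with every arc
#' (including self-loops) duplicated `multiplicity` times. This is an
#' order-2 de Bruijn design: every ordered pair of labels occurs exactly
#' `multiplicity` times cyclically, so first-order carryover conditions
#' are perfectly balanced. Arc choice is greedy on the guide function
#' (the unused outgoing arc whose target rank best matches the guide at
#' the current position), with Hierholzer splicing of leftover
#' sub-circuits so the circuit always completes exactly.
#'
#' @param x a `duration_set`, or a character vector of stimulus labels
#'   (the null label is appended automatically).
#' @param multiplicity times each ordered label pair must occur (>= 1).
#' @param guide numeric guide vector of length at least
#'   `n_labels^2 * multiplicity`; default: [make_guide()] of that length.
#' @param seed integer seed for the guide and tie-breaking.
#' @param restarts number of randomized constructions to try; the
#'   circuit whose stimulus ranks correlate best with the guide is
#'   kept (counterbalance is exact in every restart).
#' @return an object of class `trial_sequence`: list with `labels`
#'   (character vector, the emitted trial order), `label_set` (null label
#'   first), `multiplicity`, `guide`, `seed` and `duration_set` (or
#'   `NULL`).
#' @examples
#' ds <- make_duration_set(300, 900, 7)
#' ts <- generate_sequence(ds, multiplicity = 8, seed = 1)
#' length(ts$labels)           # 512
#' range(transition_counts(ts)) # 8 8
#' @export
generate_sequence <- function(x, multiplicity = 8, guide = NULL,
                              seed = NULL, restarts = 8) {
  labs <- seq_labels(x)
  k <- length(labs)
  if (multiplicity < 1) stop("`multiplicity` must be at least 1")
  m <- as.integer(multiplicity)
  n_arcs <- k * k * m
  if (is.null(guide)) {
    glen <- max(n_arcs, 64L)
    pr <- c(min(20, max(2, glen / 4)), min(40, glen))
    guide <- make_guide(glen, 2, pr, seed = derive_seed(
      if (is.null(seed)) 0 else seed, "guide"))
  }
  if (length(guide) < n_arcs)
    stop("`guide` must have length >= n_labels^2 * multiplicity")
  # scale guide onto the stimulus rank range [1, k-1]; the null label is
  # guide-neutral (mid-range rank) so blanks do not cluster in guide
  # troughs and bias the local stimulus context around null trials
  rng <- range(guide[seq_len(n_arcs)])
  gs <- if (diff(rng) == 0) rep(k / 2, n_arcs) else
    1 + (guide[seq_len(n_arcs)] - rng[1]) / diff(rng) * (k - 2)
  ranks <- c(k / 2, seq_len(k - 1))

  path <- with_seed(seed, {
    build_circuit <- function() {
      remaining <- matrix(m, k, k)
      walk <- function(u, pos) {
        # greedy closed walk; in a balanced digraph it can only stall at u
        nodes <- integer(2 * k * k * m)
        nodes[1] <- u
        len <- 1L
        cur <- u
        repeat {
          cand <- which(remaining[cur, ] > 0L)
          if (length(cand) == 0L) break
          g <- gs[((pos - 1L) %% n_arcs) + 1L]
          # guide match tempered by the remaining stock of each arc, so
          # well-matching arcs are rationed across the whole walk rather
          # than exhausted early (which would anti-correlate the tail)
          d <- abs(ranks[cand] - g) - remaining[cur, cand] / m +
            runif(length(cand), 0, 1e-3)
          v <- cand[which.min(d)]
          remaining[cur, v] <<- remaining[cur, v] - 1L
          len <- len + 1L
          nodes[len] <- v
          cur <- v
          pos <- pos + 1L
        }
        nodes[seq_len(len)]
      }
      start <- which.min(abs(ranks - gs[1]))
      path <- walk(start, 1L)
      # splice in sub-circuits at nodes that still have unused out-arcs
      while (sum(remaining) > 0L) {
        at <- which(rowSums(remaining)[path] > 0L)[1]
        if (is.na(at)) stop("internal error: Eulerian circuit incomplete")
        sub <- walk(path[at], at)
        path <- append(path[-at], sub, after = at - 1L)
      }
      path
    }
    # the greedy walk is stochastic (jittered tie-breaks): keep the
    # restart whose stimulus ranks best track the guide
    best_path <- NULL
    best_score <- -Inf
    for (r in seq_len(max(1L, as.integer(restarts)))) {
      p <- build_circuit()
      emit <- p[seq_len(n_arcs)]
      stim <- emit != 1L
      score <- if (sd(ranks[emit[stim]]) == 0) 0 else
        cor(gs[which(stim)], ranks[emit[stim]])
      if (score > best_score) {
        best_score <- score
        best_path <- p
      }
    }
    best_path
  })
  stopifnot(length(path) == n_arcs + 1L, path[1] == path[n_arcs + 1L])
  structure(
    list(labels = labs[path[seq_len(n_arcs)]], label_set = labs,
         multiplicity = m, guide = guide, seed = seed,
         duration_set = if (inherits(x, "duration_set")) x else NULL),
    class = "trial_sequence")
}

#' @export
print.trial_sequence <- function(x, ...) {
  cat("<trial_sequence> ", length(x$labels), " trials over ",
      length(x$label_set), " labels, multiplicity ", x$multiplicity,
      "\n", sep = "")
  invisible(x)
}

#' Cyclic ordered-pair transition counts
#'
#' Counts every ordered label pair `(trial i, trial i+1)` in a sequence,
#' including the wrap-around pair from last to first trial. For a
#' counterbalanced sequence every entry equals the multiplicity.
#'
#' @param x a `trial_sequence`, or a character vector of labels (with
#'   optional `levels` giving the label set).
#' @param levels label set; defaults to the sequence's label set or the
#'   sorted unique labels.
#' @return integer matrix (from-label x to-label); sums to the sequence
#'   length.
#' @export
transition_counts <- function(x, levels = NULL) {
  s <- if (inherits(x, "trial_sequence")) x$labels else as.character(x)
  if (length(s) == 0) stop("sequence is empty")
  if (is.null(levels))
    levels <- if (inherits(x, "trial_sequence")) x$label_set else
      sort(unique(s))
  from <- factor(s, levels = levels)
  to <- factor(c(s[-1], s[1]), levels = levels)
  tab <- table(from, to)
  mat <- matrix(as.integer(tab), nrow = length(levels),
                dimnames = list(from = levels, to = levels))
  mat
}
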