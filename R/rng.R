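# Seed plumbing: every exported stochastic entry point takes a `seed`
# argument; internal stages derive named substreams from it so that one
# master seed fixes the whole pipeline without the substreams colliding.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state. With `seed = NULL` the code runs against the
#' current RNG stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a substream seed from a master seed
#'
#' Deterministic integer hash mixing a master seed with a stream index
#' (or stream name). Values stay strictly below 2^31 so they are valid
#' R integer seeds.
#'
#' @param master integer master seed.
#' @param stream integer index or character stream name.
#' @return integer seed.
#' @export
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  if (is.character(stream)) {
    stream <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  }
  stopifnot(is.numeric(stream), length(stream) == 1L)
  m <- 2147483629 # largest prime < 2^31
  h <- (abs(master) %% m)
  h <- (h * 48271 + abs(stream) * 16807 + 12345) %% m
  as.integer(h %% 2147483591L + 1)
}
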