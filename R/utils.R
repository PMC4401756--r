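# Seed handling: every stochastic function takes an explicit seed, uses it
# locally, and restores the caller's RNG state on exit, so pipeline stages
# are reproducible in isolation and never perturb user code.

set_local_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a stream seed from a master seed
#'
#' Deterministically maps a master seed and a character key (e.g. a stage
#' name or population id) to a 31-bit integer seed, so each pipeline stage
#' and each population draws from an independently reproducible stream.
#'
#' @param master Master integer seed.
#' @param key Character scalar naming the stream.
#' @return A single integer in \code{[0, 2^31 - 1)}.
#' @export
derive_seed <- function(master, key) {
  h <- sum(utf8ToInt(as.character(key)) * (31 ^ (seq_along(utf8ToInt(as.character(key))) %% 7)))
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
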