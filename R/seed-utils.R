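#' Deterministic sub-seed derivation
#'
#' Derives a child seed from a master seed and a sequence of integer or
#' character tags, so that independent stages (per plot, per flight date, per
#' hold-out draw) can be re-run standalone and still reproduce the exact
#' stream they saw inside a full pipeline run.
#'
#' A polynomial rolling hash over the tags, reduced modulo the Mersenne prime
#' 2^31 - 1, keeps the result a valid positive R integer seed.
#'
#' @param seed master integer seed.
#' @param ... integer or character tags identifying the sub-stream.
#' @return a positive integer seed.
#' @keywords internal
sub_seed <- function(seed, ...) {
  tags <- list(...)
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (tag in tags) {
    codes <- if (is.character(tag)) utf8ToInt(paste(tag, collapse = "|")) else as.numeric(tag)
    for (v in codes) {
      h <- (h * 131 + (v %% m) + 17) %% m
    }
  }
  as.integer(h %% (m - 1) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded helpers do not disturb
#' the caller's random stream.
#'
#' @param seed integer seed passed to [set.seed()].
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
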