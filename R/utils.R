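# Internal helpers: RNG isolation and seed-stream splitting.

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seeds: all randomness in a run flows from one master seed
# through this splitter (documented stream-splitting rule).  Sub-seeds stay
# below 2^31 - 1 so they are valid R integer seeds.
#' @keywords internal
#' @noRd
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
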