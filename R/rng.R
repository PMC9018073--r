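#' Derive a child seed from a master seed
#'
#' Counter-based scheme used everywhere an ensemble or pipeline stage needs
#' independent, order-invariant streams: run `i` of an ensemble seeded with
#' `master` always uses `derive_seed(master, i)`, no matter when it executes.
#' Results stay within the 32-bit integer range R requires of `set.seed()`.
#'
#' @param master master seed (single integer).
#' @param index non-negative counter (run index, stage index, ...).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, index) {
  as.integer((as.double(master) + as.double(index)) %% 2147483647)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
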