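# Small shared helpers.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state,
#' so seeded generators are pure functions of their configuration and do
#' not disturb the session RNG stream.  Seeds are folded into the 32-bit
#' range accepted by [set.seed()].
#'
#' @param seed Integer (or larger numeric; folded modulo 2^31 - 1).
#' @param code Expression to evaluate.
#' @return Value of `code`.
#' @export
with_seed <- function(seed, code) {
  seed <- as.integer(abs(as.numeric(seed)) %% (2^31 - 1))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' @keywords internal
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 104729 * as.numeric(index)) %%
               (2^31 - 1))
}
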