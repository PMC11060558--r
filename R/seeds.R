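#' Derive a subsystem seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' streams (network construction, stimulus generation, neuron noise), so that
#' e.g. lesioning a network or changing the protocol never perturbs the
#' construction randomness.
#'
#' @param master integer master seed.
#' @param stream character name of the random stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "construction")
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.character(stream), length(stream) == 1L)
  codes <- utf8ToInt(stream)
  h <- sum(codes * (seq_along(codes) * 131 + 7)) %% 2147483647
  as.integer((abs(as.numeric(master)) * 48271 + h * 16807 + 1) %% 2147483647)
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
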