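# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive per-stage random seeds from one master seed
#'
#' All randomness in a pipeline run flows from a single master seed; each
#' stage receives its own derived seed so that adding or removing one stage
#' does not perturb the streams of the others.
#'
#' @param seed master seed (single integer).
#' @param n number of seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

# run `expr` under `seed` when given, untouched RNG passthrough otherwise
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
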