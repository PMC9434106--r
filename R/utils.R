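# Small internal helpers shared across modules.

# 31-bit multiplicative hash chain. All intermediates stay below 2^53 so the
# arithmetic is exact in doubles.
.hash_mix <- function(h, x) ((h * 48271) %% 2147483647 + x) %% 2147483647

.hash_value <- function(x) {
  if (is.character(x)) {
    h <- 7
    for (cc in utf8ToInt(x)) h <- (h * 31 + cc) %% 2147483647
    h
  } else {
    abs(as.double(x)) %% 2147483647
  }
}

#' Derive a reproducible child seed from a master seed
#'
#' Every source of randomness in the package draws from its own stream, seeded
#' by hashing the master seed together with a stream label (and, where
#' relevant, entity identifiers such as sample names).  Removing one sample or
#' reordering pair evaluation therefore never perturbs the draws made for the
#' others.
#'
#' @param master integer master seed.
#' @param ... further components (strings or integers) identifying the stream.
#' @return an integer seed in \code{[1, 2^31)} suitable for \code{set.seed}.
#' @examples
#' derive_seed(42, "rarefy", "sample_01")
#' @export
derive_seed <- function(master, ...) {
  h <- .hash_value(master)
  for (p in list(...)) h <- .hash_mix(h, .hash_value(p))
  as.integer(h %% 2147483562 + 1)
}

# Round half away from zero (base round() rounds half to even).
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# rethrow any condition with the pipeline stage name prefixed
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}
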