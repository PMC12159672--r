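# Shared helpers: deterministic seed derivation and small numeric utilities.

#' Derive a reproducible sub-seed
#'
#' Deterministically maps a global seed plus one or more string/numeric labels
#' (e.g. a stage name or clip id) to an integer in \[0, 2^31 - 2\], so that
#' pipeline stages and per-clip simulations can be rerun independently yet
#' reproducibly.
#'
#' @param seed Integer global seed.
#' @param ... Labels (coerced to character) identifying the consumer.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  lab <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  for (k in utf8ToInt(lab)) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

inv_logit <- function(x) stats::plogis(x)

db_to_amp <- function(db) 10^(db / 20)
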