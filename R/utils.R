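# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from a master seed and integer tags.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) h <- (h * 7919 + (as.numeric(t) %% 1e6) + 1) %% 2147483647
  as.integer(h)
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Round half away from zero (printed tables use this convention, unlike R's
# banker's rounding in round()).
round_half_up <- function(x, digits = 2) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)
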