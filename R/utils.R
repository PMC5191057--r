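# Internal numeric helpers shared across modules.

# Deterministic half-up rounding on the 0-255 intensity scale (base round()
# is half-to-even, which is not reproducible across rescaled inputs).
round_half_up <- function(x) floor(x + 0.5)

clip_8bit <- function(x) pmin(pmax(x, 0), 255)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Polynomial rolling hash over a serialized object; used for report
# provenance (fingerprint only, not cryptographic).
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

stop_param <- function(...) stop(..., call. = FALSE)
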