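#' @keywords internal
"_PACKAGE"

# Round half away from zero to `digits` decimals (base round() is half-even,
# which would turn 96.515 into 96.52 or 96.51 depending on representation).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# log(sum(exp(x))) without overflow; used by the exact test at extreme tails.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Derive a per-stage seed from one global seed so that pipeline stages are
# individually re-runnable. Stays below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bsr <- function(...) stop(sprintf(...), call. = FALSE)
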