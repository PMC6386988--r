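# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed
#'
#' All randomness in a simulation flows from one session seed; each component
#' (phantom layout, subject jitter, latency jitter, ...) draws from its own
#' sub-stream so that components are independently reproducible. The
#' derivation is a small deterministic hash of the parent seed and the stream
#' name, kept within the 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed integer parent seed.
#' @param stream character scalar naming the sub-stream.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(stream)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

# Stop with a formatted message, without the call in the condition.
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort("'%s' must be a finite numeric scalar", name)
  if (strict_lower && x <= lower)
    abort("'%s' must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    abort("'%s' must be >= %g (got %g)", name, lower, x)
  if (x > upper)
    abort("'%s' must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

# Linear interpolation of a (t, value) record onto query times, holding the
# boundary values outside the recorded range.
interp_series <- function(t, value, t_out) {
  if (length(t) == 1L) return(rep(value, length(t_out)))
  approx(t, value, xout = t_out, rule = 2)$y
}
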