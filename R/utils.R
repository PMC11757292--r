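# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (strict_min) {
    if (x <= min) stopf("'%s' must be > %g (got %g)", name, min, x)
  } else if (x < min) {
    stopf("'%s' must be >= %g (got %g)", name, min, x)
  }
  if (x > max) stopf("'%s' must be <= %g (got %g)", name, max, x)
  invisible(x)
}

check_prob_vector <- function(p, name, tol = 1e-9) {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p) || any(p < 0))
    stopf("'%s' must be a non-negative numeric vector", name)
  if (abs(sum(p) - 1) > tol)
    stopf("'%s' must sum to 1 (sums to %.12g)", name, sum(p))
  invisible(p)
}

# Round half away from zero (round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
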