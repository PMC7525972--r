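# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort("'%s' must be a single finite number", name)
  x
}

assert_count <- function(x, name, min = 1L) {
  assert_scalar_number(x, name)
  if (x != round(x) || x < min)
    abort("'%s' must be an integer >= %d (got %s)", name, min, format(x))
  as.integer(x)
}

assert_fraction <- function(x, name, open_lo = FALSE, open_hi = FALSE) {
  assert_scalar_number(x, name)
  lo_ok <- if (open_lo) x > 0 else x >= 0
  hi_ok <- if (open_hi) x < 1 else x <= 1
  if (!lo_ok || !hi_ok) abort("'%s' must lie in %s0, 1%s (got %s)",
                              name, if (open_lo) "(" else "[",
                              if (open_hi) ")" else "]", format(x))
  x
}

# evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream; NULL seed means "use the ambient stream"
maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  assert_count(seed, "seed", min = 0L)
  withr::with_seed(seed, code)
}
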