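## Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stopf("`%s` must be > %g", name, lower)
  if (!strict_lower && x < lower)
    stopf("`%s` must be >= %g", name, lower)
  if (x > upper)
    stopf("`%s` must be <= %g", name, upper)
  invisible(x)
}

#' @noRd
assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stopf("`%s` must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

## Round to integers and clip to the 8-bit gray-scale range.
clip8 <- function(x) pmin(pmax(round(x), 0), 255)  # arg order keeps dim attributes

## All generators are bit-reproducible: RNG state is scoped to the call.
with_seed <- function(seed, code) withr::with_seed(seed, code)
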