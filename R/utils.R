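# Internal helpers: argument checking and reproducible sub-stream seeding.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_number <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (integer && x != round(x))
    stopf("`%s` must be an integer, got %s", name, format(x))
  if (x < lo || x > hi)
    stopf("`%s` must be in [%s, %s], got %s", name, lo, hi, format(x))
  invisible(x)
}

#' Derive a reproducible sub-stream seed
#'
#' Expands one root seed into per-unit (e.g. per-participant) seeds so that a
#' cohort is reproducible trial-for-trial and each unit's stream is
#' insensitive to how many other units are generated. A small multiplicative
#' hash keeps the result a valid 32-bit R seed.
#'
#' @param root integer root seed.
#' @param index positive integer identifying the sub-stream.
#' @return a single integer seed.
#' @export
substream_seed <- function(root, index) {
  assert_number(root, "root", integer = TRUE)
  assert_number(index, "index", lo = 0, integer = TRUE)
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps seeds in R's integer range
  h <- (as.double(root %% m) * 48271 + index * 69621 + 1) %% m
  as.integer(h)
}

# Evaluate expr under a temporary RNG state; NULL seed leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(seed, expr)
}
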