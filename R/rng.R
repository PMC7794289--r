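#' Evaluate an expression under a fixed RNG seed
#'
#' All stochastic operations in the package take an explicit integer seed and
#' evaluate their random draws inside `with_seed()`, so the caller's RNG
#' stream is never disturbed and results are reproducible bit-for-bit.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a parent seed and a stream label, so that one
# run-level seed can feed many independent operations. Kept below 2^31.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647L
  as.integer(h)
}
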