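# Internal helpers shared across modules.

# Stop with a classed condition so tests can assert on error class.
mimir_abort <- function(msg, class = "mimir_error", ...) {
  rlang::abort(msg, class = class, ...)
}

# Sigmoid used by the impulse model and its simulator.
sigmoid <- function(x) 1 / (1 + exp(-x))

# Canonical unordered pair key: gene_a < gene_b lexicographically.
order_pairs <- function(a, b) {
  swap <- a > b
  tibble(
    gene_a = ifelse(swap, b, a),
    gene_b = ifelse(swap, a, b)
  )
}

# Check a numeric vector lies in [lo, hi].
check_range <- function(x, lo, hi, what) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    mimir_abort(
      sprintf("%s outside [%g, %g]: first offending value %g",
              what, lo, hi, x[which(bad)[1]]),
      class = "mimir_range_error"
    )
  }
  invisible(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
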