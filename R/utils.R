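# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed when `seed` is non-NULL, without
# disturbing the caller's RNG state; otherwise use the ambient RNG.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %s.", name, format(min)),
          class = "blinkclean_value_error")
  }
  invisible(x)
}

assert_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || x[1] > x[2]) {
    abort(sprintf("`%s` must be a finite interval c(lower, upper) with lower <= upper.", name),
          class = "blinkclean_value_error")
  }
  invisible(x)
}

peak_to_peak <- function(x) max(x) - min(x)

size_error <- function(msg) abort(msg, class = "blinkclean_size_error")
value_error <- function(msg) abort(msg, class = "blinkclean_value_error")
format_error <- function(msg) abort(msg, class = "blinkclean_format_error")
degenerate_error <- function(msg) abort(msg, class = "blinkclean_degenerate_error")
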