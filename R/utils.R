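# internal helpers shared across modules

# fail unless x is a single finite number satisfying `ok`
check_number <- function(x, what, ok = function(v) TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !ok(x)) {
    abort(sprintf("`%s` must be a single finite number%s.", what,
                  if (identical(ok, is_positive)) " > 0" else ""))
  }
  invisible(x)
}

is_positive <- function(v) v > 0

# percentile interval endpoints for a vector of bootstrap draws
percentile_ci <- function(draws, level) {
  alpha <- (1 - level) / 2
  unname(quantile(draws, c(alpha, 1 - alpha), names = FALSE, type = 7))
}

# run `expr` under a temporary RNG state seeded with `seed` (user RNG untouched);
# with seed = NULL, uses the current RNG stream
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
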