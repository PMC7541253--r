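# internal helpers shared across modules

# run expr under a fixed RNG seed when one is given, else as-is
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
}

#' Express a count as a percentage
#'
#' Convenience used by the reporting helpers: `100 * k / n` rounded to a fixed
#' number of decimals, the form in which support and selection rates are
#' conventionally quoted.
#'
#' @param k numerator count.
#' @param n denominator count (> 0).
#' @param digits decimals to keep (default 1).
#' @return a single number, percent.
#' @export
#' @examples
#' rate_percent(629, 826)   # split-support percentage
rate_percent <- function(k, n, digits = 1) {
  stopifnot_scalar_number(k, "k")
  stopifnot_scalar_number(n, "n")
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  round(100 * k / n, digits)
}
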