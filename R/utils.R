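# shared internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Integer percentage of a count
#'
#' Small convenience for reporting: `100 * k / n` rounded to a whole percent.
#' Reports in the literature mix conventions: "at least X%" phrasing floors the
#' value, plain parenthetical percentages round to nearest.
#'
#' @param k Numerator count.
#' @param n Denominator count; must be positive.
#' @param method `"round"` (nearest integer, default) or `"floor"`.
#' @return Integer percentage.
#' @examples
#' percent_of(641, 2248)            # 29
#' percent_of(1790, 2248, "floor")  # 79
#' @export
percent_of <- function(k, n, method = c("round", "floor")) {
  method <- match.arg(method)
  stopifnot(n > 0, k >= 0)
  x <- 100 * k / n
  as.integer(if (method == "floor") floor(x) else round(x))
}

# validate a seed-derived stream offset stays a 32-bit integer
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647L)
}

# stopifnot with a formatted message
.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

# turn a named list of vectors into a two-column tibble (id, value)
.enframe_chr <- function(x, name, value) {
  tibble(!!name := names(x), !!value := unname(x))
}
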