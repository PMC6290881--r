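`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state; NULL seed leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Fold one or more small integer indices into a base seed, staying inside
# 32-bit integer range (R integers are 32-bit).
derive_seed <- function(base, ...) {
  idx <- c(...)
  s <- as.double(base) %% 2147483629
  for (i in idx) s <- (s * 1000003 + as.double(i)) %% 2147483629
  as.integer(s)
}

#' Truncate a value to two decimal places
#'
#' Reporting rule for odds ratios: truncation (not rounding) to two
#' decimals, e.g. `4.7991` prints as `4.79`.
#'
#' @param x numeric vector.
#' @return `x` truncated towards zero at the second decimal.
#' @export
trunc2 <- function(x) trunc(x * 100) / 100

#' Format a fraction as a percentage string
#'
#' @param x fraction in \[0, 1\].
#' @param digits decimals to keep after conversion to percent (rounded).
#' @return character vector like `"0.035"` (percent units, no sign).
#' @export
fmt_pct <- function(x, digits = 3) sprintf(paste0("%.", digits, "f"), round(100 * x, digits))

#' Format an odds ratio (truncated to two decimals)
#'
#' @param x numeric vector of odds ratios.
#' @return character vector like `"4.79"`.
#' @export
fmt_or <- function(x) sprintf("%.2f", trunc2(x))
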