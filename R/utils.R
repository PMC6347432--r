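#' @keywords internal
"_PACKAGE"

# Run expr with a local RNG seed, restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a label, kept within 32-bit range.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Format a count as a percentage string
#'
#' One-decimal percentage of `n` out of `total`, the convention used in the
#' categorization report tables (e.g. 48 of 80 -> "60.0").
#'
#' @param n Count (numerator).
#' @param total Total (denominator).
#' @param digits Decimal places (default 1).
#' @return Numeric percentage rounded to `digits`.
#' @examples
#' format_percent(67, 80) # 83.75% of users completing three feedback runs
#' @export
format_percent <- function(n, total, digits = 2) {
  if (total <= 0) stopf("total must be positive")
  round(100 * n / total, digits)
}
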