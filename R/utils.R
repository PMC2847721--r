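#' Geometric mean
#'
#' Geometric mean of a strictly positive numeric vector, the aggregation used
#' to combine reference-gene quantities into a normalization factor.
#'
#' @param x Numeric vector, all values > 0.
#' @param na.rm Drop missing values before averaging?
#' @return A single number, `exp(mean(log(x)))`.
#' @examples
#' geometric_mean(c(2, 4, 8)) # 4
#' @export
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) abort("geometric mean of an empty vector", class = "earnorm_error_validation")
  if (any(x <= 0, na.rm = TRUE)) {
    abort("geometric mean requires strictly positive values", class = "earnorm_error_domain")
  }
  exp(mean(log(x)))
}

abort_validation <- function(msg) abort(msg, class = "earnorm_error_validation")
abort_domain <- function(msg) abort(msg, class = "earnorm_error_domain")
abort_format <- function(msg) abort(msg, class = "earnorm_error_format")
abort_insufficient <- function(msg) abort(msg, class = "earnorm_error_insufficient_data")

# stopifnot-style scalar checks used across modules
check_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_validation(sprintf("`%s` must be a single number", name))
  }
  if (positive && x <= 0) abort_domain(sprintf("`%s` must be > 0", name))
  invisible(x)
}
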