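#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation of two paired series, with the two-sided
#' p-value from the usual t transform, as used to compare normalization
#' strategies sample by sample.
#'
#' @param x,y Numeric vectors of equal length >= 3, each with non-zero
#'   variance.
#' @return A one-row tibble: `statistic` (r), `p_value`, `method`, `n1`,
#'   `n2` (both the shared n).
#' @examples
#' pearson_r(1:4, c(1, 3, 2, 4)) # r = 0.8
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort_validation("x and y must have equal length")
  if (length(x) < 3L) abort_insufficient("Pearson correlation needs >= 3 pairs")
  if (anyNA(x) || anyNA(y)) abort_validation("x and y must be complete")
  if (sd(x) == 0 || sd(y) == 0) {
    abort_domain("correlation undefined: a series has zero variance")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(statistic = unname(ct$estimate), p_value = ct$p.value,
         method = "pearson", n1 = length(x), n2 = length(y))
}

#' Mann-Whitney U test (exact for small samples)
#'
#' Rank-sum comparison of two independent groups. For combined sample sizes
#' of 16 or fewer with no ties the two-sided p-value comes from the exact
#' null distribution of U (equivalent to enumerating all rank assignments);
#' otherwise the normal approximation with tie and continuity corrections
#' is used. The `method` field records which path ran.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @return A one-row tibble: `statistic` (U for group `a`), `p_value`,
#'   `method` (`"mann_whitney_exact"` or `"mann_whitney_normal_approx"`),
#'   `n1`, `n2`.
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6)) # U = 0, p = 0.1 exactly
#' @export
mann_whitney_exact <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) abort_insufficient("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) abort_validation("groups must be complete")
  has_ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- (length(a) + length(b) <= 16L) && !has_ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                correct = TRUE)
  )
  p <- wt$p.value
  # fully tied data carry no evidence; the approximation's 0/0 becomes p = 1
  if (is.nan(p)) p <- 1
  tibble(
    statistic = unname(wt$statistic),
    p_value = min(1, p),
    method = if (use_exact) "mann_whitney_exact" else "mann_whitney_normal_approx",
    n1 = length(a), n2 = length(b)
  )
}

#' Percentile box summary
#'
#' Quartile summary following the box-plot convention used for skewed
#' expression data: box edges at the 25th and 75th percentiles, the median
#' line, and 10th/90th-percentile whiskers reported only when ten or more
#' values are available. Percentiles use linear interpolation between order
#' statistics (quantile type 7); the convention is recorded in the output.
#'
#' @param values Numeric vector, n >= 1.
#' @return A one-row tibble: `n`, `p25`, `median`, `p75`, `p10`, `p90`
#'   (the last two `NA` when n < 10), `percentile_type`.
#' @examples
#' box_summary(1:10)
#' @export
box_summary <- function(values) {
  if (length(values) < 1L || anyNA(values)) {
    abort_validation("`values` must be non-empty and complete")
  }
  q <- quantile(values, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7, names = FALSE)
  whiskers <- length(values) >= 10L
  tibble(
    n = length(values),
    p25 = q[2L], median = q[3L], p75 = q[4L],
    p10 = if (whiskers) q[1L] else NA_real_,
    p90 = if (whiskers) q[5L] else NA_real_,
    percentile_type = "linear_interpolation_type7"
  )
}

#' Group-wise box summaries of normalized expression
#'
#' @param normalized Tibble with a `normalized` column and a grouping
#'   column.
#' @param group Name of the grouping column (default `"strategy"`).
#' @return One [box_summary()] row per group, with the group column first.
#' @export
box_summary_by <- function(normalized, group = "strategy") {
  df <- as_tibble(normalized)
  if (!group %in% names(df)) abort_format(sprintf("column '%s' not found", group))
  df %>%
    group_by(across(all_of(group))) %>%
    summarise(box_summary(.data$normalized), .groups = "drop")
}
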