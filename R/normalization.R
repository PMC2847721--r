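#' Normalize a target to a single reference
#'
#' Divides the target's relative quantity by a single reference gene's
#' quantity, sample by sample. The universal-reference strategy (expressed
#' Alu repeats as the reference "gene") uses exactly this code path.
#' Samples missing the reference are dropped with a warning.
#'
#' @param quantities Long tibble `sample`, `gene`, `quantity` (positive).
#' @param target Target gene id.
#' @param reference Reference gene id (a housekeeping gene, or the pooled
#'   EAR signal).
#' @return A tibble `sample`, `target`, `normalized`, `strategy`
#'   (`"single_reference"`), `reference_detail`.
#' @export
normalize_to_single <- function(quantities, target, reference) {
  df <- as_tibble(quantities)
  qt <- filter(df, .data$gene == target)
  qr <- filter(df, .data$gene == reference)
  if (nrow(qt) == 0L) abort_validation(sprintf("target '%s' not in `quantities`", target))
  if (nrow(qr) == 0L) abort_validation(sprintf("reference '%s' not in `quantities`", reference))
  if (any(qr$quantity <= 0)) abort_domain("reference quantities must be positive")
  dropped <- setdiff(qt$sample, qr$sample)
  if (length(dropped) > 0) {
    warn(paste0("sample(s) missing the reference were omitted: ",
                paste(dropped, collapse = ", ")))
  }
  inner_join(
    select(qt, "sample", target_quantity = "quantity"),
    select(qr, "sample", ref_quantity = "quantity"),
    by = "sample"
  ) %>%
    mutate(
      target = target,
      normalized = .data$target_quantity / .data$ref_quantity,
      strategy = "single_reference",
      reference_detail = reference
    ) %>%
    select("sample", "target", "normalized", "strategy", "reference_detail")
}

#' Normalize a target to a normalization factor
#'
#' Divides the target's relative quantity by a per-sample normalization
#' factor, typically the geometric mean of the selected stable reference
#' genes from [normalization_factor()]. With a single-gene "factor" this is
#' identical to [normalize_to_single()].
#'
#' @inheritParams normalize_to_single
#' @param nf Either a tibble `sample`, `nf` (as returned by
#'   [normalization_factor()]) or a character vector of reference genes from
#'   which the factor is computed on the fly.
#' @return A tibble `sample`, `target`, `normalized`, `strategy` (`"nf"`),
#'   `reference_detail` (comma-separated reference genes when known).
#' @export
normalize_to_nf <- function(quantities, target, nf) {
  df <- as_tibble(quantities)
  qt <- filter(df, .data$gene == target)
  if (nrow(qt) == 0L) abort_validation(sprintf("target '%s' not in `quantities`", target))
  if (is.character(nf)) {
    detail <- paste(nf, collapse = ",")
    nf <- normalization_factor(df, nf)
  } else {
    nf <- as_tibble(nf)
    if (!all(c("sample", "nf") %in% names(nf))) {
      abort_format("`nf` needs columns sample, nf (or pass reference gene names)")
    }
    detail <- attr(nf, "reference_detail") %||% "precomputed"
  }
  if (any(nf$nf <= 0)) abort_domain("normalization factors must be positive")
  dropped <- setdiff(qt$sample, nf$sample)
  if (length(dropped) > 0) {
    warn(paste0("sample(s) missing a normalization factor were omitted: ",
                paste(dropped, collapse = ", ")))
  }
  inner_join(select(qt, "sample", "quantity"), nf, by = "sample") %>%
    mutate(
      target = target,
      normalized = .data$quantity / .data$nf,
      strategy = "nf",
      reference_detail = detail
    ) %>%
    select("sample", "target", "normalized", "strategy", "reference_detail")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare two normalization strategies
#'
#' Pairs the per-sample values produced by two normalization strategies for
#' the same target (e.g. EAR-normalized vs normalization-factor-normalized),
#' and summarises their agreement with a Pearson correlation, the two
#' medians, and per-sample ratios.
#'
#' @param values_a,values_b Tibbles as returned by the `normalize_to_*`
#'   functions (columns `sample`, `normalized`; a `strategy` column is used
#'   for labelling when present). At least 3 shared samples.
#' @return An object of class `strategy_comparison`: list with `paired`
#'   (sample, value_a, value_b, ratio), `pearson` (a [pearson_r()] result),
#'   `median_a`, `median_b`, `median_ratio`, `labels`.
#' @export
compare_strategies <- function(values_a, values_b) {
  a <- as_tibble(values_a)
  b <- as_tibble(values_b)
  lab_a <- if ("strategy" %in% names(a)) a$strategy[1L] else "A"
  lab_b <- if ("strategy" %in% names(b)) b$strategy[1L] else "B"
  paired <- inner_join(
    select(a, "sample", value_a = "normalized"),
    select(b, "sample", value_b = "normalized"),
    by = "sample"
  )
  if (nrow(paired) < 3L) {
    abort_insufficient("strategy comparison needs >= 3 shared samples")
  }
  paired <- mutate(paired, ratio = .data$value_a / .data$value_b)
  structure(
    list(
      paired = paired,
      pearson = pearson_r(paired$value_a, paired$value_b),
      median_a = median(paired$value_a),
      median_b = median(paired$value_b),
      median_ratio = median(paired$ratio),
      labels = c(lab_a, lab_b)
    ),
    class = "strategy_comparison"
  )
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("<strategy_comparison>", paste(x$labels, collapse = " vs "), "\n")
  cat(sprintf("  n samples     %d\n", nrow(x$paired)))
  cat(sprintf("  Pearson r     %.3f (p = %.3g)\n", x$pearson$statistic, x$pearson$p_value))
  cat(sprintf("  medians       %.4g vs %.4g (ratio of medians %.3f)\n",
              x$median_a, x$median_b, x$median_a / x$median_b))
  invisible(x)
}

#' @method glance strategy_comparison
#' @export
glance.strategy_comparison <- function(x, ...) {
  tibble(n = nrow(x$paired), pearson_r = x$pearson$statistic,
         p_value = x$pearson$p_value, median_a = x$median_a,
         median_b = x$median_b, median_ratio = x$median_ratio)
}

#' Scatter plot of two normalization strategies
#'
#' @param object A `strategy_comparison`.
#' @param ... Unused.
#' @return A ggplot with the identity line for reference.
#' @method autoplot strategy_comparison
#' @export
autoplot.strategy_comparison <- function(object, ...) {
  ggplot2::ggplot(object$paired, ggplot2::aes(x = .data$value_a, y = .data$value_b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = object$labels[1L], y = object$labels[2L],
      title = sprintf("Pearson r = %.2f", object$pearson$statistic)
    )
}
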