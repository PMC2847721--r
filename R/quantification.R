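#' Aggregate technical replicates
#'
#' Collapses a Cq table to one row per (sample, gene): arithmetic mean,
#' sample standard deviation (n - 1 denominator) and count of the
#' non-missing Cq measurements. Averaging happens on the cycle scale, where
#' technical noise is approximately additive; transformation to quantities
#' comes after. Pairs with no usable measurement are dropped with a warning.
#'
#' @param table A `cq_tbl` (see [as_cq_table()]) or a data frame with
#'   columns `sample`, `gene`, `cq`.
#' @return A tibble with columns `sample`, `gene`, `mean_cq`, `cq_sd`
#'   (`NA` when n < 2), `n`.
#' @export
aggregate_replicates <- function(table) {
  df <- as_tibble(table)
  if (!all(c("sample", "gene", "cq") %in% names(df))) {
    abort_format("`table` needs columns sample, gene, cq")
  }
  out <- df %>%
    group_by(.data$sample, .data$gene) %>%
    summarise(
      mean_cq = mean(.data$cq[!is.na(.data$cq)]),
      cq_sd = sd(.data$cq[!is.na(.data$cq)]),
      n = sum(!is.na(.data$cq)),
      .groups = "drop"
    )
  dead <- out$n == 0L
  if (any(dead)) {
    bad <- out[dead, ]
    warn(sprintf("%d (sample, gene) pair(s) have no usable Cq and were excluded: %s",
                 nrow(bad),
                 paste(sprintf("(%s, %s)", bad$sample, bad$gene), collapse = ", ")))
    out <- out[!dead, ]
  }
  out$mean_cq[is.nan(out$mean_cq)] <- NA_real_
  out
}

#' Efficiency-corrected relative quantities
#'
#' Converts per-(sample, gene) mean Cq to a relative quantity
#' `Q = A^(Cq_min - Cq)`, where `A` is the per-cycle amplification factor of
#' the gene's assay and `Cq_min` is that gene's lowest mean Cq across
#' samples. The highest-expressing sample of each gene therefore gets
#' `Q = 1` and all quantities lie in (0, 1] — the scaling expected by the
#' gene-stability analysis, and one that cancels in every downstream ratio.
#'
#' @param aggregated Output of [aggregate_replicates()] (or any data frame
#'   with `sample`, `gene`, `mean_cq`).
#' @param amplification_factor Either a single per-cycle factor applied to
#'   all genes, or a named numeric vector of per-gene factors (genes absent
#'   from the vector fall back to `default_factor`). The default of 2
#'   assumes 100% efficiency, the usual fallback when only some assays have
#'   a standard curve.
#' @param default_factor Fallback factor for genes without an entry.
#' @return A tibble `sample`, `gene`, `mean_cq`, `quantity`.
#' @examples
#' agg <- tibble::tibble(sample = c("s1", "s2"), gene = "EAR",
#'                       mean_cq = c(20, 23))
#' relative_quantity(agg) # s2 gets 2^-3 = 0.125
#' @export
relative_quantity <- function(aggregated, amplification_factor = 2,
                              default_factor = 2) {
  df <- as_tibble(aggregated)
  if (!all(c("sample", "gene", "mean_cq") %in% names(df))) {
    abort_format("`aggregated` needs columns sample, gene, mean_cq")
  }
  if (any(is.na(df$mean_cq))) abort_validation("mean_cq must be non-missing")
  if (any(amplification_factor <= 1, na.rm = TRUE) || default_factor <= 1) {
    abort_domain("amplification factors must be > 1")
  }
  genes <- unique(df$gene)
  if (is.null(names(amplification_factor))) {
    if (length(amplification_factor) != 1L) {
      abort_validation("unnamed `amplification_factor` must be a single value")
    }
    factors <- setNames(rep(amplification_factor, length(genes)), genes)
  } else {
    factors <- setNames(rep(default_factor, length(genes)), genes)
    known <- intersect(genes, names(amplification_factor))
    factors[known] <- amplification_factor[known]
  }
  df %>%
    group_by(.data$gene) %>%
    mutate(quantity = factors[[.data$gene[1L]]]^(min(.data$mean_cq) - .data$mean_cq)) %>%
    ungroup() %>%
    select("sample", "gene", "mean_cq", "quantity")
}

#' Cq table to relative quantities in one step
#'
#' Convenience wrapper chaining [aggregate_replicates()] and
#' [relative_quantity()].
#'
#' @inheritParams aggregate_replicates
#' @inheritParams relative_quantity
#' @return A tibble `sample`, `gene`, `mean_cq`, `cq_sd`, `n`, `quantity`.
#' @export
quantify_cq <- function(table, amplification_factor = 2, default_factor = 2) {
  agg <- aggregate_replicates(table)
  q <- relative_quantity(agg, amplification_factor, default_factor)
  left_join(agg, select(q, "sample", "gene", "quantity"),
            by = c("sample", "gene"))
}
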