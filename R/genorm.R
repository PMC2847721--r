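# Quantities are handled internally as a samples x genes matrix of Q values;
# the user-facing surface is a long tibble (sample, gene, quantity).

quantity_matrix <- function(quantities) {
  df <- as_tibble(quantities)
  if (!all(c("sample", "gene", "quantity") %in% names(df))) {
    abort_format("`quantities` needs columns sample, gene, quantity")
  }
  if (any(is.na(df$quantity)) || any(df$quantity <= 0)) {
    abort_domain("all quantities must be positive and non-missing")
  }
  wide <- tidyr::pivot_wider(df[c("sample", "gene", "quantity")],
                             names_from = "gene", values_from = "quantity")
  if (anyNA(wide)) abort_validation("every sample must have a quantity for every gene")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$sample
  m
}

#' Pairwise variation between two genes
#'
#' The elementary statistic of the gene-stability analysis: the sample
#' standard deviation (n - 1 denominator) of the per-sample log2 ratio of
#' two genes' relative quantities. Two genes that are proportional across
#' samples — however different their absolute levels — have pairwise
#' variation 0, the ideal for a pair of references.
#'
#' @param q_j,q_k Positive relative quantities of two genes over the same
#'   samples, in the same order (>= 2 samples).
#' @return A single number, `sd(log2(q_j / q_k))`.
#' @examples
#' pairwise_variation(c(1, 2), c(1, 1)) # sd(c(0, 1)) = 0.7071
#' @export
pairwise_variation <- function(q_j, q_k) {
  if (length(q_j) != length(q_k)) abort_validation("q_j and q_k must cover the same samples")
  if (length(q_j) < 2L) abort_insufficient("pairwise variation needs >= 2 samples")
  if (any(q_j <= 0) || any(q_k <= 0) || anyNA(q_j) || anyNA(q_k)) {
    abort_domain("quantities must be positive and non-missing")
  }
  sd(log2(q_j / q_k))
}

#' Gene-expression stability measure M
#'
#' For each gene j, M_j is the mean of its pairwise variations against every
#' other candidate gene. Low M means the gene co-varies with the panel
#' consensus; genes with M at or above 0.5 are conventionally considered
#' unstable references.
#'
#' @param quantities Long tibble with columns `sample`, `gene`, `quantity`
#'   (all positive); every sample x gene cell present.
#' @param genes Optional character vector restricting (and ordering) the
#'   panel; default is all genes in `quantities`. Needs >= 3 genes — with
#'   two, the single shared pairwise variation cannot rank them.
#' @return A tibble `gene`, `m`, sorted by increasing `m`.
#' @export
stability_m <- function(quantities, genes = NULL) {
  m <- quantity_matrix(quantities)
  if (!is.null(genes)) {
    missing_genes <- setdiff(genes, colnames(m))
    if (length(missing_genes) > 0) {
      abort_validation(paste0("gene(s) not in `quantities`: ",
                              paste(missing_genes, collapse = ", ")))
    }
    m <- m[, genes, drop = FALSE]
  }
  if (ncol(m) < 3L) {
    abort_insufficient("stability M needs >= 3 genes (with 2 the ranking is unresolvable)")
  }
  if (nrow(m) < 2L) abort_insufficient("stability M needs >= 2 samples")
  tibble(gene = colnames(m), m = stability_m_matrix(m)) %>% arrange(.data$m)
}

# M over the columns of a samples x genes log-quantity-ready matrix.
# sd of log2(Qj/Qk) for all pairs, averaged per gene.
stability_m_matrix <- function(q) {
  lq <- log2(q)
  g <- ncol(lq)
  v <- matrix(0, g, g)
  for (j in seq_len(g - 1L)) {
    for (k in (j + 1L):g) {
      v[j, k] <- v[k, j] <- sd(lq[, j] - lq[, k])
    }
  }
  rowSums(v) / (g - 1L)
}

#' Stepwise reference-gene ranking
#'
#' Runs the full stability analysis: compute M for every candidate, drop the
#' gene with the largest M, recompute on the survivors, and repeat until two
#' genes remain. The exclusion order plus the final pair defines the
#' stability ranking (most stable last); the final two genes cannot be
#' mutually ranked — with two genes M collapses to a single shared pairwise
#' variation — and are reported rank-tied in lexicographic order. Ties at
#' the exclusion step are broken lexicographically and flagged in the
#' report.
#'
#' The `n_references` most stable genes form the selected reference set used
#' to build a normalization factor; each selected gene's M from the last
#' round in which it was evaluated is checked against `threshold`, and a
#' warning is raised if any selected gene fails the `M < threshold`
#' stability rule.
#'
#' @inheritParams stability_m
#' @param threshold Stability threshold; a gene with `M >= threshold` is
#'   considered unstable (default 0.5).
#' @param n_references Number of most-stable genes to select (default 3).
#' @return An object of class `genorm_ranking`: a list with `rounds` (tibble
#'   of round, gene, m), `exclusion_order` (least stable first), `final_pair`,
#'   `ranking` (most stable first), `selected_references`, `last_m` (per-gene
#'   M from its last evaluated round), `selected_stable` (logical, selected
#'   genes passing `M < threshold`), `threshold`, `n_samples`, `log_base`,
#'   and `ties` (rounds where the exclusion was tie-broken).
#' @seealso [stability_m()], [normalization_factor()], [tidy.genorm_ranking()]
#' @export
stepwise_ranking <- function(quantities, genes = NULL, threshold = 0.5,
                             n_references = 3L) {
  q <- quantity_matrix(quantities)
  if (!is.null(genes)) q <- q[, genes, drop = FALSE]
  if (ncol(q) < 3L) abort_insufficient("stepwise ranking needs >= 3 genes")
  check_number(threshold, "threshold", positive = TRUE)
  n_references <- as.integer(n_references)
  if (n_references < 2L || n_references > ncol(q)) {
    abort_validation("`n_references` must be between 2 and the number of genes")
  }

  remaining <- sort(colnames(q))
  rounds <- list()
  exclusion_order <- character(0)
  last_m <- setNames(rep(NA_real_, ncol(q)), remaining)
  ties <- integer(0)
  round_i <- 1L
  while (length(remaining) >= 3L) {
    m_vals <- stability_m_matrix(q[, remaining, drop = FALSE])
    names(m_vals) <- remaining
    rounds[[round_i]] <- tibble(round = round_i, gene = remaining, m = unname(m_vals))
    last_m[remaining] <- m_vals
    worst <- max(m_vals)
    # exact proportionality leaves M equal up to rounding; treat near-equal
    # maxima as a tie so the lexicographic rule is reproducible
    candidates <- sort(remaining[m_vals >= worst - 1e-12])
    if (length(candidates) > 1L) ties <- c(ties, round_i)
    out_gene <- candidates[1L]
    exclusion_order <- c(exclusion_order, out_gene)
    remaining <- setdiff(remaining, out_gene)
    round_i <- round_i + 1L
  }
  final_pair <- sort(remaining)
  ranking <- c(final_pair, rev(exclusion_order))
  selected <- ranking[seq_len(n_references)]
  selected_stable <- setNames(last_m[selected] < threshold, selected)
  if (any(!selected_stable)) {
    warn(paste0("selected reference gene(s) fail the M < ", threshold, " stability rule: ",
                paste(selected[!selected_stable], collapse = ", ")))
  }
  structure(
    list(
      rounds = bind_rows(rounds),
      exclusion_order = exclusion_order,
      final_pair = final_pair,
      ranking = ranking,
      selected_references = selected,
      last_m = last_m,
      selected_stable = selected_stable,
      threshold = threshold,
      n_samples = nrow(q),
      log_base = 2,
      ties = ties
    ),
    class = "genorm_ranking"
  )
}

#' @export
print.genorm_ranking <- function(x, ...) {
  cat("<genorm_ranking>\n")
  cat("  ranking (most to least stable): ", paste(x$ranking, collapse = ", "), "\n", sep = "")
  cat("  final pair (rank-tied): ", paste(x$final_pair, collapse = " / "), "\n", sep = "")
  cat("  selected references: ", paste(x$selected_references, collapse = ", "), "\n", sep = "")
  m <- x$last_m[x$selected_references]
  cat(sprintf("  selected M (last round): %s  [threshold %.2f]\n",
              paste(sprintf("%s=%.3f", names(m), m), collapse = ", "), x$threshold))
  if (length(x$ties) > 0) cat("  tie-broken rounds:", paste(x$ties, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a stepwise stability ranking
#'
#' @param x A `genorm_ranking`.
#' @param ... Unused.
#' @return Per-gene rows: rank (1 = most stable; the final pair shares the
#'   ranking's display order but is rank-tied), M from the gene's last
#'   evaluated round, selection and stability flags.
#' @method tidy genorm_ranking
#' @export
tidy.genorm_ranking <- function(x, ...) {
  tibble(
    gene = x$ranking,
    rank = seq_along(x$ranking),
    rank_tied = x$ranking %in% x$final_pair,
    m_last_round = unname(x$last_m[x$ranking]),
    selected = x$ranking %in% x$selected_references,
    stable = unname(x$last_m[x$ranking] < x$threshold)
  )
}

#' One-row summary of a stability ranking
#'
#' @param x A `genorm_ranking`.
#' @param ... Unused.
#' @method glance genorm_ranking
#' @export
glance.genorm_ranking <- function(x, ...) {
  tibble(
    n_genes = length(x$ranking),
    n_samples = x$n_samples,
    n_rounds = max(x$rounds$round),
    threshold = x$threshold,
    all_selected_stable = all(x$selected_stable),
    worst_selected_m = max(x$last_m[x$selected_references])
  )
}

#' Plot average stability across exclusion rounds
#'
#' Mirrors the classic stability plot: average M of the remaining genes at
#' each stepwise-exclusion round, annotated with the gene removed.
#'
#' @param object A `genorm_ranking`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot genorm_ranking
#' @export
autoplot.genorm_ranking <- function(object, ...) {
  d <- object$rounds %>%
    group_by(.data$round) %>%
    summarise(avg_m = mean(.data$m), n_genes = n(), .groups = "drop") %>%
    mutate(excluded = object$exclusion_order[.data$round])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_genes, y = .data$avg_m)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$excluded), vjust = -0.8, size = 3) +
    ggplot2::scale_x_reverse() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "genes remaining", y = "average stability M",
                  title = "Stepwise exclusion of the least stable gene")
}

#' Geometric-mean normalization factor
#'
#' Per-sample geometric mean of the relative quantities of the selected
#' reference genes — the quantity a target is divided by under multi-gene
#' normalization.
#'
#' @inheritParams stability_m
#' @param reference_genes Character vector of >= 2 reference genes.
#' @return A tibble `sample`, `nf`.
#' @examples
#' q <- tidyr::expand_grid(sample = "s1", gene = c("a", "b", "c"))
#' q$quantity <- c(2, 4, 8)
#' normalization_factor(q, c("a", "b", "c")) # nf = 4
#' @export
normalization_factor <- function(quantities, reference_genes) {
  if (length(reference_genes) < 2L) {
    abort_validation("a normalization factor needs >= 2 reference genes")
  }
  m <- quantity_matrix(quantities)
  missing_genes <- setdiff(reference_genes, colnames(m))
  if (length(missing_genes) > 0) {
    abort_validation(paste0("reference gene(s) not in `quantities`: ",
                            paste(missing_genes, collapse = ", ")))
  }
  sub <- m[, reference_genes, drop = FALSE]
  tibble(sample = rownames(m), nf = unname(apply(sub, 1L, geometric_mean)))
}
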