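# Independent oracles kept deliberately separate from the package's code
# paths: plain loops, base R only.

# brute-force stability M: for each gene, average over all other genes of
# the n-1 sd of the per-sample log2 ratio
oracle_stability_m <- function(qmat) {
  g <- ncol(qmat)
  out <- numeric(g)
  for (j in seq_len(g)) {
    vs <- c()
    for (k in seq_len(g)) {
      if (k == j) next
      r <- log(qmat[, j] / qmat[, k], base = 2)
      mu <- sum(r) / length(r)
      vs <- c(vs, sqrt(sum((r - mu)^2) / (length(r) - 1)))
    }
    out[j] <- mean(vs)
  }
  names(out) <- colnames(qmat)
  out
}

# exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to group A (tie-free inputs only)
oracle_mw <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  })
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# string reverse complement without Biostrings
oracle_revcomp <- function(s) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# deterministic pseudo-random filler sequence that avoids a given set of
# motifs appearing by chance (checked by the caller's single-hit asserts)
filler_seq <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# synthetic template with one planted amplicon of the requested size
synth_template <- function(forward, reverse, product_bp, seed = 1,
                           flank5 = 30, flank3 = 25) {
  insert <- product_bp - nchar(forward) - nchar(reverse)
  stopifnot(insert >= 0)
  paste0(filler_seq(flank5, seed), forward, filler_seq(insert, seed + 1),
         oracle_revcomp(reverse), filler_seq(flank3, seed + 2))
}

write_lines_tmp <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# small long-format quantity table from a samples x genes matrix
quantities_from_matrix <- function(qmat) {
  tibble::tibble(
    sample = rep(rownames(qmat), times = ncol(qmat)),
    gene = rep(colnames(qmat), each = nrow(qmat)),
    quantity = as.vector(qmat)
  )
}

rand_qmat <- function(n_samples, n_genes) {
  m <- matrix(2^rnorm(n_samples * n_genes, 0, 1), n_samples, n_genes)
  rownames(m) <- sprintf("s%d", seq_len(n_samples))
  colnames(m) <- sprintf("g%d", seq_len(n_genes))
  m
}
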