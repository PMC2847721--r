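#' Find amplicons of a primer pair on a transcript
#'
#' In-silico PCR against a sense-strand (plus-strand) template: the forward
#' primer is matched directly, the reverse primer as its reverse complement
#' downstream of the forward site. Reported coordinates are 1-based
#' inclusive; the amplicon spans the first base of the forward match through
#' the last base of the reverse-complement match (the reverse primer's 5'
#' end on the plus strand), so `length_bp = end - start + 1`.
#'
#' IUPAC ambiguity codes in the primers match their degenerate base sets.
#' When `max_mismatches > 0`, mismatches are never accepted in the 3'
#' terminal 3 bases of either primer, since polymerase extension requires a
#' matched 3' end. By default only the plus strand is searched (mRNA
#' templates); `both_strands = TRUE` also scans the reverse complement of
#' the template, as appropriate for genomic sequence.
#'
#' @param pair A [primer_pair()] (one row).
#' @param sequence A DNA string (sense strand, 5' to 3').
#' @param max_mismatches Maximum mismatches allowed per primer (default 0).
#' @param max_product_bp Longest product considered (default 2000).
#' @param both_strands Also search the minus strand? Default `FALSE`.
#' @return A tibble with zero or more rows: `name`, `strand`, `start`,
#'   `end`, `length_bp`, `fwd_mismatches`, `rev_mismatches`, sorted by
#'   `start`. No hit is an empty tibble, not an error.
#' @examples
#' p <- primer_pair("toy", "ACGTACGTAC", "TTTTGGGGCC")
#' # template: forward site + filler + reverse complement of the reverse primer
#' tmpl <- paste0("ACGTACGTAC", "AAAA", "GGCCCCAAAA")
#' find_amplicons(p, tmpl) # one 24-bp hit
#' @export
find_amplicons <- function(pair, sequence, max_mismatches = 0L,
                           max_product_bp = 2000L, both_strands = FALSE) {
  if (!inherits(pair, "primer_pair") || nrow(pair) != 1L) {
    abort_validation("`pair` must be a single primer_pair()")
  }
  sequence <- toupper(chartr("U", "T", as.character(sequence)))
  hits <- amplicon_scan(pair, sequence, max_mismatches, max_product_bp, "+")
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
    minus <- amplicon_scan(pair, rc, max_mismatches, max_product_bp, "-")
    if (nrow(minus) > 0) {
      # map minus-strand coordinates back onto the input sequence
      L <- nchar(sequence)
      minus <- minus %>%
        mutate(start2 = L - .data$end + 1L, end2 = L - .data$start + 1L) %>%
        mutate(start = .data$start2, end = .data$end2) %>%
        select(-"start2", -"end2")
    }
    hits <- bind_rows(hits, minus)
  }
  arrange(hits, .data$start)
}

# IUPAC degeneracy sets for primer bases (the subject base must be a plain
# nucleotide drawn from the code's set)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_mismatch_positions <- function(pattern, observed) {
  p <- strsplit(pattern, "")[[1]]
  o <- strsplit(observed, "")[[1]]
  which(!mapply(function(pc, oc) oc %in% IUPAC_SETS[[pc]], p, o))
}

# match one primer (pattern given 5'->3' as it appears on the searched
# strand) and return starts plus mismatch counts honouring the 3'-end rule
primer_matches <- function(pattern, subject, max_mismatches, three_prime_left) {
  m <- Biostrings::matchPattern(
    Biostrings::DNAString(pattern), subject,
    max.mismatch = max_mismatches, fixed = "subject"
  )
  if (length(m) == 0L) return(tibble(start = integer(0), mismatches = integer(0)))
  n <- nchar(pattern)
  starts <- BiocGenerics::start(m)
  observed <- as.character(m)
  mm <- lapply(observed, iupac_mismatch_positions, pattern = pattern)
  keep <- vapply(mm, function(pos) {
    if (length(pos) == 0L) return(TRUE)
    # positions run along the pattern; the extension-critical 3' bases are
    # the last 3 of the primer, which sit leftmost when the primer was
    # reverse-complemented onto this strand
    crit <- if (three_prime_left) seq_len(3L) else (n - 2L):n
    !any(pos %in% crit)
  }, logical(1))
  tibble(start = starts[keep], mismatches = lengths(mm)[keep])
}

amplicon_scan <- function(pair, sequence, max_mismatches, max_product_bp, strand) {
  subject <- Biostrings::DNAString(sequence)
  fwd <- primer_matches(pair$forward, subject, max_mismatches, three_prime_left = FALSE)
  rev_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pair$reverse)))
  rev <- primer_matches(rev_rc, subject, max_mismatches, three_prime_left = TRUE)
  empty <- tibble(name = character(0), strand = character(0), start = integer(0),
                  end = integer(0), length_bp = integer(0),
                  fwd_mismatches = integer(0), rev_mismatches = integer(0))
  if (nrow(fwd) == 0L || nrow(rev) == 0L) return(empty)
  len_f <- nchar(pair$forward)
  len_r <- nchar(rev_rc)
  combos <- tidyr::expand_grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  out <- purrr::pmap(combos, function(f, r) {
    fs <- fwd$start[f]
    rs <- rev$start[r]
    re <- rs + len_r - 1L
    # reverse site must lie fully downstream of the forward primer
    if (rs <= fs + len_f - 1L) return(NULL)
    len <- re - fs + 1L
    if (len > max_product_bp) return(NULL)
    tibble(name = pair$name, strand = strand, start = fs, end = re,
           length_bp = len, fwd_mismatches = fwd$mismatches[f],
           rev_mismatches = rev$mismatches[r])
  })
  out <- bind_rows(out)
  if (nrow(out) == 0L) empty else out
}

#' Validate a primer panel against template sequences
#'
#' Runs [find_amplicons()] for every primer pair against every sequence and
#' reports, per pair: whether exactly one amplicon was found anywhere, its
#' length, and whether it matches the declared expectation. Multiple hits
#' are flagged ambiguous, never a pass.
#'
#' @param pairs Tibble of primer pairs (see [read_primers()] /
#'   [primer_pair()]).
#' @param sequences Tibble `id`, `sequence` (see [read_fasta()]).
#' @inheritParams find_amplicons
#' @return A tibble, one row per primer pair: `name`, `n_hits`,
#'   `sequence_id`, `length_bp`, `expected_product_bp`, `status`
#'   (`"pass"`, `"fail"`, `"ambiguous"`, `"not_found"`).
#' @export
validate_panel <- function(pairs, sequences, max_mismatches = 0L,
                           max_product_bp = 2000L) {
  pairs <- as_tibble(pairs)
  sequences <- as_tibble(sequences)
  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    pr <- pairs[i, ]
    class(pr) <- c("primer_pair", class(tibble()))
    hits <- purrr::map2(sequences$id, sequences$sequence, function(id, sq) {
      h <- find_amplicons(pr, sq, max_mismatches, max_product_bp)
      if (nrow(h) > 0) h$sequence_id <- id
      h
    }) %>% bind_rows()
    expected <- pr$expected_product_bp
    if (nrow(hits) == 0L) {
      tibble(name = pr$name, n_hits = 0L, sequence_id = NA_character_,
             length_bp = NA_integer_, expected_product_bp = expected,
             status = "not_found")
    } else if (nrow(hits) > 1L) {
      tibble(name = pr$name, n_hits = nrow(hits), sequence_id = NA_character_,
             length_bp = NA_integer_, expected_product_bp = expected,
             status = "ambiguous")
    } else {
      ok <- !is.na(expected) && hits$length_bp == expected
      tibble(name = pr$name, n_hits = 1L, sequence_id = hits$sequence_id,
             length_bp = hits$length_bp, expected_product_bp = expected,
             status = if (is.na(expected)) "found" else if (ok) "pass" else "fail")
    }
  })
  bind_rows(rows)
}
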