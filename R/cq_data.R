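#' Replicate design of a qPCR experiment
#'
#' Records how many independent reverse-transcription (RT) reactions and how
#' many PCR replicates per RT reaction an experiment was designed with. The
#' classic design is two RT reactions, each amplified three times, for six
#' independent measurements per sample and gene.
#'
#' @param rt_replicates Expected number of RT replicates (>= 1).
#' @param pcr_replicates Expected number of PCR replicates per RT (>= 1).
#' @return A list of class `cq_design`.
#' @examples
#' cq_design(2, 3)
#' @export
cq_design <- function(rt_replicates = 2L, pcr_replicates = 3L) {
  rt <- as.integer(rt_replicates)
  pcr <- as.integer(pcr_replicates)
  if (is.na(rt) || rt < 1L || is.na(pcr) || pcr < 1L) {
    abort_validation("replicate design counts must be integers >= 1")
  }
  structure(list(rt_replicates = rt, pcr_replicates = pcr), class = "cq_design")
}

#' @export
print.cq_design <- function(x, ...) {
  cat(sprintf("<cq_design> %d RT x %d PCR replicates (%d measurements per sample x gene)\n",
              x$rt_replicates, x$pcr_replicates, x$rt_replicates * x$pcr_replicates))
  invisible(x)
}

cq_cols <- c("sample", "gene", "rt_rep", "pcr_rep", "cq")

new_cq_table <- function(df, design) {
  structure(df, class = c("cq_tbl", class(tibble())), design = design)
}

#' Build a validated Cq table
#'
#' Validates a data frame of quantification-cycle (Cq) measurements against
#' the table invariants: one row per (sample, gene, rt_rep, pcr_rep), Cq
#' missing or in (0, 60) cycles, 1-based positive replicate indices.
#' Identifiers are treated case-sensitively so that, e.g., `B2M` and `b2m`
#' are distinct genes.
#'
#' @param df Data frame with columns `sample`, `gene`, `rt_rep`, `pcr_rep`,
#'   `cq`. Missing Cq (failed/undetermined wells) is `NA`, never a sentinel.
#' @param design A [cq_design()] describing the expected replicate counts.
#' @return A `cq_tbl`: a tibble carrying the design as an attribute.
#' @export
as_cq_table <- function(df, design = cq_design()) {
  if (!inherits(design, "cq_design")) abort_validation("`design` must be a cq_design()")
  missing_cols <- setdiff(cq_cols, names(df))
  if (length(missing_cols) > 0) {
    abort_format(paste0("Cq table is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)[cq_cols]
  df$sample <- as.character(df$sample)
  df$gene <- as.character(df$gene)
  df$rt_rep <- as.integer(df$rt_rep)
  df$pcr_rep <- as.integer(df$pcr_rep)
  df$cq <- as.numeric(df$cq)
  if (any(is.na(df$sample)) || any(is.na(df$gene))) {
    abort_validation("sample and gene identifiers must be non-missing")
  }
  if (any(is.na(df$rt_rep)) || any(df$rt_rep < 1L) ||
      any(is.na(df$pcr_rep)) || any(df$pcr_rep < 1L)) {
    abort_validation("replicate indices must be positive integers (1-based)")
  }
  bad_cq <- !is.na(df$cq) & (df$cq <= 0 | df$cq >= 60)
  if (any(bad_cq)) {
    abort_validation(sprintf("Cq values must lie in (0, 60) cycles; %d value(s) out of range",
                             sum(bad_cq)))
  }
  key <- paste(df$sample, df$gene, df$rt_rep, df$pcr_rep, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- df[which(dup)[1L], ]
    abort_validation(sprintf(
      "duplicate measurement key: sample '%s', gene '%s', rt_rep %d, pcr_rep %d",
      first$sample, first$gene, first$rt_rep, first$pcr_rep))
  }
  over <- df$rt_rep > design$rt_replicates | df$pcr_rep > design$pcr_replicates
  if (any(over)) {
    abort_validation(sprintf(
      "replicate index exceeds design (%d RT x %d PCR) in %d row(s)",
      design$rt_replicates, design$pcr_replicates, sum(over)))
  }
  new_cq_table(df, design)
}

#' Read a Cq plate table from CSV
#'
#' Long-format CSV with header `sample,gene,rt_rep,pcr_rep,cq` (UTF-8, dot
#' decimal separator). An empty `cq` field denotes a missing measurement and
#' is preserved as `NA`. Every data row in the file becomes a measurement or
#' an error is raised; rows are never dropped silently.
#'
#' @param path Path to the CSV file.
#' @param design A [cq_design()]; defaults to the 2 RT x 3 PCR design.
#' @return A validated `cq_tbl` (see [as_cq_table()]).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("sample,gene,rt_rep,pcr_rep,cq", "s1,EAR,1,1,21.3"), f)
#' read_cq_table(f, cq_design(1, 1))
#' @export
read_cq_table <- function(path, design = cq_design()) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (!identical(header, cq_cols)) {
    abort_format(paste0("expected header 'sample,gene,rt_rep,pcr_rep,cq', found '",
                        paste(header, collapse = ","), "'"))
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      sample = readr::col_character(),
      gene = readr::col_character(),
      rt_rep = readr::col_integer(),
      pcr_rep = readr::col_integer(),
      cq = readr::col_double()
    )
  )
  problems <- readr::problems(raw)
  if (nrow(problems) > 0) {
    abort_format(sprintf("failed to parse %d cell(s); first problem at row %d: %s",
                         nrow(problems), problems$row[1L], problems$expected[1L]))
  }
  tbl <- as_cq_table(raw, design)
  message(sprintf("read_cq_table: %d measurement(s) from %s", nrow(tbl), path))
  tbl
}

#' Write a Cq table to CSV
#'
#' Inverse of [read_cq_table()]: round-trips every (sample, gene, rt_rep,
#' pcr_rep, cq) exactly, with missing Cq written as an empty field.
#'
#' @param table A `cq_tbl`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(table, path) {
  readr::write_csv(as_tibble(table)[cq_cols], path, na = "")
  invisible(path)
}

#' Read melt curves from CSV
#'
#' Long-format CSV with columns `well,sample,gene,temperature_c,fluorescence`.
#' Returns one curve per well, sorted by temperature, as a nested tibble.
#' A well needs at least two temperature points (the negative-derivative
#' transform needs three; a single point is rejected outright), duplicate
#' temperatures within a well are an error, and the grid must lie within
#' 50-100 degrees C.
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per well: `well`, `sample`, `gene`, and a
#'   list-column `curve` of tibbles (`temperature_c`, `fluorescence`) sorted
#'   by strictly increasing temperature.
#' @export
read_melt_curves <- function(path) {
  melt_cols <- c("well", "sample", "gene", "temperature_c", "fluorescence")
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (!identical(header, melt_cols)) {
    abort_format(paste0("expected header '", paste(melt_cols, collapse = ","),
                        "', found '", paste(header, collapse = ","), "'"))
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      well = readr::col_character(),
      sample = readr::col_character(),
      gene = readr::col_character(),
      temperature_c = readr::col_double(),
      fluorescence = readr::col_double()
    )
  )
  as_melt_curves(raw)
}

#' Validate a long table of melt-curve points
#'
#' @param df Data frame with columns `well`, `sample`, `gene`,
#'   `temperature_c`, `fluorescence`.
#' @return Nested tibble as in [read_melt_curves()].
#' @export
as_melt_curves <- function(df) {
  df <- as_tibble(df)
  if (any(is.na(df$temperature_c)) || any(is.na(df$fluorescence))) {
    abort_validation("melt-curve points must have non-missing temperature and fluorescence")
  }
  if (any(df$temperature_c < 50 | df$temperature_c > 100)) {
    abort_validation("melt temperatures must lie within [50, 100] degrees C")
  }
  out <- df %>%
    arrange(.data$well, .data$temperature_c) %>%
    group_by(.data$well, .data$sample, .data$gene) %>%
    tidyr::nest(curve = c("temperature_c", "fluorescence")) %>%
    ungroup()
  for (i in seq_len(nrow(out))) {
    tc <- out$curve[[i]]$temperature_c
    if (length(tc) < 2L) {
      abort_validation(sprintf("well '%s' has a single temperature point; a melt curve needs a grid",
                               out$well[i]))
    }
    if (any(diff(tc) <= 0)) {
      abort_validation(sprintf("well '%s' has duplicated temperature values", out$well[i]))
    }
  }
  out
}

#' Read sequences from a FASTA file
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`, so transcript
#' records can be used directly as PCR templates. Only IUPAC DNA codes
#' (including ambiguity codes and gap characters `-`) are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first word of the header) and
#'   `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort_validation("FASTA file contains no records")
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (any(!nzchar(seqs))) {
    abort_validation(sprintf("empty FASTA record: '%s'", ids[which(!nzchar(seqs))[1L]]))
  }
  allowed <- strsplit("ACGTRYSWKMBDHVN-", "")[[1]]
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[i], "")[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad) > 0) {
      abort_validation(sprintf("record '%s' contains non-IUPAC character(s): %s",
                               ids[i], paste(bad, collapse = ", ")))
    }
  }
  tibble(id = unname(ids), sequence = unname(seqs))
}

#' Define a primer pair
#'
#' @param name Assay name.
#' @param forward,reverse Primer sequences, 5' to 3', IUPAC DNA (>= 10 nt).
#' @param expected_product_bp Expected amplicon length in bp, or `NA` when
#'   unknown.
#' @return A one-row tibble of class `primer_pair`.
#' @examples
#' primer_pair("EAR", "GAGGCTGAGGCAGGAGAATCG", "GTCGCCCAGGCTGGAGTG", 87)
#' @export
primer_pair <- function(name, forward, reverse, expected_product_bp = NA_integer_) {
  forward <- toupper(forward)
  reverse <- toupper(reverse)
  iupac <- "^[ACGTRYSWKMBDHVN]+$"
  if (nchar(forward) < 10L || nchar(reverse) < 10L) {
    abort_validation("primers must be at least 10 nt long")
  }
  if (!grepl(iupac, forward) || !grepl(iupac, reverse)) {
    abort_validation("primers must be IUPAC DNA strings")
  }
  if (!is.na(expected_product_bp) && expected_product_bp < 1) {
    abort_validation("expected_product_bp must be positive or NA")
  }
  out <- tibble(name = as.character(name), forward = forward, reverse = reverse,
                expected_product_bp = as.integer(expected_product_bp))
  class(out) <- c("primer_pair", class(out))
  out
}

#' Read primer definitions from CSV
#'
#' Columns `name,forward,reverse,expected_product_bp` (the last may be empty).
#'
#' @param path CSV path.
#' @return A tibble of validated primer pairs, one row per assay.
#' @export
read_primers <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      name = readr::col_character(),
      forward = readr::col_character(),
      reverse = readr::col_character(),
      expected_product_bp = readr::col_integer()
    )
  )
  pairs <- purrr::pmap(raw, primer_pair)
  bind_rows(pairs)
}
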