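test_that("a six-measurement plate (2 RT x 3 PCR) reads into six rows", {
  lines <- c("sample,gene,rt_rep,pcr_rep,cq",
             paste("s1,EAR", rep(1:2, each = 3), rep(1:3, 2),
                   c(21.1, 21.2, 21.0, 21.3, 21.1, 21.2), sep = ","))
  f <- write_lines_tmp(lines)
  tbl <- suppressMessages(read_cq_table(f, cq_design(2, 3)))
  expect_s3_class(tbl, "cq_tbl")
  expect_equal(nrow(tbl), 6L)
  expect_equal(attr(tbl, "design")$pcr_replicates, 3L)
})

test_that("a header-only file yields an empty table and bad headers error", {
  f <- write_lines_tmp("sample,gene,rt_rep,pcr_rep,cq")
  expect_equal(nrow(suppressMessages(read_cq_table(f))), 0L)
  g <- write_lines_tmp(c("sample,gene,rep,cq", "s1,g1,1,20"))
  expect_error(read_cq_table(g), class = "earnorm_error_format")
})

test_that("duplicate measurement keys are rejected and named", {
  lines <- c("sample,gene,rt_rep,pcr_rep,cq", "s1,g1,1,1,20", "s1,g1,1,1,21")
  expect_error(suppressMessages(read_cq_table(write_lines_tmp(lines))),
               regexp = "s1.*g1", class = "earnorm_error_validation")
})

test_that("Cq values outside (0, 60) and bad replicate indices are rejected", {
  base <- data.frame(sample = "s1", gene = "g1", rt_rep = 1L, pcr_rep = 1L, cq = 20)
  expect_error(as_cq_table(transform(base, cq = 61)), class = "earnorm_error_validation")
  expect_error(as_cq_table(transform(base, cq = 0)), class = "earnorm_error_validation")
  expect_error(as_cq_table(transform(base, rt_rep = 0L)), class = "earnorm_error_validation")
  expect_error(as_cq_table(transform(base, rt_rep = 3L)), class = "earnorm_error_validation")
})

test_that("identifiers are case-sensitive: B2M and b2m stay distinct", {
  df <- data.frame(sample = "s1", gene = c("B2M", "b2m"),
                   rt_rep = 1L, pcr_rep = 1L, cq = c(20, 21))
  tbl <- as_cq_table(df, cq_design(1, 1))
  expect_equal(sort(unique(tbl$gene)), c("B2M", "b2m"))
})

test_that("write/read round-trips every key and Cq exactly, missing included", {
  set.seed(42)
  df <- expand.grid(sample = c("s1", "s2"), gene = c("gA", "gB"),
                    rt_rep = 1:2, pcr_rep = 1:3, stringsAsFactors = FALSE)
  df$cq <- round(runif(nrow(df), 15, 35), 3)
  df$cq[c(3, 17)] <- NA  # failed wells stay missing, never a sentinel
  tbl <- as_cq_table(df)
  f <- tempfile(fileext = ".csv")
  write_cq_table(tbl, f)
  # missing Cq must be an empty CSV field
  expect_true(any(grepl(",$", readLines(f)[-1])))
  back <- suppressMessages(read_cq_table(f))
  key <- function(d) d[order(d$sample, d$gene, d$rt_rep, d$pcr_rep),
                       c("sample", "gene", "rt_rep", "pcr_rep", "cq")]
  expect_equal(key(as.data.frame(back)), key(df), ignore_attr = TRUE)
  expect_equal(nrow(back), nrow(df))  # no silently dropped rows
})

test_that("melt curves read one sorted curve per well on the 55-94 grid", {
  grid <- seq(55, 94, by = 0.5)
  rows <- do.call(rbind, lapply(c("A1", "A2"), function(w) {
    data.frame(well = w, sample = "s1", gene = "EAR",
               temperature_c = grid, fluorescence = rev(seq_along(grid)))
  }))
  rows <- rows[sample(nrow(rows)), ]  # shuffled input must come back sorted
  f <- tempfile(fileext = ".csv")
  write.csv(rows, f, row.names = FALSE, quote = FALSE)
  curves <- read_melt_curves(f)
  expect_equal(nrow(curves), 2L)
  expect_equal(nrow(curves$curve[[1]]), 79L)
  expect_true(all(diff(curves$curve[[1]]$temperature_c) > 0))
})

test_that("degenerate melt input is rejected", {
  one_point <- data.frame(well = "A1", sample = "s", gene = "g",
                          temperature_c = 70, fluorescence = 1)
  expect_error(as_melt_curves(one_point), class = "earnorm_error_validation")
  dup <- data.frame(well = "A1", sample = "s", gene = "g",
                    temperature_c = c(70, 70, 71), fluorescence = 1:3)
  expect_error(as_melt_curves(dup), class = "earnorm_error_validation")
  out_of_range <- data.frame(well = "A1", sample = "s", gene = "g",
                             temperature_c = c(40, 70), fluorescence = 1:2)
  expect_error(as_melt_curves(out_of_range), class = "earnorm_error_validation")
})

test_that("FASTA records are uppercased, U-mapped and validated", {
  f <- write_lines_tmp(c(">x", "acgt"), ".fa")
  expect_equal(read_fasta(f), tibble::tibble(id = "x", sequence = "ACGT"))

  multi <- write_lines_tmp(c(">a desc", "ACGU", ">b", "ggcc", ">c", "TTAA"), ".fa")
  recs <- read_fasta(multi)
  expect_equal(recs$id, c("a", "b", "c"))
  expect_equal(recs$sequence[1], "ACGT")  # RNA U becomes T

  bad <- write_lines_tmp(c(">x", "ACJT"), ".fa")
  expect_error(read_fasta(bad), regexp = "J", class = "earnorm_error_validation")
  empty <- write_lines_tmp(c(">x", "", ">y", "ACGT"), ".fa")
  expect_error(read_fasta(empty), class = "earnorm_error_validation")
})

test_that("primer pairs enforce length and alphabet", {
  expect_s3_class(primer_pair("EAR", "GAGGCTGAGGCAGGAGAATCG", "GTCGCCCAGGCTGGAGTG", 87),
                  "primer_pair")
  expect_error(primer_pair("short", "ACGTACGT", "ACGTACGTAC"),
               class = "earnorm_error_validation")
  expect_error(primer_pair("alpha", "ACGTACGTAX", "ACGTACGTAC"),
               class = "earnorm_error_validation")
  f <- write_lines_tmp(c("name,forward,reverse,expected_product_bp",
                         "EAR,GAGGCTGAGGCAGGAGAATCG,GTCGCCCAGGCTGGAGTG,87"))
  expect_equal(read_primers(f)$expected_product_bp, 87L)
})
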