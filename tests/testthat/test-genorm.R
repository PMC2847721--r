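test_that("pairwise variation is the n-1 sd of the log2 ratio", {
  expect_equal(pairwise_variation(rep(1, 5), rep(1, 5)), 0)
  q <- c(0.2, 0.5, 1, 0.8, 0.3)
  expect_equal(pairwise_variation(q, q), 0)
  expect_equal(pairwise_variation(q, 3.7 * q), 0)  # proportional genes
  expect_equal(pairwise_variation(c(1, 2), c(1, 1)), sd(c(0, 1)))
  expect_equal(round(pairwise_variation(c(1, 2), c(1, 1)), 4), 0.7071)
  expect_error(pairwise_variation(1, 1), class = "earnorm_error_insufficient_data")
  expect_error(pairwise_variation(c(1, 2), c(1, 2, 3)), class = "earnorm_error_validation")
  expect_error(pairwise_variation(c(1, -2), c(1, 2)), class = "earnorm_error_domain")
})

test_that("M is zero for mutually proportional genes and matches the all-pairs oracle", {
  m <- cbind(g1 = c(1, 2, 4), g2 = c(2, 4, 8), g3 = c(0.5, 1, 2))
  rownames(m) <- c("s1", "s2", "s3")
  res <- stability_m(quantities_from_matrix(m))
  expect_equal(res$m, rep(0, 3))

  hand <- cbind(g1 = c(1, 0.5, 0.25), g2 = c(0.9, 0.6, 0.2), g3 = c(1, 0.4, 0.35))
  rownames(hand) <- c("s1", "s2", "s3")
  res2 <- stability_m(quantities_from_matrix(hand))
  oracle <- oracle_stability_m(hand)
  expect_equal(res2$m[match(names(oracle), res2$gene)], unname(oracle), tolerance = 1e-12)
})

test_that("a gene with doubled noise gets the strictly largest M", {
  set.seed(11)
  n <- 12
  quiet1 <- 2^rnorm(n, 0, 0.1)
  quiet2 <- 2^rnorm(n, 0, 0.1)
  noisy <- 2^rnorm(n, 0, 0.8)
  m <- cbind(quiet1 = quiet1, quiet2 = quiet2, noisy = noisy)
  rownames(m) <- sprintf("s%d", 1:n)
  res <- stability_m(quantities_from_matrix(m))
  expect_equal(res$gene[which.max(res$m)], "noisy")
})

test_that("M needs at least 3 genes and 2 samples", {
  m <- rand_qmat(4, 2)
  expect_error(stability_m(quantities_from_matrix(m)),
               class = "earnorm_error_insufficient_data")
  one_sample <- rand_qmat(1, 3)
  expect_error(stability_m(quantities_from_matrix(one_sample)),
               class = "earnorm_error_insufficient_data")
})

test_that("M and ranking are invariant to per-gene scaling and sample order", {
  set.seed(21)
  m <- rand_qmat(8, 5)
  q1 <- quantities_from_matrix(m)
  scaled <- m
  scaled[, 3] <- scaled[, 3] * 17.3
  q2 <- quantities_from_matrix(scaled)
  expect_equal(stability_m(q1), stability_m(q2), tolerance = 1e-12)

  perm <- q1[sample(nrow(q1)), ]
  expect_equal(stability_m(q1), stability_m(perm), tolerance = 1e-12)
  expect_equal(suppressWarnings(stepwise_ranking(q1)$ranking),
               suppressWarnings(stepwise_ranking(perm)$ranking))

  # NF scales by c^(1/n) when one reference is scaled by c
  nf1 <- normalization_factor(q1, c("g1", "g2", "g3"))
  nf2 <- normalization_factor(q2, c("g1", "g2", "g3"))
  expect_equal(nf2$nf / nf1$nf, rep(17.3^(1 / 3), 8), tolerance = 1e-12)
})

test_that("stepwise exclusion removes the max-M gene each round down to a final pair", {
  set.seed(5)
  m <- rand_qmat(8, 5)
  rk <- suppressWarnings(stepwise_ranking(quantities_from_matrix(m)))
  expect_equal(max(rk$rounds$round), 3L)  # 5 -> 4 -> 3 genes evaluated
  for (r in 1:3) {
    round_r <- dplyr::filter(rk$rounds, round == r)
    expect_equal(rk$exclusion_order[r], round_r$gene[which.max(round_r$m)])
  }
  expect_length(rk$final_pair, 2L)
  expect_setequal(c(rk$exclusion_order, rk$final_pair), colnames(m))
  expect_equal(rk$ranking, c(rk$final_pair, rev(rk$exclusion_order)))
})

test_that("proportional genes tie at M = 0, broken lexicographically, all stable", {
  base <- c(1, 2, 4, 3)
  m <- cbind(b = base, a = 2 * base, c = 0.5 * base)
  rownames(m) <- sprintf("s%d", 1:4)
  rk <- stepwise_ranking(quantities_from_matrix(m), n_references = 3)
  expect_equal(rk$exclusion_order, "a")  # lexicographic among an all-zero tie
  expect_equal(rk$final_pair, c("b", "c"))
  expect_length(rk$ties, 1L)
  expect_true(all(rk$selected_stable))
})

test_that("an independent random-walk gene is excluded first in >= 95/100 runs", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    n <- 8
    coreg <- 2^rnorm(n, 0, 0.15)
    m <- cbind(g1 = coreg * 2^rnorm(n, 0, 0.1), g2 = coreg * 2^rnorm(n, 0, 0.1),
               g3 = coreg * 2^rnorm(n, 0, 0.1), walker = 2^cumsum(rnorm(n, 0, 0.6)))
    rownames(m) <- sprintf("s%d", 1:n)
    rk <- suppressWarnings(stepwise_ranking(quantities_from_matrix(m)))
    if (rk$exclusion_order[1] == "walker") hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("a simulated blood panel reproduces the expected stability ordering", {
  sim <- simulate_experiment(sim_config(), seed = 1)
  q <- quantify_cq(sim$cq)
  rk <- stepwise_ranking(q, genes = c("GNB2L1", "HPRT1", "YWHAZ", "B2M", "GAPDH", "ACTB"))
  expect_equal(rk$exclusion_order[1:3], c("ACTB", "GAPDH", "B2M"))
  expect_setequal(rk$selected_references, c("GNB2L1", "HPRT1", "YWHAZ"))
  expect_true(all(rk$selected_stable))
  td <- tidy(rk)
  expect_equal(td$gene[td$rank_tied], rk$final_pair)
  expect_true(all(td$m_last_round[td$selected] < 0.5))
  expect_s3_class(autoplot(rk), "ggplot")
})

test_that("an unstable selected reference triggers a warning", {
  set.seed(3)
  n <- 8
  m <- cbind(g1 = 2^rnorm(n, 0, 1.2), g2 = 2^rnorm(n, 0, 1.1), g3 = 2^rnorm(n, 0, 1.3))
  rownames(m) <- sprintf("s%d", 1:n)
  expect_warning(rk <- stepwise_ranking(quantities_from_matrix(m)),
                 regexp = "stability rule")
  expect_false(all(rk$selected_stable))
})

test_that("the normalization factor is the geometric mean of the references", {
  m <- cbind(a = c(1, 0.5), b = c(1, 0.8), c = c(1, 0.9))
  rownames(m) <- c("s1", "s2")
  nf <- normalization_factor(quantities_from_matrix(m), c("a", "b", "c"))
  expect_equal(nf$nf[1], 1)
  expect_equal(nf$nf[2], (0.5 * 0.8 * 0.9)^(1 / 3), tolerance = 1e-12)
  expect_equal(round(nf$nf[2], 4), 0.7114)

  m2 <- cbind(a = 2, b = 4, c = 8, d = 1)
  rownames(m2) <- "s1"
  expect_equal(normalization_factor(quantities_from_matrix(m2), c("a", "b", "c"))$nf, 4)
  expect_error(normalization_factor(quantities_from_matrix(m2), character(0)),
               class = "earnorm_error_validation")
  expect_error(normalization_factor(quantities_from_matrix(m2), c("a", "zz")),
               class = "earnorm_error_validation")
})
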