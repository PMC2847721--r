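test_that("the negative derivative of simple curves is exact", {
  grid <- seq(60, 70, by = 0.5)
  lin <- tibble::tibble(temperature_c = grid, fluorescence = 100 - 2 * grid)
  d <- negative_derivative(lin)
  expect_equal(d$neg_dfdt, rep(2, length(grid) - 2))
  expect_equal(d$temperature_c, grid[-c(1, length(grid))])

  flat <- tibble::tibble(temperature_c = grid, fluorescence = rep(5, length(grid)))
  expect_equal(negative_derivative(flat)$neg_dfdt, rep(0, length(grid) - 2))

  expect_error(negative_derivative(lin[1:2, ]), class = "earnorm_error_insufficient_data")
})

test_that("a sigmoidal melt at 88.7 peaks within half a degree", {
  curve <- simulate_melt(tibble::tibble(tm = 88.7, width = 1, weight = 1))
  d <- negative_derivative(curve)
  expect_lt(abs(d$temperature_c[which.max(d$neg_dfdt)] - 88.7), 0.5)
  peaks <- call_peaks(d)
  expect_equal(nrow(peaks), 1L)
  expect_lt(abs(peaks$peak_temperature_c - 88.7), 0.5)
})

test_that("peak calling separates mixtures and honours the prominence threshold", {
  two <- simulate_melt(tibble::tibble(tm = c(80, 88.7), width = c(0.8, 0.8),
                                      weight = c(1, 1)))
  p2 <- call_peaks(negative_derivative(two))
  expect_equal(nrow(p2), 2L)
  expect_equal(p2$peak_temperature_c, sort(p2$peak_temperature_c))

  faint <- simulate_melt(tibble::tibble(tm = c(80, 88.7), width = c(0.8, 0.8),
                                        weight = c(0.05, 1)))
  p1 <- call_peaks(negative_derivative(faint), min_prominence_fraction = 0.2)
  expect_equal(nrow(p1), 1L)
  expect_lt(abs(p1$peak_temperature_c - 88.7), 0.5)

  zero <- tibble::tibble(temperature_c = seq(60, 70, 0.5), neg_dfdt = 0)
  expect_equal(nrow(call_peaks(zero)), 0L)
})

test_that("peak temperatures are invariant to uniform fluorescence scaling", {
  curve <- simulate_melt(tibble::tibble(tm = c(75, 88.7), width = c(1, 0.7),
                                        weight = c(0.6, 1)), noise_sd = 0.002, seed = 9)
  scaled <- dplyr::mutate(curve, fluorescence = fluorescence * 250)
  expect_equal(call_peaks(negative_derivative(curve))$peak_temperature_c,
               call_peaks(negative_derivative(scaled))$peak_temperature_c)
})

test_that("smoothing is optional, odd-width, and tames noisy traces", {
  noisy <- simulate_melt(tibble::tibble(tm = 85, width = 1, weight = 1),
                         noise_sd = 0.01, seed = 4)
  expect_error(negative_derivative(noisy, smooth_window = 4),
               class = "earnorm_error_validation")
  raw_peaks <- call_peaks(negative_derivative(noisy), 0.05)
  smooth_peaks <- call_peaks(negative_derivative(noisy, smooth_window = 7), 0.05)
  expect_lt(nrow(smooth_peaks), nrow(raw_peaks))
  expect_equal(nrow(smooth_peaks), 1L)
  expect_lt(abs(smooth_peaks$peak_temperature_c - 85), 1)
})

test_that("replicate concordance applies count and tolerance rules symmetrically", {
  pk <- function(...) tibble::tibble(peak_temperature_c = c(...),
                                     peak_height = rep(1, length(c(...))))
  expect_equal(replicate_concordance(list(pk(80, 88.7), pk(80, 88.7)))$status, "pass")
  expect_equal(replicate_concordance(list(pk(80, 88.7), pk(80, 85, 88.7)))$status, "fail")
  expect_equal(replicate_concordance(list(pk(80, 88.7), pk(80.3, 88.4)))$status, "pass")
  expect_equal(replicate_concordance(list(pk(80, 88.7), pk(80.8, 88.7)))$status, "fail")
  # order of replicates never changes the verdict
  expect_equal(replicate_concordance(list(pk(80.8, 88.7), pk(80, 88.7)))$status, "fail")
  expect_equal(replicate_concordance(list(pk(80, 88.7)))$status, "indeterminate")
  expect_equal(replicate_concordance(list(pk(), pk()))$status, "pass")
})

test_that("per-sample melt profiles may differ while replicates agree within sample", {
  mix_a <- tibble::tibble(tm = c(78, 84, 88.7), width = 0.7, weight = c(0.5, 0.8, 1))
  mix_b <- tibble::tibble(tm = c(81, 88.7), width = 0.7, weight = c(0.9, 1))
  wells <- tibble::tibble(
    well = c("A1", "A2", "B1", "B2"),
    sample = c("sA", "sA", "sB", "sB"),
    gene = "EAR",
    curve = list(
      simulate_melt(mix_a, noise_sd = 0.001, seed = 1),
      simulate_melt(mix_a, noise_sd = 0.001, seed = 2),
      simulate_melt(mix_b, noise_sd = 0.001, seed = 3),
      simulate_melt(mix_b, noise_sd = 0.001, seed = 4)
    )
  )
  peaks <- melt_peaks(wells)
  report <- melt_qc_report(peaks)
  expect_equal(report$status, c("pass", "pass"))
  expect_false(report$n_peaks[1] == report$n_peaks[2])
  # pooling across the two samples must fail the concordance rule
  cross <- replicate_concordance(list(peaks$peaks[[1]], peaks$peaks[[3]]))
  expect_equal(cross$status, "fail")
})
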