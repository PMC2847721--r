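# Default expected melting temperature of the pooled Alu amplicon, in
# degrees C. Editable; heterogeneous Alu products legitimately add peaks.
EAR_EXPECTED_TM <- 88.69

#' Negative derivative of a melt curve
#'
#' The standard dissociation-analysis transform: -dF/dT estimated by central
#' finite differences on the interior points of the temperature grid. Peaks
#' of this series mark product melting temperatures. No smoothing is applied
#' unless requested, keeping the transform transparent.
#'
#' @param curve Tibble with columns `temperature_c` (strictly increasing)
#'   and `fluorescence`; at least 3 points.
#' @param smooth_window Optional odd moving-average window width applied to
#'   the fluorescence before differencing (default `NULL`, no smoothing).
#' @return A tibble `temperature_c`, `neg_dfdt` over the interior grid
#'   points.
#' @export
negative_derivative <- function(curve, smooth_window = NULL) {
  curve <- as_tibble(curve)
  tc <- curve$temperature_c
  fl <- curve$fluorescence
  if (length(tc) < 3L) abort_insufficient("the derivative needs >= 3 temperature points")
  if (any(diff(tc) <= 0)) abort_validation("temperatures must be strictly increasing")
  if (!is.null(smooth_window)) {
    w <- as.integer(smooth_window)
    if (w < 1L || w %% 2L == 0L) abort_validation("`smooth_window` must be a positive odd integer")
    if (w > 1L) {
      kernel <- rep(1 / w, w)
      pad <- (w - 1L) %/% 2L
      padded <- c(rep(fl[1L], pad), fl, rep(fl[length(fl)], pad))
      fl <- stats::filter(padded, kernel, sides = 2)[(pad + 1L):(pad + length(tc))]
      fl <- as.numeric(fl)
    }
  }
  n <- length(tc)
  i <- 2L:(n - 1L)
  tibble(
    temperature_c = tc[i],
    neg_dfdt = -(fl[i + 1L] - fl[i - 1L]) / (tc[i + 1L] - tc[i - 1L])
  )
}

#' Call melting peaks from a derivative series
#'
#' Local maxima of -dF/dT whose topographic prominence is at least
#' `min_prominence_fraction` of the series' global maximum. Multiple peaks
#' are a legal, expected outcome for heterogeneous products such as pooled
#' Alu amplicons; an all-zero series yields zero peaks, not an error.
#' Peak temperatures are invariant to uniform rescaling of the fluorescence.
#'
#' @param deriv Tibble `temperature_c`, `neg_dfdt` as returned by
#'   [negative_derivative()].
#' @param min_prominence_fraction Minimum prominence relative to the global
#'   maximum of the series (default 0.2).
#' @return A tibble `peak_temperature_c`, `peak_height`, sorted by
#'   temperature.
#' @export
call_peaks <- function(deriv, min_prominence_fraction = 0.2) {
  deriv <- as_tibble(deriv)
  y <- deriv$neg_dfdt
  tc <- deriv$temperature_c
  check_number(min_prominence_fraction, "min_prominence_fraction")
  gmax <- max(y)
  empty <- tibble(peak_temperature_c = numeric(0), peak_height = numeric(0))
  if (length(y) < 3L || gmax <= 0 || all(y == y[1L])) return(empty)
  n <- length(y)
  is_max <- vapply(2L:(n - 1L), function(i) y[i] > y[i - 1L] && y[i] >= y[i + 1L], logical(1))
  idx <- (2L:(n - 1L))[is_max]
  if (length(idx) == 0L) return(empty)
  prominence <- vapply(idx, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1L)]
    higher_l <- which(left > h)
    lo_l <- min(y[(if (length(higher_l)) max(higher_l) else 1L):(i - 1L)])
    right <- y[(i + 1L):n]
    higher_r <- which(right > h)
    hi_r <- if (length(higher_r)) i + min(higher_r) else n
    lo_r <- min(y[(i + 1L):hi_r])
    h - max(lo_l, lo_r)
  }, numeric(1))
  keep <- prominence >= min_prominence_fraction * gmax
  tibble(peak_temperature_c = tc[idx[keep]], peak_height = y[idx[keep]]) %>%
    arrange(.data$peak_temperature_c)
}

#' Peak calling over a set of melt curves
#'
#' Applies [negative_derivative()] and [call_peaks()] to each well of a
#' nested melt-curve table (see [read_melt_curves()]).
#'
#' @param curves Nested tibble with columns `well`, `sample`, `gene`,
#'   `curve`.
#' @inheritParams call_peaks
#' @inheritParams negative_derivative
#' @return Nested tibble `well`, `sample`, `gene`, `peaks` (list-column of
#'   peak tibbles).
#' @export
melt_peaks <- function(curves, min_prominence_fraction = 0.2, smooth_window = NULL) {
  curves %>%
    mutate(peaks = purrr::map(.data$curve, function(cv) {
      call_peaks(negative_derivative(cv, smooth_window), min_prominence_fraction)
    })) %>%
    select("well", "sample", "gene", "peaks")
}

#' Replicate melt-curve concordance
#'
#' Heterogeneous products (pooled Alu amplicons in particular) may melt
#' differently in different biological samples, but within one sample every
#' replicate must share the melting profile. This check passes when all
#' replicates report the same number of peaks and greedily matched peaks
#' (nearest temperatures first) differ by at most `tolerance_c`. With a
#' single replicate the status is indeterminate, not pass or fail. The
#' result is invariant to replicate order.
#'
#' @param peaks_by_replicate List of peak tibbles (as from [call_peaks()]),
#'   one per replicate of one sample.
#' @param tolerance_c Maximum allowed temperature difference between matched
#'   peaks, degrees C (default 0.5).
#' @return A list with `status` (`"pass"`, `"fail"` or `"indeterminate"`),
#'   `reason`, and `max_offset_c` (worst matched-peak temperature gap, `NA`
#'   when counts differ).
#' @export
replicate_concordance <- function(peaks_by_replicate, tolerance_c = 0.5) {
  check_number(tolerance_c, "tolerance_c", positive = TRUE)
  if (length(peaks_by_replicate) < 2L) {
    return(list(status = "indeterminate",
                reason = "a single replicate cannot be checked for concordance",
                max_offset_c = NA_real_))
  }
  counts <- vapply(peaks_by_replicate, nrow, integer(1))
  if (length(unique(counts)) != 1L) {
    return(list(status = "fail",
                reason = sprintf("peak counts differ between replicates: %s",
                                 paste(counts, collapse = ", ")),
                max_offset_c = NA_real_))
  }
  if (counts[1L] == 0L) {
    return(list(status = "pass", reason = "no peaks in any replicate", max_offset_c = 0))
  }
  ref <- peaks_by_replicate[[1L]]$peak_temperature_c
  max_offset <- 0
  for (r in peaks_by_replicate[-1L]) {
    offs <- greedy_match_offsets(ref, r$peak_temperature_c)
    max_offset <- max(max_offset, offs)
  }
  if (max_offset <= tolerance_c) {
    list(status = "pass", reason = "all replicate peaks matched within tolerance",
         max_offset_c = max_offset)
  } else {
    list(status = "fail",
         reason = sprintf("matched peaks differ by up to %.2f degC (tolerance %.2f)",
                          max_offset, tolerance_c),
         max_offset_c = max_offset)
  }
}

# Greedy nearest-pair matching of two equal-length peak lists; returns the
# per-pair absolute temperature offsets (max is what concordance needs).
greedy_match_offsets <- function(a, b) {
  stopifnot(length(a) == length(b))
  offs <- numeric(length(a))
  avail_a <- seq_along(a)
  avail_b <- seq_along(b)
  for (p in seq_along(a)) {
    d <- abs(outer(a[avail_a], b[avail_b], "-"))
    best <- which(d == min(d), arr.ind = TRUE)[1L, ]
    offs[p] <- d[best[1L], best[2L]]
    avail_a <- avail_a[-best[1L]]
    avail_b <- avail_b[-best[2L]]
  }
  offs
}

#' Melt QC over a plate
#'
#' Groups called peaks by (sample, gene), runs [replicate_concordance()]
#' within each group, and returns one row per group.
#'
#' @param peak_table Output of [melt_peaks()].
#' @inheritParams replicate_concordance
#' @return A tibble `sample`, `gene`, `n_replicates`, `n_peaks`, `status`,
#'   `reason`, `max_offset_c`.
#' @export
melt_qc_report <- function(peak_table, tolerance_c = 0.5) {
  peak_table %>%
    group_by(.data$sample, .data$gene) %>%
    summarise(
      n_replicates = n(),
      n_peaks = nrow(.data$peaks[[1L]]),
      result = list(replicate_concordance(.data$peaks, tolerance_c)),
      .groups = "drop"
    ) %>%
    mutate(
      status = purrr::map_chr(.data$result, "status"),
      reason = purrr::map_chr(.data$result, "reason"),
      max_offset_c = purrr::map_dbl(.data$result, "max_offset_c")
    ) %>%
    select(-"result")
}

#' Plot melt curves with their negative derivative
#'
#' @param curves Nested melt-curve tibble (see [read_melt_curves()]).
#' @param smooth_window Passed to [negative_derivative()].
#' @return A ggplot of -dF/dT vs temperature, one line per well.
#' @export
plot_melt_curves <- function(curves, smooth_window = NULL) {
  d <- curves %>%
    mutate(deriv = purrr::map(.data$curve, negative_derivative, smooth_window = smooth_window)) %>%
    select("well", "sample", "gene", "deriv") %>%
    tidyr::unnest("deriv")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$temperature_c, y = .data$neg_dfdt,
                                  colour = .data$sample, group = .data$well)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "temperature (°C)", y = "-dF/dT",
                  title = "Melt-curve dissociation profiles")
}
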