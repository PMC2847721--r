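#' Fit a qPCR standard curve
#'
#' Ordinary least-squares fit of Cq against log10 of the relative input
#' amount of a serial dilution. The slope of this line encodes the per-cycle
#' amplification factor `A = 10^(-1/slope)` and the percent efficiency
#' `E = (A - 1) * 100`; a slope of -3.32 corresponds to perfect doubling
#' (100% efficiency). Replicate Cq values at the same dilution enter the fit
#' as separate points, preserving the error structure.
#'
#' @param points Data frame with columns `amount` (relative input amount,
#'   > 0) and `cq` (cycles). At least three points at three distinct amounts.
#' @return An object of class `standard_curve`: a list with `slope`,
#'   `intercept`, `r_squared`, `efficiency_percent`, `amplification_factor`,
#'   `n_points`, and the underlying `lm` fit.
#' @examples
#' pts <- data.frame(amount = c(1, 0.1, 0.01), cq = c(20, 23.3219, 26.6439))
#' fit_standard_curve(pts)
#' @seealso [efficiency_from_slope()], [tidy.standard_curve()]
#' @export
fit_standard_curve <- function(points) {
  points <- as_tibble(points)
  if (!all(c("amount", "cq") %in% names(points))) {
    abort_format("`points` needs columns `amount` and `cq`")
  }
  if (any(is.na(points$amount)) || any(points$amount <= 0)) {
    abort_domain("dilution amounts must be positive")
  }
  if (any(is.na(points$cq))) abort_validation("Cq values must be non-missing")
  if (nrow(points) < 3L || dplyr::n_distinct(points$amount) < 3L) {
    abort_insufficient("a standard curve needs >= 3 points at >= 3 distinct amounts")
  }
  d <- tibble(log_amount = log10(points$amount), cq = points$cq)
  fit <- lm(cq ~ log_amount, data = d)
  slope <- unname(coef(fit)[["log_amount"]])
  intercept <- unname(coef(fit)[["(Intercept)"]])
  r2 <- cor(d$cq, stats::fitted(fit))^2
  if (slope >= 0) {
    warn("standard-curve slope is non-negative; Cq should fall as input rises")
    eff <- NA_real_
    amp <- NA_real_
  } else {
    amp <- 10^(-1 / slope)
    eff <- (amp - 1) * 100
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         efficiency_percent = eff, amplification_factor = amp,
         n_points = nrow(points), fit = fit),
    class = "standard_curve"
  )
}

#' Percent amplification efficiency from a standard-curve slope
#'
#' `E = (10^(-1/slope) - 1) * 100`. A slope of `-1/log10(2) = -3.3219` gives
#' exactly 100% (template doubles each cycle); slopes shallower than that
#' give apparent efficiencies above 100%.
#'
#' @param slope Standard-curve slope in cycles per log10 dilution; must be
#'   negative.
#' @return Percent efficiency (not rounded).
#' @examples
#' efficiency_from_slope(-3.3219) # 100
#' round(efficiency_from_slope(-3.27)) # 102
#' @export
efficiency_from_slope <- function(slope) {
  check_number(slope, "slope")
  if (slope >= 0) abort_domain("slope must be negative for a valid standard curve")
  (10^(-1 / slope) - 1) * 100
}

#' Per-cycle amplification factor from a standard-curve slope
#'
#' @param slope Negative standard-curve slope.
#' @return The per-cycle fold change `10^(-1/slope)` (2 at 100% efficiency).
#' @export
amplification_factor_from_slope <- function(slope) {
  check_number(slope, "slope")
  if (slope >= 0) abort_domain("slope must be negative for a valid standard curve")
  10^(-1 / slope)
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve>\n")
  cat(sprintf("  slope      %8.4f cycles / log10(amount)\n", x$slope))
  cat(sprintf("  intercept  %8.4f cycles\n", x$intercept))
  cat(sprintf("  r^2        %8.5f\n", x$r_squared))
  cat(sprintf("  efficiency %7.1f%%  (amplification factor %.4f)\n",
              x$efficiency_percent, x$amplification_factor))
  cat(sprintf("  n points   %d\n", x$n_points))
  invisible(x)
}

#' Tidy a standard curve
#'
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @return One row per coefficient with estimate and standard error.
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "slope"),
         estimate = unname(s[, "Estimate"]),
         std_error = unname(s[, "Std. Error"]))
}

#' One-row summary of a standard curve
#'
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         efficiency_percent = x$efficiency_percent,
         amplification_factor = x$amplification_factor, n_points = x$n_points)
}

#' Plot a standard curve
#'
#' Dilution points with the fitted Cq-vs-log10(amount) line.
#'
#' @param object A `standard_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  d <- object$fit$model
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log_amount, y = .data$cq)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10(relative input amount)", y = "Cq (cycles)",
      title = sprintf("slope %.2f, efficiency %.0f%%, r² = %.3f",
                      object$slope, object$efficiency_percent, object$r_squared)
    )
}
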