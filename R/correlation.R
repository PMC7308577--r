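# Power-law relation between MPN density and COS degradation rate constant.

#' Fit a power law by log-log least squares
#'
#' Fits `y = a * x^b` by ordinary least squares of `log10(y)` on `log10(x)`,
#' the faithful reading of a reported power function together with a Pearson
#' correlation "among logarithms". Returns the prefactor `a = 10^intercept`,
#' exponent `b = slope`, the Pearson correlation of the logs with its
#' two-sided p-value (t statistic, `n - 2` degrees of freedom), and
#' `r_squared_log = pearson_r_log^2`. Non-positive pairs (e.g. below-range
#' MPN estimates) cannot enter a log fit and are excluded with a warning.
#'
#' @param x Predictor values (e.g. MPN densities), positive.
#' @param y Response values (e.g. rate constants), positive.
#' @return An object of class `power_law_fit` with elements `a`, `b`,
#'   `r_squared_log`, `pearson_r_log`, `p_value`, `n`.
#' @examples
#' x <- 10^seq(2, 9, length.out = 20)
#' fit_power_law(x, 0.0043 * x^0.2941)
#' @export
fit_power_law <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (any(!keep))
    warning(sum(!keep), " pair(s) with non-positive or missing values excluded",
            call. = FALSE)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3)
    stop("insufficient data: need >= 3 positive pairs", call. = FALSE)
  lx <- log10(x)
  ly <- log10(y)
  if (stats::var(lx) == 0)
    stop("predictor has no variation on the log scale", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  b <- unname(fit$coefficients[2])
  a <- 10^unname(fit$coefficients[1])
  r <- stats::cor(lx, ly)
  # two-sided p from the t statistic of the correlation, n - 2 df
  p <- if (abs(r) >= 1) {
    0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  structure(list(a = a, b = b, r_squared_log = r^2, pearson_r_log = r,
                 p_value = p, n = n),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: y = %.4g * x^%.4g  (n = %d)\n", x$a, x$b, x$n))
  cat(sprintf("  log-log Pearson r = %.4f, r^2 = %.4f, p = %.3g\n",
              x$pearson_r_log, x$r_squared_log, x$p_value))
  invisible(x)
}

#' Evaluate a fitted power law
#' @param object A `power_law_fit`.
#' @param newdata Positive predictor values.
#' @param ... Unused.
#' @return Predicted responses `a * newdata^b`.
#' @export
predict.power_law_fit <- function(object, newdata, ...) {
  object$a * newdata^object$b
}

#' Pair MPN estimates with sample rate constants
#'
#' Joins a COS-degrader estimates table with per-sample degradation rate
#' constants, keeping samples with an in-range (status `ok`) estimate — the
#' input to [fit_power_law()].
#'
#' @param estimates Data frame from [estimate_samples()] or [read_results()].
#' @param rate_constants Named numeric vector of normalized rate constants
#'   (names are sample ids), e.g. `attr(read_sample_table(p), "rate_constants")`.
#' @param target Which estimates to use, default `"cos_degrader"`.
#' @return A data frame with columns `sample_id`, `mpn`, `rate_constant`.
#' @export
mpn_rate_pairs <- function(estimates, rate_constants,
                           target = "cos_degrader") {
  e <- estimates[estimates$target == target & estimates$status == "ok", ]
  k <- rate_constants[e$sample_id]
  keep <- !is.na(k)
  data.frame(sample_id = e$sample_id[keep], mpn = e$mpn_per_g_dry[keep],
             rate_constant = unname(k[keep]), stringsAsFactors = FALSE)
}
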