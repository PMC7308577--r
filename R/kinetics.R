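# First-order COS decay kinetics, the pH-dependent chemical hydrolysis
# baseline, biomass-carbon calibration and the SRCB statistic.

#' Fit a first-order COS decay rate constant
#'
#' Fits `C(t) = C0 * exp(-k t)` to a headspace time course by ordinary least
#' squares of `ln C` on `t` (log-linear fit; closed form, exact on noiseless
#' exponential data). Points flagged below the detection limit are censored
#' and excluded from the fit.
#'
#' @param tc A [cos_timecourse()], or a data frame with columns `time_h`,
#'   `cos_ppmv` and optionally `below_detection`.
#' @return An object of class `rate_fit` with elements `k_per_h` (h^-1, per
#'   test tube), `c0_fit_ppmv`, `r_squared` and `n_points`.
#' @examples
#' tc <- cos_timecourse(c(0, 1, 2, 4), 30 * exp(-0.5 * c(0, 1, 2, 4)))
#' fit_rate_constant(tc)
#' @export
fit_rate_constant <- function(tc) {
  if (is.data.frame(tc)) {
    tc <- cos_timecourse(tc$time_h, tc$cos_ppmv,
                         if (is.null(tc$below_detection))
                           rep(FALSE, nrow(tc)) else as.logical(tc$below_detection))
  }
  stopifnot(inherits(tc, "cos_timecourse"))
  use <- !tc$below_detection & !is.na(tc$concentrations_ppmv)
  t <- tc$times_h[use]
  conc <- tc$concentrations_ppmv[use]
  if (length(t) < 2)
    stop("insufficient data: need >= 2 non-censored points", call. = FALSE)
  if (any(conc <= 0))
    stop("non-positive concentration among usable points", call. = FALSE)
  y <- log(conc)
  fit <- stats::lm.fit(cbind(1, t), y)
  slope <- fit$coefficients[2]
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss < .Machine$double.eps * max(1, sum(y^2))) {
    1
  } else {
    max(0, min(1, 1 - rss / tss))
  }
  structure(list(k_per_h = unname(-slope),
                 c0_fit_ppmv = unname(exp(fit$coefficients[1])),
                 r_squared = r2, n_points = length(t)),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("First-order COS decay fit: k = %.4g /h, C0 = %.4g ppmv, r^2 = %.4f (n = %d)\n",
              x$k_per_h, x$c0_fit_ppmv, x$r_squared, x$n_points))
  invisible(x)
}

#' Normalize a rate constant per gram dry sample or per mL
#'
#' Converts a per-tube rate constant to the per-mass basis used to compare
#' samples: `k / (mass_wet * (1 - water_content))` h^-1 (g dry)^-1 for
#' soil-like samples, `k / volume_ml` h^-1 mL^-1 for water samples.
#'
#' @param fit A `rate_fit` or a bare numeric rate constant (h^-1 per tube).
#' @param sample A [sample_metadata()] carrying the assay mass (or volume)
#'   and water content.
#' @return Normalized rate constant (numeric).
#' @examples
#' s <- sample_metadata("KS-13", "forest_soil", water_content = 0.297,
#'                      mass_used_g_wet = 4)
#' normalize_rate_constant(3.093, s)  # ~1.10 /h /(g dry)
#' @export
normalize_rate_constant <- function(fit, sample) {
  k <- if (inherits(fit, "rate_fit")) fit$k_per_h else fit
  stopifnot(inherits(sample, "sample_metadata"), is.finite(k))
  if (sample$sample_type == "pond_water") {
    if (is.null(sample$volume_ml))
      stop("volume_ml required for water samples", call. = FALSE)
    k / sample$volume_ml
  } else {
    if (is.null(sample$mass_used_g_wet) || sample$mass_used_g_wet <= 0)
      stop("positive mass_used_g_wet required", call. = FALSE)
    wc <- sample$water_content
    if (is.na(wc) || wc < 0 || wc >= 1)
      stop("water_content in [0, 1) required for per-dry normalization",
           call. = FALSE)
    k / (sample$mass_used_g_wet * (1 - wc))
  }
}

#' Degradation ratio over an assay
#'
#' Percent of the initial COS removed: `100 * (1 - c_end / c0)`. Values may
#' slightly exceed the 0-100 range under measurement noise and are returned
#' unclipped.
#'
#' @param c0_ppmv Initial concentration (> 0).
#' @param c_end_ppmv Final concentration (>= 0). Vectorized.
#' @return Degradation ratio in percent.
#' @examples
#' degradation_ratio(30, 18)    # 40, the positivity threshold
#' degradation_ratio(30, 22.2)  # 26, chemical-only at pH 7.0
#' @export
degradation_ratio <- function(c0_ppmv, c_end_ppmv) {
  if (any(c0_ppmv <= 0)) stop("initial concentration must be > 0", call. = FALSE)
  if (any(c_end_ppmv < 0)) stop("final concentration must be >= 0", call. = FALSE)
  100 * (1 - c_end_ppmv / c0_ppmv)
}

#' Calibrate the chemical hydrolysis baseline
#'
#' COS hydrolyzes abiotically, faster at alkaline pH (base catalysis). The
#' baseline is modelled as a first-order loss with rate
#' `k(pH) = k0 + k_oh * [OH-]`, `[OH-] = 10^(pH - 14)` M: a pH-independent
#' term plus a hydroxide-catalyzed term. Two anchor observations of the
#' chemical-only degraded fraction over a fixed duration determine both
#' parameters exactly (a 2x2 linear system in `k0`, `k_oh` after converting
#' fractions to rates).
#'
#' @param anchors Data frame with columns `pH` and `fraction` (degraded
#'   fraction over `duration_h`, in (0, 1)); exactly two rows with distinct
#'   pH.
#' @param duration_h Duration over which the anchor fractions were observed.
#' @return An object of class `hydrolysis_model` with `k0_per_h` and
#'   `k_oh_per_M_h`.
#' @examples
#' m <- calibrate_hydrolysis(data.frame(pH = c(7, 7.5), fraction = c(0.26, 0.32)))
#' chemical_fraction(m, 7.25, 24)
#' @export
calibrate_hydrolysis <- function(anchors, duration_h = 24) {
  if (is.list(anchors) && !is.data.frame(anchors))
    anchors <- do.call(rbind, lapply(anchors, function(a)
      data.frame(pH = a[[1]], fraction = a[[2]])))
  stopifnot(is.data.frame(anchors), all(c("pH", "fraction") %in% names(anchors)))
  if (nrow(anchors) != 2) stop("exactly two anchors required", call. = FALSE)
  if (anchors$pH[1] == anchors$pH[2])
    stop("anchor pH values must be distinct", call. = FALSE)
  f <- anchors$fraction
  if (any(f <= 0 | f >= 1))
    stop("anchor fractions must be in (0, 1)", call. = FALSE)
  k <- -log(1 - f) / duration_h
  oh <- 10^(anchors$pH - 14)
  k_oh <- (k[2] - k[1]) / (oh[2] - oh[1])
  k0 <- k[1] - k_oh * oh[1]
  if (k_oh < 0 || k0 < 0)
    stop("anchors imply a negative rate term; calibration failed", call. = FALSE)
  structure(list(k0_per_h = k0, k_oh_per_M_h = k_oh), class = "hydrolysis_model")
}

#' @export
print.hydrolysis_model <- function(x, ...) {
  cat(sprintf("Chemical hydrolysis model: k(pH) = %.4g + %.4g * 10^(pH-14)  [/h]\n",
              x$k0_per_h, x$k_oh_per_M_h))
  invisible(x)
}

#' First-order chemical hydrolysis rate at a given pH
#' @param model A `hydrolysis_model`.
#' @param pH pH value(s).
#' @return Rate constant(s) in h^-1.
#' @export
hydrolysis_rate <- function(model, pH) {
  stopifnot(inherits(model, "hydrolysis_model"))
  model$k0_per_h + model$k_oh_per_M_h * 10^(pH - 14)
}

#' Chemical-only degraded fraction
#'
#' Fraction of COS lost to abiotic hydrolysis: `1 - exp(-d * k(pH))`.
#' Monotone nondecreasing in both pH and duration.
#'
#' @param model A `hydrolysis_model` from [calibrate_hydrolysis()].
#' @param pH pH value(s).
#' @param duration_h Duration (h), >= 0.
#' @return Degraded fraction(s) in `[0, 1)`.
#' @export
chemical_fraction <- function(model, pH, duration_h) {
  if (any(duration_h < 0)) stop("duration must be >= 0", call. = FALSE)
  1 - exp(-duration_h * hydrolysis_rate(model, pH))
}

#' Fit a biomass-carbon standard curve
#'
#' Ordinary least squares of instrument signal on milligrams of glucose
#' carbon; the default standards are 0.05, 0.5, 1 and 3 mg C.
#'
#' @param signals Instrument readings for the standards.
#' @param standards_mg Carbon content of the standards (mg).
#' @return An object of class `biomass_calibration` with `slope`, `intercept`
#'   and `standards_mg`.
#' @examples
#' cal <- biomass_calibration(2 * c(0.05, 0.5, 1, 3))
#' biomass_carbon(4.4, cal)  # 2.2 mg C
#' @export
biomass_calibration <- function(signals, standards_mg = c(0.05, 0.5, 1, 3)) {
  stopifnot(length(signals) == length(standards_mg), length(signals) >= 2)
  fit <- stats::lm.fit(cbind(1, standards_mg), signals)
  slope <- unname(fit$coefficients[2])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration error: non-positive slope", call. = FALSE)
  structure(list(slope = slope, intercept = unname(fit$coefficients[1]),
                 standards_mg = standards_mg),
            class = "biomass_calibration")
}

#' Convert an instrument signal to biomass carbon
#'
#' Inverts the standard curve: `(signal - intercept) / slope`. Negative
#' results are clamped to 0 and flagged `low_biomass` (attribute `flag`).
#'
#' @param signal Instrument reading(s).
#' @param cal A [biomass_calibration()].
#' @return Biomass carbon in mg, with a character attribute `flag`
#'   (`"ok"` or `"low_biomass"` per element).
#' @export
biomass_carbon <- function(signal, cal) {
  stopifnot(inherits(cal, "biomass_calibration"))
  mg <- (signal - cal$intercept) / cal$slope
  flag <- ifelse(mg < 0, "low_biomass", "ok")
  mg <- pmax(mg, 0)
  attr(mg, "flag") <- flag
  mg
}

#' Specific rate constant of COS degradation normalized by biomass (SRCB)
#'
#' `srcb = (k_suspension - k_blank) / biomass_mg_c`, in h^-1 mg^-1 carbon:
#' the cell suspension's first-order rate constant, minus the uninoculated
#' blank's, divided by the suspension's biomass carbon. A negative difference
#' is reported as-is and flagged `negative`; biomass below the 0.2 mg lower
#' end of the linear validity range (0.2-5 mg C) is flagged `low_biomass`.
#'
#' @param k_suspension_per_h Rate constant of the cell suspension (h^-1).
#' @param k_blank_per_h Rate constant of the uninoculated blank (h^-1).
#' @param biomass_mg_c Biomass carbon of the suspension (mg, > 0).
#' @return An object of class `srcb_value` with `srcb`, the inputs and a
#'   `flag` in `{"ok", "negative", "low_biomass"}`.
#' @examples
#' compute_srcb(1.40, 0.10, 0.5)  # srcb = 2.6 /h /mg C
#' @export
compute_srcb <- function(k_suspension_per_h, k_blank_per_h, biomass_mg_c) {
  if (biomass_mg_c <= 0) stop("biomass must be > 0", call. = FALSE)
  srcb <- (k_suspension_per_h - k_blank_per_h) / biomass_mg_c
  flag <- if (k_suspension_per_h < k_blank_per_h) {
    "negative"
  } else if (biomass_mg_c < 0.2) {
    "low_biomass"
  } else "ok"
  structure(list(srcb = srcb, k_suspension_per_h = k_suspension_per_h,
                 k_blank_per_h = k_blank_per_h, biomass_mg_c = biomass_mg_c,
                 flag = flag),
            class = "srcb_value")
}

#' @export
print.srcb_value <- function(x, ...) {
  cat(sprintf("SRCB = %.3g /h /mg C (k_susp %.3g, k_blank %.3g, biomass %.3g mg; %s)\n",
              x$srcb, x$k_suspension_per_h, x$k_blank_per_h, x$biomass_mg_c,
              x$flag))
  invisible(x)
}
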