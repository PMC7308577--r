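# Two-step MPN core: positivity calling, tube patterns, three-level window
# selection, maximum-likelihood estimation under the Poisson single-hit
# model, Cochran-style confidence intervals, and conversion to density.

#' Call tube positivity from repeated measurements
#'
#' Scores each tube of a two-step MPN experiment. A tube is COS-positive when
#' its degradation ratio reaches the threshold (inclusive `>=`) on ANY
#' available measurement day: positivity can be transient, so scoring the
#' maximum over days avoids undercounting. Growth positivity is the OR of the
#' turbidity flags. Missing measurements (the published em-dash) are skipped;
#' a tube with no usable measurement at all is excluded with a warning.
#'
#' @param obs A tube observation table ([read_tube_table()] or
#'   [simulate_experiment()] output): one row per tube and day.
#' @param cfg A [run_config()]; its `positivity_threshold_pct` is the COS
#'   calling threshold.
#' @return A data frame (class `tube_calls`) with one row per tube:
#'   `sample_id`, `level_exponent`, `replicate`, `growth_positive`,
#'   `cos_positive`, `first_positive_day`.
#' @examples
#' tab <- read_tube_table(cosmpn_example("tubes_ks13.csv"))
#' calls <- call_tubes(tab, run_config())
#' subset(calls, level_exponent >= 7)
#' @export
call_tubes <- function(obs, cfg = run_config()) {
  stopifnot(is.data.frame(obs), inherits(cfg, "run_config"))
  thr <- cfg$positivity_threshold_pct
  ratio <- obs$degradation_ratio_pct
  derive <- is.na(ratio) & !is.na(obs$residual_ppmv) & !is.na(obs$initial_ppmv)
  if (any(derive))
    ratio[derive] <- degradation_ratio(obs$initial_ppmv[derive],
                                       obs$residual_ppmv[derive])
  key <- interaction(obs$sample_id, obs$level_exponent, obs$replicate,
                     drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(obs)), key)
  rows <- lapply(idx, function(i) {
    r <- ratio[i]
    tb <- obs$turbid[i]
    if (all(is.na(r)) && all(is.na(tb))) return(NULL)
    hit <- !is.na(r) & r >= thr
    data.frame(sample_id = obs$sample_id[i[1]],
               level_exponent = obs$level_exponent[i[1]],
               replicate = obs$replicate[i[1]],
               growth_positive = if (all(is.na(tb))) NA else
                 any(tb == 1, na.rm = TRUE),
               cos_positive = if (all(is.na(r))) NA else any(hit),
               first_positive_day = if (any(hit))
                 min(obs$day[i][hit]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " tube(s) with no usable measurement excluded",
            call. = FALSE)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- out[order(out$sample_id, out$level_exponent, out$replicate), ]
  rownames(out) <- NULL
  class(out) <- c("tube_calls", class(out))
  out
}

#' Build a tube pattern from calls
#'
#' Counts positive tubes per dilution level for one sample, for either the
#' COS-degradation calls or the growth (turbidity) calls, and attaches the
#' relative inoculum volumes `v_i = base^-(e_i - e_min)`.
#'
#' @param calls A `tube_calls` data frame for a single sample.
#' @param design The [dilution_design()]; every level and replicate of the
#'   design must be present in `calls`.
#' @param which `"cos"` or `"growth"`.
#' @return An object of class `tube_pattern` with `levels`, `positives`,
#'   `tubes` and `relative_volumes`.
#' @export
build_pattern <- function(calls, design, which = c("cos", "growth")) {
  which <- match.arg(which)
  stopifnot(inherits(design, "dilution_design"))
  if (length(unique(calls$sample_id)) > 1)
    stop("calls span multiple samples; build one pattern per sample",
         call. = FALSE)
  col <- if (which == "cos") "cos_positive" else "growth_positive"
  lv <- design$level_exponents
  n <- design$tubes_per_level
  pos <- integer(length(lv))
  for (j in seq_along(lv)) {
    sub <- calls[calls$level_exponent == lv[j], ]
    if (nrow(sub) != n || !setequal(sub$replicate, seq_len(n)))
      stop("missing replicate(s) at level ", lv[j], call. = FALSE)
    if (any(is.na(sub[[col]])))
      stop("missing ", which, " call at level ", lv[j], call. = FALSE)
    pos[j] <- sum(sub[[col]])
  }
  structure(list(levels = lv, positives = pos,
                 tubes = rep(n, length(lv)),
                 relative_volumes = design$dilution_base^(-(lv - lv[1])),
                 dilution_base = design$dilution_base),
            class = "tube_pattern")
}

#' @export
print.tube_pattern <- function(x, ...) {
  cat("Tube pattern (positives/tubes by level exponent):\n")
  cat(paste(sprintf("%d: %d/%d", x$levels, x$positives, x$tubes),
            collapse = "  "), "\n")
  invisible(x)
}

#' Select the three-level scoring window
#'
#' Classical three-tube bookkeeping: take the highest dilution level at which
#' every tube is positive, plus the next two higher-exponent (more dilute)
#' levels; stray positives beyond the window are folded into the window's
#' last level (capped at the number of tubes). If no fully-positive level
#' exists the three lowest levels are used; if the selected window is still
#' fully positive there is no finite estimate and the pattern is flagged
#' `above_range`; an all-negative window is flagged `below_range`.
#'
#' @param pattern A [build_pattern()] result with at least three levels.
#' @return A list (class `mpn_window`) with `levels` (three exponents),
#'   `positives`, `tubes`, `relative_volumes` (1, 1/base, 1/base^2) and
#'   `status` in `{"ok", "below_range", "above_range"}`.
#' @examples
#' d <- dilution_design()
#' tab <- read_tube_table(cosmpn_example("tubes_ks13.csv"), d)
#' pat <- build_pattern(call_tubes(tab), d, "cos")
#' select_levels(pat)  # levels 7-9, counts 3, 1, 1
#' @export
select_levels <- function(pattern) {
  stopifnot(inherits(pattern, "tube_pattern"))
  L <- length(pattern$levels)
  if (L < 3) stop("selection error: need >= 3 dilution levels", call. = FALSE)
  p <- pattern$positives
  n <- pattern$tubes
  full <- which(p == n)
  start <- if (length(full) == 0) 1L else max(full)
  if (start + 2L > L) start <- L - 2L
  win <- start:(start + 2L)
  p_win <- p[win]
  if (start + 2L < L) {
    stray <- sum(p[(start + 3L):L])
    p_win[3] <- min(p_win[3] + stray, n[win[3]])
  }
  status <- if (all(p_win == n[win])) {
    "above_range"
  } else if (sum(p_win) == 0) {
    "below_range"
  } else "ok"
  structure(list(levels = pattern$levels[win], positives = p_win,
                 tubes = n[win],
                 relative_volumes = pattern$dilution_base^(-(0:2)),
                 dilution_base = pattern$dilution_base,
                 status = status),
            class = "mpn_window")
}

mpn_score <- function(lambda, p, n, v) {
  ev <- exp(-lambda * v)
  sum(p * v * ev / (1 - ev)) - sum((n - p) * v)
}

#' Maximum-likelihood MPN estimate for one tube pattern
#'
#' Solves the MPN score equation under the Poisson single-hit model,
#' \deqn{\sum_i p_i v_i e^{-\lambda v_i} / (1 - e^{-\lambda v_i})
#'       = \sum_i (n_i - p_i) v_i,}
#' where `p_i` of `n_i` tubes at relative inoculum volume `v_i` are positive,
#' by bracketed root finding on `log(lambda)` over `[1e-6, 1e6]` to a
#' relative tolerance below 1e-9. The estimate is expressed per
#' largest-inoculum tube (`v = 1`).
#'
#' @param pattern An `mpn_window` (from [select_levels()]) or `tube_pattern`,
#'   or a numeric vector of positive counts.
#' @param n Tubes per level (used when `pattern` is numeric).
#' @param v Relative inoculum volumes (used when `pattern` is numeric).
#' @return The MLE `lambda` (organisms per `v = 1` tube). An all-negative
#'   pattern returns 0; an all-positive pattern has no finite MLE and errors.
#' @examples
#' mpn_ml(c(3, 1, 1))  # ~7.49, the classical "75" entry at v = 0.1
#' @export
mpn_ml <- function(pattern, n = rep(3, length(pattern)),
                   v = 10^-(seq_along(pattern) - 1)) {
  if (inherits(pattern, c("tube_pattern", "mpn_window"))) {
    p <- pattern$positives
    n <- pattern$tubes
    v <- pattern$relative_volumes
  } else {
    p <- pattern
  }
  stopifnot(length(p) == length(n), length(p) == length(v),
            all(p >= 0), all(p <= n), all(v > 0))
  if (all(p == 0)) return(0)
  if (all(p == n))
    stop("above_range: all tubes positive, no finite MPN estimate",
         call. = FALSE)
  f <- function(u) mpn_score(exp(u), p, n, v)
  root <- stats::uniroot(f, lower = log(1e-6), upper = log(1e6),
                         tol = 1e-12)
  exp(root$root)
}

#' Cochran-style confidence interval for an MPN estimate
#'
#' The standard error of `log10(MPN)` for a serial-dilution design is
#' approximated as `0.58 * sqrt(log10(base) / tubes_per_level)`; the 95%
#' interval is the estimate times `10^(+/- 1.96 SE)`. For the three-tube
#' tenfold design the multiplicative factor is about 4.5.
#'
#' @param lambda MPN point estimate (> 0), any unit.
#' @param design A [dilution_design()] (only `dilution_base` and
#'   `tubes_per_level` are used).
#' @param conf_z Normal quantile for the interval (1.96 for 95%).
#' @return Numeric vector `c(ci_low, ci_high)` in the units of `lambda`.
#' @export
mpn_confidence_interval <- function(lambda, design, conf_z = 1.96) {
  stopifnot(inherits(design, "dilution_design"))
  if (!is.finite(lambda) || lambda <= 0) return(c(NA_real_, NA_real_))
  se <- 0.58 * sqrt(log10(design$dilution_base) / design$tubes_per_level)
  fac <- 10^(conf_z * se)
  c(lambda / fac, lambda * fac)
}

#' Convert a window-level MPN to density per gram dry (or per mL)
#'
#' The MLE `lambda` counts organisms per largest-inoculum tube of the
#' selected window. For soil-like samples that tube received
#' `inoculum_ml * (soil_mass / (soil_mass + diluent)) * base^-e_min` grams of
#' wet sample (with the standard 3 g in 30 mL and a 1 mL inoculum,
#' `10^-(e_min + 1)` g wet), so the density is `lambda` divided by that mass
#' and by `(1 - water_content)` for the dry-weight basis. Water samples are
#' diluted directly and reported per mL: `lambda * base^e_min / inoculum_ml`.
#'
#' @param lambda MPN per reference (`v = 1`) tube of the window.
#' @param selected_levels The window's level exponents (its minimum is used).
#' @param design The [dilution_design()].
#' @param sample A [sample_metadata()] (water content for soils).
#' @return Density in MPN (g dry)^-1, or MPN mL^-1 for water samples.
#' @export
to_density <- function(lambda, selected_levels, design, sample) {
  stopifnot(inherits(design, "dilution_design"),
            inherits(sample, "sample_metadata"), is.finite(lambda))
  e_min <- min(selected_levels)
  if (sample$sample_type == "pond_water") {
    return(lambda * design$dilution_base^e_min / design$inoculum_ml)
  }
  wc <- sample$water_content
  if (is.na(wc) || wc < 0 || wc >= 1)
    stop("water_content in [0, 1) required for per-dry conversion",
         call. = FALSE)
  total_ml <- design$soil_mass_g_wet + design$diluent_ml
  g_wet_per_tube <- design$inoculum_ml * design$soil_mass_g_wet / total_ml *
    design$dilution_base^(-e_min)
  lambda / (g_wet_per_tube * (1 - wc))
}

#' Full two-step MPN estimation for one sample
#'
#' Composes the pipeline — [call_tubes()], [build_pattern()],
#' [select_levels()], [mpn_ml()], [mpn_confidence_interval()],
#' [to_density()] — for both targets: chemoorganotrophs (growth/turbidity
#' pattern) and COS degraders (threshold pattern).
#'
#' @param obs Tube observation table for one sample.
#' @param design The [dilution_design()].
#' @param sample The [sample_metadata()].
#' @param cfg A [run_config()].
#' @return A named list with elements `cos` and `growth`, each an
#'   `mpn_estimate`: `sample_id`, `target`, `lambda_per_ref_tube`,
#'   `selected_levels`, `pattern`, `mpn_per_g_dry` (per mL for water),
#'   `ci_low`, `ci_high`, `status`, `basis`.
#' @examples
#' d <- dilution_design()
#' tab <- read_tube_table(cosmpn_example("tubes_ks13.csv"), d)
#' ks13 <- sample_metadata("KS-13", "forest_soil", water_content = 0.297,
#'                         pH = 5.28, toc = 4.8, mass_used_g_wet = 4)
#' est <- estimate_sample(tab, d, ks13, run_config())
#' est$cos$mpn_per_g_dry  # ~1.1e9, vs the published table-based 9.6e8
#' @export
estimate_sample <- function(obs, design, sample, cfg = run_config()) {
  calls <- call_tubes(obs, cfg)
  calls <- calls[calls$sample_id == sample$sample_id, ]
  one <- function(which) {
    pat <- build_pattern(calls, design, which)
    win <- select_levels(pat)
    target <- if (which == "cos") "cos_degrader" else "chemoorganotroph"
    basis <- if (sample$sample_type == "pond_water") "per_ml" else "per_g_dry"
    if (win$status == "below_range") {
      est <- list(lambda_per_ref_tube = 0, mpn_per_g_dry = 0,
                  ci_low = NA_real_, ci_high = NA_real_)
    } else if (win$status == "above_range") {
      est <- list(lambda_per_ref_tube = NA_real_, mpn_per_g_dry = NA_real_,
                  ci_low = NA_real_, ci_high = NA_real_)
    } else {
      lam <- mpn_ml(win)
      dens <- to_density(lam, win$levels, design, sample)
      ci <- mpn_confidence_interval(dens, design)
      est <- list(lambda_per_ref_tube = lam, mpn_per_g_dry = dens,
                  ci_low = ci[1], ci_high = ci[2])
    }
    structure(c(list(sample_id = sample$sample_id, target = target,
                     selected_levels = win$levels, pattern = win$positives,
                     status = win$status, basis = basis), est),
              class = "mpn_estimate")
  }
  list(cos = one("cos"), growth = one("growth"))
}

#' @export
print.mpn_estimate <- function(x, ...) {
  cat(sprintf("MPN estimate [%s, %s]: pattern (%s) at levels (%s)\n",
              x$sample_id, x$target, paste(x$pattern, collapse = ", "),
              paste(x$selected_levels, collapse = ", ")))
  unit <- if (identical(x$basis, "per_ml")) "MPN/mL" else "MPN/(g dry)"
  if (x$status == "ok") {
    cat(sprintf("  %.3g %s (95%% CI %.3g - %.3g), lambda = %.4g per reference tube\n",
                x$mpn_per_g_dry, unit, x$ci_low, x$ci_high,
                x$lambda_per_ref_tube))
  } else {
    cat(sprintf("  status: %s\n", x$status))
  }
  invisible(x)
}

#' Estimate all samples in a tube table
#'
#' Runs [estimate_sample()] for every sample present in `obs` and returns the
#' flat estimates table (both targets per sample).
#'
#' @param obs Tube observation table (possibly many samples).
#' @param samples Named list of [sample_metadata()] (e.g. from
#'   [read_sample_table()]).
#' @param design The [dilution_design()].
#' @param cfg A [run_config()].
#' @return A data frame as produced by [estimates_table()].
#' @export
estimate_samples <- function(obs, samples, design, cfg = run_config()) {
  ids <- unique(obs$sample_id)
  ests <- list()
  for (id in ids) {
    if (is.null(samples[[id]]))
      stop("no sample metadata for sample_id '", id, "'", call. = FALSE)
    pair <- estimate_sample(obs[obs$sample_id == id, , drop = FALSE],
                            design, samples[[id]], cfg)
    ests <- c(ests, pair)
  }
  estimates_table(ests)
}

#' Generated three-tube MPN lookup table
#'
#' Enumerates all `(tubes_per_level + 1)^3` positive-count patterns for a
#' three-level window of the given design and tabulates the
#' maximum-likelihood MPN per reference tube with Cochran-style confidence
#' bounds. The all-negative and all-positive rows carry the `below_range` /
#' `above_range` sentinels. Useful for documentation and for cross-checking
#' against published three-tube tables.
#'
#' @param design A [dilution_design()].
#' @return A data frame with columns `p1,p2,p3,lambda,ci_low,ci_high,status`.
#' @examples
#' tab <- mpn_lookup_table()
#' tab[tab$p1 == 3 & tab$p2 == 1 & tab$p3 == 1, ]
#' @export
mpn_lookup_table <- function(design = dilution_design()) {
  n <- design$tubes_per_level
  v <- design$dilution_base^(-(0:2))
  grid <- expand.grid(p3 = 0:n, p2 = 0:n, p1 = 0:n)[, 3:1]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- as.integer(grid[i, ])
    if (all(p == 0)) {
      data.frame(p1 = p[1], p2 = p[2], p3 = p[3], lambda = 0,
                 ci_low = NA_real_, ci_high = NA_real_, status = "below_range")
    } else if (all(p == n)) {
      data.frame(p1 = p[1], p2 = p[2], p3 = p[3], lambda = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, status = "above_range")
    } else {
      lam <- mpn_ml(p, rep(n, 3), v)
      ci <- mpn_confidence_interval(lam, design)
      data.frame(p1 = p[1], p2 = p[2], p3 = p[3], lambda = lam,
                 ci_low = ci[1], ci_high = ci[2], status = "ok")
    }
  })
  do.call(rbind, rows)
}
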