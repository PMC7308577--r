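# Synthetic two-step MPN experiments: Poisson inoculation across a tenfold
# dilution series, lag-rise-decline growth, degrader-proportional COS
# degradation over the chemical background, GC measurement noise with
# censoring at the detection limit.

# Carbon content of a single bacterial cell, mg (~200 fg C). Sets the
# inoculum-size dependence of the time to peak biomass.
.cell_carbon_mg <- 2e-10

# Normal(mean, sd) truncated to (0, Inf) by inverse-CDF sampling: a tube that
# truly contains degrader cells must have a positive specific rate, so the
# truncation leaves no point mass at zero.
rtrunc_norm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

#' Simulation configuration
#'
#' Complete parameterization of a synthetic two-step MPN experiment. The
#' defaults emulate the forest-soil scenario: true chemoorganotroph and COS
#' degrader densities of 9.6e8 (g dry)^-1, the standard nine-level three-tube
#' tenfold design, buffered medium at pH 7.0 over the calibrated chemical
#' hydrolysis background, a 0.5 mg C biomass plateau per tube, and 3%
#' multiplicative GC noise on residual concentrations censored at 1.97 ppmv.
#'
#' @param seed Integer seed; makes every output reproducible.
#' @param density_het_per_g_dry True chemoorganotroph density, (g dry)^-1.
#' @param density_cos_per_g_dry True COS-degrader density, (g dry)^-1; must
#'   not exceed the chemoorganotroph density.
#' @param design A [dilution_design()].
#' @param sample A [sample_metadata()] (water content sets the wet-to-dry
#'   conversion of the inoculated mass).
#' @param srcb_mean,srcb_sd Per-tube SRCB distribution (normal, truncated at
#'   0), h^-1 mg^-1 C.
#' @param biomass_peak_mg Carrying-capacity biomass carbon per tube (mg C in
#'   the 2-mL assay aliquot).
#' @param growth_lag_d Lag before growth starts (days).
#' @param growth_rise_d Days a single-cell inoculum needs after the lag to
#'   reach peak biomass (larger inocula peak proportionally earlier on the
#'   log-biomass scale).
#' @param decline_rate_per_d Post-peak decline of log10 biomass per day.
#' @param hydrolysis A `hydrolysis_model` for the abiotic background.
#' @param medium_pH pH of the buffered assay medium.
#' @param measurement_sd_pct Multiplicative Gaussian noise on measured
#'   residual COS, percent.
#' @param detection_limit_ppmv GC detection limit; residuals below it are
#'   flagged censored.
#' @param cos_initial_ppmv Initial COS concentration of the assay.
#' @param assay_duration_h Duration of the degradation assay (h).
#' @param measurement_days First-step days on which the assay is run.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 7, density_cos_per_g_dry = 1e6,
#'                   density_het_per_g_dry = 1e6)
#' @export
sim_config <- function(seed = 1,
                       density_het_per_g_dry = 9.6e8,
                       density_cos_per_g_dry = 9.6e8,
                       design = dilution_design(),
                       sample = sample_metadata("SIM-1", "forest_soil",
                                                water_content = 0.297,
                                                pH = 5.3, toc = 4.8,
                                                mass_used_g_wet = 4),
                       srcb_mean = 1.5, srcb_sd = 1.0,
                       biomass_peak_mg = 0.5,
                       growth_lag_d = 1, growth_rise_d = 4,
                       decline_rate_per_d = 0.05,
                       hydrolysis = calibrate_hydrolysis(
                         data.frame(pH = c(7, 7.5), fraction = c(0.26, 0.32))),
                       medium_pH = 7.0,
                       measurement_sd_pct = 3,
                       detection_limit_ppmv = 1.97,
                       cos_initial_ppmv = 30,
                       assay_duration_h = 24,
                       measurement_days = c(4, 11, 18, 40)) {
  stopifnot(inherits(design, "dilution_design"),
            inherits(sample, "sample_metadata"),
            inherits(hydrolysis, "hydrolysis_model"))
  if (density_cos_per_g_dry > density_het_per_g_dry)
    stop("COS-degrader density cannot exceed chemoorganotroph density",
         call. = FALSE)
  if (min(density_het_per_g_dry, density_cos_per_g_dry) < 0 ||
      srcb_mean < 0 || srcb_sd < 0 || biomass_peak_mg <= 0 ||
      measurement_sd_pct < 0 || decline_rate_per_d < 0)
    stop("rates, densities and noise levels must be non-negative",
         call. = FALSE)
  structure(list(seed = as.integer(seed),
                 density_het_per_g_dry = density_het_per_g_dry,
                 density_cos_per_g_dry = density_cos_per_g_dry,
                 design = design, sample = sample,
                 srcb_mean = srcb_mean, srcb_sd = srcb_sd,
                 biomass_peak_mg = biomass_peak_mg,
                 growth_lag_d = growth_lag_d, growth_rise_d = growth_rise_d,
                 decline_rate_per_d = decline_rate_per_d,
                 hydrolysis = hydrolysis, medium_pH = medium_pH,
                 measurement_sd_pct = measurement_sd_pct,
                 detection_limit_ppmv = detection_limit_ppmv,
                 cos_initial_ppmv = cos_initial_ppmv,
                 assay_duration_h = assay_duration_h,
                 measurement_days = measurement_days),
            class = "sim_config")
}

# Grams dry sample delivered to one tube at a dilution level.
grams_dry_at_level <- function(cfg, level_exponent) {
  d <- cfg$design
  total_ml <- d$soil_mass_g_wet + d$diluent_ml
  wc <- cfg$sample$water_content
  d$inoculum_ml * d$soil_mass_g_wet / total_ml *
    d$dilution_base^(-level_exponent) * (1 - wc)
}

# Piecewise-linear log10-biomass trajectory: flat at the inoculum biomass
# during the lag, rises at a fixed log-slope to the plateau, then declines.
# Vectorized over tubes (n_het) against a vector of days; returns a matrix
# tubes x days in mg C.
biomass_matrix <- function(n_het, days, cfg) {
  peak <- cfg$biomass_peak_mg
  rho <- (log10(peak) - log10(.cell_carbon_mg)) / cfg$growth_rise_d
  b0 <- pmax(n_het, 1) * .cell_carbon_mg  # dummy floor; masked for n_het = 0
  lb0 <- log10(pmin(b0, peak))
  t_peak <- cfg$growth_lag_d + pmax(log10(peak) - lb0, 0) / rho
  out <- vapply(days, function(d) {
    lb <- ifelse(d < cfg$growth_lag_d, lb0,
          ifelse(d < t_peak, lb0 + rho * (d - cfg$growth_lag_d),
                 log10(peak) - cfg$decline_rate_per_d * (d - t_peak)))
    ifelse(n_het == 0, 0, 10^lb)
  }, numeric(length(n_het)))
  matrix(out, nrow = length(n_het))
}

# Core generator: given inoculated cell counts and per-tube SRCB, produce the
# measured observation table. Consumes RNG draws only for measurement noise.
simulate_measurements <- function(cfg, n_het, n_cos, srcb, levels, reps) {
  days <- cfg$measurement_days
  nt <- length(n_het)
  nd <- length(days)
  B <- biomass_matrix(n_het, days, cfg)
  share <- ifelse(n_het > 0, n_cos / n_het, 0)
  k_bio <- (srcb * share) * B
  k_chem <- hydrolysis_rate(cfg$hydrolysis, cfg$medium_pH)
  resid_true <- cfg$cos_initial_ppmv *
    exp(-cfg$assay_duration_h * (k_chem + k_bio))
  noise <- matrix(stats::rnorm(nt * nd, 0, cfg$measurement_sd_pct / 100),
                  nrow = nt)
  resid_meas <- pmax(resid_true * (1 + noise), 0)
  below <- resid_meas < cfg$detection_limit_ppmv
  obs <- data.frame(
    sample_id = cfg$sample$sample_id,
    level_exponent = rep(levels, times = nd),
    replicate = rep(reps, times = nd),
    day = rep(days, each = nt),
    turbid = rep(as.integer(n_het >= 1), times = nd),
    degradation_ratio_pct = degradation_ratio(cfg$cos_initial_ppmv,
                                              as.vector(resid_meas)),
    residual_ppmv = as.vector(resid_meas),
    initial_ppmv = cfg$cos_initial_ppmv,
    below_detection = as.vector(below),
    stringsAsFactors = FALSE)
  obs <- obs[order(obs$level_exponent, obs$replicate, obs$day), ]
  rownames(obs) <- NULL
  list(obs = obs, k_bio = k_bio, biomass = B)
}

#' Simulate one tube of a two-step MPN experiment
#'
#' Draws the inoculated chemoorganotroph count from a Poisson law with mean
#' `density * grams-dry` at the given level (COS degraders as a binomial
#' thinning, so degraders never exceed chemoorganotrophs), grows the tube
#' along the lag-rise-decline trajectory, and measures the 24-h degradation
#' ratio on each measurement day with multiplicative GC noise. Consumes the
#' current RNG state; seed the session (or use [simulate_experiment()]) for
#' reproducibility.
#'
#' @param cfg A [sim_config()].
#' @param level_exponent Dilution level of the tube.
#' @param replicate Replicate index recorded in the output.
#' @return A list with `truth` (one-row data frame: cells, SRCB, per-day
#'   biomass and biological rate constant) and `observations` (one row per
#'   measurement day, `tubes.csv` layout plus `below_detection`).
#' @export
simulate_tube <- function(cfg, level_exponent, replicate = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  gdry <- grams_dry_at_level(cfg, level_exponent)
  n_het <- stats::rpois(1, cfg$density_het_per_g_dry * gdry)
  p_cos <- if (cfg$density_het_per_g_dry > 0)
    cfg$density_cos_per_g_dry / cfg$density_het_per_g_dry else 0
  n_cos <- stats::rbinom(1, n_het, p_cos)
  srcb <- rtrunc_norm_pos(1, cfg$srcb_mean, cfg$srcb_sd)
  m <- simulate_measurements(cfg, n_het, n_cos, srcb,
                             levels = level_exponent, reps = replicate)
  truth <- data.frame(level_exponent = level_exponent, replicate = replicate,
                      n_het_cells = n_het, n_cos_cells = n_cos, srcb = srcb)
  days <- cfg$measurement_days
  truth[paste0("biomass_mg_day", days)] <- as.list(m$biomass[1, ])
  truth[paste0("k_bio_day", days)] <- as.list(m$k_bio[1, ])
  list(truth = truth, observations = m$obs)
}

#' Simulate a complete two-step MPN experiment
#'
#' Generates the full design (all dilution levels x replicates x measurement
#' days) for one sample. Deterministic under the configuration seed: the same
#' `sim_config` always yields byte-identical tables. The truth ledger (cell
#' counts, per-tube SRCB, biomass trajectories) is kept separate from the
#' observations, which have the `tubes.csv` layout.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `mpn_simulation`: a list with `observations`,
#'   `truth` and `config`.
#' @examples
#' sim <- simulate_experiment(sim_config(seed = 42))
#' head(sim$observations)
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  d <- cfg$design
  levels <- rep(d$level_exponents, each = d$tubes_per_level)
  reps <- rep(seq_len(d$tubes_per_level), times = length(d$level_exponents))
  gdry <- grams_dry_at_level(cfg, levels)
  n_het <- stats::rpois(length(levels), cfg$density_het_per_g_dry * gdry)
  p_cos <- if (cfg$density_het_per_g_dry > 0)
    cfg$density_cos_per_g_dry / cfg$density_het_per_g_dry else 0
  n_cos <- stats::rbinom(length(levels), n_het, p_cos)
  srcb <- rtrunc_norm_pos(length(levels), cfg$srcb_mean, cfg$srcb_sd)
  m <- simulate_measurements(cfg, n_het, n_cos, srcb, levels, reps)
  truth <- data.frame(level_exponent = levels, replicate = reps,
                      n_het_cells = n_het, n_cos_cells = n_cos, srcb = srcb)
  days <- cfg$measurement_days
  for (j in seq_along(days)) {
    truth[[paste0("biomass_mg_day", days[j])]] <- m$biomass[, j]
    truth[[paste0("k_bio_day", days[j])]] <- m$k_bio[, j]
  }
  structure(list(observations = m$obs, truth = truth, config = cfg),
            class = "mpn_simulation")
}

#' @export
print.mpn_simulation <- function(x, ...) {
  cat(sprintf("Simulated two-step MPN experiment: %d tubes x %d days (seed %d)\n",
              nrow(x$truth), length(x$config$measurement_days), x$config$seed))
  cat(sprintf("  true densities: %.3g het, %.3g COS degraders per g dry\n",
              x$config$density_het_per_g_dry, x$config$density_cos_per_g_dry))
  invisible(x)
}

#' Simulate a panel of samples on a power law
#'
#' Draws sample densities log-uniformly over `10^2` to `10^9` and rate
#' constants `y = a * x^b * 10^eps` with `eps ~ N(0, noise_sd_log)` — the
#' statistical structure assumed by [fit_power_law()].
#'
#' @param n_samples Number of samples.
#' @param a,b Power-law prefactor and exponent (positive).
#' @param noise_sd_log Standard deviation of the lognormal scatter (log10
#'   units).
#' @param seed Integer seed.
#' @param log10_range Range of `log10(density)` to draw from.
#' @return A data frame with columns `density` and `rate_constant`.
#' @examples
#' panel <- simulate_panel(20, 0.0043, 0.2941, noise_sd_log = 0, seed = 1)
#' fit_power_law(panel$density, panel$rate_constant)
#' @export
simulate_panel <- function(n_samples, a = 0.0043, b = 0.2941,
                           noise_sd_log = 0.2, seed = 1,
                           log10_range = c(2, 9)) {
  stopifnot(a > 0, b > 0, n_samples >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x <- 10^stats::runif(n_samples, log10_range[1], log10_range[2])
  eps <- stats::rnorm(n_samples, 0, noise_sd_log)
  data.frame(density = x, rate_constant = a * x^b * 10^eps)
}

#' Simulate a cell-suspension COS time course
#'
#' Generates the headspace time course of a washed cell suspension with a
#' given biomass: `C(t) = C0 * exp(-(k_blank + srcb * biomass) * t)` with
#' multiplicative Gaussian noise per point and censoring at the detection
#' limit. Used to study the linearity of the fitted rate constant in biomass
#' (the premise of the SRCB statistic). Consumes the current RNG state.
#'
#' @param biomass_mg_c Biomass carbon of the suspension (mg).
#' @param srcb True specific rate constant, h^-1 mg^-1 C.
#' @param k_blank_per_h Abiotic blank rate constant, h^-1.
#' @param times_h Measurement times (h).
#' @param noise_sd_pct Multiplicative noise on concentrations, percent.
#' @param c0_ppmv Initial COS concentration.
#' @param detection_limit_ppmv Censoring threshold.
#' @return A [cos_timecourse()].
#' @export
simulate_suspension <- function(biomass_mg_c, srcb, k_blank_per_h = 0.0125,
                                times_h = c(0, 0.5, 1, 2),
                                noise_sd_pct = 1, c0_ppmv = 30,
                                detection_limit_ppmv = 1.97) {
  k <- k_blank_per_h + srcb * biomass_mg_c
  conc <- c0_ppmv * exp(-k * times_h)
  conc <- pmax(conc * (1 + stats::rnorm(length(times_h), 0, noise_sd_pct / 100)),
               0)
  cos_timecourse(times_h, conc, conc < detection_limit_ppmv)
}

#' Run the estimation pipeline on a simulated experiment
#'
#' Convenience wrapper: applies [estimate_sample()] to a simulation's
#' observation table with a [run_config()] matching the simulation's assay
#' constants.
#'
#' @param sim An `mpn_simulation` from [simulate_experiment()].
#' @param cfg Optional [run_config()]; by default one is built from the
#'   simulation configuration.
#' @return The `list(cos =, growth =)` pair of `mpn_estimate`s.
#' @export
estimate_simulation <- function(sim, cfg = NULL) {
  stopifnot(inherits(sim, "mpn_simulation"))
  sc <- sim$config
  if (is.null(cfg))
    cfg <- run_config(cos_initial_ppmv = sc$cos_initial_ppmv,
                      assay_duration_h = sc$assay_duration_h,
                      detection_limit_ppmv = sc$detection_limit_ppmv,
                      measurement_days = sc$measurement_days,
                      design = sc$design)
  estimate_sample(sim$observations, sc$design, sc$sample, cfg)
}
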