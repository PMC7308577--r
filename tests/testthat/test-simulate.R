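test_that("identical configurations give identical simulated tables", {
  cfg <- sim_config(seed = 123)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$observations, s2$observations)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_experiment(sim_config(seed = 124))
  expect_false(identical(s1$observations, s3$observations))
})

test_that("the simulator leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_experiment(sim_config(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("tube truth respects the thinning and turbidity invariants", {
  sim <- simulate_experiment(sim_config(seed = 2, density_het_per_g_dry = 1e8,
                                        density_cos_per_g_dry = 1e7))
  expect_true(all(sim$truth$n_cos_cells <= sim$truth$n_het_cells))
  obs4 <- sim$observations[sim$observations$day == 4, ]
  key <- paste(obs4$level_exponent, obs4$replicate)
  tkey <- paste(sim$truth$level_exponent, sim$truth$replicate)
  expect_equal(obs4$turbid[match(tkey, key)],
               as.integer(sim$truth$n_het_cells >= 1))
  expect_true(all(sim$truth$biomass_mg_day4[sim$truth$n_het_cells == 0] == 0))
})

test_that("the zero-class law holds per level over many tubes", {
  # three informative levels, ~1000 tubes: non-turbid fraction ~ exp(-lambda v)
  design <- dilution_design(level_exponents = 6:8, tubes_per_level = 340)
  cfg <- sim_config(seed = 31, density_het_per_g_dry = 1e7,
                    density_cos_per_g_dry = 1e7, design = design)
  sim <- simulate_experiment(cfg)
  lam <- 1e7 * 0.1 * 10^-(6:8) * (1 - cfg$sample$water_content)
  p0 <- exp(-lam)
  for (j in 1:3) {
    lvl <- (6:8)[j]
    frac <- mean(sim$truth$n_het_cells[sim$truth$level_exponent == lvl] == 0)
    se <- sqrt(p0[j] * (1 - p0[j]) / 340)
    expect_lt(abs(frac - p0[j]), max(3 * se, 0.01))
  }
})

test_that("a mean inoculum of ten cells leaves almost no empty tubes", {
  # lambda v = 10: zero-class probability exp(-10); over 1000 tubes the
  # turbid fraction stays within binomial 99% bounds of 1 - exp(-10)
  design <- dilution_design(level_exponents = c(6, 7, 8),
                            tubes_per_level = 334)
  dens <- 10 / (0.1 * 1e-6 * (1 - 0.297))
  sim <- simulate_experiment(sim_config(seed = 17, density_het_per_g_dry = dens,
                                        density_cos_per_g_dry = dens,
                                        design = design))
  n6 <- sim$truth$n_het_cells[sim$truth$level_exponent == 6]
  p <- 1 - exp(-10)
  bounds <- qbinom(c(0.005, 0.995), length(n6), p) / length(n6)
  frac <- mean(n6 >= 1)
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("no residual below the detection limit lacks its censored flag", {
  sim <- simulate_experiment(sim_config(seed = 8))
  obs <- sim$observations
  expect_true(all(obs$below_detection[obs$residual_ppmv < 1.97]))
  expect_false(any(obs$below_detection[obs$residual_ppmv >= 1.97]))
  expect_gt(sum(obs$below_detection), 0)  # dense sample: censoring occurs
})

test_that("without degraders the ratios center on the chemical background", {
  design <- dilution_design(level_exponents = 2:4, tubes_per_level = 30)
  cfg <- sim_config(seed = 4, density_het_per_g_dry = 1e8,
                    density_cos_per_g_dry = 0, design = design)
  sim <- simulate_experiment(cfg)
  r <- sim$observations$degradation_ratio_pct
  expect_equal(mean(r), 26, tolerance = 0.05)
  expect_false(any(call_tubes(sim$observations,
                              run_config(design = design))$cos_positive))
})

test_that("a sterile sample yields no turbidity and no biology above the blank", {
  design <- dilution_design(level_exponents = 2:4, tubes_per_level = 10)
  sim <- simulate_experiment(sim_config(seed = 6, density_het_per_g_dry = 0,
                                        density_cos_per_g_dry = 0,
                                        design = design))
  expect_true(all(sim$observations$turbid == 0))
  expect_true(all(sim$truth$n_het_cells == 0))
  expect_lt(max(sim$observations$degradation_ratio_pct), 40)
})

test_that("COS-positive tubes are a subset of growth-positive tubes", {
  for (s in 1:20) {
    sim <- simulate_experiment(sim_config(seed = s, density_het_per_g_dry = 1e6,
                                          density_cos_per_g_dry = 3e5))
    calls <- call_tubes(sim$observations, run_config())
    expect_true(all(!calls$cos_positive | calls$growth_positive))
    est <- estimate_simulation(sim)
    if (est$cos$status == "ok" && est$growth$status == "ok")
      expect_lte(est$cos$mpn_per_g_dry, est$growth$mpn_per_g_dry * (1 + 1e-9))
  }
})

test_that("dense samples produce transient positives needing repeated measurement", {
  n_with_transient <- sum(vapply(1:100, function(s) {
    sim <- simulate_experiment(sim_config(seed = s))
    obs <- sim$observations
    obs <- obs[order(obs$level_exponent, obs$replicate, obs$day), ]
    any(vapply(split(obs, paste(obs$level_exponent, obs$replicate)),
               function(g) {
                 r <- g$degradation_ratio_pct
                 any(r >= 40) && tail(r, 1) < 40
               }, logical(1)))
  }, logical(1)))
  expect_gte(n_with_transient, 10)
})

test_that("simulate_tube agrees with the experiment-level generator contract", {
  cfg <- sim_config(seed = 1)
  set.seed(42)
  one <- simulate_tube(cfg, level_exponent = 6)
  expect_equal(nrow(one$observations), length(cfg$measurement_days))
  expect_equal(one$truth$n_het_cells >= 1,
               one$observations$turbid[1] == 1)
  expect_true(all(one$observations$initial_ppmv == 30))
})

test_that("panel generation is seeded and exact in the noiseless limit", {
  p1 <- simulate_panel(20, 0.0043, 0.2941, 0.2, seed = 5)
  p2 <- simulate_panel(20, 0.0043, 0.2941, 0.2, seed = 5)
  expect_identical(p1, p2)
  p0 <- simulate_panel(10, 0.0043, 0.2941, 0, seed = 9)
  fit <- fit_power_law(p0$density, p0$rate_constant)
  expect_equal(fit$a, 0.0043, tolerance = 1e-10)
  expect_equal(fit$b, 0.2941, tolerance = 1e-10)
  p3 <- simulate_panel(3, 1, 1, 0.5, seed = 2)
  expect_equal(fit_power_law(p3$density, p3$rate_constant)$n, 3)
})

test_that("suspension time courses make the fitted rate linear in biomass", {
  set.seed(21)
  biomass <- seq(0.2, 5, length.out = 12)
  k_fit <- vapply(biomass, function(b) {
    fit_rate_constant(simulate_suspension(b, srcb = 0.8,
                                          noise_sd_pct = 1))$k_per_h
  }, numeric(1))
  expect_gt(cor(k_fit, biomass), 0.97)
})
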