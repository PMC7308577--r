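test_that("tube calling scores the maximum over days with an inclusive threshold", {
  tab <- read_tube_table(table2_path(), dilution_design())
  calls <- call_tubes(tab, run_config())
  g <- function(lvl, rep) calls[calls$level_exponent == lvl &
                                  calls$replicate == rep, ]
  # transient positive: single day over threshold suffices
  expect_true(g(8, 2)$cos_positive)
  expect_equal(g(8, 2)$first_positive_day, 18)
  # never reaches 40
  expect_false(g(8, 1)$cos_positive)
  # exactly 40 counts (inclusive comparison)
  expect_true(g(6, 1)$cos_positive)
  expect_equal(g(6, 1)$first_positive_day, 11)
  # the missing day-40 cell is skipped, not treated as negative or zero
  expect_true(g(7, 2)$cos_positive)
})

test_that("tubes with no usable measurement are excluded with a warning", {
  obs <- data.frame(sample_id = "S", level_exponent = c(2, 2), replicate = c(1, 2),
                    day = 4, turbid = c(1, NA),
                    degradation_ratio_pct = c(50, NA),
                    residual_ppmv = NA, initial_ppmv = 30)
  expect_warning(calls <- call_tubes(obs, run_config()), "excluded")
  expect_equal(nrow(calls), 1)
})

test_that("the full tube pattern counts positives per level", {
  d <- dilution_design()
  tab <- read_tube_table(table2_path(), d)
  calls <- call_tubes(tab)
  pat <- build_pattern(calls, d, "cos")
  expect_equal(pat$levels, 2:10)
  expect_equal(pat$positives, c(3, 3, 3, 3, 3, 3, 1, 1, 0))
  expect_equal(pat$relative_volumes, 10^-(0:8))
  growth <- build_pattern(calls, d, "growth")
  expect_equal(growth$positives, c(3, 3, 3, 3, 3, 3, 1, 1, 0))
  # missing replicate is a validation error
  expect_error(build_pattern(calls[-1, ], d, "cos"), "missing replicate")
})

test_that("window selection follows the three-tube bookkeeping", {
  mk <- function(p, e = seq(2, length.out = length(p))) {
    structure(list(levels = as.integer(e), positives = p,
                   tubes = rep(3L, length(p)),
                   relative_volumes = 10^-(seq_along(p) - 1),
                   dilution_base = 10), class = "tube_pattern")
  }
  w <- select_levels(mk(c(3, 3, 3, 3, 3, 3, 1, 1, 0), 2:10))
  expect_equal(w$levels, 7:9)
  expect_equal(w$positives, c(3, 1, 1))
  expect_equal(w$status, "ok")
  # all-negative: three lowest levels, below range
  w0 <- select_levels(mk(rep(0L, 6), 2:7))
  expect_equal(w0$levels, 2:4)
  expect_equal(w0$positives, c(0, 0, 0))
  expect_equal(w0$status, "below_range")
  # stray positive beyond the window folds into its last level
  wf <- select_levels(mk(c(3, 3, 1, 0, 1, 0), 2:7))
  expect_equal(wf$levels, 3:5)
  expect_equal(wf$positives, c(3, 1, 1))
  # fully positive everywhere: three highest, above range
  wa <- select_levels(mk(rep(3L, 5), 2:6))
  expect_equal(wa$levels, 4:6)
  expect_equal(wa$status, "above_range")
  expect_error(select_levels(mk(c(1, 0))), "3 dilution levels")
})

test_that("the MPN MLE matches frozen classical-scale values", {
  expect_equal(mpn_ml(c(3, 1, 1)), 7.488523, tolerance = 1e-6)
  expect_equal(mpn_ml(c(3, 3, 0)), 23.97895, tolerance = 1e-6)
  expect_equal(mpn_ml(c(0, 0, 0)), 0)
  expect_error(mpn_ml(c(3, 3, 3)), "above_range")
})

test_that("the MLE agrees with brute-force likelihood maximization on all estimable patterns", {
  grid <- expand.grid(p1 = 0:3, p2 = 0:3, p3 = 0:3)
  grid <- grid[rowSums(grid) > 0 & rowSums(grid) < 9, ]
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    p <- as.integer(grid[i, ])
    if (all(p == 3)) next
    lam <- mpn_ml(p)
    ora <- mpn_oracle(p)
    worst <- max(worst, abs(lam - ora) / ora)
  }
  expect_lt(worst, 1e-4)
})

test_that("the MLE is monotone in every positive count", {
  for (i in 1:3) {
    for (p1 in 0:3) for (p2 in 0:3) for (p3 in 0:3) {
      p <- c(p1, p2, p3)
      if (p[i] == 3) next
      q <- p
      q[i] <- q[i] + 1
      if (all(q == 3) || sum(p) == 0) next
      expect_gte(mpn_ml(q), mpn_ml(p) - 1e-9)
    }
  }
})

test_that("the MLE is equivariant under rescaling of the inoculum volumes", {
  v <- 10^-(0:2)
  for (cc in c(0.1, 3, 50)) {
    expect_equal(mpn_ml(c(3, 1, 1), v = cc * v),
                 mpn_ml(c(3, 1, 1), v = v) / cc, tolerance = 1e-7)
    expect_equal(mpn_ml(c(2, 1, 0), v = cc * v),
                 mpn_ml(c(2, 1, 0), v = v) / cc, tolerance = 1e-7)
  }
})

test_that("the Cochran interval has the classical three-tube tenfold width", {
  d <- dilution_design()
  ci <- mpn_confidence_interval(7.5, d)
  fac <- 10^(1.96 * 0.58 * sqrt(1 / 3))
  expect_equal(fac, 4.532437, tolerance = 1e-6)
  expect_equal(ci, c(7.5 / fac, 7.5 * fac), tolerance = 1e-9)
  # factor tends to 1 as replication grows
  wide <- dilution_design(tubes_per_level = 1e5)
  ci2 <- mpn_confidence_interval(7.5, wide)
  expect_equal(ci2[2] / ci2[1], 1, tolerance = 0.02)
})

test_that("density conversion follows the dilution bookkeeping", {
  d <- dilution_design()
  # level-7 window, 3 g in 30 mL: reference tube got 1e-8 g wet
  expect_equal(to_density(7.488523, 7:9, d, ks13_sample()),
               7.488523 * 1e8 / (1 - 0.297), tolerance = 1e-9)
  expect_equal(to_density(0, 2:4, d, ks13_sample()), 0)
  pond <- sample_metadata("P", "pond_water", volume_ml = 10)
  expect_equal(to_density(7.5, 1:3, d, pond), 75)
})

test_that("the forest-soil fixture reproduces the published density end to end", {
  d <- dilution_design()
  tab <- read_tube_table(table2_path(), d)
  est <- estimate_sample(tab, d, ks13_sample())
  expect_equal(est$cos$pattern, c(3, 1, 1))
  expect_equal(est$cos$selected_levels, 7:9)
  ratio <- est$cos$mpn_per_g_dry / 9.6e8
  expect_gt(ratio, 1 / 1.25)
  expect_lt(ratio, 1.25)
  # the growth pattern is identical, so the chemoorganotroph density matches
  expect_equal(est$growth$mpn_per_g_dry, est$cos$mpn_per_g_dry)
  expect_true(est$cos$ci_low <= est$cos$mpn_per_g_dry &&
                est$cos$mpn_per_g_dry <= est$cos$ci_high)
})

test_that("an all-negative table gives below-range estimates of zero", {
  d <- dilution_design(level_exponents = 2:5)
  obs <- expand.grid(level_exponent = 2:5, replicate = 1:3,
                     day = c(4, 11))
  obs <- data.frame(sample_id = "NEG", obs, turbid = 0,
                    degradation_ratio_pct = 26, residual_ppmv = NA,
                    initial_ppmv = 30)
  est <- estimate_sample(obs, d, sample_metadata("NEG", "forest_soil",
                                                 water_content = 0.3,
                                                 mass_used_g_wet = 4))
  expect_equal(est$cos$status, "below_range")
  expect_equal(est$cos$mpn_per_g_dry, 0)
  expect_equal(est$growth$status, "below_range")
})

test_that("the generated lookup table covers all patterns and matches the MLE", {
  tab <- mpn_lookup_table()
  expect_equal(nrow(tab), 64)
  expect_equal(sum(tab$status == "above_range"), 1)
  expect_equal(sum(tab$status == "below_range"), 1)
  row311 <- tab[tab$p1 == 3 & tab$p2 == 1 & tab$p3 == 1, ]
  expect_equal(row311$lambda, 7.488523, tolerance = 1e-6)
  ok <- tab[tab$status == "ok", ]
  expect_true(all(ok$ci_low <= ok$lambda & ok$lambda <= ok$ci_high))
})
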