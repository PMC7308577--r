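# Shared test helpers: an independent brute-force MPN oracle and the
# forest-soil reference sample.

# Independent oracle for the MPN MLE: maximize the binomial log-likelihood of
# the positive-tube pattern directly over log(lambda), with no use of the
# score equation that mpn_ml() solves.
mpn_oracle <- function(p, n = rep(3, length(p)), v = 10^-(seq_along(p) - 1)) {
  loglik <- function(lam) sum(p * log(1 - exp(-lam * v)) - (n - p) * lam * v)
  opt <- optimize(function(u) loglik(exp(u)), c(log(1e-6), log(1e6)),
                  maximum = TRUE, tol = 1e-12)
  exp(opt$maximum)
}

ks13_sample <- function() {
  sample_metadata("KS-13", "forest_soil", water_content = 0.297,
                  pH = 5.28, toc = 4.8, mass_used_g_wet = 4)
}

table2_path <- function() cosmpn_example("tubes_ks13.csv")

# Noiseless exponential time course helper
exp_course <- function(k, times = c(0, 1, 2, 4), c0 = 30,
                       below = rep(FALSE, length(times))) {
  cos_timecourse(times, c0 * exp(-k * times), below)
}
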