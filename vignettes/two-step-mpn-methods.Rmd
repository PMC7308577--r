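---
title: "Two-step MPN enumeration of COS-degrading microorganisms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step MPN enumeration of COS-degrading microorganisms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosmpn)
```

## The measurement problem

Carbonyl sulfide (COS) is degraded in aqueous culture by two superimposed
processes: abiotic hydrolysis (COS + H2O -> CO2 + H2S), which accelerates
sharply with pH, and enzymatic degradation by microorganisms carrying
beta-class carbonic anhydrase family enzymes. A plain dilution-to-extinction
count of "COS-degrading" tubes is therefore confounded: every tube loses COS
whether or not anything grows in it. The two-step most probable number (MPN)
design separates the processes. In the first step, serial tenfold dilutions
of an environmental suspension are grown on dilute organic medium and scored
for chemoorganotrophic growth by turbidity. In the second step, an aliquot of
each grown culture is sealed with 30 ppmv COS for 24 h and scored as a COS
degrader only when its degradation ratio clearly exceeds what chemistry alone
can do.

`cosmpn` implements this full quantitative pipeline: positivity calling,
maximum-likelihood MPN estimation with confidence intervals and unit
conversion, the first-order kinetics used to characterize samples and
isolates, the power-law relation between cell density and degradation rate,
and a synthetic-data generator that gives every stage a testable ground
truth.

## Positivity calling

A culture is COS-positive when its 24-h degradation ratio,
$100\,(1 - C_{24}/C_0)$, reaches the threshold (default 40%). Two details of
`call_tubes()` matter in practice:

* **The comparison is inclusive** (`>= 40`). Tubes sitting exactly at the
  threshold are positive; with whole-percent measurements this is not an
  edge case but a real decision that changes patterns.
* **Scoring is the maximum over all measurement days** (default days 4, 11,
  18 and 40 of the first step). Slow-growing cultures at high dilution can
  be transiently positive — above the threshold at one measurement and back
  near the chemical baseline later, as dead biomass stops degrading — so a
  single measurement day systematically undercounts. A missing measurement
  day is skipped, never treated as zero or negative.

The degradation ratio is used raw, not blank-corrected: negative tubes sit
at the chemical background (roughly 26–32%), and the threshold is placed
above that background rather than subtracting it. Ratios slightly above
100% (measurement overshoot) are retained unclipped with a warning, since
clipping would bias threshold comparisons near 100%.

## MPN estimation

Under the Poisson single-hit model a tube at relative inoculum volume $v_i$
is positive with probability $1 - e^{-\lambda v_i}$, where $\lambda$ is the
expected number of culturable organisms in the largest inoculum. With $p_i$
of $n_i$ tubes positive, `mpn_ml()` solves the score equation

$$\sum_i \frac{p_i v_i e^{-\lambda v_i}}{1 - e^{-\lambda v_i}}
  = \sum_i (n_i - p_i)\,v_i$$

by bisection-based root finding on $\log\lambda$ over $[10^{-6}, 10^6]$ to a
relative tolerance below $10^{-9}$. The score function is strictly
decreasing with a guaranteed sign change for every estimable pattern, so the
solution is deterministic and unique. We chose maximum likelihood over the
published three-tube lookup tables because it is exact, reproduces the table
values to their rounding, and generalizes to any design;
`mpn_lookup_table()` regenerates the full 64-pattern table for
cross-checking. The all-negative pattern returns 0 (`below_range`); the
all-positive pattern has no finite MLE (`above_range`).

Three-level windows are selected by the classical bookkeeping
(`select_levels()`): the highest dilution level at which all tubes are
positive anchors the window, the next two more-dilute levels complete it,
and stray positives beyond the window are folded into its last level,
capped at the number of tubes. If no fully positive level exists the three
lowest levels are used.

Confidence intervals are Cochran-style: the standard error of
$\log_{10}$ MPN is approximated by
$0.58\sqrt{\log_{10}(\text{base})/n}$, giving a multiplicative 95% factor
of about 4.5 for the three-tube tenfold design. This width is a property of
the design, not of the data, which is why heavier replication is the only
way to narrow it.

### Dilution bookkeeping

Unit conversion is where MPN pipelines silently disagree, so the convention
is fixed explicitly. The primary suspension is 3 g wet sample in 30 mL
total; dilution level $n$ is a $10^{-n}$ dilution of that suspension, and a
1-mL inoculum at level $n$ therefore carries $10^{-(n+1)}$ g wet sample.
`to_density()` divides $\lambda$ by the wet grams in the window's reference
tube and by $(1 - \text{water content})$ for the per-gram-dry basis. Water
samples are diluted directly and reported per mL. An alternative reading of
the level labels (level $n$ = $10^{-n}$ g) would shift every density about
ninefold; the adopted convention is the one consistent with published
three-tube-table results for the packaged forest-soil experiment, which it
reproduces within about 11% (exact ML vs. rounded table entry).

```{r table2}
design <- dilution_design()
tab <- read_tube_table(cosmpn_example("tubes_ks13.csv"), design)
ks13 <- read_sample_table(cosmpn_example("samples.csv"))[["KS-13"]]
est <- estimate_sample(tab, design, ks13)
est$cos
```

## Kinetics

Headspace time courses follow first-order decay, $C(t) = C_0 e^{-kt}$.
`fit_rate_constant()` fits $\ln C$ on $t$ by ordinary least squares:
closed-form, deterministic, and exact on noiseless exponentials, which is
also what the test suite asserts. Points at or below the gas chromatograph
detection limit (1.97 ppmv) are censored and excluded rather than imputed —
the simplest policy that leaves the log-linear fit unbiased. A nonlinear
refinement would change estimates only under strongly heteroscedastic
noise and is deliberately out of scope.

Rate constants are compared across samples after normalization: per gram
dry sample for soils (`k / (mass_wet (1 - wc))`, with 4 g wet as the assay
default) or per mL for water samples (10 mL default).

The chemical background is modelled as base-catalyzed first-order loss,
$k(\mathrm{pH}) = k_0 + k_{OH}\,[\mathrm{OH^-}]$ with
$[\mathrm{OH^-}] = 10^{\mathrm{pH}-14}$ M. This is the minimal form that is
monotone in pH and passes exactly through two anchor observations of the
chemical-only 24-h fraction; with the default anchors (26% at pH 7.0, 32%
at pH 7.5) the calibrated parameters are $k_0 \approx 1.09\times10^{-2}$
h$^{-1}$ and $k_{OH} \approx 1.63\times10^{4}$ M$^{-1}$h$^{-1}$.
`calibrate_hydrolysis()` solves the 2-by-2 system analytically and refuses
anchors implying negative rate terms.

Isolate activity is compared by SRCB — the specific rate constant of COS
degradation normalized by biomass carbon:
$(k_{\text{suspension}} - k_{\text{blank}}) / B$ in h$^{-1}$ mg$^{-1}$ C,
with biomass measured against a glucose-carbon standard curve (default
standards 0.05, 0.5, 1 and 3 mg C, ordinary least squares). SRCB is
meaningful where the rate constant is linear in biomass, roughly 0.2–5 mg C
per suspension; values computed below that range are flagged
`low_biomass`, and a suspension slower than its blank is flagged
`negative` with the value reported rather than suppressed.

## The density–activity relation

Sample-level degradation rate constants are related to COS-degrader
densities by a power law, $y = a x^b$, fitted by ordinary least squares of
$\log_{10} y$ on $\log_{10} x$ (`fit_power_law()`); log-space fitting is
the faithful reading of a correlation computed "among logarithms", and it
makes the reported $r^2$ and Pearson $r$ of the fit the same quantity,
$r = \mathrm{sign}(b)\sqrt{r^2}$. Samples with below-range (zero) MPN are
excluded, not imputed: their logarithm is undefined and their information
content about the slope is nil. The two-sided p-value comes from the
t statistic with $n-2$ degrees of freedom.

## What the simulator emulates

`simulate_experiment()` generates complete synthetic experiments with known
ground truth:

* **Poisson inoculation.** Each tube at level $n$ receives
  $\mathrm{Poisson}(D \cdot g_{\text{dry}})$ chemoorganotrophs, where $D$ is
  the true density; COS degraders are a binomial thinning of that count, so
  a degrader can never appear without a chemoorganotroph. The zero-class law
  $P(\text{no growth}) = e^{-\lambda v}$ is asserted against the generator
  in the tests.
* **Growth.** Per-tube biomass follows a lag–rise–decline trajectory,
  piecewise linear in $\log_{10}$ biomass: flat at the inoculum's carbon
  content (200 fg C per cell) during a 1-day lag, rising at a fixed log
  slope — so sparser inocula peak later, which is what makes high-dilution
  tubes turn positive only on later measurement days — to a 0.5 mg C
  plateau, then declining at 0.05 log units per day. The decline, combined
  with between-tube variability in specific activity, produces the
  transient positives that motivate repeated measurement.
* **Degradation.** On each measurement day the 24-h fraction is
  $1 - \exp(-24\,(k_{\text{chem}} + s\,\phi\,B))$, where $s$ is the tube's
  SRCB (normal with mean 1.5 and sd 1.0 h$^{-1}$mg$^{-1}$C, truncated to
  positive values by inverse-CDF sampling — a tube that truly contains
  degrader cells must have positive activity), $\phi$ the degrader share of
  the inoculum, and $B$ the biomass. The SRCB spread spans the range
  observed across real isolates (roughly 0.03–3.3).
* **Measurement.** Gaussian multiplicative noise (3% sd) acts on the
  residual concentration — the quantity the chromatograph actually reads —
  not on the ratio; residuals below 1.97 ppmv are flagged censored.

Defaults mimic the forest-soil reference experiment (both densities
9.6×10⁸ (g dry)⁻¹, water content 0.297, buffered medium at pH 7.0). All
randomness derives from the configuration seed, and the generator restores
the caller's RNG state, so identical configurations give byte-identical
tables.

What the simulator does **not** model: community dynamics beyond neutral
competition (the degrader share is fixed at the inoculum ratio), Monod
growth or pH drift in the tube (media are buffered), COS production by
soils, headspace–liquid partitioning, and temperature dependence (all
kinetics are at a single nominal temperature). Passing recovery tests on
simulated data therefore demonstrates that the estimator chain is correct
under the stated statistical model, not that any particular soil obeys that
model.

## Statistical behaviour of the estimator

The recovery study run by the test suite and the acceptance script (500
simulated experiments at each true density of $10^4$, $10^6$ and $10^8$
(g dry)$^{-1}$; sizes chosen to make Monte-Carlo error small relative to
the bands being checked) shows the expected picture for a three-tube
design:

* the signed median $\log_{10}$ error is within 0.15 of zero,
* the Cochran-style 95% interval covers truth in 95–98% of runs,
* but the *median absolute* $\log_{10}$ error is about 0.22. This is
  discreteness, not a defect: when the true $\lambda$ at the reference
  level is about 7, the two most probable patterns, (3,1,0) and (3,2,0),
  have MLEs 4.30 and 9.33 — 0.21 and 0.12 log units away — and no estimator
  can split a pattern's probability mass. Order-of-magnitude comparisons,
  which is how MPN densities are used, are unaffected.

## Numerical and degenerate-input policy

* Root finding for the MLE brackets $\log\lambda$ in $[\log 10^{-6},
  \log 10^6]$; the bracket is guaranteed by a sign change for every
  estimable pattern.
* Constant time courses fit $k = 0$ with $r^2$ defined as 1 (zero residual
  on zero variance) rather than NaN.
* Estimate CSVs are written at full double precision (`%.17g`), so
  write-then-read is exact, including the `below_range` / `above_range`
  sentinels and missing-value flags.
* Negative biomass inversions are clamped to zero and flagged, protecting
  downstream divisions.
* All-negative and all-positive experiments flow through the pipeline as
  statuses, not errors, and exit the command-line interface with code 0.

## Command-line interface

The `inst/cli/cosmpn` script exposes the pipeline as subcommands
(`simulate`, `call`, `mpn`, `kinetics`, `srcb`, `correlate`, `table`), each
a thin composition of the exported functions; results are CSV files under
`--out-dir` plus a `manifest.txt` with the tool version, seed, flags and
input digests. Logging goes to standard error so outputs compose in
pipelines.
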