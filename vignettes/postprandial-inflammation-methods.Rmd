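---
title: "Methods: postprandial inflammation, path models and Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: postprandial inflammation, path models and Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppimr)
```

## The problem

Sequential mixed meals produce overlapping glucose and triglyceride (TG)
excursions over 0–6 h, and these excursions drive an acute inflammatory
response. GlycA (an NMR composite of acute-phase glycoprotein glycans,
mmol/L) is measured at fasting, 4 h and 6 h together with IL-6; the
analytical questions are (i) which *features* of the metabolic response
track postprandial inflammation, (ii) how variable the inflammatory
response is between people, and (iii) whether the adiposity → TG →
inflammation chain is causal and how much of it is mediated. `ppimr`
implements that chain as composable, tested stages. Because
individual-level data of this kind are access-controlled, a synthetic
cohort and synthetic GWAS summary statistics with planted ground truth
stand in for the real inputs; every stage is exercised against them.

## Curve featurization

A postprandial curve is a strictly increasing sampled time grid starting
at 0 (fasting) with non-negative concentrations. All features are defined
on sampled points; there is no smoothing or interpolation beyond the
trapezoids the grid implies, because the standard sampling grid contains
every time point the features need.

* **iAUC** uses the positive-increment ("Wolever-style") convention:
  increments below fasting are clipped to zero at the sampled points
  before trapezoidal integration. The signed net area is available via
  `convention = "net"`. The positive-increment default was chosen because
  "incremental AUC" without a formula conventionally means exactly this
  in the meal-response literature.
* **Windowed maxima** use closed windows ([0, 120] and [240, 360] min for
  the two glucose peaks, [0, 360] for TG); boundary samples belong to the
  window, and ties resolve to the earliest time (this affects only Tmax).
* Peak times (Tmax) are computed and emitted but excluded from default
  model inputs (`feature_names()`), since they are descriptive rather
  than predictive here.
* Degenerate inputs fail loudly: windows containing fewer than two
  samples, unsampled rise times, and missing required time points raise
  errors naming the offending time.

## The synthetic cohort

`simulate_cohort()` draws a cohort of healthy adults (default n = 1000,
age 18–65 y, 28% male, BMI 25.6 ± 5 kg/m²) with:

* **Glucose**: baseline plus two Gaussian peaks (breakfast peak at
  30 min, lunch peak at 300 min). A symmetric Gaussian peak at 30 min
  necessarily has a tail at t = 0, so the baseline parameter (4.21
  mmol/L) is set such that the *observed* fasting value — baseline plus
  tail — lands at about 4.91 ± 0.50 mmol/L, the 30-min rise at about
  2.1 mmol/L and the first peak at about 7.0 mmol/L. The cost of the
  closed-form peak shape is that the simulated curve decays back toward
  baseline faster after 60 min than real glucose curves do; no feature
  used downstream depends on that part of the shape.
* **TG**: baseline (1.05 ± 0.50 mmol/L) plus one late Gaussian peak.
  The peak *time* is participant-random (300 ± 30 min): lipemia kinetics
  genuinely vary between people, and this kinetic variability is what
  decorrelates the 4-h and 6-h TG values (a symmetric peak exactly
  between them would otherwise make them statistically
  indistinguishable, and no "matching time point" structure could
  exist). Sampled TG peaks average ≈ 2.1 mmol/L and the 6-h value
  ≈ 1.8 mmol/L.
* **Markers**: latent standardized GlycA scores follow a planted linear
  system — VFM → fasting TG (0.30), fasting TG → fasting GlycA (0.57),
  VFM → fasting GlycA (0.17), and 6-h GlycA driven by fasting GlycA
  (0.30), the latent 6-h TG value (0.70) and the first glucose peak
  amplitude (0.15) — mapped to mmol/L with the observed scale
  (1.32 ± 0.18 fasting, 1.38 ± 0.28 at 6 h). These defaults give a GlycA
  responder fraction near 60% and feature–marker correlations near the
  observed regime (r ≈ 0.8 for 6-h TG vs 6-h GlycA, ≈ 0.1–0.15 for the
  first glucose peak). IL-6 (0.48 ± 0.28 marker units fasting, mean 6-h
  rise 0.87 with SD chosen so ~94% of participants rise) is drawn
  independently of every glucose/TG quantity, reflecting the finding
  that postprandial IL-6 correlates with neither response (plausibly a
  cannulation artifact); IL-6 units are treated as opaque "marker
  units" because the unit printed for IL-6 in the source material is
  almost certainly a typo.
* **Exactness**: latent standardized scores are computed from the
  *realized* (truncated-at-zero) covariates, so with all noise SDs set
  to zero the markers are exact linear functions of the emitted values
  and planted slopes are recoverable by regression to machine precision.
  Truncation points sit ≥ 1.9 SDs from the means, so they affect a few
  percent of draws at most.
* Covariates (age, sex, BMI, weight, 10 microbiome principal components)
  are mutually independent except the planted VFM → TG path — the
  minimal structure that keeps the downstream tests identifiable.
* All randomness in one simulator call flows from a single seeded
  generator (one `set.seed(config$seed)` at entry). Per-participant
  sub-streams were considered and rejected: nothing downstream needs
  stability under config edits, and a single stream keeps the generator
  simple and bit-reproducible.

What passing tests on this cohort do **not** show: the generator is
linear-Gaussian with independent measurement noise; real cohorts have
skewed TG distributions, twin structure, assay batch effects and
nonlinear coupling, none of which are emulated. Recovery of planted
effects demonstrates correctness of the estimators, not real-world
effect sizes.

## Characterization choices

* "Increase" is strict (6 h − fasting > 0); a configurable tolerance
  band `epsilon` supports an "unchanged" category, since reported
  riser/decliner percentages in this literature often do not sum to 100.
* Levene's test centers on the group **mean** (classic Levene) by
  default, with `center = "median"` (Brown–Forsythe) available; the test
  is one-way ANOVA on absolute deviations via `stats::lm`.
* Correlations use raw GlycA and ln(IL-6 + 1); the log transform applies
  to IL-6 only.
* The repeated-measures interaction test dichotomizes age at the cohort
  median (no standard coding exists) and drops participants missing a
  time point, reporting the count.
* Percent figures follow two print conventions: integers are rounded
  (168.75 → 169) and one-decimal values are truncated (42.769 → 42.7);
  `format_percent()` implements both so report tables can be matched
  digit for digit. The mediated proportion is likewise truncated to an
  integer percent (0.2954 → 29%).

## Prediction choices

* Random-forest hyperparameters: 500 trees, `mtry = p/3`, 5-fold CV —
  conventional regression-forest defaults; all configurable and logged
  in the report object. Forests are grown single-threaded with a fixed
  seed, so reports are deterministic.
* Q² is fixed as 1 − PRESS/TSS with TSS about the grand mean; negative
  values are reported as-is (they mean the model is not predictive).
  R² is the in-sample fit of the full model and is labelled as such.
* The "70% GlycA cutoff" for ROC analysis is interpreted as the 70th
  empirical percentile of the outcome defining the positive class
  (type-7 interpolated quantile); this is an interpretation, flagged
  here, and alternative readings are deliberately not guessed.
* The AUC confidence interval uses the DeLong placement-value variance
  rather than a bootstrap, for determinism; the point estimate is the
  Mann–Whitney identity with half-weight ties.

## Path analysis

The path model is manifest-variable only (no latent factors), estimated
on the complete-case covariance matrix: free parameters are edge
coefficients, residual variances for endogenous nodes, and a full free
covariance block for exogenous nodes. The ML discrepancy
F = log|Σ(θ)| + tr(SΣ(θ)⁻¹) − log|S| − p is minimized with BFGS on a
parametrization that keeps variances positive (log-variances; Cholesky
with log-diagonal for the exogenous block), starting from the
equation-wise least-squares solution computed from S — for a recursive
system that start is already the global optimum, and the quasi-Newton
pass (relative tolerance 1e-8) verifies it. There is no randomness:
fits are deterministic from the data. χ² = (n − 1)·F; standard errors
come from the inverse observed information (numerical Hessian of the
log-likelihood); the baseline model for CFI/TLI is the conventional
independence model, whose χ² has the closed form −(n−1)·log|R|. TLI
above 1 is capped with the raw value retained. Missingness beyond
complete-case deletion (e.g. FIML) is out of scope. Fit indices are
reported without verdicts: conventional cutoffs conflict often enough
(a model can have CFI > 0.99 and RMSEA > 0.1 simultaneously) that
adjudication is left to the analyst.

## Two-sample MR

The estimators operate on harmonized instruments: tables are intersected
on SNP id, outcome effects are sign-flipped when the allele pair is
swapped, incompatible pairs are dropped with a warning, and
strand-ambiguous palindromic SNPs with EAF in [0.42, 0.58] (a common
default, configurable) are excluded. Instruments are assumed independent
— the synthetic generator guarantees it, and LD clumping is out of
scope.

Method-level choices, following the originating methods literature since
names alone do not pin formulas down:

* Wald SE is first-order (σ_Γ/|γ̂|) by default with a second-order
  option; IVW offers fixed and multiplicative random-effects
  (SE inflated by max(1, √(Q/(J−1)))) models, defaulting to random.
* MR-Egger orients instruments to positive exposure effects, uses
  weights 1/σ²_Γ, floors the residual SD at 1, and tests on t with J−2
  df. With the intercept constrained to zero it reduces exactly to
  fixed-effect IVW.
* MR-PRESSO simulates **both** the exposure and outcome associations in
  its parametric null, as in the originating method. Simulating only the
  outcome side is measurably anti-conservative (the global test rejects
  a clean null far too often) because observed residuals carry the
  exposure-side sampling noise that an outcome-only null lacks. Outlier
  p-values are Bonferroni-corrected; the distortion test removes random
  same-size SNP sets. Defaults: 1000 simulations, 1000 removals, seeded.
* MR-RAPS solves the profile-score equation by minimizing the profile
  objective on an expanding bracket (the score itself vanishes at ±∞, so
  naive root bracketing can fail); the overdispersion variance τ² solves
  the companion moment equation, floored at zero, alternating with the
  slope; the Huber constant is 1.345 and the SE is a sandwich estimate.
* Leave-one-out flags exclusions that flip the sign or move the estimate
  by more than one full-sample **fixed-effect** SE; the random-effects
  SE is itself inflated by the outlier under test and would mask exactly
  the influence being screened for.

## The synthetic GWAS generator

`simulate_gwas()` emulates a modern two-sample setting: a large exposure
GWAS (default n = 500k, as for lipid consortia) and a smaller outcome
GWAS (n = 60k, as for NMR metabolomics panels), allele frequencies
Uniform(0.05, 0.95), SEs 1/√(2p(1−p)n), and per-SNP noncentralities
Uniform(0.5, 1.5) × mean F (default mean F = 200). This regime matches
an instrument set selected at genome-wide significance — every F is far
above the weak-instrument threshold of 20 — and keeps IVW in the regime
it is designed for (verified: bias ≈ −0.002 on a planted effect of 0.5,
95% CI coverage ≈ 0.955). Directional pleiotropy is planted **relative
to the exposure-increasing allele**: that is how the Egger intercept
defines it, and pleiotropy planted in raw allele coding would be
balanced away by orientation. Outlier displacement is specified in units
of the SNP's outcome SE, so "a 10σ outlier" is literal.
`simulate_network_gwas()` builds the six association tables of a
mediation triplet (exposure and mediator instrument sets against all
three traits) under a planted chain with defaults α = 0.127, β = 0.494,
total effect 0.217 — the visceral-fat / fasting-TG / GlycA regime, with
mediated proportion ≈ 29% — and a null reverse path.

## Network MR

Each mediation path is an IVW fit (the conventional headline estimator;
others are available per edge through the `mr_*` functions), with
per-edge heterogeneity, Egger-intercept and instrument-F diagnostics
attached. The mediated effect is exactly α·β and the proportion α·β/γ;
its SE is the first-order delta method. No uncertainty convention for
the mediated proportion is standard, so the delta-method SE is clearly
an extension, retained alongside the full-precision fraction. Only
single-mediator chains are supported.

## Problem sizes used by the test suite

The suite exercises: IVW bias/coverage at J = 50 over 500 replicates;
Egger-intercept recovery of planted pleiotropy 0.05 over 500 replicates;
MR-PRESSO power and null behavior over 100 replicates each at 1000
simulations; RAPS–IVW agreement over 50 replicates; path-coefficient
recovery at n = 10⁵; Levene size over 2000 null replicates; network-MR
proportion recovery over 200 replicates; and a 10⁶-draw Monte-Carlo
oracle for the cohort's planted correlations. These sizes were chosen so
Monte-Carlo error is comfortably below each tolerance while the whole
suite stays around five minutes on one core.

## Known limitations

* The cohort generator is linear-Gaussian; heavy tails, heteroscedastic
  assay noise and twin relatedness are not represented.
* Harmonization has no strand inference beyond the palindromic EAF rule
  and no proxy-SNP lookup.
* The path-model fitter targets recursive (acyclic) systems with
  uncorrelated residuals; non-recursive models and residual covariances
  among endogenous nodes are rejected by specification.
* MR assumes independent instruments; correlated instruments require
  LD-aware methods that are out of scope here.
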