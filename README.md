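# ppimr

Postprandial inflammation analysis with path models and Mendelian
randomization.

After a mixed-nutrient meal, circulating glucose and triglycerides (TG)
rise and fall on very different time courses, and both excursions feed an
acute inflammatory response. GlycA — a composite NMR signal from the
glycan groups of acute-phase glycoproteins — is a stable, clinically
relevant inflammation biomarker that responds to meals, unlike most
cytokines; IL-6 rises postprandially but largely independently of the
metabolic response. `ppimr` is a pipeline for dissecting this system in
metabolic-challenge cohorts (sequential breakfast/lunch meals, dense 0–6 h
blood sampling, GlycA and IL-6 at 0/4/6 h): it featurizes the
concentration curves, characterizes the inflammatory response,
ranks its metabolic predictors, fits manifest-variable path models, and
estimates causal effects from GWAS summary statistics with a from-scratch
two-sample and network Mendelian-randomization (MR) toolkit. Because
individual-level cohort data of this kind are access-controlled, the
package ships seeded generators for a synthetic cohort and synthetic GWAS
summary statistics with planted ground truth, so every stage is testable
end to end.

It is aimed at nutrition / cardiometabolic epidemiologists and
biostatisticians who want the full chain — curve → feature → association →
causal decomposition — in one tested, reproducible package.

## What it computes

**Curve features** (per participant, on sampled points only): fasting
value; incremental AUC over a window, the positive-increment trapezoid

&nbsp;&nbsp;&nbsp;&nbsp;iAUC = Σᵢ ½·(max(cᵢ−c₀,0) + max(cᵢ₊₁−c₀,0))·(tᵢ₊₁−tᵢ);

rises from fasting at 30/60 min (glucose) and 6 h (TG); windowed maxima
Cmax with their times Tmax — first (0–2 h) and second (4–6 h) glucose
peaks, 0–6 h TG peak.

**Characterization**: responder fractions (6 h > fasting), percent
changes, cross-sectional CV = 100·sd/mean, Levene's variance-heterogeneity
test, feature–marker Pearson correlation grids, and mixed repeated-measures
ANOVA interactions with sex or age group.

**Prediction**: cross-validated random forests with Q² = 1 − PRESS/TSS,
multivariable OLS with standardized β and variance inflation factors,
percentile-cutoff ROC analysis with DeLong confidence intervals.

**Path analysis**: maximum-likelihood fitting of a recursive linear system
on observed variables, minimizing
F = log|Σ(θ)| + tr(SΣ(θ)⁻¹) − log|S| − p, with χ² = (n−1)F and the
CFI / TLI / RMSEA fit panel.

**Two-sample MR** on harmonized summary statistics: per-SNP Wald ratios
β̂ⱼ = Γ̂ⱼ/γ̂ⱼ; IVW β̂ = Σwⱼβ̂ⱼ/Σwⱼ with wⱼ = γ̂ⱼ²/σ²_Γⱼ (fixed and
multiplicative-random-effects); MR-Egger regression with the pleiotropy
intercept; Cochran's Q and Rücker's Q′; MR-PRESSO global, outlier and
distortion tests; MR-RAPS profile-score estimation with optional
overdispersion and Huber loss; leave-one-out; instrument F statistics.

**Network MR**: the α/β/γ mediation decomposition — mediated effect α·β,
mediated proportion α·β/γ with a delta-method SE — plus a reverse-path
bidirectionality check.

## Worked example

```r
library(ppimr)

dat <- simulate_cohort(cohort_config(seed = 42))
#> <cohort_dataset> 1000 participants, 18000 curve samples, 6000 marker values (seed 42)

feats <- extract_curve_features(dat$curves)
responder_summary(dat$markers, "GlycA")[, c("fraction_rising", "pct_rise")]
#>   fraction_rising pct_rise
#> 1           0.606     4.93
```

60.6% of simulated participants show a postprandial GlycA rise, and the
cohort-mean 6-h increase is 4.9% — the planted "modest mean shift, large
interindividual spread" regime. Which curve feature drives the 6-h GlycA
level?

```r
g6 <- dplyr::filter(dat$markers, marker == "GlycA", time_h == 6)
md <- dplyr::inner_join(feats,
        dplyr::select(g6, participant_id, glyca_6h = value),
        by = "participant_id")
rf_rank(md[feature_names()], md$glyca_6h, seed = 42)
#> <rf_report> R2 (in-sample) = 0.943, Q2 (CV) = 0.680 [n = 1000, 500 trees, 5 folds]
#>   feature    importance  share  rank
#> 1 tg_at_6h        24.6  0.323      1
#> 2 tg_max          14.6  0.192      2
#> 3 tg_fasting      10.9  0.144      3
```

The forest recovers the planted structure: the TG value at the matching
time point dominates, glycemic features rank far below, and the
cross-validated Q² of 0.68 says about two thirds of the 6-h GlycA variance
is genuinely predictable from the metabolic response.

```r
gw <- simulate_network_gwas(network_gwas_config(seed = 42))
run_network_mr(gw$exp_exposure, gw$exp_mediator, gw$exp_outcome,
               gw$med_mediator, gw$med_exposure, gw$med_outcome)
#> <network_mr> IVW path estimates (random model)
#>   path                                   beta     se        p n_snp
#> 1 alpha (exposure -> mediator)        0.102   0.0103 2.24e-23    50
#> 2 beta (mediator -> outcome)          0.482   0.0127 0           50
#> 3 gamma (total, exposure -> outcome)  0.217   0.0103 1.43e-98    50
#> 4 reverse (mediator -> exposure)     -0.00798 0.0103 4.37e- 1    50
#> mediated effect 0.102 x 0.482 = 0.0494; proportion 0.228 (22%)
```

The triplet was simulated with a visceral-fat → fasting-TG → GlycA chain
(planted α = 0.127, β = 0.494, total effect γ = 0.217, mediated proportion
≈ 29%). One 50-SNP realization recovers the decomposition within sampling
error — here 22%, with individual estimates within roughly two standard
errors of their planted values — and the reverse mediator → exposure edge
is correctly null (p = 0.44).

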