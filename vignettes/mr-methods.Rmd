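---
title: "Mendelian randomization for adiposity and mental health: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mendelian randomization for adiposity and mental health}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipomr)
```

## The problem

Observationally, higher adiposity is associated with depression, anxiety
and lower well-being, but those associations are confounded (deprivation,
smoking, reverse causation through illness-related weight change, and so
on). Mendelian randomization (MR) uses genetic variants as instrumental
variables: alleles are allocated at random at conception, so a variant
that raises BMI is — under the instrumental-variable assumptions —
independent of the confounders of the BMI–depression relationship and can
identify a causal effect.

`adipomr` implements the full analysis pipeline such a study runs:

1. **Observational regressions** of each mental-health outcome on the
   inverse-normalized exposure, adjusted for covariates (the baseline
   against which MR estimates are contrasted).
2. **One-sample MR** by two-stage least squares (2SLS) with a weighted
   genetic risk score (GRS) as the instrument.
3. **Two-sample MR** on per-SNP summary statistics: Wald ratios combined
   by multiplicative random-effects IVW, with MR-Egger, weighted median
   and penalized weighted median as pleiotropy-robust sensitivity
   estimators, plus Cochran's Q and the Egger intercept as diagnostics.
4. **Non-linear MR**: local average causal effects (LACE) in deciles of
   the IV-free exposure, integrated into a continuity-constrained
   piecewise-linear causal curve, with heterogeneity and quadratic
   non-linearity tests.

Because the individual-level data such studies use are access-restricted,
the package ships a synthetic-cohort generator with known generative
truth. Every estimator in the package is validated by parameter recovery
against that truth; this vignette records the models, the defaults, and
the design decisions.

## The generative model

`simulate_cohort()` draws, for `n` individuals and `M` SNPs:

* genotypes `g_ij ~ Binomial(2, MAF_j)` with `MAF_j ~ U(0.05, 0.5)`,
  independent across SNPs (no LD): the instruments this design emulates
  are pre-pruned genome-wide-significant loci, so LD modelling would add
  nothing testable;
* a standard-normal confounder `U`;
* exposure `x_i = Σ_j γ_j g_ij + a U_i + ε_i`, standardized to mean 0,
  SD 1, with the per-allele effects `γ_j` scaled so that the genetic
  score explains exactly `exposure_h2` of the exposure variance (using
  the Hardy–Weinberg variance `2 MAF (1 − MAF)` per SNP). The default
  `exposure_h2 = 0.016` mirrors a 72-SNP BMI instrument set explaining
  1.6% of BMI variance; weak favourable/unfavourable-adiposity-like
  instrument classes use 0.002 and 0.006. A raw scale
  (mean 26.8, SD 4.6 kg/m²) is attached for reporting;
* outcome latent scale `η_i = f(x_i) + b U_i + Σ_j α_j g_ij + ε_i` with
  unit residual SD. `f` is linear (`θx`), quadratic (`θx²`, the U-shape
  probe) or threshold. Continuous outcomes are `η` itself; binary
  outcomes are Bernoulli through `logistic(c0 + η)` with `c0` solved by
  bisection so the mean prevalence hits the target (tolerance 1e-4 on
  the mean predicted probability, relative to the prevalence). The
  default prevalence 0.018 matches a current-depression-like rare
  outcome. The logistic liability link is used because the estimand of
  interest is an odds ratio;
* direct (pleiotropic) SNP–outcome effects `α_j`: zero (`none`),
  mean-zero normal (`balanced`), nonzero-mean normal independent of `γ`
  (`directional`, which respects InSIDE), or
  `α_j = ρ γ_j + noise` (`inside_violating`, the standard construction
  for demonstrating Egger bias);
* covariates (age, sex, centre, deprivation, smoking) drawn
  independently of genotype, with an optional sex-specific causal slope,
  so adjusted and stratified analyses can be contrasted against
  unadjusted ones.

Everything is seeded; an identical configuration reproduces a cohort
bit-for-bit, and each stage derives its stream from the master seed by a
fixed offset so stages can be re-run independently.

**What the simulator does not emulate**: linkage disequilibrium,
relatedness, population structure, genotyping error, item-level
questionnaire structure, or missing data. Passing recovery tests on these
cohorts therefore demonstrates the estimators' correctness under the
models' own assumptions, not robustness to those real-data complications.

## Phenotype preparation and observational stage

Exposures are inverse-normal transformed before analysis
(`inverse_normal_transform()`), so all effects are per 1 SD of exposure.
The rank-based transform uses the Blom offset,
`z = Φ⁻¹((r − 3/8)/(n + 1/4))`, with average ranks for ties: the offset
flavour is a convention, chosen once for determinism; any monotone
transform of the input yields identical output.

`fit_observational()` fits logistic (binary) or linear (continuous)
regression of outcome on exposure plus an arbitrary adjustment set
(default: age, sex, centre, deprivation, smoking; sex-stratified fits
drop sex). Perfect separation or non-convergence withholds the estimate
with an explicit status rather than returning a silent number. Mutual
adjustment of correlated outcomes (depression/anxiety) is expressed by
naming one outcome in the other's adjustment set.

## Instruments

`build_grs()` computes `score_i = Σ_j w_j d_ij` with *external* discovery
weights, flipping dosages (`d → 2 − d`) where the weight's effect allele
is the genotype's other allele; unresolvable variants are excluded with a
logged reason. External weights avoid winner's-curse bias; for simulated
cohorts the generating `γ_j` play that role. The score is standardized
for regression use, which also makes it invariant to simultaneous
allele-label flips with weight negation.

`harmonize()` aligns exposure and outcome summary statistics to the
exposure-raising allele convention. Palindromic (A/T, C/G) variants with
effect-allele frequency in [0.42, 0.58] are excluded as strand-ambiguous;
this conservative standard window is adopted even though a single-cohort
design never faces strand ambiguity, because the two-sample module also
accepts user-supplied external summary files. Harmonization is a normal
form: applying it twice equals applying it once, and every input variant
is accounted for exactly once (retained or excluded with a reason).

Instrument strength is summarized by the variance explained and
`F = R²(n − 2)/(1 − R²)`; `F < 10` raises a weak-instrument flag that
propagates onto estimates.

## One-sample MR

`tsls()` is the two-stage least-squares estimator: exposure on GRS
(stage 1), outcome on the stage-1 fitted values (stage 2), covariates in
both stages when supplied (the standard 2SLS contract). For continuous
outcomes the SE is recomputed from the structural residuals
`y − Xβ̂` with the observed exposure — the proper 2SLS variance, not the
naive stage-2 one. For binary outcomes the second stage is logistic on
fitted values; its model SE is reported with the known caveats
(plug-in uncertainty ignored, odds ratios non-collapsible), and a seeded
individual-resampling bootstrap SE (default 1000 draws) is available
because no analytic SE is exact for this estimator. With a single
instrument and linear stages, `tsls()` equals `cov(g, y)/cov(g, x)` to
machine precision, which is the oracle its tests use.

Sensitivity analyses reuse the same estimator: `run_exclusion_sensitivity()`
re-runs it on a declaratively selected subset (e.g. excluding medication
users) and logs retained/excluded counts;
`recode_case_subtype()` splits cases into subtype-vs-controls and
remaining-cases-vs-controls outcomes (the atypical-depression pattern).

## Two-sample MR

Per-variant Wald ratios `θ_j = Γ̂_j/γ̂_j` carry first-order delta SEs
`se_j = se(Γ̂_j)/|γ̂_j|`, consistent with the NOME assumption (the
SNP-exposure associations treated as measured without error); a
second-order option that propagates `se(γ̂_j)` exists behind a flag.

* **IVW** combines ratios with weights `1/se_j²`. "Random effects" is
  implemented as the multiplicative model — SE inflated by
  `max(1, √(Q/(k−1)))` — which is the MR-standard choice among the
  random-effects variants.
* **MR-Egger** is the weighted regression of `Γ̂` on `γ̂` with a free
  intercept (weights `1/se(Γ̂)²`), on the exposure-raising orientation.
  The slope is consistent under InSIDE even with all variants
  pleiotropic; the intercept is the directional-pleiotropy test. Both
  SEs receive the same multiplicative inflation with `k − 2` df.
  P-values are normal by default (common MR practice); a t-reference
  with `k − 2` df is available. A design where all exposure betas are
  equal is flagged as collinear and the slope withheld.
* **Weighted median**: sort ratios, form cumulative normalized-weight
  midpoints `s_j = Σ_{i<j} p_i + p_j/2`, interpolate at `s = 0.5`.
  Consistent while valid instruments hold > 50% of weight. The
  **penalized** variant first downweights by the Cochran's Q
  contribution, `w'_j = w_j min(1, 20 P(χ²₁ > q_j))`; the penalty
  constant 20 follows the original construction and is exposed as a
  parameter. SEs for both come from a seeded parametric bootstrap
  (betas resampled from normal(observed, SE), default 1000 draws); the
  bootstrap is parametric rather than nonparametric because the
  estimator's input is the summary table itself.

Two properties worth noting, both exercised by the test suite: the
median's robustness guarantee is asymptotic in instrument precision —
when per-ratio sampling noise is comparable to the pleiotropic offsets,
the weighted median is pulled toward the contaminated side like any
quantile of an overlapping mixture — and two-sample IVW built from two
modest disjoint halves of one cohort is attenuated toward the null by
weak-instrument regression dilution (the expected factor is
`Σγ² / (Σγ² + Σse(γ̂)²)`, i.e. roughly `F/(F+1)` at mean per-SNP F).
Neither is an implementation artifact; both are properties of the
estimators themselves and are visible in the recovery experiments at
their stated sample sizes.

## Non-linear MR

`iv_free_exposure()` residualizes the exposure on the GRS and re-centres
at the exposure mean: the residual is exactly orthogonal to the
instrument, so stratifying on it (unlike on the exposure itself) does not
induce collider bias. `stratify_exposure()` forms equal-count strata —
deciles by default, the pre-specified choice — with deterministic
tie-breaking by stable rank.

Within each stratum, the LACE is the ratio of the IV–outcome slope
(logistic for binary outcomes, so LACEs are log-odds per exposure unit)
to the IV–exposure slope, each re-estimated within the stratum (the
denominators are *not* borrowed from the full sample; a shared
denominator is a different estimator and is deliberately not the
default). The SE is first-order delta on the numerator. A stratum is
flagged and its LACE withheld when it has fewer than 30 individuals,
fewer than 10 cases (binary), a non-convergent logistic fit, or a
denominator slope indistinguishable from zero (p > 0.05) — a near-zero
denominator makes the ratio arbitrarily unstable, and reporting it would
be noise.

`piecewise_curve()` integrates the LACE slopes into a continuous curve:
value at knot `k` is `Σ_{j≤k} lace_j × width_j`, referenced to 0 at the
first knot, so continuity holds *by construction* and is asserted, not
estimated. Pointwise 95% bands come from a bootstrap that resamples
individuals within strata (preserving stratum sizes), 500 draws by
default, seeded. Two tests summarize non-linearity: Cochran's Q across
LACEs (χ², S − 1 df) and a quadratic test that meta-regresses LACEs on
stratum mean exposures with inverse-variance weights.

## Pipeline and reporting

`run_pipeline()` executes the full matrix (instrument sets × outcomes ×
strata × methods) from one seeded `run_config()`; any failing cell is
caught and recorded as a row with status `error` (or `withheld` when a
guard withheld the result) rather than aborting the matrix. Outputs are
tidy TSVs plus a manifest with an md5 config hash, so a rerun under the
same configuration is byte-identical — numeric formatting in the writers
is fixed for exactly that reason. Nominal p-values are reported
throughout, matching the analysis design this package mirrors; an
optional, clearly-labelled Bonferroni column is available in
`report_results()`.

## Numerical choices and problem sizes

* Logistic fits: IRLS tolerance 1e-8, iteration cap 100; non-convergence
  is an explicit error or flag, never a silent result.
* Per-SNP GWAS scans are closed-form (linear) or batched IRLS
  (logistic), unit-tested for equality with `lm()`/`glm()` at 1e-6.
* Liability intercept: bisection, tolerance 1e-4 (relative to the
  prevalence) on the mean predicted probability.
* The recovery experiments in the test suite use cohorts of 20 000–40 000
  individuals and 72 SNPs with replicate counts between 100 and 2000,
  chosen so each experiment's Monte-Carlo error is small relative to the
  effect it checks while the whole suite stays desk-scale; the
  full-cohort preset (n = 145 668) is exercised where only a single
  realization is needed (e.g. prevalence calibration, the F-statistic).
* For the median-robustness experiment the per-variant outcome SE is set
  small (0.002) so ratio noise is well below the pleiotropic offsets —
  the regime in which the median's breakdown guarantee operates (see the
  two-sample section for why).
* The quadratic-power experiment uses `f(x) = 0.1 x²`: a closed-form
  power calculation at decile strata of a standard-normal exposure with
  n = 20 000 and h² = 0.016 puts the meta-regression slope near
  3.5 standard errors, i.e. comfortably above 80% power, which is why
  that effect size was fixed in advance.

## Known limitations

* Logistic-stage 2SLS SEs are approximate (see above); use the bootstrap
  option when the SE matters.
* The two-sample module assumes the two samples are independent; the
  split-sample construction guarantees this in simulation, but
  user-supplied overlapping GWAS would violate it silently.
* No LD-aware modelling, no MR-PRESSO/mode-based estimators, no
  multivariable MR, and no fractional-polynomial non-linear curve (the
  piecewise-linear function is the only non-linear method, by design).
* Covariate adjustment of the within-stratum non-linear regressions is
  exposed via the building blocks but off by default; LACE units follow
  whatever exposure scale is passed in and are echoed in the output.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_individuals = 20000, seed = 1,
                  causal_coef = 0.405, outcome_kind = "binary")
coh <- simulate_cohort(cfg)
grs <- cohort_grs(coh)
instrument_strength(grs, coh$exposure)
tsls(coh, "y")
h <- harmonize(cohort_to_summary_stats(coh, "y"))
mr_ivw(wald_ratios(h), scale = "log-odds per SD exposure")
mr_egger(h, scale = "log-odds per SD exposure")
```
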