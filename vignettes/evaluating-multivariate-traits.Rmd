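---
title: "Evaluating multivariate traits for genetic discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multivariate traits for genetic discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemeval)
```

## The problem

A learned embedding of high-content data is a multivariate quantitative
trait. Running GWAS on its dimensions can produce many genome-wide
significant (GWS) associations, but an association with an embedding
dimension is not evidence that the variant matters for any disease. This
package separates the two questions:

* **Heritability** — how much genetic signal does the trait carry?
* **Disease relevance** — do the variants associated with the trait
  improve prediction of a gold-standard disease label?

Both are computed from the same two-cohort design: a *discovery* cohort
(GWAS, clumping, polygenic-score weights) and a disjoint *evaluation*
cohort (scoring and the relevance test). The split is strict; no
evaluation subject ever influences a weight.

## Model and assumptions

### Orthogonalization

Embedding dimensions are correlated, so their per-dimension Wald
statistics are not independent. `fit_pca()` is fit on the discovery cohort
(standardized columns by default — embedding scales are arbitrary) and
both cohorts are projected with the stored centering, scaling and
loadings. Eigenvector signs are fixed deterministically (largest-magnitude
loading positive). A sign flip negates the component's GWAS betas and its
score weights coherently, so the combined statistic and the relevance
evaluation are unaffected. The number of components m is user-chosen
(`select_m()`: fixed, default 5, or a cumulative-variance threshold); the
automated choice of m is deliberately simple because downstream results
are reported per choice of m, not optimized over it.

### Per-component GWAS and the combined statistic

`run_gwas()` fits ordinary least squares per variant with an intercept and
optional covariates. Wald p-values use the standard-normal reference — the
asymptotic argument that justifies combining the statistics — rather than
the t reference; at the sample sizes where GWAS is meaningful the two are
indistinguishable, and at toy sizes (n of a few dozen) the normal
reference is mildly anti-conservative. Missing dosages are mean-imputed
per variant (the standard convention; it keeps n constant across
variants); zero-variance variants are reported with beta 0 and p 1 and
flagged. No mixed-model or relatedness adjustment is provided: the
intended cohorts are unrelated subjects, with ancestry PCs entering as
ordinary covariates.

With orthogonal components, `combine_stats()` forms T = sum of squared
Wald statistics, referred to a central chi-square with m degrees of
freedom. Orthogonality is what licenses the sum; the package asserts
component orthogonality at fit time rather than estimating a correlation
correction.

### Clumping and heritability metrics

`clump()` is the standard greedy procedure: visit significant variants in
ascending p order; each unpruned one becomes an index variant and prunes
its in-window, high-R² partners. Ties in p are broken by (chromosome,
position, id) so results are identical across platforms. Defaults:
p1 = 5e-8, R² > 0.1, window 250 kb — the R² threshold is the stricter of
the two community conventions and the window is the common default; both
are parameters because no single choice suits all LD structures.
`heritability_metrics()` then reports the number of clumped GWS hits and
the mean/median of T at those hits. Heritability clumping uses the
multivariate p-values; score building uses per-component p-values, because
a variant can be GWS in aggregate yet not GWS for any single component —
in that case no per-component score exists and the relevance test is
reported "not evaluable" rather than silently run on nothing.

### Polygenic scores and the relevance test

`build_weights()` takes each component's clumped GWS index variants with
their estimated betas; `score_prs()` computes plain weighted dosage sums
(weights are reported with respect to the effect allele; an allele-swapped
variant is scored on the complemented dosage under the `flip` policy).
Scores are z-standardized inside `relevance_test()` for numerical
stability; every reported metric and p-value is invariant to positive
affine rescaling of predictors, so this is cosmetic.

`relevance_test()` compares the full GLM (scores + covariates) with the
reduced GLM (covariates) on in-sample prediction metrics: r² and MAE for
continuous outcomes, AUROC (pairwise concordance, ties at one half) and
AUPRC (average precision — conventions for interpolated PR curves differ,
so the step-wise integral is used and documented) for binary outcomes. The
contrast is a ratio by default, matching how such comparisons are
conventionally tabulated; the two-sided exceedance is computed on the log
scale because a raw ratio is not sign-symmetric. The null is built by
permuting the score rows *once, jointly* — destroying only the
score-outcome link while preserving inter-score correlation — then
drawing B bootstrap resamples and refitting both models on each. A
re-permute-per-resample variant is available (`permute_per_resample`) for
sensitivity analysis; the single-permutation reading is the default.
Logistic fits that separate fall back to a weakly ridge-penalized IRLS
(lambda 1e-6, intercept unpenalized) so a resampling loop never aborts;
the fallback is flagged.

**Known limitation — the test is conservative.** Under the null, the
observed contrast is itself an in-sample improvement from adding
uninformative predictors (in-sample full-model fit never falls below the
reduced model), and the bootstrap null contrasts carry that same
improvement plus resampling variance. The null distribution therefore
stochastically dominates the observed contrast, and the realized type-I
error at alpha = 0.05 is far below 0.05 (empirically ~0 across hundreds
of replicate null datasets, at several sample sizes and under both
permutation variants). The test never over-rejects; a significant result
can be trusted, but near-threshold p-values are not uniformly calibrated.
The package reports the procedure as defined rather than recalibrating it.

## The simulator

`simulate_dataset()` generates the validation conditions: dosages
Binomial(2, MAF) with MAF ~ U(0.05, 0.5), independent across variants
(linkage equilibrium), placed 400 kb apart so every pair falls outside the
default clump window by construction. Components follow the infinitesimal
model Z_k = G_k beta_k + eps_k with beta_k ~ N(0, h²/n_k I) on
standardized causal dosages (realized sample mean/sd) and
eps_k ~ N(0, 1 − h²); causal sets are disjoint across components, making
the expected inter-component correlation exactly zero, which is why the
generated components stand in for already-orthogonalized embedding PCs and
the pipeline's PCA stage is skipped (`orthogonalize = FALSE`) when
analysing them — rerunning PCA on two near-unit-variance, near-orthogonal
columns is an arbitrary rotation that adds nothing. The liability is
Y = sum_k gamma_k Z_k + gamma_A age + gamma_S sex + eps, eps ~ N(0,1),
with gamma_c = sqrt(f_c / f_eps) so each standardized component's share of
Var(Y) equals its configured fraction f_c; age is U(40, 69) (a typical
biobank recruitment range) and sex Bernoulli(1/2). Three scenarios:
`high_high` (as generated), `high_low` (Y permuted within each cohort),
`low_low` (each Z column and Y independently permuted within each cohort).
All randomness flows from one master seed through named substreams, so a
configuration identifies a dataset exactly.

What the simulator does *not* emulate: LD structure, population
stratification, relatedness, allele-frequency/effect-size coupling, and
binary disease via liability thresholding. Passing tests on these data
therefore validate the statistical machinery — calibration of T under the
null, greedy clumping against an exhaustive oracle, OLS against closed
forms, heritability recovery, scenario ordering — but say nothing about
robustness to LD or confounding in real cohorts.

## Study conditions used in tests and the acceptance script

The reduced-scale conditions are 5,000 + 5,000 subjects, 2,000 variants,
m = 2 components with h² = 0.2 over n_k = 20 causal variants each, and
liability fractions of 10% for each component, age, and sex, with B = 999.
The per-causal-variant noncentrality is n h²/n_k = 50, i.e. near-saturated
GWS power, chosen to mirror the saturated-power regime of a full-scale
(hundreds of thousands of subjects, n_k = 1000) design at desk scale. In
that regime the scores recover essentially the whole genetic component of
each Z_k, so the expected full/reduced r² ratio is
(0.20 + 2 × 0.02) / 0.20 = 1.20 and the expected MAE ratio is
sqrt(0.76 / 0.80) ≈ 0.97; the high/high replicates concentrate there, the
high/low scenario reproduces the same hit count with non-significant
relevance, and the low/low scenario yields zero hits (expected false
positives ≈ 2000 × 5e-8 per component) and a "not evaluable" relevance
row. Quantities that depend on a specific biobank's LD and panel — e.g. a
particular hit count in the thousands or a particular mean chi-square —
are functions of that cohort and are not reproduced here.

Numerical choices worth knowing: clump ties broken lexicographically;
zero-variance predictions get r² = 0 by convention; a phenotype fully
explained by covariates short-circuits to beta = 0, p = 1 for all
variants; the PLINK 1 writer refuses fractional dosages (the format cannot
encode them); and subject order is canonicalized by sorted id everywhere,
so aligning already-aligned inputs is a no-op.

```{r, eval = FALSE}
cfg <- sim_config(scenario = "high_high", seed = 1)
ds  <- simulate_dataset(cfg)
run <- run_pipeline(ds$discovery, ds$evaluation,
                    trait_cols = c("PC1", "PC2"),
                    orthogonalize = FALSE, seed = 1)
summary(run)
```
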