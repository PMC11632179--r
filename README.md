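# gemeval

Genetic evaluation of multivariate traits and embeddings.

Machine-learning embeddings of high-content data (imaging, molecular
profiles) are increasingly used as quantitative traits in genome-wide
association studies (GWAS). An embedding can be highly heritable — yielding
many genome-wide significant (GWS) loci — and still tell you nothing about
the disease you care about. `gemeval` evaluates a multivariate trait on the
two axes separately, for statistical geneticists and ML researchers deciding
*which* embedding to carry into genetic discovery:

**Heritability.** Given K trait dimensions, the components are
orthogonalized (PCA fit on the discovery cohort). For each component k a
univariate GWAS is run per variant G,

    PC_k = beta_k G + gamma_k' X + eps,

giving Wald statistics Z_k = beta_k / SE(beta_k). Because the components
are orthogonal, the Z_k are asymptotically independent standard normal
under the null, so

    T = sum_{k=1}^m Z_k^2  ~  chi^2_m

is a multivariate test of "G is associated with at least one component".
After greedy LD clumping (per region, keep only the lowest-p variant;
prune partners with R^2 above threshold inside the window), heritability is
summarized by the number of independent GWS hits (p <= 5e-8) and the mean
and median chi-square at those hits.

**Disease relevance.** For each component, the clumped GWS variants and
their betas define a polygenic score PRS_i = sum_j beta_j G_ij, computed on
a held-out evaluation cohort. A full GLM (all per-component PRSs +
covariates) is compared with a reduced GLM (covariates only) on prediction
metrics — squared correlation and mean absolute error for continuous
outcomes, AUROC and average-precision AUPRC for binary ones — via a
contrast Delta (full/reduced ratio by default). Significance comes from a
permutation-plus-bootstrap null: permute the PRS rows once (jointly), draw
B bootstrap resamples, refit both models on each, and report

    p = (1 + #{|Delta_b| >= |Delta_obs|}) / (1 + B),

so the smallest attainable p is 1/(1+B) (0.001 at the default B = 999).

The package also ships the infinitesimal-model simulator used to validate
that the two axes are disentangled: variants in linkage equilibrium,
components Z_k = G_k beta_k + eps_k with beta_k ~ N(0, h^2/n_k I), and a
liability Y in which each component, age, and sex explain configurable
variance fractions, under three scenarios (high/high, high/low, low/low
heritability/relevance).

## Worked example

```r
library(gemeval)

cfg <- sim_config(n_discovery = 5000, n_evaluation = 5000, n_variants = 2000,
                  m_pcs = 2, h2 = 0.2, n_causal = 20,
                  scenario = "high_high", seed = 7)
ds  <- simulate_dataset(cfg)
run <- run_pipeline(ds$discovery, ds$evaluation, trait_cols = c("PC1", "PC2"),
                    orthogonalize = FALSE, seed = 7)
print(run)
```

```
gemeval run
  5000 discovery / 5000 evaluation subjects, 2000 variants, m = 2
Heritability evaluation
  GWS hits (p <= 5e-08, clumped): 20
  mean chi2 at hits:   100.063
  median chi2 at hits: 76.095
Disease-relevance test (permutation + bootstrap)
  family: linear, contrast: ratio, B = 999, n = 5000, PRS columns = 2
  r2     full 0.2404  reduced 0.2120  ratio 1.1341  p = 0.001
  mae    full 0.8939  reduced 0.9122  ratio 0.9800  p = 0.001
```

Reading it: 20 independent loci reach genome-wide significance for the
combined two-component test, with a mean chi-square of 100 at those loci
(strong per-locus signal). On the held-out cohort, adding the two
per-component polygenic scores raises the liability-prediction r² from
0.212 to 0.240 (ratio 1.13) and lowers the MAE (ratio 0.98); both
improvements sit at the permutation floor p = 0.001 — this embedding is
both heritable and disease relevant. Under the `low_low` scenario the same
pipeline reports 0 hits and a "not evaluable" relevance test.

A thin command-line wrapper is installed at `inst/scripts/gemeval`
(`simulate`, `run-all`, `compare` subcommands over YAML configs).

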