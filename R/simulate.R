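#' Simulation configuration
#'
#' Describes the generative architecture used to validate that heritability
#' and disease relevance are disentangled: variants in linkage equilibrium,
#' embedding components from a per-component infinitesimal genetic model,
#' and a continuous disease liability in which each component, age, and sex
#' explain fixed fractions of the variance. Three scenarios cover the
#' corners of the two evaluation axes: `high_high` (components heritable and
#' the liability depends on them), `high_low` (liability permuted: the
#' components stay heritable but no longer predict the outcome), and
#' `low_low` (components and liability permuted: neither axis remains).
#'
#' The defaults are the reduced-scale study conditions used throughout the
#' package's tests: 5,000 discovery + 5,000 evaluation subjects, 2,000
#' variants, two components with 20% heritability spread over 20 disjoint
#' causal variants each, and 10% of liability variance per component and
#' per demographic covariate. At this scale the per-causal-variant
#' noncentrality is n h2 / n_k = 50, i.e. near-saturated discovery power,
#' mirroring the saturated-power regime of the full-scale design.
#'
#' @param n_discovery,n_evaluation subject counts for the two disjoint
#'   cohorts.
#' @param n_variants total variant count.
#' @param maf_range minor-allele-frequency interval, within (0, 0.5\].
#' @param m_pcs number of simulated embedding components.
#' @param h2 per-component narrow-sense heritability, in \[0, 1).
#' @param n_causal causal variants per component (disjoint across
#'   components unless `overlap_causal`).
#' @param variance_fractions named list/vector with entries `pc` (length
#'   `m_pcs` or scalar), `age`, `sex`: each element's share of liability
#'   variance; must sum to < 1.
#' @param scenario `"high_high"`, `"high_low"`, or `"low_low"`.
#' @param overlap_causal allow causal sets to overlap across components.
#' @param seed integer master seed; every random draw flows from it through
#'   named substreams.
#' @return An object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_discovery = 5000, n_evaluation = 5000,
                       n_variants = 2000, maf_range = c(0.05, 0.5),
                       m_pcs = 2, h2 = 0.2, n_causal = 20,
                       variance_fractions = list(pc = 0.1, age = 0.1,
                                                 sex = 0.1),
                       scenario = c("high_high", "high_low", "low_low"),
                       overlap_causal = FALSE, seed = 1L) {
  scenario <- match.arg(scenario)
  if (h2 < 0 || h2 >= 1)
    gem_stop("h2 must lie in [0, 1)", "gemeval_validation_error")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    gem_stop("maf_range must lie within (0, 0.5]", "gemeval_validation_error")
  if (!overlap_causal && n_causal * m_pcs > n_variants)
    gem_stop("disjoint causal sets need n_causal * m_pcs <= n_variants",
             "gemeval_validation_error")
  f_pc <- rep(variance_fractions$pc, length.out = m_pcs)
  fr <- c(f_pc, age = variance_fractions$age, sex = variance_fractions$sex)
  if (any(fr < 0) || sum(fr) >= 1)
    gem_stop("variance fractions must be non-negative and sum to < 1",
             "gemeval_validation_error")
  structure(list(n_discovery = n_discovery, n_evaluation = n_evaluation,
                 n_variants = n_variants, maf_range = maf_range,
                 m_pcs = m_pcs, h2 = h2, n_causal = n_causal,
                 f_pc = f_pc, f_age = variance_fractions$age,
                 f_sex = variance_fractions$sex,
                 scenario = scenario, overlap_causal = overlap_causal,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Named substreams derived from the master seed: one set.seed() at the
## master seed yields well-separated child seeds, so adding a stage never
## shifts the draws of another.
substream_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, 6L),
           c("genotypes", "effects", "noise", "covariates", "liability",
             "permutation"))
}

#' Simulate genotypes in linkage equilibrium
#'
#' Dosages are drawn Binomial(2, MAF) independently across variants, with
#' MAF uniform in `maf_range`. Variants are placed on one synthetic
#' chromosome at 400 kb spacing, so every pair lies outside any standard
#' clump window — LD pruning is then vacuous by construction, matching the
#' "variants in linkage equilibrium" design.
#'
#' @param n number of subjects.
#' @param n_variants number of variants.
#' @param maf_range MAF interval within (0, 0.5\].
#' @param seed integer seed.
#' @param subject_prefix prefix for generated subject ids.
#' @return A [genotype_matrix()] with attribute `maf` (the drawn per-variant
#'   frequencies).
#' @export
simulate_genotypes <- function(n, n_variants, maf_range = c(0.05, 0.5),
                               seed = 1L, subject_prefix = "S") {
  set.seed(seed)
  maf <- runif(n_variants, maf_range[1], maf_range[2])
  dos <- matrix(rbinom(n * n_variants, 2L, rep(maf, each = n)),
                nrow = n, ncol = n_variants)
  variants <- data.frame(chrom = "1",
                         pos_bp = 400000L * seq_len(n_variants),
                         id = sprintf("rs%06d", seq_len(n_variants)),
                         effect_allele = "A", other_allele = "G",
                         stringsAsFactors = FALSE)
  ids <- sprintf("%s%06d", subject_prefix, seq_len(n))
  g <- genotype_matrix(dos, variants, ids)
  attr(g, "maf") <- maf
  g
}

#' Simulate embedding components under the infinitesimal model
#'
#' For each component k, `n_causal` causal variants are chosen (disjoint
#' across components by default), their dosages standardized to mean 0 and
#' variance 1, effects drawn `beta_k ~ N(0, h2/n_causal I)`, and
#' `Z_k = G_k beta_k + eps_k` with `eps_k ~ N(0, 1 - h2)`. Effect draws are
#' independent across components, so with disjoint causal sets the
#' expected correlation between components is exactly zero — the simulated
#' components play the role of already-orthogonalized embedding PCs.
#'
#' @param genotypes a [genotype_matrix()].
#' @param m_pcs number of components.
#' @param h2 per-component heritability in \[0, 1).
#' @param n_causal causal variants per component.
#' @param seed integer seed.
#' @param overlap_causal allow causal sets to overlap.
#' @return List with `Z` (subjects x m matrix, columns `PC1..PCm`), `causal`
#'   (list of causal variant id vectors), `beta` (list of effect vectors),
#'   `genetic` (subjects x m matrix of true genetic values `G_k beta_k`),
#'   and `realized_h2` (per-component var(genetic)/var(Z)).
#' @export
simulate_pcs <- function(genotypes, m_pcs = 2, h2 = 0.2, n_causal = 20,
                         seed = 1L, overlap_causal = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n <- nrow(genotypes$dosages)
  p <- ncol(genotypes$dosages)
  set.seed(seed)
  usable <- which(apply(genotypes$dosages, 2L, sd) > 0)
  if (length(usable) < (if (overlap_causal) n_causal else n_causal * m_pcs))
    gem_stop("not enough polymorphic variants for the requested causal sets",
             "gemeval_validation_error")
  pool <- sample(usable)
  Z <- matrix(NA_real_, n, m_pcs, dimnames = list(subject_ids(genotypes),
                                                  paste0("PC", seq_len(m_pcs))))
  genetic <- Z
  causal <- vector("list", m_pcs)
  beta <- vector("list", m_pcs)
  realized <- numeric(m_pcs)
  for (k in seq_len(m_pcs)) {
    idx <- if (overlap_causal) sample(usable, n_causal)
           else pool[((k - 1L) * n_causal + 1L):(k * n_causal)]
    Gk <- scale(genotypes$dosages[, idx, drop = FALSE])
    bk <- rnorm(n_causal, 0, sqrt(h2 / n_causal))
    gk <- drop(Gk %*% bk)
    zk <- gk + rnorm(n, 0, sqrt(1 - h2))
    Z[, k] <- zk
    genetic[, k] <- gk
    causal[[k]] <- genotypes$variants$id[idx]
    beta[[k]] <- setNames(bk, genotypes$variants$id[idx])
    realized[k] <- var(gk) / var(zk)
  }
  list(Z = Z, causal = causal, beta = beta, genetic = genetic,
       realized_h2 = realized)
}

#' Simulate a continuous disease liability
#'
#' `Y = sum_k gamma_k Z_k + gamma_A age + gamma_S sex + eps`,
#' `eps ~ N(0, 1)`, with the components, age, and sex standardized and
#' coefficients `gamma_c = sqrt(f_c / f_eps)` (where `f_eps = 1 - sum f_c`)
#' so each component's share of `Var(Y)` equals its configured fraction.
#'
#' @param Z subjects x m matrix of embedding components.
#' @param age,sex numeric vectors (any location/scale; standardized
#'   internally).
#' @param f_pc vector of per-component variance fractions (recycled to m).
#' @param f_age,f_sex variance fractions for age and sex.
#' @param seed integer seed for the residual draw.
#' @return Numeric liability vector.
#' @export
simulate_liability <- function(Z, age, sex, f_pc = 0.1, f_age = 0.1,
                               f_sex = 0.1, seed = 1L) {
  Z <- as.matrix(Z)
  m <- ncol(Z)
  f_pc <- rep(f_pc, length.out = m)
  fr <- c(f_pc, f_age, f_sex)
  f_eps <- 1 - sum(fr)
  if (any(fr < 0) || f_eps <= 0)
    gem_stop("variance fractions must be non-negative and sum to < 1",
             "gemeval_validation_error")
  gam <- sqrt(fr / f_eps)
  set.seed(seed)
  std <- function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  comps <- cbind(apply(Z, 2L, std), std(age), std(sex))
  drop(comps %*% gam) + rnorm(nrow(Z), 0, 1)
}

#' Apply a validation scenario to a simulated dataset
#'
#' `high_high` leaves the dataset unchanged. `high_low` permutes the
#' liability Y across subjects (within the discovery and evaluation cohorts
#' separately), so the components remain heritable but no longer predict
#' the outcome. `low_low` additionally permutes every Z column (independent
#' shuffles) and Y, destroying both the genotype-component and
#' component-outcome links.
#'
#' @param dataset a [simulate_dataset()] result generated under
#'   `high_high`.
#' @param scenario target scenario.
#' @param seed integer seed for the permutations.
#' @return The modified `sim_dataset`.
#' @export
apply_scenario <- function(dataset, scenario = c("high_high", "high_low",
                                                 "low_low"), seed = 1L) {
  scenario <- match.arg(scenario)
  if (scenario == "high_high") {
    dataset$truth$scenario <- scenario
    return(dataset)
  }
  set.seed(seed)
  pc_cols <- grep("^PC", names(dataset$discovery$tables$pheno), value = TRUE)
  for (role in c("discovery", "evaluation")) {
    tab <- dataset[[role]]$tables$pheno
    n <- nrow(tab)
    if (scenario == "low_low")
      for (cl in pc_cols) tab[[cl]] <- tab[[cl]][sample.int(n)]
    tab$Y <- tab$Y[sample.int(n)]
    dataset[[role]]$tables$pheno <- tab
  }
  dataset$truth$scenario <- scenario
  dataset
}

#' Simulate a complete two-cohort validation dataset
#'
#' Generates genotypes, embedding components, demographics (age uniform on
#' 40-69, sex Bernoulli(1/2)) and liability for `n_discovery +
#' n_evaluation` subjects under one master seed, splits them into disjoint
#' discovery and evaluation cohorts, and applies the configured scenario.
#'
#' @param config a [sim_config()].
#' @return An object of class `sim_dataset`: list with `discovery` and
#'   `evaluation` [align_cohort()] bundles (table `pheno` holding
#'   `subject_id, PC1..PCm, age, sex, Y`), `truth` (causal sets, effect
#'   vectors, per-component realized heritability, scenario), and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ss <- substream_seeds(config$seed)
  n <- config$n_discovery + config$n_evaluation
  g <- simulate_genotypes(n, config$n_variants, config$maf_range,
                          seed = ss[["genotypes"]])
  pcs <- simulate_pcs(g, config$m_pcs, config$h2, config$n_causal,
                      seed = ss[["effects"]],
                      overlap_causal = config$overlap_causal)
  set.seed(ss[["covariates"]])
  age <- runif(n, 40, 69)
  sex <- rbinom(n, 1L, 0.5)
  y <- simulate_liability(pcs$Z, age, sex, config$f_pc, config$f_age,
                          config$f_sex, seed = ss[["liability"]])
  pheno <- data.frame(subject_id = subject_ids(g), pcs$Z, age = age,
                      sex = sex, Y = y, stringsAsFactors = FALSE,
                      check.names = FALSE)
  disc_ids <- subject_ids(g)[seq_len(config$n_discovery)]
  eval_ids <- subject_ids(g)[config$n_discovery + seq_len(config$n_evaluation)]
  discovery <- align_cohort(g[match(disc_ids, subject_ids(g)), ],
                            pheno = pheno[pheno$subject_id %in% disc_ids, ],
                            role = "discovery")
  evaluation <- align_cohort(g[match(eval_ids, subject_ids(g)), ],
                             pheno = pheno[pheno$subject_id %in% eval_ids, ],
                             role = "evaluation")
  ds <- structure(list(discovery = discovery, evaluation = evaluation,
                       truth = list(causal = pcs$causal, beta = pcs$beta,
                                    realized_h2 = pcs$realized_h2,
                                    genetic = pcs$genetic,
                                    scenario = "high_high"),
                       config = config),
                  class = "sim_dataset")
  apply_scenario(ds, config$scenario, seed = ss[["permutation"]])
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset (%s): %d + %d subjects, %d variants, %d components\n",
              x$truth$scenario, x$config$n_discovery, x$config$n_evaluation,
              x$config$n_variants, x$config$m_pcs))
  cat(sprintf("  realized per-component h2: %s\n",
              paste(sprintf("%.3f", x$truth$realized_h2), collapse = ", ")))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' PLINK 1 triples (dosages are hard genotype calls, so the encoding is
#' lossless) plus phenotype TSVs per cohort and a truth JSON.
#'
#' @param dataset a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (role in c("discovery", "evaluation")) {
    b <- dataset[[role]]
    write_genotypes(b$genotypes, file.path(dir, role), format = "plink1")
    write.table(b$tables$pheno, file.path(dir, paste0(role, "_pheno.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- list(causal = dataset$truth$causal,
                beta = lapply(dataset$truth$beta, as.list),
                realized_h2 = dataset$truth$realized_h2,
                scenario = dataset$truth$scenario)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
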