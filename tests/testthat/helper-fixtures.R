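# Fixture builders and independent oracles used across the suite.

# Small genotype matrix with controllable positions; dosages drawn in code.
make_toy_genotypes <- function(n = 20, p = 5, seed = 1,
                               chrom = rep("1", p),
                               pos = 1000L * seq_len(p),
                               dosages = NULL) {
  set.seed(seed)
  if (is.null(dosages))
    dosages <- matrix(rbinom(n * p, 2, 0.4), n, p)
  variants <- data.frame(chrom = chrom, pos_bp = pos,
                         id = sprintf("v%03d", seq_len(p)),
                         effect_allele = "A", other_allele = "G",
                         stringsAsFactors = FALSE)
  genotype_matrix(dosages, variants, sprintf("S%03d", seq_len(n)))
}

# Independent per-variant OLS oracle built on stats::lm.
lm_gwas_oracle <- function(y, g, covariates = NULL) {
  p <- ncol(g$dosages)
  out <- data.frame(beta = numeric(p), se = numeric(p))
  for (j in seq_len(p)) {
    df <- data.frame(y = y, g = g$dosages[, j])
    if (!is.null(covariates)) df <- cbind(df, covariates)
    fit <- summary(lm(y ~ ., data = df))
    out$beta[j] <- fit$coefficients["g", "Estimate"]
    out$se[j] <- fit$coefficients["g", "Std. Error"]
  }
  out
}

# Exhaustive greedy clumping reference: repeatedly take the most significant
# unpruned variant, then prune its in-window, high-r2 partners.
oracle_clump <- function(stats, r2_map, p1, r2_threshold, window_kb) {
  pos <- setNames(stats$pos_bp, stats$id)
  chrom <- setNames(stats$chrom, stats$id)
  cand <- stats[stats$p <= p1, , drop = FALSE]
  cand <- cand[order(cand$p, cand$chrom, cand$pos_bp, cand$id), , drop = FALSE]
  pruned <- character()
  index <- character()
  assignments <- character()
  linked <- function(v) {
    hits <- r2_map[(r2_map$id1 == v | r2_map$id2 == v) &
                     r2_map$r2 > r2_threshold, , drop = FALSE]
    partner <- ifelse(hits$id1 == v, hits$id2, hits$id1)
    partner[chrom[partner] == chrom[v] &
              abs(pos[partner] - pos[v]) <= window_kb * 1000]
  }
  for (v in cand$id) {
    if (v %in% pruned) next
    index <- c(index, v)
    for (w in setdiff(linked(v), c(pruned, index))) {
      pruned <- c(pruned, w)
      assignments[w] <- v
    }
  }
  list(index_variants = index, assignments = assignments)
}

# Tiny aligned two-cohort dataset for pipeline tests.
make_toy_dataset <- function(n = 200, p = 50, seed = 42) {
  cfg <- sim_config(n_discovery = n, n_evaluation = n, n_variants = p,
                    m_pcs = 2, h2 = 0.3, n_causal = 5, seed = seed)
  simulate_dataset(cfg)
}
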