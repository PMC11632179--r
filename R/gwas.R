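#' Univariate GWAS of one trait component by ordinary least squares
#'
#' Fits, for every variant, the linear model
#' `PC = intercept + beta * dosage + covariates`, and reports the Wald
#' statistic `z = beta / se` with a two-sided p-value from the standard
#' normal reference (the asymptotic distribution of the Wald statistic; at
#' very small n this is slightly anti-conservative relative to the t
#' reference). The implementation residualizes the phenotype and all dosage
#' columns against the covariate design once and then solves each
#' single-variant regression from cross-products, which is algebraically
#' identical to fitting each model separately (Frisch–Waugh–Lovell).
#'
#' Missing dosages are mean-imputed per variant first, so n is constant
#' across variants. Variants with zero dosage variance after imputation
#' carry no information and are emitted with `beta = 0`, `z = 0`, `p = 1`
#' and `flagged = TRUE`.
#'
#' @param phenotype numeric vector (one component's scores), aligned with
#'   the genotype rows.
#' @param genotypes a [genotype_matrix()] for the same subjects, same order.
#' @param covariates optional numeric matrix or data.frame of covariates
#'   (no intercept column; one is prepended). Must be full column rank.
#' @param pc_index integer label carried into the output (which component
#'   this scan belongs to).
#' @return A data.frame of class `gwas_stats` with one row per variant:
#'   `id, chrom, pos_bp, effect_allele, n, beta, se, z, p, flagged`, and
#'   attribute `pc_index`.
#' @export
run_gwas <- function(phenotype, genotypes, covariates = NULL, pc_index = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  y <- as.numeric(phenotype)
  n <- length(y)
  if (n != nrow(genotypes$dosages))
    gem_stop("phenotype length does not match genotype rows",
             "gemeval_validation_error")
  if (anyNA(y))
    gem_stop("phenotype contains missing values", "gemeval_validation_error")
  G <- genotypes$dosages
  if (anyNA(G)) {
    genotypes <- impute_missing_dosages(genotypes)
    G <- genotypes$dosages
  }
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    storage.mode(cv) <- "double"
    if (anyNA(cv))
      gem_stop("covariates contain missing values", "gemeval_validation_error")
    if (is.null(colnames(cv))) colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
    X <- cbind(X, cv)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    gem_stop(paste0("covariate design is rank deficient; collinear column(s): ",
                    paste(bad, collapse = ", ")),
             "gemeval_validation_error")
  }
  if (n < ncol(X) + 2L)
    gem_stop("need at least (number of covariates + 2) subjects",
             "gemeval_validation_error")
  Q <- qr.Q(qx)
  ytil <- y - Q %*% crossprod(Q, y)
  # phenotype fully explained by the covariate design (e.g. constant):
  # nothing left for any variant to explain
  if (sum(ytil^2) <= 1e-14 * max(1, sum(y^2))) ytil[] <- 0
  Gtil <- G - Q %*% crossprod(Q, G)
  gss <- colSums(Gtil^2)
  gy <- as.vector(crossprod(Gtil, ytil))
  df <- n - ncol(X) - 1L
  flagged <- gss < 1e-12
  beta <- ifelse(flagged, 0, gy / ifelse(flagged, 1, gss))
  rss <- pmax(sum(ytil^2) - beta * gy, 0)
  se <- sqrt((rss / df) / ifelse(flagged, NA_real_, gss))
  z <- ifelse(flagged | !is.finite(se) | se == 0, 0, beta / se)
  p <- ifelse(z == 0, 1, 2 * pnorm(-abs(z)))
  out <- data.frame(id = genotypes$variants$id,
                    chrom = genotypes$variants$chrom,
                    pos_bp = genotypes$variants$pos_bp,
                    effect_allele = genotypes$variants$effect_allele,
                    n = n,
                    beta = beta, se = se, z = z, p = p,
                    flagged = flagged | se == 0 | !is.finite(se),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gwas_stats", "data.frame")
  attr(out, "pc_index") <- as.integer(pc_index)
  out
}

#' Per-component GWAS for a matrix of component scores
#'
#' Runs [run_gwas()] for each column of a component score matrix against the
#' same genotypes and covariates. The covariate residualization is shared
#' across components, so this is substantially faster than m separate calls
#' while returning numerically identical results.
#'
#' @param pcs subjects x m matrix of component scores (e.g. from
#'   [predict.pc_model()]).
#' @inheritParams run_gwas
#' @return A list of `gwas_stats`, one per component, named `PC1..PCm`.
#' @export
batch_gwas <- function(pcs, genotypes, covariates = NULL) {
  pcs <- as.matrix(pcs)
  out <- lapply(seq_len(ncol(pcs)), function(k)
    run_gwas(pcs[, k], genotypes, covariates, pc_index = k))
  names(out) <- if (!is.null(colnames(pcs))) colnames(pcs)
                else paste0("PC", seq_len(ncol(pcs)))
  out
}

#' Write univariate summary statistics in PLINK 2 style
#'
#' Columns: `#CHROM POS ID A1 OBS_CT BETA SE T_STAT P`.
#'
#' @param stats a `gwas_stats` data.frame from [run_gwas()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  tab <- data.frame(`#CHROM` = stats$chrom, POS = stats$pos_bp, ID = stats$id,
                    A1 = stats$effect_allele, OBS_CT = stats$n,
                    BETA = stats$beta, SE = stats$se, T_STAT = stats$z,
                    P = stats$p, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
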