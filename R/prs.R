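#' Build a polygenic score weight table for one component
#'
#' Takes the clumped, genome-wide significant index variants of one
#' component's GWAS and uses their estimated betas as score weights. A
#' component with no GWS index variant yields an empty table (flagged via
#' attribute `empty`); its relevance evaluation is skipped downstream.
#'
#' @param stats a `gwas_stats` data.frame for one component.
#' @param clumps a [clump()]ed set formed from `stats`.
#' @param gws_p genome-wide significance cutoff (default 5e-8).
#' @return A data.frame of class `weights_table` with columns
#'   `id, effect_allele, weight`, rows ordered by genome position;
#'   attributes `pc_index` and `empty`.
#' @export
build_weights <- function(stats, clumps, gws_p = 5e-8) {
  stopifnot(inherits(clumps, "clumped_set"))
  rows <- match(clumps$index_variants, stats$id)
  rows <- rows[stats$p[rows] <= gws_p]
  rows <- rows[order(stats$chrom[rows], stats$pos_bp[rows], stats$id[rows])]
  out <- data.frame(id = stats$id[rows],
                    effect_allele = stats$effect_allele[rows],
                    weight = stats$beta[rows],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("weights_table", "data.frame")
  attr(out, "pc_index") <- attr(stats, "pc_index")
  attr(out, "empty") <- nrow(out) == 0L
  out
}

#' Score subjects with a polygenic weight table
#'
#' `PRS_i = sum_j weight_j * dosage_ij`, the plain weighted allele-count
#' sum. Under `allele_policy = "flip"`, a weight variant whose alleles are
#' swapped relative to the genotype file is scored on the complemented
#' dosage `2 - g`; under `"strict"` any allele mismatch is an error.
#'
#' @param genotypes a [genotype_matrix()] for the cohort to score (missing
#'   dosages are mean-imputed).
#' @param weights a [build_weights()] table.
#' @param allele_policy `"strict"` or `"flip"`.
#' @return Named numeric vector of scores, one per subject (all zero for an
#'   empty weight table).
#' @export
score_prs <- function(genotypes, weights, allele_policy = c("strict", "flip")) {
  allele_policy <- match.arg(allele_policy)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  ids <- subject_ids(genotypes)
  if (nrow(weights) == 0L)
    return(setNames(numeric(length(ids)), ids))
  j <- match(weights$id, genotypes$variants$id)
  if (anyNA(j))
    gem_stop(paste0("weight variant(s) absent from genotypes: ",
                    paste(weights$id[is.na(j)], collapse = ", ")),
             "gemeval_validation_error")
  if (anyNA(genotypes$dosages))
    genotypes <- impute_missing_dosages(genotypes)
  G <- genotypes$dosages[, j, drop = FALSE]
  same <- genotypes$variants$effect_allele[j] == weights$effect_allele
  # a swap means the weight's effect allele is the genotype file's other
  # allele, so the dosage is complemented (2 - g)
  swapped <- !same & genotypes$variants$other_allele[j] == weights$effect_allele
  if (any(!same & !swapped))
    gem_stop(paste0("allele mismatch for variant(s): ",
                    paste(weights$id[!same & !swapped], collapse = ", ")),
             "gemeval_validation_error")
  if (any(swapped)) {
    if (allele_policy == "strict")
      gem_stop(paste0("swapped alleles under strict policy: ",
                      paste(weights$id[swapped], collapse = ", ")),
               "gemeval_validation_error")
    G[, swapped] <- 2 - G[, swapped, drop = FALSE]
  }
  drop(G %*% weights$weight)
}

#' Write a weight table as PLINK --score compatible TSV
#'
#' Columns `ID A1 BETA`.
#'
#' @param weights a `weights_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  tab <- data.frame(ID = weights$id, A1 = weights$effect_allele,
                    BETA = weights$weight)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-subject polygenic scores as TSV
#'
#' @param scores subjects x m matrix (or named vector) of scores.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prs <- function(scores, path) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("PRS_PC", seq_len(ncol(scores)))
  tab <- data.frame(subject_id = rownames(scores), scores,
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
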