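#' Construct a genotype dosage matrix
#'
#' The central genotype container: a subjects-by-variants matrix of allele
#' dosages in \[0, 2\] (counts of the effect allele, possibly fractional after
#' imputation, `NA` for missing) together with per-variant metadata. Variants
#' are stored sorted by (chromosome, position); all downstream association,
#' clumping and scoring code assumes this ordering.
#'
#' @param dosages numeric matrix, subjects in rows, variants in columns.
#' @param variants data.frame with columns `chrom` (character), `pos_bp`
#'   (1-based integer position), `id`, `effect_allele`, `other_allele`.
#'   One row per column of `dosages`.
#' @param subject_ids character vector of unique subject identifiers, one per
#'   row of `dosages`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` (dimnames set to subject and variant ids) and `variants`.
#' @export
genotype_matrix <- function(dosages, variants, subject_ids) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  needed <- c("chrom", "pos_bp", "id", "effect_allele", "other_allele")
  missing_cols <- setdiff(needed, names(variants))
  if (length(missing_cols) > 0)
    gem_stop(paste0("variant table lacks column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "gemeval_validation_error")
  variants$chrom <- as.character(variants$chrom)
  variants$pos_bp <- as.integer(variants$pos_bp)
  if (nrow(variants) != ncol(dosages))
    gem_stop(sprintf("dosages have %d variant columns but %d variant records",
                     ncol(dosages), nrow(variants)),
             "gemeval_validation_error")
  if (length(subject_ids) != nrow(dosages))
    gem_stop(sprintf("dosages have %d rows but %d subject ids",
                     nrow(dosages), length(subject_ids)),
             "gemeval_validation_error")
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids))
    gem_stop("duplicated subject ids", "gemeval_validation_error")
  if (anyDuplicated(variants$id))
    gem_stop(paste0("duplicated variant id(s): ",
                    paste(unique(variants$id[duplicated(variants$id)]),
                          collapse = ", ")),
             "gemeval_validation_error")
  rng <- range(dosages, na.rm = TRUE)
  if (!all(is.finite(rng)) && any(!is.na(dosages)))
    gem_stop("non-finite dosage values", "gemeval_validation_error")
  if (any(!is.na(dosages)) && (rng[1] < 0 || rng[2] > 2))
    gem_stop("dosage values outside [0, 2]", "gemeval_validation_error")
  # canonical variant order: (chrom, pos_bp), ids as tie-break
  ord <- order(variants$chrom, variants$pos_bp, variants$id)
  variants <- variants[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  rownames(variants) <- NULL
  dimnames(dosages) <- list(subject_ids, variants$id)
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$variants$chrom), collapse = ", ")))
  nmiss <- sum(is.na(x$dosages))
  if (nmiss > 0) cat(sprintf("  missing dosages: %d\n", nmiss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by subjects and/or variants
#'
#' @param x a [genotype_matrix()].
#' @param i subject selector (indices, logical, or subject ids).
#' @param j variant selector (indices, logical, or variant ids).
#' @param ... ignored.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  if (is.character(j)) j <- match(j, x$variants$id)
  d <- x$dosages[i, j, drop = FALSE]
  v <- x$variants[j, , drop = FALSE]
  genotype_matrix(d, v, rownames(d))
}

#' Subject identifiers of a genotype container
#'
#' @param x a [genotype_matrix()].
#' @return Character vector of subject ids, in storage order.
#' @export
subject_ids <- function(x) UseMethod("subject_ids")

#' @export
subject_ids.genotype_matrix <- function(x) rownames(x$dosages)

#' Impute missing genotype dosages by the per-variant mean
#'
#' Each missing dosage is replaced by the mean dosage of that variant over the
#' non-missing subjects — the standard genome-wide association convention,
#' which keeps the sample size constant across variants. Variants that are
#' all-missing or have zero variance after imputation cannot carry
#' association signal and are flagged for downstream exclusion (all-missing
#' columns are set to dosage 0).
#'
#' @param g a [genotype_matrix()].
#' @return A `genotype_matrix` with no missing values and an attribute
#'   `excluded`: character vector of flagged variant ids.
#' @export
impute_missing_dosages <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  all_missing <- colSums(!is.na(d)) == 0L
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    mu[all_missing] <- 0
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2L]]
  }
  vars <- apply(d, 2L, stats::var)
  excluded <- colnames(d)[all_missing | vars == 0]
  out <- genotype_matrix(d, g$variants, rownames(d))
  attr(out, "excluded") <- excluded
  out
}

#' Align genotypes and subject tables into a cohort bundle
#'
#' Restricts a genotype matrix and one or more subject tables to their common
#' subjects and puts every member in a single canonical order (sorted subject
#' id), so that rows line up exactly across all downstream computations.
#'
#' @param genotypes a [genotype_matrix()].
#' @param ... one or more subject tables: data.frames with a `subject_id`
#'   column (named arguments become the table names in the bundle).
#' @param role cohort role, `"discovery"` or `"evaluation"`.
#' @return An object of class `cohort_bundle`: list with `genotypes`,
#'   `tables` (list of aligned data.frames), `role`, and `dropped` (named
#'   counts of subjects dropped from each input).
#' @export
align_cohort <- function(genotypes, ..., role = c("discovery", "evaluation")) {
  role <- match.arg(role)
  tables <- list(...)
  if (length(tables) == 0)
    gem_stop("at least one subject table is required", "gemeval_validation_error")
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- paste0("table", seq_along(tables))
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (!is.data.frame(tab) || !"subject_id" %in% names(tab))
      gem_stop(sprintf("table '%s' must be a data.frame with a subject_id column", nm),
               "gemeval_validation_error")
    if (anyDuplicated(tab$subject_id))
      gem_stop(sprintf("table '%s' has duplicated subject ids", nm),
               "gemeval_validation_error")
    if (anyDuplicated(names(tab)))
      gem_stop(sprintf("table '%s' has duplicated column names", nm),
               "gemeval_validation_error")
  }
  ids <- Reduce(intersect, c(list(subject_ids(genotypes)),
                             lapply(tables, function(t) as.character(t$subject_id))))
  if (length(ids) == 0)
    gem_stop("no subjects shared across genotypes and tables",
             "gemeval_validation_error")
  ids <- sort(ids)
  dropped <- c(genotypes = nrow(genotypes$dosages) - length(ids),
               vapply(tables, function(t) nrow(t) - length(ids), 0L))
  g <- genotypes[match(ids, subject_ids(genotypes)), ]
  tables <- lapply(tables, function(t) {
    out <- t[match(ids, as.character(t$subject_id)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  structure(list(genotypes = g, tables = tables, role = role,
                 dropped = dropped),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("cohort_bundle (%s): %d subjects, %d variants, %d table(s)\n",
              x$role, nrow(x$genotypes$dosages), ncol(x$genotypes$dosages),
              length(x$tables)))
  invisible(x)
}
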