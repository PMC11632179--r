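#' Combine per-component Wald statistics into a chi-square test
#'
#' Because the components are orthogonal by construction, their per-variant
#' Wald statistics are asymptotically independent standard normal under the
#' null, so `T = sum_k z_k^2` follows a central chi-square with m degrees of
#' freedom. Large T rejects the null that the variant is associated with
#' none of the m components.
#'
#' @param per_pc list of `gwas_stats` (one per component) over the identical
#'   variant set, e.g. from [batch_gwas()].
#' @return A data.frame of class `mv_stats`: `id, chrom, pos_bp, T_stat, p`
#'   with attribute `m` (degrees of freedom).
#' @export
combine_stats <- function(per_pc) {
  if (!is.list(per_pc) || length(per_pc) < 1)
    gem_stop("need at least one per-component summary-statistic set",
             "gemeval_validation_error")
  ref <- per_pc[[1L]]
  for (k in seq_along(per_pc)) {
    ids_k <- per_pc[[k]]$id
    if (!identical(ids_k, ref$id)) {
      diff <- union(setdiff(ids_k, ref$id), setdiff(ref$id, ids_k))
      gem_stop(paste0("variant sets differ across components; symmetric difference: ",
                      paste(head(diff, 10L), collapse = ", "),
                      if (length(diff) > 10L) " ..." else ""),
               "gemeval_validation_error")
    }
  }
  m <- length(per_pc)
  zmat <- vapply(per_pc, function(s) s$z, numeric(nrow(ref)))
  if (is.null(dim(zmat))) zmat <- matrix(zmat, nrow = 1L)
  T_stat <- rowSums(zmat^2)
  out <- data.frame(id = ref$id, chrom = ref$chrom, pos_bp = ref$pos_bp,
                    T_stat = T_stat,
                    p = pchisq(T_stat, df = m, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  class(out) <- c("mv_stats", "data.frame")
  attr(out, "m") <- m
  out
}

#' Pairwise dosage correlation (R-squared) within a genomic window
#'
#' Squared Pearson correlation of dosage vectors for every variant pair on
#' the same chromosome whose positions are at most `window_kb` apart. Pairs
#' involving a zero-variance variant get R-squared 0 (flagged).
#'
#' @param genotypes a [genotype_matrix()] with no missing dosages (run
#'   [impute_missing_dosages()] first).
#' @param window_kb window half-width in kilobases (default 250).
#' @return A data.frame of class `r2_map` with columns `id1, id2, r2`
#'   (each unordered pair once) and attribute `window_kb`.
#' @export
pairwise_r2 <- function(genotypes, window_kb = 250) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (anyNA(genotypes$dosages))
    gem_stop("dosages contain missing values; impute first",
             "gemeval_validation_error")
  v <- genotypes$variants
  window_bp <- window_kb * 1000
  n <- nrow(genotypes$dosages)
  pieces <- list()
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    if (length(idx) < 2L) next
    pos <- v$pos_bp[idx]  # already sorted within chromosome
    # enumerate only in-window pairs: hi[j] = last variant within window of j
    hi <- findInterval(pos + window_bp, pos)
    a <- rep.int(seq_along(idx), pmax(hi - seq_along(idx), 0L))
    b <- sequence(pmax(hi - seq_along(idx), 0L)) + a
    if (length(a) == 0L) next
    d <- genotypes$dosages[, idx, drop = FALSE]
    ctr <- sweep(d, 2L, colMeans(d))
    ss <- sqrt(colSums(ctr^2))
    num <- numeric(length(a))
    chunk <- max(1L, floor(5e6 / n))  # bound the pairwise working set
    for (s0 in seq(1L, length(a), by = chunk)) {
      s1 <- min(s0 + chunk - 1L, length(a))
      num[s0:s1] <- colSums(ctr[, a[s0:s1], drop = FALSE] *
                              ctr[, b[s0:s1], drop = FALSE])
    }
    den <- ss[a] * ss[b]
    r2 <- ifelse(den > 0, (num / den)^2, 0)  # zero-variance partners -> 0
    pieces[[ch]] <- data.frame(id1 = v$id[idx[a]], id2 = v$id[idx[b]],
                               r2 = r2, stringsAsFactors = FALSE)
  }
  out <- if (length(pieces)) do.call(rbind, pieces)
         else data.frame(id1 = character(), id2 = character(), r2 = numeric())
  rownames(out) <- NULL
  class(out) <- c("r2_map", "data.frame")
  attr(out, "window_kb") <- window_kb
  out
}

#' Greedy LD clumping of summary statistics
#'
#' Iterates significant variants (p <= `p1`) in ascending p order; each not
#' already pruned becomes an index variant, and all remaining variants
#' within `window_kb` with R-squared above `r2_threshold` to it are pruned
#' and assigned to it — so per LD region only the most significant variant
#' is retained. Ties in p are broken by (chrom, pos, id) for determinism.
#'
#' @param stats an `mv_stats` or `gwas_stats` data.frame (needs columns
#'   `id, chrom, pos_bp, p`).
#' @param r2_map output of [pairwise_r2()] over the same variants.
#' @param p1 significance cutoff for entering the clump procedure
#'   (default 5e-8).
#' @param r2_threshold R-squared above which a variant is pruned
#'   (default 0.1).
#' @param window_kb maximum distance for pruning, in kb (default 250).
#' @return An object of class `clumped_set`: list with `index_variants`
#'   (ordered by ascending p) and `assignments` (named character vector
#'   mapping each pruned id to its index id).
#' @export
clump <- function(stats, r2_map, p1 = 5e-8, r2_threshold = 0.1,
                  window_kb = 250) {
  ord <- order(stats$p, stats$chrom, stats$pos_bp, stats$id)
  sel <- ord[stats$p[ord] <= p1]
  pos <- setNames(stats$pos_bp, stats$id)
  chrom <- setNames(stats$chrom, stats$id)
  pvals <- setNames(stats$p, stats$id)
  # adjacency: partners exceeding the r2 threshold, within the window
  nb <- list()
  if (nrow(r2_map) > 0) {
    keep <- r2_map$r2 > r2_threshold &
      chrom[r2_map$id1] == chrom[r2_map$id2] &
      abs(pos[r2_map$id1] - pos[r2_map$id2]) <= window_kb * 1000
    rm2 <- r2_map[keep, , drop = FALSE]
    if (nrow(rm2) > 0) {
      edges <- rbind(data.frame(a = rm2$id1, b = rm2$id2),
                     data.frame(a = rm2$id2, b = rm2$id1))
      nb <- split(edges$b, edges$a)
    }
  }
  pruned <- character()
  assignments <- character()
  index <- character()
  for (i in sel) {
    vid <- stats$id[i]
    if (vid %in% pruned) next
    index <- c(index, vid)
    partners <- setdiff(nb[[vid]], c(pruned, index))
    if (length(partners)) {
      pruned <- c(pruned, partners)
      assignments[partners] <- vid
    }
  }
  structure(list(index_variants = index, assignments = assignments,
                 p1 = p1, r2_threshold = r2_threshold,
                 window_kb = window_kb, p_values = pvals),
            class = "clumped_set")
}

#' @export
print.clumped_set <- function(x, ...) {
  cat(sprintf("clumped_set: %d index variant(s), %d pruned (p1 = %g, r2 > %g, window %g kb)\n",
              length(x$index_variants), length(x$assignments),
              x$p1, x$r2_threshold, x$window_kb))
  invisible(x)
}

#' Heritability metrics from clumped multivariate statistics
#'
#' The number of independent genome-wide significant (GWS) index variants
#' gauges the trait's heritability; their mean and median combined
#' chi-square gauges signal strength (a higher mean chi-square means a
#' smaller sample suffices for discovery). With zero hits the mean and
#' median are undefined and reported as `NA`.
#'
#' @param stats an `mv_stats` (or `gwas_stats`) data.frame.
#' @param clumps a [clump()]ed set produced from `stats` at `p1 >= gws_p`.
#' @param gws_p genome-wide significance cutoff (default 5e-8).
#' @return An object of class `heritability_report`: list with
#'   `n_gws_hits`, `mean_chi2`, `median_chi2`, `gws_threshold`.
#' @export
heritability_metrics <- function(stats, clumps, gws_p = 5e-8) {
  stopifnot(inherits(clumps, "clumped_set"))
  if (clumps$p1 < gws_p)
    gem_stop("clumps were formed at p1 below the GWS cutoff",
             "gemeval_validation_error")
  stat_col <- if ("T_stat" %in% names(stats)) "T_stat" else "z"
  rows <- match(clumps$index_variants, stats$id)
  gws <- rows[stats$p[rows] <= gws_p]
  tvals <- if (stat_col == "z") stats$z[gws]^2 else stats$T_stat[gws]
  structure(list(n_gws_hits = length(gws),
                 mean_chi2 = if (length(gws)) mean(tvals) else NA_real_,
                 median_chi2 = if (length(gws)) median(tvals) else NA_real_,
                 gws_threshold = gws_p),
            class = "heritability_report")
}

#' @export
print.heritability_report <- function(x, ...) {
  cat("Heritability evaluation\n")
  cat(sprintf("  GWS hits (p <= %g, clumped): %d\n", x$gws_threshold,
              x$n_gws_hits))
  if (x$n_gws_hits > 0) {
    cat(sprintf("  mean chi2 at hits:   %.3f\n", x$mean_chi2))
    cat(sprintf("  median chi2 at hits: %.3f\n", x$median_chi2))
  } else {
    cat("  mean/median chi2: - (no hits)\n")
  }
  invisible(x)
}

#' Write multivariate summary statistics as TSV
#'
#' Columns: `#CHROM POS ID T_STAT DF P`.
#'
#' @param stats an `mv_stats` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mv_stats <- function(stats, path) {
  tab <- data.frame(`#CHROM` = stats$chrom, POS = stats$pos_bp, ID = stats$id,
                    T_STAT = stats$T_stat, DF = attr(stats, "m"), P = stats$p,
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a clump report in PLINK .clumped style
#'
#' One row per index variant with its p-value and an `SP2` column listing
#' the pruned members assigned to it (`NONE` if none).
#'
#' @param clumps a `clumped_set`.
#' @param stats the statistics the clumps were formed from.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clumped <- function(clumps, stats, path) {
  idx <- clumps$index_variants
  rows <- match(idx, stats$id)
  sp2 <- vapply(idx, function(v) {
    mem <- names(clumps$assignments)[clumps$assignments == v]
    if (length(mem)) paste(mem, collapse = ",") else "NONE"
  }, character(1))
  tab <- data.frame(`#CHROM` = stats$chrom[rows], POS = stats$pos_bp[rows],
                    ID = idx, P = stats$p[rows], SP2 = sp2,
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
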