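#' Run the end-to-end genetic evaluation workflow
#'
#' Orchestrates the two evaluation axes over a discovery/evaluation cohort
#' pair: (optionally) orthogonalize the trait columns by PCA on the
#' discovery cohort; per-component GWAS on discovery; combine the Wald
#' statistics into the chi-square test, clump by LD, and compute
#' heritability metrics; then per-component clumping, weight building and
#' polygenic scoring of the evaluation cohort; and finally the
#' permutation-plus-bootstrap disease-relevance test. Discovery subjects
#' never enter the relevance evaluation and evaluation subjects never enter
#' GWAS or clumping.
#'
#' @param discovery,evaluation [align_cohort()] bundles whose first (or
#'   named `pheno`) table carries the trait, covariate and outcome columns.
#'   Subject sets must be disjoint.
#' @param trait_cols character vector naming the multivariate trait
#'   (embedding) columns.
#' @param outcome_col name of the disease/outcome column in the evaluation
#'   table.
#' @param gwas_covariate_cols covariate columns for the GWAS model (default
#'   none).
#' @param relevance_covariate_cols covariate columns for the relevance
#'   models (default `c("age", "sex")`).
#' @param family `"linear"` or `"logistic"` relevance models.
#' @param orthogonalize fit a PCA on the discovery traits and analyse its
#'   components (default `TRUE`); set `FALSE` when the trait columns are
#'   already orthogonal components (as the simulator's are).
#' @param standardize passed to [fit_pca()].
#' @param m_policy,m_value component-count policy, see [select_m()].
#' @param gws_p genome-wide significance cutoff (default 5e-8).
#' @param r2_threshold,window_kb clumping parameters (defaults 0.1, 250).
#' @param B bootstrap resamples for the relevance test (default 999).
#' @param contrast `"ratio"` or `"difference"` metric contrast.
#' @param seed integer seed for the relevance test resampling.
#' @param out_dir optional directory; when given, all intermediates
#'   (summary statistics, clump reports, weights, scores, reports and a run
#'   manifest) are written there.
#' @return An object of class `gemeval_run`: list with `heritability`
#'   (a [heritability_metrics()] report), `relevance` (a [relevance_test()]
#'   object), `mv_stats`, `per_pc_stats`, `weights`, `prs`, `m`,
#'   `pc_model` (when orthogonalizing), `manifest`, and echoed parameters.
#' @export
run_pipeline <- function(discovery, evaluation, trait_cols,
                         outcome_col = "Y",
                         gwas_covariate_cols = NULL,
                         relevance_covariate_cols = c("age", "sex"),
                         family = c("linear", "logistic"),
                         orthogonalize = TRUE, standardize = TRUE,
                         m_policy = c("fixed", "variance_threshold"),
                         m_value = NULL,
                         gws_p = 5e-8, r2_threshold = 0.1, window_kb = 250,
                         B = 999, contrast = c("ratio", "difference"),
                         seed = 1L, out_dir = NULL) {
  family <- match.arg(family)
  m_policy <- match.arg(m_policy)
  contrast <- match.arg(contrast)
  stopifnot(inherits(discovery, "cohort_bundle"),
            inherits(evaluation, "cohort_bundle"))
  if (length(intersect(subject_ids(discovery$genotypes),
                       subject_ids(evaluation$genotypes))) > 0)
    gem_stop("discovery and evaluation subject sets must be disjoint",
             "gemeval_validation_error")
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  tick <- function(name, start) {
    stages[[name]] <<- round(proc.time()[["elapsed"]] - start, 3)
  }
  get_tab <- function(b) {
    if ("pheno" %in% names(b$tables)) b$tables$pheno else b$tables[[1L]]
  }
  disc_tab <- get_tab(discovery)
  eval_tab <- get_tab(evaluation)

  ## stage 1: orthogonalization
  s <- proc.time()[["elapsed"]]
  pc_model <- NULL
  if (orthogonalize) {
    pc_model <- fit_pca(disc_tab[, trait_cols, drop = FALSE],
                        standardize = standardize)
    m <- if (is.null(m_value)) min(5L, pc_model$K)
         else select_m(pc_model, m_policy, m_value)
    pcs_disc <- predict(pc_model, disc_tab[, trait_cols, drop = FALSE], m = m)
  } else {
    m <- length(trait_cols)
    pcs_disc <- as.matrix(disc_tab[, trait_cols, drop = FALSE])
    colnames(pcs_disc) <- paste0("PC", seq_len(m))
  }
  tick("orthogonalize", s)

  ## stage 2: per-component GWAS on discovery
  s <- proc.time()[["elapsed"]]
  gw_cov <- if (length(gwas_covariate_cols))
    disc_tab[, gwas_covariate_cols, drop = FALSE] else NULL
  gdisc <- impute_missing_dosages(discovery$genotypes)
  per_pc <- batch_gwas(pcs_disc, gdisc, gw_cov)
  tick("gwas", s)

  ## stage 3: combine, clump, heritability
  s <- proc.time()[["elapsed"]]
  mv <- combine_stats(per_pc)
  r2m <- pairwise_r2(gdisc, window_kb = window_kb)
  mv_clumps <- clump(mv, r2m, p1 = gws_p, r2_threshold = r2_threshold,
                     window_kb = window_kb)
  herit <- heritability_metrics(mv, mv_clumps, gws_p = gws_p)
  tick("heritability", s)

  ## stage 4: per-component weights and evaluation-cohort scores
  s <- proc.time()[["elapsed"]]
  geval <- impute_missing_dosages(evaluation$genotypes)
  weights <- vector("list", m)
  prs <- matrix(0, nrow(geval$dosages), m,
                dimnames = list(subject_ids(geval),
                                paste0("PRS_PC", seq_len(m))))
  for (k in seq_len(m)) {
    cl_k <- clump(per_pc[[k]], r2m, p1 = gws_p,
                  r2_threshold = r2_threshold, window_kb = window_kb)
    weights[[k]] <- build_weights(per_pc[[k]], cl_k, gws_p = gws_p)
    if (!attr(weights[[k]], "empty"))
      prs[, k] <- score_prs(geval, weights[[k]])
  }
  tick("prs", s)

  ## stage 5: relevance test on evaluation
  s <- proc.time()[["elapsed"]]
  rel_cov <- if (length(relevance_covariate_cols))
    eval_tab[, relevance_covariate_cols, drop = FALSE] else NULL
  relevance <- relevance_test(eval_tab[[outcome_col]], prs, rel_cov,
                              family = family, B = B, contrast = contrast,
                              seed = seed)
  tick("relevance", s)

  manifest <- list(package_version = as.character(packageVersion("gemeval")),
                   seed = seed, gws_p = gws_p, r2_threshold = r2_threshold,
                   window_kb = window_kb, B = B, contrast = contrast,
                   family = family, m = m,
                   n_discovery = nrow(gdisc$dosages),
                   n_evaluation = nrow(geval$dosages),
                   n_variants = ncol(gdisc$dosages),
                   stage_seconds = stages,
                   total_seconds = round(proc.time()[["elapsed"]] - t0, 3))
  run <- structure(list(heritability = herit, relevance = relevance,
                        mv_stats = mv, per_pc_stats = per_pc,
                        weights = weights, prs = prs, m = m,
                        pc_model = pc_model, manifest = manifest,
                        eval_subject_ids = subject_ids(geval)),
                   class = "gemeval_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.gemeval_run <- function(x, ...) {
  cat("gemeval run\n")
  cat(sprintf("  %d discovery / %d evaluation subjects, %d variants, m = %d\n",
              x$manifest$n_discovery, x$manifest$n_evaluation,
              x$manifest$n_variants, x$m))
  print(x$heritability)
  print(x$relevance)
  invisible(x)
}

#' @export
summary.gemeval_run <- function(object, ...) {
  print(object)
  cat("  stage seconds:",
      paste(names(object$manifest$stage_seconds),
            unlist(object$manifest$stage_seconds), sep = "=",
            collapse = ", "), "\n")
  invisible(object)
}

## One flat summary row in the conventional reporting layout
## (relevance ratios and p-values, then hit count and mean chi2).
run_summary_row <- function(run, label = "trait") {
  h <- run$heritability
  r <- run$relevance
  row <- data.frame(trait = label,
                    metric1_ratio = NA_real_, metric1_p = NA_real_,
                    metric2_ratio = NA_real_, metric2_p = NA_real_,
                    n_hits = h$n_gws_hits, mean_chi2 = h$mean_chi2,
                    stringsAsFactors = FALSE)
  if (isTRUE(r$evaluable)) {
    row$metric1_ratio <- r$metrics$delta_obs[1L]
    row$metric1_p <- r$metrics$p_value[1L]
    row$metric2_ratio <- r$metrics$delta_obs[2L]
    row$metric2_p <- r$metrics$p_value[2L]
    names(row)[2:5] <- c(paste0(r$metrics$metric[1L], "_ratio"),
                         paste0(r$metrics$metric[1L], "_p"),
                         paste0(r$metrics$metric[2L], "_ratio"),
                         paste0(r$metrics$metric[2L], "_p"))
  }
  row
}

#' Compare completed runs on the two evaluation axes
#'
#' One row per run with its heritability metrics (hit count, mean
#' chi-square) and relevance metrics (contrasts and p-values; `NA` where a
#' run was not evaluable). No composite ranking is computed: traits are
#' reported on both axes, because greater heritability does not imply
#' greater disease relevance.
#'
#' @param runs list of `gemeval_run` objects over the same evaluation
#'   cohort.
#' @param labels optional character labels, one per run.
#' @return A data.frame, one row per run.
#' @export
compare_embeddings <- function(runs, labels = NULL) {
  if (length(runs) < 2L)
    gem_stop("need at least two runs to compare", "gemeval_validation_error")
  if (is.null(labels)) labels <- paste0("trait", seq_along(runs))
  ids <- lapply(runs, `[[`, "eval_subject_ids")
  for (i in seq_along(ids)[-1L])
    if (!identical(ids[[i]], ids[[1L]]))
      gem_stop("runs were made on different evaluation cohorts",
               "gemeval_validation_error")
  rows <- Map(run_summary_row, runs, labels)
  nm <- names(rows[[1L]])
  rows <- lapply(rows, function(r) { names(r) <- nm; r })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Persist a run's artifacts: summary statistics per component,
## multivariate statistics, clump report, weights, scores, reports and a
## manifest with per-file checksums.
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (k in seq_along(run$per_pc_stats)) {
    f <- file.path(dir, sprintf("gwas_PC%d.tsv", k))
    write_summary_stats(run$per_pc_stats[[k]], f)
    files <- c(files, f)
    if (!attr(run$weights[[k]], "empty")) {
      fw <- file.path(dir, sprintf("weights_PC%d.tsv", k))
      write_weights(run$weights[[k]], fw)
      files <- c(files, fw)
    }
  }
  f <- file.path(dir, "mv_stats.tsv")
  write_mv_stats(run$mv_stats, f)
  files <- c(files, f)
  f <- file.path(dir, "prs.tsv")
  write_prs(run$prs, f)
  files <- c(files, f)
  h <- run$heritability
  f <- file.path(dir, "heritability.json")
  jsonlite::write_json(list(n_gws_hits = h$n_gws_hits,
                            mean_chi2 = h$mean_chi2,
                            median_chi2 = h$median_chi2,
                            gws_threshold = h$gws_threshold),
                       f, auto_unbox = TRUE, digits = NA, na = "null")
  files <- c(files, f)
  r <- run$relevance
  f <- file.path(dir, "relevance.json")
  rel <- if (isTRUE(r$evaluable))
    list(evaluable = TRUE, contrast = r$contrast_type, B = r$B,
         seed = r$seed, metrics = r$metrics)
  else list(evaluable = FALSE)
  jsonlite::write_json(rel, f, auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  files <- c(files, f)
  manifest <- run$manifest
  manifest$files <- lapply(setNames(files, basename(files)), function(fp)
    list(path = fp, md5 = unname(tools::md5sum(fp))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
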