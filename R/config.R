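#' Read a YAML/JSON run configuration
#'
#' A configuration either carries a `simulation` block (fields of
#' [sim_config()]) or an `inputs` block naming genotype file sets and
#' phenotype tables for the discovery and evaluation cohorts, plus the
#' pipeline options of [run_pipeline()] (`trait_cols`, `outcome_col`,
#' covariate columns, `family`, `gws_p`, `B`, `seed`, ...).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return The configuration as a named list (class `gemeval_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    gem_stop(paste0("no such config file: ", path), "gemeval_format_error")
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  structure(cfg, class = c("gemeval_config", "list"))
}

#' Execute a full run from a configuration
#'
#' @param config a list from [read_run_config()] (or constructed in code).
#' @param out_dir optional output directory passed to [run_pipeline()].
#' @param verbose log stage progress to stderr.
#' @return The `gemeval_run` object.
#' @export
run_from_config <- function(config, out_dir = NULL, verbose = FALSE) {
  log_msg <- function(...) if (verbose) message("[gemeval] ", sprintf(...))
  if (!is.null(config$simulation)) {
    sc <- config$simulation
    log_msg("simulating dataset (scenario %s)",
            sc$scenario %||% "high_high")
    cfg <- sim_config(
      n_discovery = sc$n_discovery %||% 5000,
      n_evaluation = sc$n_evaluation %||% 5000,
      n_variants = sc$n_variants %||% 2000,
      maf_range = unlist(sc$maf_range %||% c(0.05, 0.5)),
      m_pcs = sc$m_pcs %||% 2,
      h2 = sc$h2 %||% 0.2,
      n_causal = sc$n_causal %||% 20,
      variance_fractions = sc$variance_fractions %||%
        list(pc = 0.1, age = 0.1, sex = 0.1),
      scenario = sc$scenario %||% "high_high",
      seed = sc$seed %||% config$seed %||% 1L)
    ds <- simulate_dataset(cfg)
    discovery <- ds$discovery
    evaluation <- ds$evaluation
    trait_cols <- config$trait_cols %||% paste0("PC", seq_len(cfg$m_pcs))
    orthogonalize <- config$orthogonalize %||% FALSE
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    fmt <- inp$format %||% "plink1"
    log_msg("reading cohorts")
    load_cohort <- function(role) {
      g <- read_genotypes(inp$genotypes[[role]], format = fmt)
      tab <- read.table(inp$pheno[[role]], header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE, check.names = FALSE)
      align_cohort(g, pheno = tab, role = role)
    }
    discovery <- load_cohort("discovery")
    evaluation <- load_cohort("evaluation")
    trait_cols <- config$trait_cols
    if (is.null(trait_cols))
      gem_stop("config must name trait_cols for file inputs",
               "gemeval_validation_error")
    orthogonalize <- config$orthogonalize %||% TRUE
  } else {
    gem_stop("config needs a 'simulation' or an 'inputs' block",
             "gemeval_validation_error")
  }
  log_msg("running pipeline")
  run_pipeline(
    discovery, evaluation, trait_cols = trait_cols,
    outcome_col = config$outcome_col %||% "Y",
    gwas_covariate_cols = config$gwas_covariate_cols,
    relevance_covariate_cols = config$relevance_covariate_cols %||%
      c("age", "sex"),
    family = config$family %||% "linear",
    orthogonalize = orthogonalize,
    standardize = config$standardize %||% TRUE,
    m_policy = config$m_policy %||% "fixed",
    m_value = config$m_value,
    gws_p = config$gws_p %||% 5e-8,
    r2_threshold = config$r2_threshold %||% 0.1,
    window_kb = config$window_kb %||% 250,
    B = config$B %||% 999,
    contrast = config$contrast %||% "ratio",
    seed = config$seed %||% 1L,
    out_dir = out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Thin dispatcher used by the installed `gemeval` script
#' (`inst/scripts/gemeval`). Subcommands:
#' \describe{
#'   \item{simulate}{`--config sim.yaml --out dir` — write a simulated
#'     dataset (PLINK triples, phenotype TSVs, truth JSON).}
#'   \item{run-all}{`--config run.yaml --out dir` — execute the full
#'     workflow and write all intermediates, reports and a manifest.}
#'   \item{compare}{`--runs dir1,dir2,... --out file.tsv` — tabulate the
#'     summary rows of completed runs.}
#' }
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Exit status (0 on success), invisibly.
#' @export
gemeval_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: gemeval <simulate|run-all|compare> [options]\n",
    "  simulate --config sim.yaml --out DIR [--verbose]\n",
    "  run-all  --config run.yaml --out DIR [--verbose]\n",
    "  compare  --runs DIR1,DIR2[,...] --out FILE\n")
  if (length(args) < 1L) {
    cat(usage)
    return(invisible(1L))
  }
  cmd <- args[1L]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 0) default else args[i[1L] + 1L]
  }
  verbose <- "--verbose" %in% args
  if (cmd == "simulate") {
    cfg <- read_run_config(opt("--config"))
    sc <- cfg$simulation %||% cfg
    config <- sim_config(
      n_discovery = sc$n_discovery %||% 5000,
      n_evaluation = sc$n_evaluation %||% 5000,
      n_variants = sc$n_variants %||% 2000,
      maf_range = unlist(sc$maf_range %||% c(0.05, 0.5)),
      m_pcs = sc$m_pcs %||% 2, h2 = sc$h2 %||% 0.2,
      n_causal = sc$n_causal %||% 20,
      variance_fractions = sc$variance_fractions %||%
        list(pc = 0.1, age = 0.1, sex = 0.1),
      scenario = sc$scenario %||% "high_high",
      seed = sc$seed %||% 1L)
    ds <- simulate_dataset(config)
    write_sim_dataset(ds, opt("--out", "."))
    if (verbose) message("[gemeval] wrote simulated dataset to ",
                         opt("--out", "."))
    return(invisible(0L))
  }
  if (cmd == "run-all") {
    cfg <- read_run_config(opt("--config"))
    run <- run_from_config(cfg, out_dir = opt("--out"), verbose = verbose)
    print(run)
    return(invisible(0L))
  }
  if (cmd == "compare") {
    dirs <- strsplit(opt("--runs", ""), ",")[[1L]]
    rows <- lapply(dirs, function(d) {
      h <- jsonlite::read_json(file.path(d, "heritability.json"),
                               simplifyVector = TRUE)
      r <- jsonlite::read_json(file.path(d, "relevance.json"),
                               simplifyVector = TRUE)
      data.frame(trait = basename(d),
                 metric1_ratio = if (isTRUE(r$evaluable)) r$metrics$delta_obs[1] else NA,
                 metric1_p = if (isTRUE(r$evaluable)) r$metrics$p_value[1] else NA,
                 metric2_ratio = if (isTRUE(r$evaluable)) r$metrics$delta_obs[2] else NA,
                 metric2_p = if (isTRUE(r$evaluable)) r$metrics$p_value[2] else NA,
                 n_hits = h$n_gws_hits,
                 mean_chi2 = if (is.null(h$mean_chi2)) NA else h$mean_chi2)
    })
    out <- do.call(rbind, rows)
    dest <- opt("--out")
    if (is.null(dest)) print(out)
    else write.table(out, dest, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(0L))
  }
  cat(usage)
  invisible(1L)
}
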