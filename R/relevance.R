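## Disease-relevance evaluation: does the set of per-component polygenic
## scores improve prediction of a disease label over covariates alone?
## Full model:    g{E(D | PRS, X)} = sum_k beta_k PRS_k + gamma' X
## Reduced model: g{E(D | X)}      = gamma' X
## Significance via a permutation-plus-bootstrap null: permute the PRS rows
## once (jointly, preserving inter-score correlation), then refit both
## models on B bootstrap resamples and compare contrasts.

## Fit a linear or logistic model and return in-sample predictions.
## Logistic fits that fail to converge or separate perfectly fall back to a
## weakly ridge-penalized IRLS (lambda 1e-6) so resampling loops never abort.
fit_and_predict <- function(y, X, family = c("linear", "logistic")) {
  family <- match.arg(family)
  if (family == "linear") {
    fit <- lm.fit(X, y)
    return(list(pred = drop(X %*% ifelse(is.na(fit$coefficients), 0,
                                         fit$coefficients)),
                separation = FALSE))
  }
  if (!all(y %in% c(0, 1)))
    gem_stop("logistic family requires labels coded {0,1}",
             "gemeval_validation_error")
  if (length(unique(y)) < 2L)
    gem_stop("logistic family requires both classes present",
             "gemeval_validation_error")
  sep <- FALSE
  fit <- withCallingHandlers(
    tryCatch(stats::glm.fit(X, y, family = stats::binomial()),
             error = function(e) NULL),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  bad <- is.null(fit) || !fit$converged || sep ||
    any(!is.finite(fit$coefficients))
  if (bad) {
    co <- ridge_logistic(X, y, lambda = 1e-6)
    eta <- drop(X %*% co)
    return(list(pred = stats::plogis(eta), separation = TRUE))
  }
  list(pred = fit$fitted.values, separation = FALSE)
}

## Ridge-penalized logistic regression by IRLS; intercept unpenalized
## (assumed to be column 1). Small fixed lambda keeps coefficients finite
## under perfect separation while leaving well-posed fits essentially
## unchanged.
ridge_logistic <- function(X, y, lambda = 1e-6, maxit = 100L, tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(rep(lambda, p))
  pen[1L, 1L] <- 0
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  drop(beta)
}

#' Prediction-performance metrics for the relevance evaluation
#'
#' Binary labels: area under the ROC curve by the pairwise-concordance
#' (Mann-Whitney) definition with ties counted one half, and area under the
#' precision-recall curve by the average-precision (step-wise integral)
#' definition. Continuous labels: squared Pearson correlation and mean
#' absolute error. A zero-variance prediction against a continuous label is
#' given r2 = 0 by convention.
#'
#' @param d observed labels (numeric; \{0,1\} for binary).
#' @param dhat predictions (probabilities or fitted values).
#' @param family `"linear"` or `"logistic"`.
#' @return Named numeric vector: `r2, mae` (linear) or `auroc, auprc`
#'   (logistic).
#' @export
prediction_metrics <- function(d, dhat, family = c("linear", "logistic")) {
  family <- match.arg(family)
  if (length(d) != length(dhat))
    gem_stop("label and prediction lengths differ", "gemeval_validation_error")
  if (family == "linear") {
    r2 <- if (sd(dhat) == 0 || sd(d) == 0) 0 else cor(d, dhat)^2
    return(c(r2 = r2, mae = mean(abs(d - dhat))))
  }
  if (!all(d %in% c(0, 1)) || length(unique(d)) < 2L)
    gem_stop("binary metrics need labels in {0,1} with both classes",
             "gemeval_validation_error")
  c(auroc = auroc(d, dhat), auprc = average_precision(d, dhat))
}

## Mann-Whitney AUROC; midranks make ties count 1/2.
auroc <- function(d, score) {
  npos <- sum(d == 1)
  nneg <- sum(d == 0)
  r <- rank(score)
  (sum(r[d == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

## Average precision: sum over score thresholds of precision times the
## recall increment (tied scores enter as one threshold).
average_precision <- function(d, score) {
  ord <- order(score, decreasing = TRUE)
  d <- d[ord]
  score <- score[ord]
  tp <- cumsum(d == 1)
  fp <- cumsum(d == 0)
  last <- !duplicated(score, fromLast = TRUE)  # last row of each tie group
  tp <- tp[last]
  fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(d == 1)
  sum(prec * diff(c(0, rec)))
}

#' Permutation-plus-bootstrap test of polygenic-score disease relevance
#'
#' Compares a full generalized linear model (per-component polygenic scores
#' plus covariates) against a reduced model (covariates alone) for
#' predicting a disease label on a held-out evaluation cohort. The contrast
#' `Delta` (full/reduced ratio by default, difference optionally) of each
#' performance metric is tested against a null built by first permuting the
#' PRS rows jointly — rendering them non-informative while preserving their
#' mutual correlation — then drawing B bootstrap resamples (with
#' replacement), refitting both models on each, and computing the null
#' contrast. The p-value is
#' `p = (1 + #\{|Delta_b| >= |Delta_obs|\}) / (1 + B)`,
#' with the comparison taken on a symmetric scale (log of the ratio when
#' `contrast = "ratio"`, the raw difference otherwise), so its floor is
#' `1/(1+B)`.
#'
#' PRS columns are z-standardized internally for numerical stability; all
#' reported metrics and p-values are invariant to positive affine rescaling
#' of the predictors.
#'
#' @param d disease labels on the evaluation cohort (numeric; \{0,1\} for
#'   `family = "logistic"`).
#' @param prs matrix (or vector) of per-component polygenic scores, rows
#'   aligned with `d`. Zero-variance (empty-weight) columns are dropped; if
#'   none remain the test is not evaluable.
#' @param covariates optional covariate matrix/data.frame (no intercept).
#' @param family `"linear"` (r2 and MAE metrics) or `"logistic"` (AUROC and
#'   AUPRC).
#' @param B number of bootstrap resamples (default 999, giving a p-value
#'   floor of 0.001).
#' @param contrast `"ratio"` (full/reduced, as conventionally reported) or
#'   `"difference"`.
#' @param seed integer seed controlling the permutation and the resamples;
#'   identical seeds give bit-identical reports.
#' @param permute_per_resample re-draw the PRS permutation inside every
#'   bootstrap resample instead of once globally (sensitivity analysis;
#'   default `FALSE`).
#' @return An object of class `relevance_test`: list with `metrics` (a
#'   data.frame with `metric, full, reduced, delta_obs, p_value`),
#'   `null_deltas` (B x n_metrics matrix of null contrasts),
#'   `contrast_type`, `B`, `seed`, `family`, `evaluable`, `n`.
#' @export
relevance_test <- function(d, prs, covariates = NULL,
                           family = c("linear", "logistic"), B = 999,
                           contrast = c("ratio", "difference"), seed = 1L,
                           permute_per_resample = FALSE) {
  family <- match.arg(family)
  contrast <- match.arg(contrast)
  d <- as.numeric(d)
  n <- length(d)
  prs <- as.matrix(prs)
  if (nrow(prs) != n)
    gem_stop("PRS rows do not match label length", "gemeval_validation_error")
  keep <- apply(prs, 2L, sd) > 0
  prs <- prs[, keep, drop = FALSE]
  if (ncol(prs) == 0L) {
    out <- structure(list(metrics = NULL, null_deltas = NULL,
                          contrast_type = contrast, B = B, seed = seed,
                          family = family, evaluable = FALSE, n = n),
                     class = "relevance_test")
    return(out)
  }
  prs <- scale(prs)  # numerical hygiene; metrics are affine invariant
  Xr <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    storage.mode(cv) <- "double"
    if (is.null(colnames(cv))) colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
    Xr <- cbind(Xr, cv)
  }
  Xf <- cbind(Xr, prs)
  if (qr(Xf)$rank < ncol(Xf))
    gem_stop("full-model design is rank deficient", "gemeval_validation_error")

  metric_pair <- function(Xfull, Xred, yy) {
    mf <- prediction_metrics(yy, fit_and_predict(yy, Xfull, family)$pred, family)
    mr <- prediction_metrics(yy, fit_and_predict(yy, Xred, family)$pred, family)
    rbind(full = mf, reduced = mr)
  }
  obs <- metric_pair(Xf, Xr, d)
  delta_fun <- if (contrast == "ratio") function(f, r) f / r else `-`
  star_fun <- if (contrast == "ratio") function(f, r) log(f / r) else `-`
  delta_obs <- delta_fun(obs["full", ], obs["reduced", ])
  star_obs <- star_fun(obs["full", ], obs["reduced", ])

  set.seed(seed)
  perm <- sample.int(n)
  prs_perm <- prs[perm, , drop = FALSE]
  nmet <- ncol(obs)
  null_star <- matrix(NA_real_, B, nmet,
                      dimnames = list(NULL, colnames(obs)))
  prs_cols <- (ncol(Xr) + 1L):ncol(Xf)
  for (b in seq_len(B)) {
    if (permute_per_resample) prs_perm <- prs[sample.int(n), , drop = FALSE]
    idx <- sample.int(n, n, replace = TRUE)
    Xfb <- Xf[idx, , drop = FALSE]
    Xfb[, prs_cols] <- prs_perm[idx, , drop = FALSE]
    mb <- metric_pair(Xfb, Xr[idx, , drop = FALSE], d[idx])
    null_star[b, ] <- star_fun(mb["full", ], mb["reduced", ])
  }
  p_value <- vapply(seq_len(nmet), function(j)
    (1 + sum(abs(null_star[, j]) >= abs(star_obs[j]), na.rm = TRUE)) / (1 + B),
    numeric(1))
  metrics <- data.frame(metric = colnames(obs),
                        full = as.numeric(obs["full", ]),
                        reduced = as.numeric(obs["reduced", ]),
                        delta_obs = as.numeric(delta_obs),
                        p_value = p_value,
                        stringsAsFactors = FALSE)
  structure(list(metrics = metrics, null_deltas = null_star,
                 contrast_type = contrast, B = B, seed = seed,
                 family = family, evaluable = TRUE, n = n,
                 n_prs = ncol(prs)),
            class = "relevance_test")
}

#' @export
print.relevance_test <- function(x, digits = 4, ...) {
  cat("Disease-relevance test (permutation + bootstrap)\n")
  if (!x$evaluable) {
    cat("  not evaluable: no informative polygenic-score column\n")
    return(invisible(x))
  }
  cat(sprintf("  family: %s, contrast: %s, B = %d, n = %d, PRS columns = %d\n",
              x$family, x$contrast_type, x$B, x$n, x$n_prs))
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-6s full %.*f  reduced %.*f  %s %.*f  p = %.4g\n",
                m$metric[i], digits, m$full[i], digits, m$reduced[i],
                x$contrast_type, digits, m$delta_obs[i], m$p_value[i]))
  invisible(x)
}

#' @export
summary.relevance_test <- function(object, ...) {
  print(object, ...)
  if (object$evaluable) {
    cat(sprintf("  p-value floor at this B: %.4g\n", 1 / (1 + object$B)))
  }
  invisible(object)
}
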