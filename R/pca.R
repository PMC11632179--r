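#' Orthogonalize a multivariate trait by principal component analysis
#'
#' Embedding dimensions are generally correlated and on arbitrary scales, so
#' per-dimension association statistics are not independent. Fitting a PCA on
#' the discovery cohort and carrying its components forward gives
#' uncorrelated (on the fitting cohort), variance-ordered components whose
#' Wald statistics can be combined into a chi-square test.
#'
#' The eigenvector sign is arbitrary; for determinism each loading column is
#' flipped so that its largest-magnitude entry is positive. Downstream
#' quantities that matter — the combined chi-square statistic and polygenic
#' score based relevance — are invariant to these sign flips (a flipped
#' component simply has all betas and score weights negated).
#'
#' @param traits numeric matrix or data.frame, subjects x K trait columns;
#'   no missing values.
#' @param standardize scale columns to unit variance before rotation
#'   (default `TRUE`, appropriate for embedding dimensions of arbitrary
#'   scale).
#' @return An object of class `pc_model`: list with `center`, `scale`
#'   (`NULL` when `standardize = FALSE`), `loadings` (K x K orthonormal),
#'   `variance_explained` (non-increasing, sums to 1), `sdev`, and `K`.
#' @export
fit_pca <- function(traits, standardize = TRUE) {
  x <- as.matrix(traits)
  storage.mode(x) <- "double"
  if (anyNA(x))
    gem_stop("traits contain missing values; PCA requires complete cases",
             "gemeval_validation_error")
  if (nrow(x) <= ncol(x))
    gem_stop("need more subjects than trait columns to fit a PCA",
             "gemeval_validation_error")
  if (is.null(colnames(x))) colnames(x) <- paste0("trait", seq_len(ncol(x)))
  sds <- apply(x, 2L, sd)
  if (any(sds == 0))
    gem_stop(paste0("zero-variance trait column(s): ",
                    paste(colnames(x)[sds == 0], collapse = ", ")),
             "gemeval_validation_error")
  pr <- prcomp(x, center = TRUE, scale. = standardize)
  rot <- pr$rotation
  # deterministic sign: largest-|loading| entry of each component positive
  for (k in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, k]))
    if (rot[i, k] < 0) rot[, k] <- -rot[, k]
  }
  structure(list(center = pr$center,
                 scale = if (standardize) pr$scale else NULL,
                 loadings = rot,
                 variance_explained = pr$sdev^2 / sum(pr$sdev^2),
                 sdev = pr$sdev,
                 K = ncol(x)),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("pc_model: %d components%s\n", x$K,
              if (is.null(x$scale)) "" else " (standardized input)"))
  ve <- round(100 * x$variance_explained, 1)
  cat("  variance explained (%):", paste(ve, collapse = ", "), "\n")
  invisible(x)
}

#' Project trait data onto fitted principal components
#'
#' Applies the stored centering/scaling and rotation, so evaluation-cohort
#' subjects are projected with discovery-fit parameters (no leakage).
#'
#' @param object a [fit_pca()] model.
#' @param newdata subjects x K matrix or data.frame with the same trait
#'   columns the model was fit on.
#' @param m number of leading components to keep (default all K).
#' @param ... ignored.
#' @return Subjects x `m` matrix of component scores (class `pc_matrix`),
#'   columns named `PC1..PCm`; row names taken from `newdata`.
#' @export
predict.pc_model <- function(object, newdata, m = object$K, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (ncol(x) != object$K)
    gem_stop(sprintf("model was fit on %d trait columns, got %d",
                     object$K, ncol(x)),
             "gemeval_validation_error")
  if (m < 1 || m > object$K)
    gem_stop("m must be between 1 and K", "gemeval_validation_error")
  x <- sweep(x, 2L, object$center, "-")
  if (!is.null(object$scale)) x <- sweep(x, 2L, object$scale, "/")
  scores <- x %*% object$loadings[, seq_len(m), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(m))
  class(scores) <- c("pc_matrix", class(scores))
  scores
}

#' Choose the number of components to test
#'
#' @param model a [fit_pca()] model.
#' @param policy `"fixed"` (take `value` components) or
#'   `"variance_threshold"` (smallest m whose cumulative variance explained
#'   reaches `value`).
#' @param value integer in \[1, K\] for `"fixed"`; fraction in (0, 1\] for
#'   `"variance_threshold"`.
#' @return Integer m.
#' @export
select_m <- function(model, policy = c("fixed", "variance_threshold"),
                     value = 5) {
  policy <- match.arg(policy)
  stopifnot(inherits(model, "pc_model"))
  if (policy == "fixed") {
    m <- as.integer(value)
    if (is.na(m) || m < 1 || m > model$K)
      gem_stop(sprintf("fixed m must be an integer in [1, %d]", model$K),
               "gemeval_validation_error")
    return(m)
  }
  if (!is.numeric(value) || value <= 0 || value > 1)
    gem_stop("variance threshold must lie in (0, 1]",
             "gemeval_validation_error")
  as.integer(which(cumsum(model$variance_explained) >= value - 1e-12)[1L])
}
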