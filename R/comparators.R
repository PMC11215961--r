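#' Construct a selection result
#'
#' The common currency of the benchmark: one method's selected cis variants
#' for one gene, with the per-variant score the selection was based on
#' (absolute coefficient or p-value).
#'
#' @param gene_id gene identifier.
#' @param method method label.
#' @param selected integer indices of selected variants (columns of the
#'   gene's dosage matrix).
#' @param scores numeric vector, one score per cis variant.
#' @param threshold_used the decision threshold applied, if any.
#' @return A list of class `selection_result`.
#' @export
selection_result <- function(gene_id, method, selected, scores,
                             threshold_used = NA_real_) {
  structure(list(gene_id = as.character(gene_id), method = as.character(method),
                 selected = sort(as.integer(selected)), scores = scores,
                 threshold_used = threshold_used),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result [", x$method, "] ", x$gene_id, ": ",
      length(x$selected), " of ", length(x$scores), " variants\n", sep = "")
  invisible(x)
}

glmnet_foldid <- function(n, n_folds, seed) {
  draw <- function() sample(rep(seq_len(n_folds), length.out = n))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' L0+L1 selector (cross-validated)
#'
#' Wraps [select_by_cv()] into the common `selection_result` schema:
#' variants with nonzero coefficients at the CV-chosen penalty pair are the
#' selected causal eQTL candidates.
#'
#' @inheritParams select_by_cv
#' @param gene_id gene identifier for the result.
#' @param ... passed to [select_by_cv()] (grids, tolerances, ...).
#' @return A [selection_result()] with `scores` = absolute standardized
#'   coefficients.
#' @export
fit_l0l1_select <- function(X, y, n_folds = 5, seed = NULL,
                            gene_id = "gene", ...) {
  fit <- select_by_cv(X, y, n_folds = n_folds, seed = seed, ...)
  selection_result(gene_id, "l0l1", fit$support, abs(fit$beta_std))
}

#' LASSO selector
#'
#' `cv.glmnet` lasso fit; the selected set is the nonzero coefficients at
#' the CV-error-minimizing penalty.
#'
#' @inheritParams fit_l0l1_select
#' @return A [selection_result()] with `scores` = absolute coefficients.
#' @export
fit_lasso_select <- function(X, y, n_folds = 5, seed = NULL,
                             gene_id = "gene") {
  cv <- glmnet::cv.glmnet(X, y, alpha = 1, nfolds = n_folds,
                          foldid = glmnet_foldid(nrow(X), n_folds, seed))
  beta <- drop(coef(cv, s = "lambda.min"))[-1]
  selection_result(gene_id, "lasso", which(beta != 0), abs(beta))
}

#' Elastic Net selector
#'
#' `cv.glmnet` with mixing parameter `l1_ratio` (glmnet's `alpha`);
#' `l1_ratio = 1` reduces to the LASSO selector.
#'
#' @inheritParams fit_l0l1_select
#' @param l1_ratio L1 share of the penalty, in (0, 1]; default 0.5.
#' @return A [selection_result()] with `scores` = absolute coefficients.
#' @export
fit_elastic_net_select <- function(X, y, l1_ratio = 0.5, n_folds = 5,
                                   seed = NULL, gene_id = "gene") {
  stopifnot(l1_ratio > 0, l1_ratio <= 1)
  cv <- glmnet::cv.glmnet(X, y, alpha = l1_ratio, nfolds = n_folds,
                          foldid = glmnet_foldid(nrow(X), n_folds, seed))
  beta <- drop(coef(cv, s = "lambda.min"))[-1]
  selection_result(gene_id, "elasticnet", which(beta != 0), abs(beta))
}

#' Thresholded Ridge selector
#'
#' Ridge keeps every coefficient nonzero, so selection needs an explicit
#' cutoff: the ridge fit (CV-selected L2 penalty) is computed on
#' unit-variance-standardized dosages and variants with absolute
#' standardized coefficient at or above `tau` (default 0.6, boundary
#' inclusive) are selected.
#'
#' @inheritParams fit_l0l1_select
#' @param tau absolute-coefficient selection threshold on the standardized
#'   scale, >= 0.
#' @return A [selection_result()] with `scores` = absolute standardized
#'   coefficients and `threshold_used = tau`.
#' @export
fit_ridge_select <- function(X, y, n_folds = 5, seed = NULL, tau = 0.6,
                             gene_id = "gene") {
  stopifnot(tau >= 0)
  sds <- apply(X, 2, sd)
  sds[sds == 0] <- 1
  Xs <- scale(X, scale = sds)
  cv <- glmnet::cv.glmnet(Xs, y, alpha = 0, nfolds = n_folds,
                          standardize = FALSE,
                          foldid = glmnet_foldid(nrow(X), n_folds, seed))
  beta <- drop(coef(cv, s = "lambda.min"))[-1]
  selection_result(gene_id, "ridge", which(abs(beta) >= tau), abs(beta),
                   threshold_used = tau)
}

#' Single-variant association selector with per-gene Bonferroni control
#'
#' Regresses expression on each cis variant separately (simple linear
#' regression, two-sided t-test) and selects variants with
#' `p < alpha / m`, `m` the number of cis SNPs tested — the per-gene
#' Bonferroni rule single-variant eQTL mappers use to control the
#' family-wise type-I error. The comparison is strict: a p-value exactly at
#' the threshold is not selected. Zero-variance variants get `p = 1`.
#'
#' @inheritParams fit_l0l1_select
#' @param alpha family-wise error budget per gene; default 0.05.
#' @return A [selection_result()] with `scores` = p-values and
#'   `threshold_used = alpha / m`.
#' @export
marginal_association_select <- function(X, y, alpha = 0.05,
                                        gene_id = "gene") {
  p <- marginal_pvalues(X, y)
  thr <- alpha / ncol(X)
  selection_result(gene_id, "marginal", which(p < thr), p,
                   threshold_used = thr)
}

#' Per-variant simple-regression p-values
#'
#' Two-sided t-test of the slope in `y ~ x_j`, computed in closed form for
#' all columns at once. Invariant to affine rescaling of `y` or any column.
#'
#' @param X dosage matrix.
#' @param y expression vector.
#' @return Numeric vector of p-values (1 for zero-variance columns).
#' @export
marginal_pvalues <- function(X, y) {
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples for a slope t-test")
  xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  syy <- sum(yc^2)
  pv <- rep(1, ncol(X))
  ok <- sxx > 0 & syy > 0
  if (any(ok)) {
    sxy <- drop(crossprod(xc[, ok, drop = FALSE], yc))
    r2 <- pmin(sxy^2 / (sxx[ok] * syy), 1)
    tstat <- sqrt((n - 2) * r2 / pmax(1 - r2, .Machine$double.eps))
    pv[ok] <- 2 * pt(-tstat, df = n - 2)
  }
  names(pv) <- colnames(X)
  pv
}
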