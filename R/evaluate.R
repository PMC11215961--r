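#' Confusion counts between a selected set and the truth
#'
#' @param selected variant identifiers (or indices) selected by a method.
#' @param truth the true causal identifiers for the same gene.
#' @return Named integer vector `c(tp, fp, fn)`.
#' @export
confusion_counts <- function(selected, truth) {
  selected <- unique(selected)
  truth <- unique(truth)
  tp <- length(intersect(selected, truth))
  c(tp = tp, fp = length(selected) - tp, fn = length(truth) - tp)
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`,
#' `f1 = 2PR/(P+R)`; each degenerate ratio (empty selection, empty truth,
#' or both) is 0 by convention, so an all-zero model scores 0 rather than
#' propagating `NaN`.
#'
#' @param tp,fp,fn nonnegative counts, or a single vector `c(tp, fp, fn)`
#'   as returned by [confusion_counts()].
#' @return List of class `eval_result` with fields `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
f1_score <- function(tp, fp = NULL, fn = NULL) {
  if (is.null(fp) && length(tp) == 3) {
    fn <- tp[[3]]; fp <- tp[[2]]; tp <- tp[[1]]
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: tp=%d fp=%d fn=%d  P=%.3f R=%.3f F1=%.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Symmetric F1 (Dice) similarity of two variant sets
#'
#' `2 |A∩B| / (|A| + |B|)` — the F1 score with either set taken as truth,
#' used e.g. to compare the causal-eQTL sets of two tissues. Two empty sets
#' score 0 by convention.
#'
#' @param set_a,set_b finite vectors of variant identifiers.
#' @return Similarity in \[0, 1\].
#' @export
set_similarity_f1 <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  if (length(a) + length(b) == 0) return(0)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Pairwise similarity matrix of per-group eQTL sets
#'
#' @param sets named list of variant-identifier vectors (e.g. one per
#'   tissue).
#' @return Symmetric matrix of [set_similarity_f1()] values, unit diagonal
#'   for non-empty sets.
#' @export
pairwise_set_similarity <- function(sets) {
  k <- length(sets)
  m <- matrix(0, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in i:k) {
      m[i, j] <- m[j, i] <- set_similarity_f1(sets[[i]], sets[[j]])
    }
  }
  m
}

builtin_selector <- function(method, n_folds, l1_ratio, ridge_tau,
                             marginal_alpha, lambda0_grid, lambda1_grid) {
  switch(method,
    l0l1 = function(X, y, seed, gene_id, truth) {
      fit_l0l1_select(X, y, n_folds = n_folds, seed = seed,
                      gene_id = gene_id, lambda0_grid = lambda0_grid,
                      lambda1_grid = lambda1_grid)
    },
    lasso = function(X, y, seed, gene_id, truth) {
      fit_lasso_select(X, y, n_folds, seed, gene_id)
    },
    elasticnet = function(X, y, seed, gene_id, truth) {
      fit_elastic_net_select(X, y, l1_ratio, n_folds, seed, gene_id)
    },
    ridge = function(X, y, seed, gene_id, truth) {
      fit_ridge_select(X, y, n_folds, seed, ridge_tau, gene_id)
    },
    marginal = function(X, y, seed, gene_id, truth) {
      marginal_association_select(X, y, marginal_alpha, gene_id)
    },
    oracle = function(X, y, seed, gene_id, truth) {
      selection_result(gene_id, "oracle", truth, rep(0, ncol(X)))
    },
    none = function(X, y, seed, gene_id, truth) {
      selection_result(gene_id, "none", integer(0), rep(0, ncol(X)))
    },
    stop("unknown method: ", method)
  )
}

#' Benchmark selectors over a grid of simulated conditions
#'
#' For every (architecture, number of causal SNPs, heritability) cell,
#' simulates `n_genes` genes — each with its own freshly drawn
#' LD-structured genotype block — runs every method on each gene, scores
#' the selected sets against the simulation truth and aggregates. The
#' per-gene F1 is macro-averaged across genes by default (`average =
#' "micro"` pools the confusion counts instead). Deterministic given
#' `seed`; per-cell and per-gene seeds are pre-drawn, so results for a cell
#' do not depend on which other cells run.
#'
#' @param architectures character vector of architecture names.
#' @param n_causal_list integer vector of causal-SNP counts (logic
#'   architectures only accept 2).
#' @param h2_list numeric vector of target heritabilities.
#' @param methods character vector among `"l0l1"`, `"lasso"`,
#'   `"elasticnet"`, `"ridge"`, `"marginal"`, `"oracle"`, `"none"`, or a
#'   named list of functions `f(X, y, seed, gene_id, truth)` returning a
#'   [selection_result()].
#' @param n_genes simulated genes per cell.
#' @param n_samples,variants_per_gene,maf_low,maf_high,ld_rho panel shape
#'   passed to [simulate_genotype_panel()].
#' @param n_folds CV folds for the fitted selectors.
#' @param l1_ratio,ridge_tau,marginal_alpha comparator settings.
#' @param lambda0_grid,lambda1_grid optional fixed grids for the L0+L1
#'   selector (default: per-gene [default_lambda_grids()]).
#' @param effect_mode,theta effect settings passed to [sim_config()].
#' @param average `"macro"` (mean of per-gene F1) or `"micro"` (pooled
#'   counts).
#' @param seed master seed.
#' @return data.frame with one row per (architecture, n_causal, h2,
#'   method): `mean_f1`, `mean_precision`, `mean_recall`, `total_selected`,
#'   `n_genes_evaluated`, `n_failed`. Per-gene scores are attached as
#'   `attr(, "per_gene")`.
#' @export
benchmark_grid <- function(architectures = "additive", n_causal_list = 2,
                           h2_list = c(0.02, 0.05, 0.1),
                           methods = c("l0l1", "lasso", "elasticnet",
                                       "ridge", "marginal"),
                           n_genes = 100, n_samples = 670,
                           variants_per_gene = 50, maf_low = 0.05,
                           maf_high = 0.5, ld_rho = 0.3, n_folds = 5,
                           l1_ratio = 0.5, ridge_tau = 0.6,
                           marginal_alpha = 0.05, lambda0_grid = NULL,
                           lambda1_grid = NULL, effect_mode = "gaussian",
                           theta = 1, average = c("macro", "micro"),
                           seed = 1) {
  average <- match.arg(average)
  if (is.character(methods)) {
    methods <- stats::setNames(lapply(methods, builtin_selector,
                                      n_folds = n_folds, l1_ratio = l1_ratio,
                                      ridge_tau = ridge_tau,
                                      marginal_alpha = marginal_alpha,
                                      lambda0_grid = lambda0_grid,
                                      lambda1_grid = lambda1_grid),
                               methods)
  }
  cells <- expand.grid(architecture = architectures, n_causal = n_causal_list,
                       h2 = h2_list, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  cells <- cells[cells$architecture == "additive" | cells$n_causal == 2, ,
                 drop = FALSE]
  cell_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max, nrow(cells)))

  per_gene <- list()
  summary_rows <- list()
  for (ci in seq_len(nrow(cells))) {
    arch <- cells$architecture[ci]
    k <- cells$n_causal[ci]
    h2 <- cells$h2[ci]
    cfg <- sim_config(arch, n_causal = k, h2 = h2,
                      effect_mode = effect_mode, theta = theta)
    gene_seeds <- withr::with_seed(cell_seeds[ci],
      matrix(sample.int(.Machine$integer.max, 3 * n_genes), ncol = 3,
             byrow = TRUE))
    rows <- list()
    for (gi in seq_len(n_genes)) {
      panel <- simulate_genotype_panel(n_samples, variants_per_gene, maf_low,
                                       maf_high, ld_rho,
                                       seed = gene_seeds[gi, 1])
      gene <- tryCatch(
        simulate_expression(panel, config = cfg, seed = gene_seeds[gi, 2]),
        error = function(e) NULL)
      if (is.null(gene)) next # degenerate after redraws: gene skipped
      gene_id <- sprintf("%s_k%d_h%g_gene%04d", arch, k, h2, gi)
      for (mname in names(methods)) {
        sel <- tryCatch(
          methods[[mname]](panel$dosages, gene$expression,
                           gene_seeds[gi, 3], gene_id, gene$causal_indices),
          error = function(e) {
            message("benchmark_grid: ", mname, " failed on ", gene_id, ": ",
                    conditionMessage(e))
            NULL
          })
        if (is.null(sel)) {
          rows[[length(rows) + 1]] <- data.frame(
            architecture = arch, n_causal = k, h2 = h2, method = mname,
            gene = gene_id, tp = NA_integer_, fp = NA_integer_,
            fn = NA_integer_, f1 = NA_real_, precision = NA_real_,
            recall = NA_real_, n_selected = NA_integer_)
          next
        }
        cc <- confusion_counts(sel$selected, gene$causal_indices)
        ev <- f1_score(cc)
        rows[[length(rows) + 1]] <- data.frame(
          architecture = arch, n_causal = k, h2 = h2, method = mname,
          gene = gene_id, tp = ev$tp, fp = ev$fp, fn = ev$fn, f1 = ev$f1,
          precision = ev$precision, recall = ev$recall,
          n_selected = length(sel$selected))
      }
    }
    cell_df <- do.call(rbind, rows)
    per_gene[[ci]] <- cell_df
    for (mname in names(methods)) {
      md <- cell_df[cell_df$method == mname, , drop = FALSE]
      ok <- !is.na(md$f1)
      if (average == "macro") {
        mf1 <- mean(md$f1[ok]); mp <- mean(md$precision[ok])
        mr <- mean(md$recall[ok])
      } else {
        pooled <- f1_score(sum(md$tp[ok]), sum(md$fp[ok]), sum(md$fn[ok]))
        mf1 <- pooled$f1; mp <- pooled$precision; mr <- pooled$recall
      }
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        architecture = arch, n_causal = k, h2 = h2, method = mname,
        mean_f1 = mf1, mean_precision = mp, mean_recall = mr,
        total_selected = sum(md$n_selected[ok]),
        n_genes_evaluated = sum(ok), n_failed = sum(!ok))
    }
  }
  out <- do.call(rbind, summary_rows)
  rownames(out) <- NULL
  attr(out, "per_gene") <- do.call(rbind, per_gene)
  out
}
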