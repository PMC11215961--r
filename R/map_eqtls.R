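#' Map causal cis-eQTLs for every gene in a study
#'
#' For each gene: take the cis-window variants around its TSS, apply the
#' MAF filter, and run the L0+L1 selector — either at fixed penalties, by
#' cross-validated penalty selection (the default), or as a
#' stability-selection ensemble. Genes with fewer than `min_variants` cis
#' SNPs after filtering are skipped with a message (mirroring the usual
#' restriction to genes with two or more SNPs).
#'
#' @param panel a [genotype_panel()].
#' @param expression samples x genes matrix; sample order must match the
#'   panel.
#' @param gene_map data.frame with `gene_id`, `chrom`, `tss` (see
#'   [read_gene_map()]); only genes present in `expression` are fitted.
#' @param window_bp cis-window half-width (default 1 Mb).
#' @param min_maf MAF filter applied within each cis-window (default 0.01;
#'   0 keeps all polymorphic variants).
#' @param min_variants minimum cis SNPs required to fit a gene.
#' @param lambda0,lambda1 fixed penalties; when either is `NULL` the pair
#'   is chosen by [select_by_cv()].
#' @param n_folds,seed CV settings.
#' @param n_boot,subsample_frac,freq_threshold stability-ensemble settings
#'   (see [stability_ensemble()]); `n_boot = 1` (default) disables the
#'   ensemble.
#' @return data.frame with one row per selected variant: `gene_id`,
#'   `variant_id`, `beta` (original dosage scale; `NA` for ensemble
#'   selections whose final fit excluded the variant) and
#'   `selection_frequency` (1 outside ensemble mode).
#' @export
map_causal_eqtls <- function(panel, expression, gene_map, window_bp = 1e6,
                             min_maf = 0.01, min_variants = 2,
                             lambda0 = NULL, lambda1 = NULL, n_folds = 5,
                             seed = NULL, n_boot = 1, subsample_frac = 1,
                             freq_threshold = 0.5) {
  stopifnot(inherits(panel, "genotype_panel"))
  genes <- gene_map[gene_map$gene_id %in% colnames(expression), ,
                    drop = FALSE]
  gene_seeds <- if (is.null(seed)) rep(list(NULL), nrow(genes))
                else as.list(withr::with_seed(seed,
                       sample.int(.Machine$integer.max, nrow(genes))))
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    region <- cis_variants(panel, gid, genes$chrom[i], genes$tss[i],
                           window_bp)
    idx <- region$variant_indices
    if (length(idx) > 0 && min_maf > 0) {
      idx <- idx[panel$maf[idx] >= min_maf & panel$maf[idx] > 0]
    } else {
      idx <- idx[panel$maf[idx] > 0]
    }
    if (length(idx) < min_variants) {
      message("map_causal_eqtls: skipping ", gid, " (",
              length(idx), " usable cis variants)")
      next
    }
    X <- panel$dosages[, idx, drop = FALSE]
    y <- expression[, gid]
    if (n_boot > 1) {
      ens <- stability_ensemble(X, y, n_boot = n_boot,
                                subsample_frac = subsample_frac,
                                freq_threshold = freq_threshold,
                                n_folds = n_folds, seed = gene_seeds[[i]])
      fit <- select_by_cv(X, y, n_folds = n_folds, seed = gene_seeds[[i]])
      sel <- ens$support
      freq <- ens$frequencies[sel]
      beta <- ifelse(sel %in% fit$support, fit$beta[sel], NA_real_)
    } else if (!is.null(lambda0) && !is.null(lambda1)) {
      fit <- fit_l0l1(X, y, lambda0, lambda1)
      sel <- fit$support
      freq <- rep(1, length(sel))
      beta <- fit$beta[sel]
    } else {
      fit <- select_by_cv(X, y, n_folds = n_folds, seed = gene_seeds[[i]])
      sel <- fit$support
      freq <- rep(1, length(sel))
      beta <- fit$beta[sel]
    }
    if (length(sel) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = gid, variant_id = panel$variants$variant_id[idx[sel]],
      beta = unname(beta), selection_frequency = unname(freq),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(0), variant_id = character(0),
                      beta = numeric(0), selection_frequency = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
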