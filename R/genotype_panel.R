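#' Construct a genotype panel
#'
#' A `genotype_panel` bundles a samples-by-variants ALT-allele dosage matrix
#' with its variant metadata. Dosages are 0/1/2 for hard calls; fractional
#' values in \[0, 2\] are allowed (mean-imputed or dosage data). Minor-allele
#' frequencies are computed from the dosages and kept in sync by every
#' operation that subsets variants.
#'
#' @param dosages numeric matrix, n_samples x n_variants, entries in \[0, 2\].
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`; one row per column of `dosages`.
#' @param sample_ids character vector of row identifiers (defaults to
#'   rownames of `dosages` or `sample1..n`).
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosages`, `variants`, `sample_ids`, `maf`.
#' @export
genotype_panel <- function(dosages, variants, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("variant_id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols) > 0) {
    stop("variants is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(variants) != ncol(dosages)) {
    stop("variants has ", nrow(variants), " rows but dosages has ",
         ncol(dosages), " columns")
  }
  if (anyDuplicated(variants$variant_id)) {
    stop("variant_ids must be unique")
  }
  if (any(!is.finite(dosages)) || any(dosages < 0) || any(dosages > 2)) {
    stop("dosages must be finite and in [0, 2] (impute missing calls first)")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages)
    if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(dosages)))
  }
  if (length(sample_ids) != nrow(dosages)) {
    stop("sample_ids length does not match number of dosage rows")
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$variant_id
  variants$pos <- as.integer(variants$pos)
  structure(
    list(dosages = dosages, variants = variants,
         sample_ids = as.character(sample_ids), maf = panel_maf(dosages)),
    class = "genotype_panel"
  )
}

# ALT-allele frequency folded to the minor allele: maf = min(f, 1 - f),
# f = sum(x) / (2n). Independent of which allele is ALT.
panel_maf <- function(dosages) {
  f <- colSums(dosages) / (2 * nrow(dosages))
  unname(pmin(f, 1 - f))
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel: ", nrow(x$dosages), " samples x ", ncol(x$dosages),
      " variants\n", sep = "")
  if (ncol(x$dosages) > 0) {
    cat("  chrom: ", paste(unique(x$variants$chrom), collapse = ", "),
        "; MAF range: ", sprintf("%.3f-%.3f", min(x$maf), max(x$maf)),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Subset a panel to a set of variant columns
#'
#' @param panel a [genotype_panel()].
#' @param idx integer vector of variant column indices (order preserved).
#' @return A `genotype_panel` with the selected variants; MAF recomputed.
#' @export
subset_variants <- function(panel, idx) {
  stopifnot(inherits(panel, "genotype_panel"))
  idx <- as.integer(idx)
  genotype_panel(panel$dosages[, idx, drop = FALSE],
                 panel$variants[idx, , drop = FALSE],
                 panel$sample_ids)
}

#' Remove rare and monomorphic variants
#'
#' Drops variants with minor-allele frequency below `min_maf`. Monomorphic
#' variants (MAF exactly 0) are always removed, even at `min_maf = 0`,
#' because they carry no association information and break standardization.
#' The number of removed variants is reported via `message()`.
#'
#' @param panel a [genotype_panel()].
#' @param min_maf minimum minor-allele frequency in \[0, 0.5\]; default 0.01.
#'   Set to 0 to keep every polymorphic variant.
#' @return Filtered `genotype_panel`; errors if no variant survives.
#' @export
filter_variants <- function(panel, min_maf = 0.01) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must be in [0, 0.5]")
  keep <- panel$maf >= min_maf & panel$maf > 0
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message("filter_variants: removed ", n_removed, " of ", length(keep),
            " variants (maf < ", min_maf, " or monomorphic)")
  }
  if (!any(keep)) {
    stop("filter_variants: no variants remain after MAF filtering",
         call. = FALSE)
  }
  subset_variants(panel, which(keep))
}

#' Variants in a gene's cis-window
#'
#' Returns the indices of panel variants on `chrom` within the closed
#' interval `[tss - window_bp, tss + window_bp]` around the transcription
#' start site — the candidate set for per-gene eQTL selection.
#'
#' @param panel a [genotype_panel()].
#' @param gene_id gene identifier carried through to the result.
#' @param chrom chromosome of the gene's TSS.
#' @param tss 1-based transcription start site position.
#' @param window_bp half-width of the cis-window in base pairs (default 1e6).
#' @return A list of class `cis_region` with `gene_id`, `chrom`, `tss`,
#'   `window_bp` and `variant_indices` (possibly empty; callers typically
#'   skip genes with too few cis variants).
#' @export
cis_variants <- function(panel, gene_id, chrom, tss, window_bp = 1e6) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (window_bp <= 0) stop("window_bp must be positive")
  tss <- as.numeric(tss)
  hit <- panel$variants$chrom == as.character(chrom) &
    abs(panel$variants$pos - tss) <= window_bp
  structure(
    list(gene_id = as.character(gene_id), chrom = as.character(chrom),
         tss = as.integer(tss), window_bp = as.numeric(window_bp),
         variant_indices = which(hit)),
    class = "cis_region"
  )
}

#' @export
print.cis_region <- function(x, ...) {
  cat("cis_region ", x$gene_id, ": chr", x$chrom, ":", x$tss, " +/- ",
      x$window_bp, " bp, ", length(x$variant_indices), " variants\n", sep = "")
  invisible(x)
}
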