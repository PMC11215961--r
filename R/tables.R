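#' Read an expression TSV (samples x genes)
#'
#' First column is the sample identifier; every remaining column is one
#' gene's expression.
#'
#' @param path TSV file.
#' @return Numeric matrix, samples x genes, with sample rownames.
#' @export
read_expression_tsv <- function(path) {
  dt <- fread_tsv(path)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- as.character(dt[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix as TSV
#'
#' @param expr numeric matrix, samples x genes, with sample rownames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  dt <- data.table::data.table(sample_id = rownames(expr))
  for (g in colnames(expr)) dt[[g]] <- expr[, g]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a GTEx-style expression BED
#'
#' Columns: chrom, start (0-based, TSS-1), end, gene_id, then one column per
#' sample. Returns both the expression matrix and a gene map usable with
#' [cis_variants()].
#'
#' @param path BED file (with or without a leading `#` on the header).
#' @return List with `expression` (samples x genes matrix) and `genes`
#'   (data.frame: gene_id, chrom, tss).
#' @export
read_expression_bed <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  names(dt)[1] <- sub("^#", "", names(dt)[1])
  names(dt)[1:4] <- c("chrom", "start", "end", "gene_id")
  expr <- t(as.matrix(dt[, -(1:4), with = FALSE]))
  colnames(expr) <- dt$gene_id
  storage.mode(expr) <- "double"
  list(expression = expr,
       genes = data.frame(gene_id = dt$gene_id,
                          chrom = as.character(dt$chrom),
                          tss = as.integer(dt$start) + 1L,
                          stringsAsFactors = FALSE))
}

#' Read a gene map TSV (gene_id, chrom, tss)
#'
#' @param path TSV file with header columns `gene_id`, `chrom`, `tss`.
#' @return data.frame with those three columns.
#' @export
read_gene_map <- function(path) {
  dt <- fread_tsv(path)
  dt$chrom <- as.character(dt$chrom)
  req <- c("gene_id", "chrom", "tss")
  if (!all(req %in% names(dt))) {
    stop("gene map must have columns: ", paste(req, collapse = ", "))
  }
  as.data.frame(dt[, req, with = FALSE])
}

#' Read externally computed selections (e.g. from other fine-mapping tools)
#'
#' A generic importer so methods not implemented here can join the benchmark:
#' a TSV with at least `gene_id` and `variant_id` columns, one row per
#' selected variant.
#'
#' @param path TSV file.
#' @param method label attached to the imported selections.
#' @return data.frame with columns gene_id, variant_id, method.
#' @export
read_selections_tsv <- function(path, method = "external") {
  dt <- fread_tsv(path)
  if (!all(c("gene_id", "variant_id") %in% names(dt))) {
    stop("selections TSV must have gene_id and variant_id columns")
  }
  data.frame(gene_id = as.character(dt$gene_id),
             variant_id = as.character(dt$variant_id),
             method = method, stringsAsFactors = FALSE)
}
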