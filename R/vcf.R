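#' Read a VCF into a genotype panel
#'
#' Biallelic SNP records are converted to ALT-allele dosages. When a `DS`
#' (dosage) FORMAT field is present it is preferred over `GT` and clipped to
#' \[0, 2\]; otherwise `GT` alleles are counted. Missing calls are imputed to
#' the per-variant mean dosage. Multiallelic records are skipped with a
#' message reporting the count.
#'
#' @param path VCF file (plain or bgzipped).
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "", fixed = TRUE)
  if (any(multi)) {
    message("read_vcf: skipped ", sum(multi), " multiallelic record(s)")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0) stop("read_vcf: no biallelic records in ", path)

  fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("DS" %in% fmt_keys) {
    dos <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    dos <- pmin(pmax(dos, 0), 2)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dos <- apply(gt, 2, count_alt_alleles)
    dim(dos) <- dim(gt)
  }
  dos <- t(dos) # vcfR is variants x samples; panel is samples x variants
  dos <- impute_mean(dos)

  sample_ids <- colnames(vcf@gt)[-1]
  genotype_panel(dos,
                 data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                            pos = as.integer(fix$POS), ref = fix$REF,
                            alt = fix$ALT, stringsAsFactors = FALSE),
                 sample_ids)
}

count_alt_alleles <- function(gt) {
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) == 0 || any(a == ".") || any(is.na(a))) return(NA_real_)
    sum(a != "0")
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
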