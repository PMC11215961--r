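#' Read a PLINK 1 bed/bim/fam fileset into a genotype panel
#'
#' Decodes the SNP-major 2-bit `.bed` encoding. Dosages count copies of the
#' `.bim` allele-1 (A1), which this package treats as the ALT allele (see
#' [write_plink()]); missing calls are imputed to the per-variant mean
#' dosage so downstream regression sees a dense matrix. Sample order follows
#' `.fam`, variant order follows `.bim`.
#'
#' @param prefix path prefix; `prefix.bed`, `prefix.bim`, `prefix.fam` must
#'   exist.
#' @return A [genotype_panel()].
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  for (f in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(f)) stop("missing PLINK file: ", f)
  }
  bim <- data.table::fread(bim_path, header = FALSE,
                           col.names = c("chrom", "variant_id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = list(character = c(1, 2, 5, 6)))
  fam <- data.table::fread(fam_path, header = FALSE,
                           colClasses = list(character = c(1, 2)))
  n <- nrow(fam)
  p <- nrow(bim)
  bytes_per_variant <- ceiling(n / 4)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK .bed file (bad magic): ", bed_path)
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed files are supported")
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_variant * p) {
    stop(".bed size inconsistent with .bim/.fam dimensions")
  }

  # 2 bits per sample, sample 1 in the low bits of the first byte:
  # 00 = hom A1 (dosage 2), 10 = het (1), 11 = hom A2 (0), 01 = missing.
  bits <- matrix(as.integer(rawToBits(body)), nrow = 2)
  codes <- bits[1, ] + 2L * bits[2, ]                  # per 2-bit field
  codes <- matrix(codes, nrow = 4 * bytes_per_variant) # fields x variants
  codes <- codes[seq_len(n), , drop = FALSE]
  lookup <- c(2, NA, 1, 0)
  dos <- matrix(lookup[codes + 1L], nrow = n, ncol = p)

  dos <- impute_mean(dos)
  sample_ids <- as.character(fam[[2]])
  genotype_panel(dos,
                 data.frame(variant_id = bim$variant_id, chrom = bim$chrom,
                            pos = bim$pos, ref = bim$a2, alt = bim$a1,
                            stringsAsFactors = FALSE),
                 sample_ids)
}

#' Write a genotype panel as a PLINK 1 bed/bim/fam fileset
#'
#' Dosages are rounded to hard calls; the ALT allele is written as `.bim`
#' allele 1, so [read_plink()] round-trips dosage matrices of hard calls
#' exactly.
#'
#' @param panel a [genotype_panel()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- nrow(panel$dosages)
  p <- ncol(panel$dosages)
  v <- panel$variants

  bim <- data.frame(chrom = v$chrom, variant_id = v$variant_id, cm = 0,
                    pos = v$pos, a1 = v$alt, a2 = v$ref)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t",
                     col.names = FALSE)
  fam <- data.frame(fid = panel$sample_ids, iid = panel$sample_ids,
                    pat = 0, mat = 0, sex = 0, pheno = -9)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t",
                     col.names = FALSE)

  hard <- round(panel$dosages)
  code_map <- c(3L, 2L, 0L) # dosage 0,1,2 -> 2-bit code 11, 10, 00
  bytes_per_variant <- ceiling(n / 4)
  out <- raw(3 + bytes_per_variant * p)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  pad <- 4 * bytes_per_variant - n
  for (j in seq_len(p)) {
    codes <- c(code_map[hard[, j] + 1L], rep(0L, pad))
    bits <- rbind(codes %% 2L, codes %/% 2L)
    block <- packBits(as.integer(bits) > 0, type = "raw")
    out[3 + (j - 1) * bytes_per_variant + seq_len(bytes_per_variant)] <- block
  }
  writeBin(out, paste0(prefix, ".bed"))
  invisible(prefix)
}

# Column-wise mean imputation of missing dosages; an all-missing column
# becomes 0 (monomorphic, removed by any MAF filter).
impute_mean <- function(dos) {
  nas <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    mu <- colMeans(dos, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    dos[nas] <- mu[nas[, 2]]
  }
  dos
}
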