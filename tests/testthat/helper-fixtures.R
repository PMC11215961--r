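# Fixtures are built in code; nothing binary ships with the package.

# tiny panel with explicit hard-call dosages (samples x variants)
make_test_panel <- function(dosages, chrom = "1", pos = NULL) {
  dosages <- as.matrix(dosages)
  p <- ncol(dosages)
  if (is.null(pos)) pos <- seq(1000, by = 1000, length.out = p)
  genotype_panel(dosages,
                 data.frame(variant_id = paste0("rs", seq_len(p)),
                            chrom = chrom, pos = pos, ref = "A", alt = "G",
                            stringsAsFactors = FALSE))
}

# random regression instance with a sparse true signal
make_instance <- function(seed, n = 30, p = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- sample(4:10, 1)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p) * rbinom(p, 1, 0.4)
  y <- drop(X %*% beta) + rnorm(n)
  list(X = X, y = y, p = p)
}

# plain-text VCF fixture mirroring a dosage matrix (ALT counts)
write_test_vcf <- function(dosages, path, chrom = "1", pos = NULL,
                           extra_lines = character(0)) {
  n <- nrow(dosages)
  p <- ncol(dosages)
  if (is.null(pos)) pos <- seq(1000, by = 1000, length.out = p)
  gt_map <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("sample", seq_len(n))), collapse = "\t"))
  for (j in seq_len(p)) {
    gts <- ifelse(is.na(dosages[, j]), "./.", gt_map[dosages[, j] + 1])
    lines <- c(lines, paste(c(chrom, pos[j], paste0("rs", j), "A", "G", ".",
                              "PASS", ".", "GT", gts), collapse = "\t"))
  }
  writeLines(c(lines, extra_lines), path)
  path
}
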