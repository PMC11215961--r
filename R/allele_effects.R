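#' Genotype classes from dosages
#'
#' Partitions samples by rounded dosage into the 0/1/2 genotype classes
#' (round-half-even, so a dosage of 1.5 rounds to 2 and 0.5 to 0, as base R
#' rounds). Classes with fewer than `min_n` samples are dropped with a
#' message; a variant with fewer than 2 surviving classes is untestable.
#'
#' @param dosages per-sample dosages for one variant.
#' @param min_n minimum class size retained (default 3).
#' @return List with `group` (integer genotype per retained sample, NA for
#'   dropped), `keep` (logical retained-sample mask) and `testable`
#'   (at least 2 classes survive).
#' @export
genotype_classes <- function(dosages, min_n = 3) {
  g <- as.integer(round(dosages))
  g[g < 0L] <- 0L
  g[g > 2L] <- 2L
  sizes <- table(g)
  small <- names(sizes)[sizes < min_n]
  if (length(small) > 0) {
    message("genotype_classes: dropped class(es) ",
            paste(small, collapse = ", "), " with < ", min_n, " samples")
    g[g %in% as.integer(small)] <- NA_integer_
  }
  keep <- !is.na(g)
  list(group = g, keep = keep, testable = length(unique(g[keep])) >= 2)
}

#' One-way ANOVA of expression across genotype classes
#'
#' Classical fixed-effects one-way ANOVA: `F` is the between-class mean
#' square over the within-class mean square on `(k-1, n-k)` degrees of
#' freedom (computed via `stats::oneway.test` with equal variances). Two
#' degenerate cases have declared conventions: identical class means with
#' nonzero within-class variance give `F = 0, p = 1`; zero variance both
#' between and within classes gives `p = 1`.
#'
#' @param expression expression values.
#' @param grouping genotype class per sample (vector, or the list returned
#'   by [genotype_classes()]).
#' @param gene_id,variant_id identifiers carried into the result.
#' @return List of class `anova_result`: `gene_id`, `variant_id`,
#'   `group_sizes`, `group_means`, `f_stat`, `p_value`.
#' @export
one_way_anova <- function(expression, grouping, gene_id = NA_character_,
                          variant_id = NA_character_) {
  if (is.list(grouping)) {
    expression <- expression[grouping$keep]
    grouping <- grouping$group[grouping$keep]
  }
  grouping <- factor(grouping)
  k <- nlevels(grouping)
  n <- length(expression)
  if (k < 2) stop("one_way_anova: need at least 2 genotype classes")
  if (n <= k) stop("one_way_anova: need more samples than classes")
  sizes <- tabulate(grouping, nbins = k)
  if (any(sizes < 2)) stop("one_way_anova: every class needs >= 2 samples")
  means <- stats::setNames(as.numeric(tapply(expression, grouping, mean)),
                           levels(grouping))

  ss_within <- sum(tapply(expression, grouping,
                          function(v) sum((v - mean(v))^2)))
  ss_between <- sum(sizes * (means - mean(expression))^2)
  if (ss_within == 0 && ss_between == 0) {
    f <- 0; pv <- 1
  } else if (ss_within == 0) {
    f <- Inf; pv <- 0
  } else {
    ow <- stats::oneway.test(expression ~ grouping, var.equal = TRUE)
    f <- unname(ow$statistic)
    pv <- unname(ow$p.value)
    if (ss_between == 0) { f <- 0; pv <- 1 }
  }
  structure(list(gene_id = gene_id, variant_id = variant_id,
                 group_sizes = stats::setNames(sizes, levels(grouping)),
                 group_means = means, f_stat = f, p_value = pv),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("anova_result ", x$gene_id, "/", x$variant_id, ": F = ",
      signif(x$f_stat, 5), ", p = ", signif(x$p_value, 4), ", n = ",
      paste(x$group_sizes, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Genotype-class ANOVA for a table of (gene, variant) pairs
#'
#' Applies [genotype_classes()] + [one_way_anova()] to each selected
#' (eQTL, gene) pair — the allele-effect screen run on selected eQTLs to
#' ask whether the genotype classes differ in expression at all.
#' Untestable pairs (monomorphic or dominated by tiny classes) are reported
#' with `NA` statistics rather than dropped.
#'
#' @param panel a [genotype_panel()].
#' @param expression samples x genes matrix (sample order matching the
#'   panel).
#' @param selections data.frame with columns `gene_id`, `variant_id`
#'   (e.g. from [read_selections_tsv()]).
#' @param min_n minimum genotype-class size (see [genotype_classes()]).
#' @return data.frame: gene_id, variant_id, n0, n1, n2, mean0, mean1,
#'   mean2, f_stat, p_value, testable.
#' @export
anova_scan <- function(panel, expression, selections, min_n = 3) {
  stopifnot(inherits(panel, "genotype_panel"))
  out <- vector("list", nrow(selections))
  for (i in seq_len(nrow(selections))) {
    gid <- selections$gene_id[i]
    vid <- selections$variant_id[i]
    vi <- match(vid, panel$variants$variant_id)
    row <- data.frame(gene_id = gid, variant_id = vid, n0 = 0L, n1 = 0L,
                      n2 = 0L, mean0 = NA_real_, mean1 = NA_real_,
                      mean2 = NA_real_, f_stat = NA_real_,
                      p_value = NA_real_, testable = FALSE)
    if (!is.na(vi) && gid %in% colnames(expression)) {
      cls <- suppressMessages(genotype_classes(panel$dosages[, vi], min_n))
      if (cls$testable) {
        res <- one_way_anova(expression[, gid], cls, gid, vid)
        for (lev in names(res$group_sizes)) {
          row[[paste0("n", lev)]] <- res$group_sizes[[lev]]
          row[[paste0("mean", lev)]] <- res$group_means[[lev]]
        }
        row$f_stat <- res$f_stat
        row$p_value <- res$p_value
        row$testable <- TRUE
      }
    }
    out[[i]] <- row
  }
  do.call(rbind, out)
}
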