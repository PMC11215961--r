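#' Simulation configuration for one gene
#'
#' Describes how a gene's expression is generated from its cis genotypes.
#' Four genetic architectures are supported:
#' \describe{
#'   \item{additive}{expression is the weighted sum of the causal dosages;
#'     effects default to independent standard-normal draws.}
#'   \item{heterogeneous}{a single effect applies to samples carrying an ALT
#'     allele at either of two causal SNPs (one copy suffices).}
#'   \item{recessive}{the effect applies only to samples carrying ALT at
#'     both causal SNPs.}
#'   \item{compensatory}{the effect applies when exactly one of the two
#'     causal SNPs carries ALT.}
#' }
#' The three logic architectures require exactly 2 causal SNPs and use a
#' single effect size `theta`. "Carrying" means dosage >= 1 by default;
#' `carrier_mode = "homozygote"` switches to the stricter dosage == 2
#' reading.
#'
#' @param architecture one of `"additive"`, `"heterogeneous"`,
#'   `"recessive"`, `"compensatory"`.
#' @param n_causal number of causal SNPs (any count for additive, must be 2
#'   for the logic architectures). `0` gives a pure-noise null gene.
#' @param h2 target heritability, in (0, 1\]; `h2 = 1` means no
#'   environmental noise.
#' @param effect_mode `"gaussian"` (additive default: iid N(0,1) effects) or
#'   `"fixed"` (all effects equal `theta`).
#' @param theta effect size for fixed mode and for the logic architectures.
#' @param carrier_mode `"carrier"` (dosage >= 1) or `"homozygote"`
#'   (dosage == 2) interpretation of allele presence in the logic
#'   architectures.
#' @param max_redraws how many times to redraw the causal set when the
#'   genetic values are degenerate (zero variance, e.g. no carrier of the
#'   logic pattern) before giving up.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(architecture = c("additive", "heterogeneous",
                                        "recessive", "compensatory"),
                       n_causal = 2, h2 = 0.1,
                       effect_mode = c("gaussian", "fixed"), theta = 1,
                       carrier_mode = c("carrier", "homozygote"),
                       max_redraws = 10) {
  architecture <- match.arg(architecture)
  effect_mode <- match.arg(effect_mode)
  carrier_mode <- match.arg(carrier_mode)
  if (architecture != "additive" && n_causal != 2) {
    stop("architecture '", architecture, "' requires exactly 2 causal SNPs")
  }
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  structure(list(architecture = architecture, n_causal = as.integer(n_causal),
                 h2 = h2, effect_mode = effect_mode, theta = theta,
                 carrier_mode = carrier_mode,
                 max_redraws = as.integer(max_redraws)),
            class = "sim_config")
}

#' Simulate an LD-structured genotype panel
#'
#' Each sample is the sum of two haplotypes. Haplotypes are generated from a
#' latent first-order autoregressive Gaussian process along the variant
#' axis (correlation `ld_rho` between adjacent variants), thresholded at
#' each variant's MAF quantile, so adjacent-variant allelic correlation
#' rises monotonically with `ld_rho` — a single-knob stand-in for local LD.
#' Per-variant target MAFs are drawn uniformly from
#' \[`maf_low`, `maf_high`\]; the ALT allele is the minor allele.
#'
#' @param n_samples,n_variants panel dimensions.
#' @param maf_low,maf_high MAF spectrum bounds, 0 < maf_low <= maf_high <= 0.5.
#' @param ld_rho latent AR(1) parameter in \[0, 1).
#' @param seed optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @param chrom,pos_start,pos_step variant coordinates: variant j sits at
#'   `pos_start + (j-1) * pos_step` on `chrom`.
#' @return A [genotype_panel()].
#' @export
simulate_genotype_panel <- function(n_samples, n_variants, maf_low = 0.05,
                                    maf_high = 0.5, ld_rho = 0.3,
                                    seed = NULL, chrom = "1",
                                    pos_start = 1e6, pos_step = 1000) {
  if (maf_low <= 0 || maf_low > maf_high || maf_high > 0.5) {
    stop("need 0 < maf_low <= maf_high <= 0.5")
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  draw <- function() {
    maf <- runif(n_variants, maf_low, maf_high)
    n_hap <- 2 * n_samples
    z <- matrix(0, n_hap, n_variants)
    z[, 1] <- rnorm(n_hap)
    if (n_variants > 1) {
      innov_sd <- sqrt(1 - ld_rho^2)
      for (j in 2:n_variants) {
        z[, j] <- ld_rho * z[, j - 1] + innov_sd * rnorm(n_hap)
      }
    }
    alleles <- sweep(z, 2, qnorm(maf), `<`)
    dos <- alleles[seq_len(n_samples), , drop = FALSE] +
      alleles[n_samples + seq_len(n_samples), , drop = FALSE]
    storage.mode(dos) <- "double"
    ids <- sprintf("snp%05d", seq_len(n_variants))
    genotype_panel(dos,
                   data.frame(variant_id = ids, chrom = chrom,
                              pos = pos_start + (seq_len(n_variants) - 1) *
                                pos_step,
                              ref = "A", alt = "G",
                              stringsAsFactors = FALSE))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Draw a causal SNP set uniformly at random
#'
#' @param region a `cis_region` (from [cis_variants()]) or an integer number
#'   of candidate variants.
#' @param k number of causal SNPs; must not exceed the candidate count.
#' @param seed optional integer for a reproducible draw.
#' @return Sorted integer vector of `k` distinct indices (into the panel for
#'   a `cis_region` input, 1..p otherwise).
#' @export
draw_causal_set <- function(region, k, seed = NULL) {
  pool <- if (inherits(region, "cis_region")) region$variant_indices
          else seq_len(region)
  if (k > length(pool)) {
    stop("gene has ", length(pool), " candidate variants, cannot draw ", k,
         " causal SNPs", call. = FALSE)
  }
  if (k == 0) return(integer(0))
  draw <- function() sort(pool[sample.int(length(pool), k)])
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Genetic values under a genetic architecture
#'
#' Maps causal dosages to each sample's genetic contribution `g`:
#' additive `g = X_causal %*% coefficients`; the logic architectures apply a
#' single effect `theta = coefficients[1]` when the two-SNP carrier pattern
#' holds (see [sim_config()] for the patterns and the carrier threshold).
#'
#' @param dosages samples x variants dosage matrix.
#' @param causal_indices columns of `dosages` that are causal.
#' @param architecture architecture name as in [sim_config()].
#' @param coefficients per-causal effects (additive) or a single `theta`
#'   (logic architectures).
#' @param carrier_mode `"carrier"` (dosage >= 1) or `"homozygote"`.
#' @return Numeric vector `g`, one value per sample.
#' @export
genetic_values <- function(dosages, causal_indices, architecture,
                           coefficients, carrier_mode = "carrier") {
  if (length(causal_indices) == 0) return(rep(0, nrow(dosages)))
  xc <- dosages[, causal_indices, drop = FALSE]
  if (architecture == "additive") {
    if (length(coefficients) != ncol(xc)) {
      stop("additive architecture needs one coefficient per causal SNP")
    }
    return(drop(xc %*% coefficients))
  }
  if (ncol(xc) != 2) {
    stop("architecture '", architecture, "' requires exactly 2 causal SNPs")
  }
  theta <- coefficients[1]
  thr <- if (carrier_mode == "homozygote") 2 else 1
  carries <- xc >= thr
  pattern <- switch(architecture,
    heterogeneous = carries[, 1] | carries[, 2],
    recessive     = carries[, 1] & carries[, 2],
    compensatory  = xor(carries[, 1], carries[, 2]),
    stop("unknown architecture: ", architecture)
  )
  theta * as.numeric(pattern)
}

#' Environmental variance for a target heritability
#'
#' Solves `sigma_g2 / (sigma_g2 + sigma_e2) = h2` for the noise variance,
#' using the population (1/n) variance of the realized genetic values so the
#' calibration is exact in-sample: `sigma_e2 = Var(g) * (1 - h2) / h2`.
#'
#' @param g genetic values.
#' @param h2 target heritability in (0, 1\].
#' @return `sigma_e2` (0 when `h2 = 1`). Errors if `Var(g) = 0` — such a
#'   gene is degenerate (e.g. no carrier of a logic pattern) and must be
#'   redrawn or skipped.
#' @export
calibrate_environmental_variance <- function(g, h2) {
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  sigma_g2 <- pop_var(g)
  if (sigma_g2 == 0) {
    stop("degenerate gene: genetic values have zero variance", call. = FALSE)
  }
  sigma_g2 * (1 - h2) / h2
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Simulate one gene's expression with ground truth
#'
#' Draws the causal SNP set and effects, computes genetic values under the
#' configured architecture, calibrates the noise variance to the target
#' heritability, and returns `y = g + e` with all ground truth attached.
#' Degenerate draws (zero genetic variance) are redrawn up to
#' `config$max_redraws` times before erroring.
#'
#' @param panel a [genotype_panel()].
#' @param region a `cis_region` restricting the candidate variants; `NULL`
#'   uses every panel variant.
#' @param config a [sim_config()].
#' @param seed optional integer for a reproducible gene.
#' @return A list of class `simulated_gene`: `gene_id`, `causal_indices`
#'   (panel column indices), `causal_variant_ids`, `coefficients`,
#'   `genetic_values`, `sigma_g2`, `sigma_e2`, `expression`, plus the
#'   `architecture` and `h2` used.
#' @export
simulate_expression <- function(panel, region = NULL, config = sim_config(),
                                seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  if (is.null(region)) {
    region <- structure(list(gene_id = "gene1", chrom = panel$variants$chrom[1],
                             tss = NA_integer_, window_bp = NA_real_,
                             variant_indices = seq_len(ncol(panel$dosages))),
                        class = "cis_region")
  }
  draw <- function() {
    for (attempt in seq_len(config$max_redraws + 1L)) {
      causal <- draw_causal_set(region, config$n_causal)
      coefs <- if (config$architecture == "additive" &&
                   config$effect_mode == "gaussian") {
        rnorm(length(causal))
      } else {
        rep(config$theta, max(1, length(causal)))
      }
      g <- genetic_values(panel$dosages, causal, config$architecture, coefs,
                          config$carrier_mode)
      sigma_g2 <- pop_var(g)
      if (sigma_g2 > 0 || config$n_causal == 0) break
    }
    if (sigma_g2 == 0 && config$n_causal > 0) {
      stop("degenerate gene after ", config$max_redraws,
           " redraws: genetic values constant", call. = FALSE)
    }
    if (config$n_causal == 0) {
      sigma_e2 <- 1
    } else {
      sigma_e2 <- sigma_g2 * (1 - config$h2) / config$h2
    }
    e <- if (sigma_e2 > 0) rnorm(nrow(panel$dosages), 0, sqrt(sigma_e2))
         else rep(0, nrow(panel$dosages))
    structure(
      list(gene_id = region$gene_id, region = region, causal_indices = causal,
           causal_variant_ids = panel$variants$variant_id[causal],
           coefficients = if (length(causal)) coefs else numeric(0),
           genetic_values = g, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
           expression = g + e, architecture = config$architecture,
           h2 = config$h2),
      class = "simulated_gene")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a multi-gene study (panel + expression + truth)
#'
#' Convenience wrapper generating `n_genes` independent cis regions, each
#' with its own freshly simulated genotype block, laid out head-to-tail on
#' one chromosome so the result round-trips through PLINK files. Per-gene
#' seeds are pre-drawn from `seed`, so enlarging `n_genes` never perturbs
#' earlier genes.
#'
#' @param n_genes number of genes.
#' @param n_samples samples shared by all genes.
#' @param variants_per_gene cis-window size in SNPs.
#' @param config a [sim_config()].
#' @param maf_low,maf_high,ld_rho passed to [simulate_genotype_panel()].
#' @param seed integer master seed.
#' @return List with `panel` (combined [genotype_panel()]), `genes` (list of
#'   `simulated_gene`), `expression` (samples x genes matrix), `truth`
#'   (data.frame: gene_id, variant_id, coefficient, architecture, h2,
#'   sigma_g2, sigma_e2) and `gene_map` (gene_id, chrom, tss).
#' @export
simulate_study <- function(n_genes, n_samples, variants_per_gene = 50,
                           config = sim_config(), maf_low = 0.05,
                           maf_high = 0.5, ld_rho = 0.3, seed = 1) {
  # row-major layout: gene i always consumes draws 2i-1, 2i, so growing
  # n_genes leaves earlier genes untouched
  gene_seeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max, 2 * n_genes), ncol = 2,
           byrow = TRUE))
  blocks <- vector("list", n_genes)
  genes <- vector("list", n_genes)
  span <- variants_per_gene * 1000
  for (i in seq_len(n_genes)) {
    block <- simulate_genotype_panel(
      n_samples, variants_per_gene, maf_low, maf_high, ld_rho,
      seed = gene_seeds[i, 1], chrom = "1",
      pos_start = 1e6 + (i - 1) * (span + 1000), pos_step = 1000)
    block$variants$variant_id <- sprintf("g%04d_%s", i,
                                         block$variants$variant_id)
    colnames(block$dosages) <- block$variants$variant_id
    region <- structure(
      list(gene_id = sprintf("gene%04d", i), chrom = "1",
           tss = as.integer(block$variants$pos[1] + span %/% 2),
           window_bp = span, variant_indices = seq_len(variants_per_gene)),
      class = "cis_region")
    genes[[i]] <- simulate_expression(block, region, config,
                                      seed = gene_seeds[i, 2])
    blocks[[i]] <- block
  }
  panel <- genotype_panel(
    do.call(cbind, lapply(blocks, `[[`, "dosages")),
    do.call(rbind, lapply(blocks, `[[`, "variants")),
    blocks[[1]]$sample_ids)
  # re-index per-block regions into the combined panel
  offset <- 0L
  for (i in seq_len(n_genes)) {
    genes[[i]]$region$variant_indices <-
      genes[[i]]$region$variant_indices + offset
    genes[[i]]$causal_indices <- genes[[i]]$causal_indices + offset
    offset <- offset + variants_per_gene
  }
  expr <- vapply(genes, `[[`, numeric(n_samples), "expression")
  colnames(expr) <- vapply(genes, `[[`, character(1), "gene_id")
  rownames(expr) <- panel$sample_ids
  truth <- do.call(rbind, lapply(genes, function(gn) {
    if (length(gn$causal_indices) == 0) return(NULL)
    data.frame(gene_id = gn$gene_id, variant_id = gn$causal_variant_ids,
               coefficient = gn$coefficients, architecture = gn$architecture,
               h2 = gn$h2, sigma_g2 = gn$sigma_g2, sigma_e2 = gn$sigma_e2,
               stringsAsFactors = FALSE)
  }))
  gene_map <- data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    chrom = "1",
    tss = vapply(genes, function(gn) gn$region$tss, integer(1)),
    stringsAsFactors = FALSE)
  list(panel = panel, genes = genes, expression = expr, truth = truth,
       gene_map = gene_map)
}
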