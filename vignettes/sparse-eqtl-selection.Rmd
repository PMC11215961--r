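---
title: "Sparse L0+L1 selection of causal cis-eQTLs: model, simulation design and numerical choices"
author: "sparseqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse L0+L1 selection of causal cis-eQTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparseqtl)
```

## The model

For one gene, let $y \in \mathbb{R}^n$ be its expression across $n$
individuals and $X \in \{0,1,2\}^{n \times p}$ the ALT-allele dosages of
the $p$ SNPs in its cis-window. `sparseqtl` estimates the causal variant
set as the support of

$$\hat\beta = \arg\min_\beta \; \tfrac{1}{2}\lVert y - X\beta\rVert_2^2
  + \lambda_0 \lVert\beta\rVert_0 + \lambda_1 \lVert\beta\rVert_1 .$$

The two penalties do different work. The L1 term shrinks coefficients and
keeps the fitted expression close to the data, but on its own it cannot
separate a causal SNP from its linkage-disequilibrium (LD) proxies: when
columns are nearly collinear the convex penalty is indifferent to
spreading weight across them. The L0 term charges a fixed price
$\lambda_0$ per nonzero coefficient, so adding an LD proxy that explains
little *additional* variance never pays. The assumptions are those of any
per-gene sparse regression eQTL model: expression depends linearly (or
through the simulated logic architectures, not linearly — see below) on a
small number of cis variants, errors are homoscedastic, and samples are
exchangeable (no relatedness or population-structure adjustment is
attempted; covariates such as expression PCs must be regressed out
beforehand).

### Optimization

The objective is nonconvex (the L0 term is discontinuous at zero), so the
solver combines two moves, both implemented in C++:

1. **Cyclic coordinate descent.** With columns scaled to unit sum of
   squares, the one-dimensional subproblem has the exact closed-form
   minimizer implemented in `threshold_update()`: soft-threshold the
   partial-residual correlation by $\lambda_1$, then keep the result $t$
   only if $t^2/2 \ge \lambda_0$. Ties at the boundary keep the nonzero.
   Updates use Gram-matrix ("covariance") bookkeeping, so a full sweep
   costs $O(p^2)$ after a one-time $O(np^2)$ setup — for cis windows
   ($p \le$ a few hundred) this is far cheaper than residual updates.
2. **Local swap search.** Coordinate-wise optima of a nonconvex objective
   can be poor; after descent converges, every (drop active $j$, admit
   inactive $k$) exchange is scored in $O(1)$ per pair from the same Gram
   quantities, the best strictly improving swap is applied, and descent
   resumes. The loop ends when no swap improves the objective.

The objective is non-increasing across every sweep and accepted swap (the
returned `objective_trace` lets callers audit this), so termination is
guaranteed. On small instances ($p \le 10$) the solution can be compared
against `l0l1_exhaustive()`, a deliberately independent brute force that
enumerates all $2^p$ supports and solves each restricted convex problem;
the test suite requires the solver to be within 1% of that optimum on at
least 95% of 200 random instances.

### Choosing the penalties

`fit_l0l1_path()` fits a two-dimensional grid, warm-starting along
descending $\lambda_0$ within each $\lambda_1$. Defaults: 50 log-spaced
$\lambda_1$ values spanning four decades down from
$\lambda_{1,\max} = \max_j |x_j^\top y|$ (the smallest value with an
all-zero solution), and 20 log-spaced $\lambda_0$ values spanning four
decades down from $\lambda_{1,\max}^2/2$ (the hard threshold no single
column can pass), plus 0. Grids are on the $\tfrac12$RSS loss scale, not
the mean-loss scale.

`select_by_cv()` runs K-fold cross-validation (default $K = 5$) of mean
squared prediction error over the grid, restandardizing within each
training fold. Two selection rules are provided:

* `rule = "min"` refits at the error-minimizing grid point, breaking
  exact ties toward the sparser point (larger $\lambda_0$, then larger
  $\lambda_1$).
* `rule = "1se"` (the default) takes the sparsest point whose CV error is
  within one standard error of the minimum.

The default was a genuinely open design choice. Plain CV-minimization is
known to admit spurious variants — measured here, a pure-noise gene
receives an empty model only ~60% of the time, and a single strong causal
variant is recovered *exactly* (no extras) only ~70% of the time. Under
the one-standard-error rule both rates reach ~100% in the same Monte
Carlo designs (these are the `select_by_cv` property tests), and the
selector's defining virtue — selecting far fewer SNPs than LASSO while
holding accuracy — is preserved at low heritability too. The cost is
conservatism: at $h^2 = 0.02$ the default rule often selects nothing.
Users who prefer power over parsimony can switch to `rule = "min"`.

`stability_ensemble()` optionally repeats CV selection on subsamples
drawn without replacement and keeps variants selected in at least a
threshold fraction. It is off by default (`n_boot = 1`, where it reduces
exactly to a single CV fit), because the core method is the penalized
regression; the ensemble trades computation for stability on noisy genes.

## The simulation framework

`simulate_genotype_panel()` emulates a local LD block: per-variant target
MAFs are uniform on `[maf_low, maf_high]` (default 0.05–0.5), haplotypes
come from a latent AR(1) Gaussian process along the variant axis
thresholded at each MAF quantile, and a sample's dosage is the sum of two
haplotypes. The single parameter `ld_rho` (default 0.3) monotonically
controls adjacent-variant allelic correlation. This emulates the feature
that matters for the selection problem — correlated candidate columns —
and deliberately omits much that real panels have: no recombination
hotspots or block boundaries, no allele-frequency/LD coupling, no
population structure or relatedness, no rare-variant tail below
`maf_low`. Passing the benchmarks here therefore shows that a selector
separates causal variants from smooth local LD at realistic sample
sizes; it does not certify performance on real cohort structure, which is
why `genotype_io` lets real PLINK/VCF panels be substituted directly.

`simulate_expression()` builds one gene under a configured architecture:

* **additive** — $g = \sum_j \beta_j x_j$ over $k$ causal SNPs drawn
  uniformly without replacement, effects i.i.d. standard normal;
* **heterogeneous** — effect $\theta$ if the sample carries ALT at
  either of two causal SNPs;
* **recessive** — $\theta$ only if it carries ALT at both;
* **compensatory** — $\theta$ only if it carries ALT at exactly one.

"Carries" means dosage $\ge 1$ by default. The alternative reading of
allele presence — homozygosity, dosage $= 2$ — is a defensible
interpretation for the recessive pattern in particular, so it is exposed
as `carrier_mode = "homozygote"` rather than asserted away. The logic
architectures use a single effect $\theta$ (default 1; its magnitude is
irrelevant once heritability is fixed, since noise is scaled to match)
and require exactly two causal SNPs.

Noise is calibrated *exactly in sample*: with $\sigma_g^2$ the population
($1/n$) variance of the realized genetic values,
$\sigma_e^2 = \sigma_g^2 (1 - h^2)/h^2$ and
$y = g + e$, $e \sim N(0, \sigma_e^2)$. Using the population variance
makes the calibration an identity rather than an expectation; the
acceptance suite verifies that the mean realized $\mathrm{Var}(g) /
\mathrm{Var}(y)$ over 1000 genes stays within $\pm 0.02$ of the target
for every architecture and $h^2 \in \{0.02, 0.05, 0.1, 0.5\}$. A gene
whose genetic values are constant (e.g. no carrier of a recessive
pattern) has no defined calibration; it is redrawn up to `max_redraws`
times and otherwise skipped — silently absorbing such genes as $h^2 = 0$
would bias every benchmark cell downward.

All randomness flows through explicit seeds; multi-gene helpers pre-draw
per-gene seed rows, so enlarging a study never perturbs earlier genes.

## Comparators and evaluation

Four baseline selectors share the `selection_result` schema so the
harness is selector-agnostic:

* **LASSO** and **elastic net** (mixing 0.5; a stated choice — the value
  is rarely reported in eQTL applications): `cv.glmnet` nonzeros at the
  CV-minimizing penalty.
* **Thresholded ridge**: ridge keeps every coefficient nonzero, so
  variants are selected when the absolute coefficient on unit-variance
  standardized dosages is at least `tau = 0.6` (boundary inclusive).
  Applying the threshold on the standardized scale makes the rule
  invariant to dosage coding and expression units; on the raw scale the
  same number would mean different things for a MAF-0.05 and a MAF-0.5
  SNP.
* **Marginal association**: per-SNP simple-regression t-tests with the
  per-gene Bonferroni rule, selected iff $p < \alpha/m$ strictly
  ($\alpha = 0.05$, $m$ = cis-SNP count); zero-variance SNPs get $p = 1$.

Selections are scored against the simulation truth by precision, recall
and F1, with every degenerate ratio (empty selection and/or empty truth)
defined as 0 — an all-zero model should score 0, not NaN. Per-gene F1 is
macro-averaged across genes by default because each gene is one
selection problem; pooled (micro) averaging is available via
`average = "micro"`. `set_similarity_f1()` is the symmetric Dice form of
the same statistic, used to compare eQTL sets between conditions or
tissues. `one_way_anova()` provides the classical fixed-effects F-test of
expression across rounded genotype classes (classes under `min_n = 3`
samples are dropped; no multiple-testing correction is applied inside the
module — callers own that choice).

## Genotype input conventions

Dosages count ALT alleles (PLINK A1 is stored as ALT by `write_plink()`),
while MAF is computed orientation-independently as $\min(f, 1-f)$.
Missing hard calls are mean-imputed per variant — the standard choice for
penalized-regression pipelines, keeping $X$ dense without inventing LD
structure. Coordinates are 1-based; cis-windows are closed intervals
$[\mathrm{TSS} - w, \mathrm{TSS} + w]$ with $w$ defaulting to 1 Mb, the
conventional cis definition. The default MAF filter is 0.01 and can be
set to 0 (monomorphic variants are always removed; they carry no
information and break standardization). Genes with fewer than 2 usable
cis SNPs are skipped.

## Numerical choices and degenerate inputs

* Fitting standardization: columns of $X$ centered and scaled to unit sum
  of squares, $y$ centered; this makes the thresholding update exact and
  the penalties comparable across SNPs. Reported coefficients are
  back-transformed to the dosage scale; the support is scale-invariant.
  Zero-variance columns are frozen at zero rather than dropped, so
  indices are stable.
* Convergence: relative objective change below `tol = 1e-7` per sweep;
  `max_iter = 1000` sweeps per descent phase, `max_swaps = 100` accepted
  swaps. Non-convergence is reported via `converged = FALSE`, never an
  exception.
* Swap acceptance requires improvement beyond $10^{-10}$ to avoid cycling
  on floating-point ties.
* CV folds with zero response variance are skipped with a message.
* ANOVA conventions: equal group means with positive within-group
  variance give $F = 0, p = 1$; zero variance everywhere gives $p = 1$;
  zero within-group variance with distinct means gives $p = 0$.

## Problem sizes used by the test and acceptance suites

The suites simulate at the scale the benchmark design calls for while
staying desk-sized: solver/oracle agreement on 200 instances of $n = 30$,
$p \le 10$; heritability calibration on 1000 genes per architecture ×
heritability cell ($n = 300$, $p = 10$); causal-pair recovery on 100
genes at $n = 500$, $p = 50$, $\rho = 0.3$, $h^2 = 0.5$; the
heritability-trend benchmark on 300 genes at $n = 670$ (a typical large
eQTL tissue panel) for $h^2 \in \{0.02, 0.1\}$; and family-wise error on
10,000 null genes with $m = 20$. `scripts/acceptance.R` re-runs the same
computations at moderately reduced replicate counts and writes every
quantity with the problem size used.

## Known limitations

* No covariate or latent-factor adjustment; residualize expression first.
* Mean imputation only; no phasing, no BGEN/PGEN input.
* The genotype generator's LD is stationary AR(1) — no haplotype blocks,
  no MAF-dependent LD; conclusions about real panels need real panels.
* The logic architectures are two-SNP patterns with a single shared
  effect; higher-order epistasis is out of scope.
* Selection-frequency ensembles subsample individuals, not genes; no
  cross-gene information sharing of any kind.
* The per-gene model assumes independent samples; related individuals
  will inflate apparent precision.
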