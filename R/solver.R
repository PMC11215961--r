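#' L0+L1 penalized least-squares objective
#'
#' Evaluates `J(beta) = (1/2) ||y - X beta||^2 + lambda0 ||beta||_0 +
#' lambda1 ||beta||_1` exactly as given — no standardization is applied, so
#' this can audit a fit on either the standardized or the original scale.
#'
#' @param X design matrix, samples x variants.
#' @param y response vector.
#' @param beta coefficient vector.
#' @param lambda0 per-nonzero (L0) penalty, >= 0.
#' @param lambda1 absolute-value (L1) penalty, >= 0.
#' @return The objective value.
#' @export
l0l1_objective <- function(X, y, beta, lambda0, lambda1) {
  r <- y - drop(X %*% beta)
  0.5 * sum(r^2) + lambda0 * sum(beta != 0) + lambda1 * sum(abs(beta))
}

#' One-dimensional L0+L1 thresholding update
#'
#' The exact scalar minimizer of the coordinate subproblem for a column
#' with unit sum of squares: soft-threshold the partial-residual
#' correlation `rho` by `lambda1`, then keep the result only if the
#' improvement it buys, `t^2 / 2`, covers the per-nonzero price `lambda0`
#' (equivalently `|t| >= sqrt(2 lambda0)`; ties keep the nonzero).
#' With `lambda0 = 0` this is the lasso soft-thresholding rule; with
#' `lambda1 = 0` it is best-subset hard thresholding.
#'
#' @param rho partial-residual correlation `x_j' (y - X_{-j} beta_{-j})`.
#' @param lambda0,lambda1 penalties, >= 0.
#' @return The updated scalar coefficient.
#' @export
threshold_update <- function(rho, lambda0, lambda1) {
  t <- sign(rho) * pmax(abs(rho) - lambda1, 0)
  ifelse(0.5 * t^2 >= lambda0 & t != 0, t, 0)
}

# Center y; center X columns and scale them to unit sum of squares.
# Zero-variance columns get scale 1 and an all-zero column (their
# coefficient can never leave 0).
standardize_xy <- function(X, y) {
  X <- as.matrix(X)
  cx <- colMeans(X)
  Xc <- sweep(X, 2, cx)
  scale <- sqrt(colSums(Xc^2))
  zero <- scale <= 0
  scale[zero] <- 1
  Xs <- sweep(Xc, 2, scale, `/`)
  my <- mean(y)
  list(Xs = Xs, yc = y - my, center = cx, scale = scale, y_mean = my,
       zero = zero)
}

# Back-transform standardized coefficients to the dosage scale and compute
# the intercept.
unstandardize_beta <- function(beta_std, std) {
  beta <- beta_std / std$scale
  intercept <- std$y_mean - sum(std$center * beta)
  list(beta = beta, intercept = intercept)
}

#' Fit the L0+L1 model at one penalty pair
#'
#' Minimizes the penalized squared-error objective by cyclic coordinate
#' descent with the [threshold_update()] rule, alternating with a local
#' combinatorial search: every (drop active j, admit inactive k) swap is
#' scored, the best strictly improving swap is taken, and descent resumes,
#' until no swap improves the objective. The objective never increases
#' across a sweep or an accepted swap. Fitting happens on standardized data
#' (columns of `X` scaled to unit sum of squares, `y` centered); both
#' coefficient scales are returned.
#'
#' @param X dosage matrix, samples x variants.
#' @param y expression vector.
#' @param lambda0,lambda1 penalties, >= 0.
#' @param beta_init optional warm start (standardized scale).
#' @param tol relative objective-change convergence tolerance per sweep.
#' @param max_iter maximum coordinate-descent sweeps per descent phase.
#' @param max_swaps maximum accepted local-search swaps.
#' @return An object of class `l0l1_fit`: `beta` (original scale, named),
#'   `beta_std`, `intercept`, `support` (integer indices of nonzeros),
#'   `penalty`, `objective` (standardized scale), `n_iterations`,
#'   `n_swaps`, `converged`, `objective_trace` (objective after every sweep
#'   and accepted swap — non-increasing by construction), `cv_error`
#'   (NULL unless fit via
#'   [select_by_cv()]).
#' @export
fit_l0l1 <- function(X, y, lambda0 = 0, lambda1 = 0, beta_init = NULL,
                     tol = 1e-7, max_iter = 1000, max_swaps = 100) {
  stopifnot(nrow(X) == length(y), lambda0 >= 0, lambda1 >= 0)
  std <- standardize_xy(X, y)
  p <- ncol(X)
  if (is.null(beta_init)) beta_init <- rep(0, p)
  res <- .cpp_fit_l0l1(std$Xs, std$yc, lambda0, lambda1, beta_init, tol,
                       as.integer(max_iter), as.integer(max_swaps))
  beta_std <- drop(res$beta)
  bt <- unstandardize_beta(beta_std, std)
  names(bt$beta) <- colnames(X)
  structure(
    list(beta = bt$beta, beta_std = beta_std, intercept = bt$intercept,
         support = which(beta_std != 0),
         penalty = list(lambda0 = lambda0, lambda1 = lambda1),
         objective = as.numeric(res$objective),
         n_iterations = res$n_iterations, n_swaps = res$n_swaps,
         converged = res$converged, objective_trace = res$trace,
         cv_error = NULL),
    class = "l0l1_fit")
}

#' @export
print.l0l1_fit <- function(x, ...) {
  cat("l0l1_fit: |support| = ", length(x$support),
      ", lambda0 = ", signif(x$penalty$lambda0, 4),
      ", lambda1 = ", signif(x$penalty$lambda1, 4),
      ", objective = ", signif(x$objective, 6), "\n", sep = "")
  invisible(x)
}

#' Default two-dimensional penalty grids
#'
#' `lambda1`: 50 log-spaced values from `lambda1_max = max_j |x_j' y|` (the
#' smallest L1 penalty with an all-zero solution, on standardized data)
#' down four decades. `lambda0`: 20 log-spaced values from
#' `lambda1_max^2 / 2` (the hard threshold no single column can pass) down
#' four decades, plus 0.
#'
#' @param X,y data on the original scale (standardized internally).
#' @param n_lambda1,n_lambda0 grid sizes.
#' @param decades dynamic range of each grid in log10 units.
#' @return List with sorted-descending `lambda0` and `lambda1` vectors.
#' @export
default_lambda_grids <- function(X, y, n_lambda1 = 50, n_lambda0 = 20,
                                 decades = 4) {
  std <- standardize_xy(X, y)
  l1max <- max(abs(crossprod(std$Xs, std$yc)))
  if (l1max <= 0) l1max <- 1
  lambda1 <- 10^seq(log10(l1max), log10(l1max) - decades,
                    length.out = n_lambda1)
  l0max <- 0.5 * l1max^2
  lambda0 <- c(10^seq(log10(l0max), log10(l0max) - decades,
                      length.out = n_lambda0), 0)
  list(lambda0 = lambda0, lambda1 = lambda1)
}

#' Warm-started fits along a 2-D penalty grid
#'
#' Fits every (lambda0, lambda1) pair, warm-starting along the descending
#' lambda0 path within each lambda1. Support size need not be monotone in
#' lambda0 (the objective is nonconvex); no such ordering is asserted.
#'
#' @inheritParams fit_l0l1
#' @param lambda0_grid,lambda1_grid penalty grids, sorted descending;
#'   `NULL` uses [default_lambda_grids()].
#' @return An object of class `l0l1_path`: `grid` (data.frame with
#'   lambda0, lambda1, objective, support_size, n_iterations, converged),
#'   `beta_std` (p x n_grid matrix), and the standardization recipe used.
#' @export
fit_l0l1_path <- function(X, y, lambda0_grid = NULL, lambda1_grid = NULL,
                          tol = 1e-7, max_iter = 1000, max_swaps = 100) {
  if (is.null(lambda0_grid) || is.null(lambda1_grid)) {
    g <- default_lambda_grids(X, y)
    if (is.null(lambda0_grid)) lambda0_grid <- g$lambda0
    if (is.null(lambda1_grid)) lambda1_grid <- g$lambda1
  }
  lambda0_grid <- sort(lambda0_grid, decreasing = TRUE)
  lambda1_grid <- sort(lambda1_grid, decreasing = TRUE)
  std <- standardize_xy(X, y)
  res <- .cpp_fit_path(std$Xs, std$yc, lambda0_grid, lambda1_grid, tol,
                       as.integer(max_iter), as.integer(max_swaps))
  grid <- expand.grid(lambda0 = lambda0_grid, lambda1 = lambda1_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$objective <- as.numeric(res$objective)
  grid$support_size <- colSums(res$beta != 0)
  grid$n_iterations <- res$n_iterations
  grid$converged <- res$converged
  structure(list(grid = grid, beta_std = res$beta, std = std,
                 variant_ids = colnames(X)),
            class = "l0l1_path")
}

#' @export
print.l0l1_path <- function(x, ...) {
  cat("l0l1_path: ", nrow(x$grid), " penalty pairs, support sizes ",
      min(x$grid$support_size), "-", max(x$grid$support_size), "\n", sep = "")
  invisible(x)
}

#' Cross-validated penalty selection for the L0+L1 model
#'
#' K-fold cross-validation of mean squared prediction error over the 2-D
#' penalty grid; standardization is recomputed inside each training fold.
#' The model is refit on the full data at the chosen grid point. Under
#' `rule = "1se"` (default) the chosen point is the sparsest one — largest
#' `lambda0`, then largest `lambda1` — whose CV error is within one
#' standard error of the minimum, which suppresses the spurious extra
#' variants plain CV-minimization is known to admit. `rule = "min"` takes
#' the error-minimizing point outright, with exact ties broken toward the
#' sparser point.
#'
#' @inheritParams fit_l0l1_path
#' @param n_folds number of folds (>= 2).
#' @param seed optional integer seed for the fold assignment.
#' @param rule `"1se"` (default) or `"min"`; see Details.
#' @return An `l0l1_fit` (see [fit_l0l1()]) with `cv_error` set and a
#'   `cv_table` attribute (the per-grid-point CV errors and their standard
#'   errors).
#' @export
select_by_cv <- function(X, y, lambda0_grid = NULL, lambda1_grid = NULL,
                         n_folds = 5, seed = NULL, rule = c("1se", "min"),
                         tol = 1e-7, max_iter = 1000, max_swaps = 100) {
  rule <- match.arg(rule)
  n <- nrow(X)
  stopifnot(n_folds >= 2, n >= n_folds)
  if (is.null(lambda0_grid) || is.null(lambda1_grid)) {
    g <- default_lambda_grids(X, y)
    if (is.null(lambda0_grid)) lambda0_grid <- g$lambda0
    if (is.null(lambda1_grid)) lambda1_grid <- g$lambda1
  }
  lambda0_grid <- sort(lambda0_grid, decreasing = TRUE)
  lambda1_grid <- sort(lambda1_grid, decreasing = TRUE)
  assign_folds <- function() sample(rep(seq_len(n_folds), length.out = n))
  folds <- if (is.null(seed)) assign_folds()
           else withr::with_seed(seed, assign_folds())

  n_grid <- length(lambda0_grid) * length(lambda1_grid)
  fold_mse <- matrix(NA_real_, n_folds, n_grid)
  fold_n <- rep(0, n_folds)
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    if (pop_var(y[tr]) == 0) {
      message("select_by_cv: fold ", k, " has zero-variance y, skipped")
      next
    }
    std <- standardize_xy(X[tr, , drop = FALSE], y[tr])
    res <- .cpp_fit_path(std$Xs, std$yc, lambda0_grid, lambda1_grid, tol,
                         as.integer(max_iter), as.integer(max_swaps))
    beta_orig <- res$beta / std$scale
    intercepts <- std$y_mean - drop(crossprod(beta_orig, std$center))
    pred <- X[!tr, , drop = FALSE] %*% beta_orig
    pred <- sweep(pred, 2, intercepts, `+`)
    fold_mse[k, ] <- colMeans((pred - y[!tr])^2)
    fold_n[k] <- sum(!tr)
  }
  used <- fold_n > 0
  if (!any(used)) stop("select_by_cv: every fold was skipped")
  cv_mse <- colSums(fold_mse[used, , drop = FALSE] * fold_n[used]) /
    sum(fold_n[used])
  cv_se <- apply(fold_mse[used, , drop = FALSE], 2, sd) / sqrt(sum(used))

  grid <- expand.grid(lambda0 = lambda0_grid, lambda1 = lambda1_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$cv_error <- cv_mse
  grid$cv_se <- cv_se
  imin <- which.min(cv_mse)
  cand <- if (rule == "1se") {
    which(cv_mse <= cv_mse[imin] + cv_se[imin])
  } else {
    which(cv_mse == cv_mse[imin])
  }
  # sparser (larger-penalty) points win within the candidate set
  cand <- cand[order(grid$lambda0[cand], grid$lambda1[cand],
                     decreasing = TRUE)]
  best <- cand[1]
  fit <- fit_l0l1(X, y, grid$lambda0[best], grid$lambda1[best], tol = tol,
                  max_iter = max_iter, max_swaps = max_swaps)
  fit$cv_error <- cv_mse[best]
  attr(fit, "cv_table") <- grid
  fit
}

#' Stability-selection ensemble over subsamples
#'
#' Repeats [select_by_cv()] on random subsamples drawn without replacement
#' and retains variants selected in at least a `freq_threshold` fraction of
#' them. With `n_boot = 1` and `subsample_frac = 1` this reduces exactly to
#' a single cross-validated fit. Off by default throughout the package
#' (`n_boot = 1`); it trades computation for selection stability on noisy
#' genes.
#'
#' @inheritParams select_by_cv
#' @param n_boot number of subsamples.
#' @param subsample_frac fraction of samples per subsample, in (0, 1].
#' @param freq_threshold selection-frequency cutoff for the final support.
#' @return List of class `l0l1_ensemble`: `frequencies` (per-variant
#'   selection frequency), `support` (indices with frequency >=
#'   `freq_threshold`), `n_boot`, `freq_threshold`, and `fits` (the
#'   per-subsample `l0l1_fit`s).
#' @export
stability_ensemble <- function(X, y, lambda0_grid = NULL,
                               lambda1_grid = NULL, n_boot = 1,
                               subsample_frac = 1, freq_threshold = 0.5,
                               n_folds = 5, seed = NULL, ...) {
  stopifnot(n_boot >= 1, subsample_frac > 0, subsample_frac <= 1)
  n <- nrow(X)
  m <- max(2, round(subsample_frac * n))
  boot_seeds <- if (is.null(seed)) rep(list(NULL), n_boot)
                else as.list(withr::with_seed(seed,
                       sample.int(.Machine$integer.max, n_boot)))
  if (n_boot == 1 && subsample_frac == 1) boot_seeds <- list(seed)
  counts <- rep(0, ncol(X))
  fits <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- if (subsample_frac == 1) seq_len(n) else {
      draw <- function() sample.int(n, m)
      if (is.null(boot_seeds[[b]])) draw()
      else withr::with_seed(boot_seeds[[b]], draw())
    }
    fit <- select_by_cv(X[idx, , drop = FALSE], y[idx], lambda0_grid,
                        lambda1_grid, n_folds = n_folds,
                        seed = boot_seeds[[b]], ...)
    counts[fit$support] <- counts[fit$support] + 1
    fits[[b]] <- fit
  }
  freq <- counts / n_boot
  names(freq) <- colnames(X)
  structure(list(frequencies = freq,
                 support = which(freq >= freq_threshold & freq > 0),
                 n_boot = n_boot,
                 freq_threshold = freq_threshold, fits = fits),
            class = "l0l1_ensemble")
}

#' Brute-force L0+L1 optimum for small problems
#'
#' Enumerates every support, solves each support-restricted convex L1
#' problem by plain soft-threshold coordinate descent, adds the L0 cost of
#' the realized nonzeros, and returns the best. Exponential in `ncol(X)`
#' (capped at 20 columns); exists as an independent reference optimum for
#' validating [fit_l0l1()] on small instances, not for analysis use.
#'
#' @inheritParams fit_l0l1
#' @return List with `beta` (original scale), `beta_std`, `objective`
#'   (standardized scale, comparable to `fit_l0l1()$objective`).
#' @export
l0l1_exhaustive <- function(X, y, lambda0 = 0, lambda1 = 0) {
  std <- standardize_xy(X, y)
  res <- .cpp_exhaustive_l0l1(std$Xs, std$yc, lambda0, lambda1)
  beta_std <- drop(res$beta)
  bt <- unstandardize_beta(beta_std, std)
  list(beta = bt$beta, beta_std = beta_std, objective = res$objective)
}
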