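test_that("objective evaluates the penalized squared-error loss", {
  y <- c(3, -1, 2)
  X <- matrix(rnorm(9), 3, 3)
  expect_equal(l0l1_objective(X, y, rep(0, 3), 1, 1), 0.5 * sum(y^2))

  # lambda0 = lambda1 = 0 at the OLS solution: RSS/2 at its minimum
  fit <- lm(y ~ X - 1)
  expect_equal(l0l1_objective(X, y, coef(fit), 0, 0),
               0.5 * sum(resid(fit)^2))
  expect_lt(l0l1_objective(X, y, coef(fit), 0, 0),
            l0l1_objective(X, y, coef(fit) + 0.1, 0, 0))

  # unit-norm single column, y = 2x, beta = 1.5:
  # 0.5*(0.5)^2 + lambda0 + lambda1*1.5 = 0.125 + 0.1 + 0.3
  x <- c(1, 0, 0)
  expect_equal(l0l1_objective(cbind(x), 2 * x, 1.5, 0.1, 0.2), 0.525)
})

test_that("threshold update is soft-thresholding gated by the L0 price", {
  expect_equal(threshold_update(1.0, 0, 0.3), 0.7)    # LASSO limit
  expect_equal(threshold_update(-1.0, 0, 0.3), -0.7)
  expect_equal(threshold_update(1.0, 0.5, 0.3), 0)    # 0.7 < sqrt(2*0.5)
  expect_equal(threshold_update(2.0, 0.5, 0.5), 1.5)  # 1.5 >= 1.0
  expect_equal(threshold_update(0.1, 0, 0.3), 0)
  # boundary |t| = sqrt(2 lambda0) keeps the nonzero
  expect_equal(threshold_update(1.0, 0.5, 0), 1.0)
})

test_that("unpenalized fit matches least squares", {
  set.seed(2)
  X <- matrix(rnorm(60 * 6), 60, 6)
  y <- drop(X %*% c(1, -2, 0, 0, 0.5, 0)) + rnorm(60)
  fit <- fit_l0l1(X, y, 0, 0, tol = 1e-14, max_iter = 5000)
  ols <- coef(lm(y ~ X))
  expect_lt(max(abs(fit$beta - ols[-1])), 1e-8)
  expect_lt(abs(fit$intercept - ols[1]), 1e-8)
})

test_that("orthonormal design reduces the fit to columnwise thresholding", {
  set.seed(3)
  raw <- scale(matrix(rnorm(40 * 5), 40, 5), scale = FALSE)
  Q <- qr.Q(qr(raw)) # orthonormal and zero-mean columns
  y <- drop(Q %*% c(2, -1.5, 0.4, 0, 0)) + 0.1 * rnorm(40)
  yc <- y - mean(y)
  for (pen in list(c(0.05, 0.1), c(0.3, 0), c(0, 0.5))) {
    fit <- fit_l0l1(Q, y, pen[1], pen[2], tol = 1e-14)
    expected <- threshold_update(drop(crossprod(Q, yc)), pen[1], pen[2])
    expect_equal(unname(fit$beta_std), unname(expected), tolerance = 1e-8)
  }
})

test_that("a prohibitive L0 penalty empties the support", {
  set.seed(4)
  X <- matrix(rnorm(50 * 8), 50, 8)
  y <- drop(X %*% rnorm(8)) + rnorm(50)
  std <- sparseqtl:::standardize_xy(X, y)
  l0_big <- 0.5 * max(abs(crossprod(std$Xs, std$yc)))^2 * 1.01
  fit <- fit_l0l1(X, y, l0_big, 0)
  expect_length(fit$support, 0)
})

test_that("reported objective is recomputable from the returned fit", {
  for (s in 1:10) {
    inst <- make_instance(s)
    fit <- fit_l0l1(inst$X, inst$y, 0.2, 0.3)
    std <- sparseqtl:::standardize_xy(inst$X, inst$y)
    expect_equal(fit$objective,
                 l0l1_objective(std$Xs, std$yc, fit$beta_std, 0.2, 0.3),
                 tolerance = 1e-10)
    expect_identical(fit$support, which(fit$beta_std != 0))
  }
})

test_that("the objective never increases across sweeps or accepted swaps", {
  for (s in 1:10) {
    inst <- make_instance(s, n = 40)
    fit <- fit_l0l1(inst$X, inst$y, 0.1, 0.2)
    expect_true(all(diff(fit$objective_trace) <= 1e-12))
    # and local search can only improve on pure coordinate descent
    no_swap <- fit_l0l1(inst$X, inst$y, 0.5, 0.1, max_swaps = 0)$objective
    with_swap <- fit_l0l1(inst$X, inst$y, 0.5, 0.1)$objective
    expect_lte(with_swap, no_swap + 1e-12)
  }
})

test_that("column permutation permutes the solution identically", {
  inst <- make_instance(17, n = 50, p = 8)
  fit <- fit_l0l1(inst$X, inst$y, 0.1, 0.3, tol = 1e-13)
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  fit_p <- fit_l0l1(inst$X[, perm], inst$y, 0.1, 0.3, tol = 1e-13)
  expect_equal(unname(fit_p$beta), unname(fit$beta[perm]), tolerance = 1e-7)
})

test_that("solver reaches the exhaustive-support optimum on small problems", {
  # a slice of the full 200-instance check run in the acceptance suite
  gaps <- vapply(1:40, function(s) {
    inst <- make_instance(s)
    set.seed(s + 5000)
    l0 <- runif(1, 0.01, 1)
    l1 <- runif(1, 0.01, 1)
    fit <- fit_l0l1(inst$X, inst$y, l0, l1)
    ora <- l0l1_exhaustive(inst$X, inst$y, l0, l1)
    expect_gte(fit$objective, ora$objective - 1e-9) # oracle is a lower bound
    (fit$objective - ora$objective) / max(abs(ora$objective), 1e-12)
  }, numeric(1))
  expect_gte(mean(gaps <= 0.01), 0.95)
})

test_that("pure-L1 paths match glmnet and grids behave as documented", {
  set.seed(31)
  X <- matrix(rnorm(80 * 10), 80, 10)
  y <- drop(X %*% c(2, -1, rep(0, 8))) + rnorm(80)
  std <- sparseqtl:::standardize_xy(X, y)
  grids <- default_lambda_grids(X, y)
  expect_equal(grids$lambda1[1], max(abs(crossprod(std$Xs, std$yc))))
  expect_equal(min(grids$lambda0), 0)

  # lambda0 = 0 path equals the convex solver on the same grid
  lam1 <- grids$lambda1[seq(1, 50, by = 7)]
  path <- fit_l0l1_path(X, y, lambda0_grid = 0, lambda1_grid = lam1,
                        tol = 1e-14, max_iter = 5000)
  gfit <- glmnet::glmnet(std$Xs, std$yc, lambda = sort(lam1, TRUE) / 80,
                         standardize = FALSE, intercept = FALSE,
                         thresh = 1e-14)
  expect_lt(max(abs(path$beta_std - as.matrix(gfit$beta))), 1e-4)

  # lambda0 above (1/2) lambda1_max^2 gives an empty fit; exactly at the
  # boundary the best column ties and the thresholding rule keeps it
  path0 <- fit_l0l1_path(X, y,
                         lambda0_grid = grids$lambda0[1] * (1 + 1e-9),
                         lambda1_grid = 0)
  expect_equal(path0$grid$support_size[1], 0)
  at_boundary <- fit_l0l1_path(X, y, lambda0_grid = grids$lambda0[1],
                               lambda1_grid = 0)
  expect_lte(at_boundary$grid$support_size[1], 1)

  # single grid point equals the one-shot fit
  single <- fit_l0l1_path(X, y, lambda0_grid = 0.2, lambda1_grid = 0.4)
  one <- fit_l0l1(X, y, 0.2, 0.4)
  expect_equal(drop(single$beta_std), one$beta_std, tolerance = 1e-10)
  expect_equal(single$grid$objective, one$objective, tolerance = 1e-10)
})

test_that("cross-validation selects sparse truth and breaks ties upward", {
  # all-empty grid: every point ties, the largest penalties must win
  set.seed(41)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- rnorm(60)
  big <- 1e6
  for (rule in c("min", "1se")) {
    fit <- select_by_cv(X, y, lambda0_grid = c(big, big / 2),
                        lambda1_grid = c(big, big / 2), seed = 1,
                        rule = rule)
    expect_length(fit$support, 0)
    expect_equal(fit$penalty$lambda0, big)
    expect_equal(fit$penalty$lambda1, big)
  }

  # "min" refits at the CV-error-minimizing grid point
  set.seed(42)
  Xs <- matrix(rnorm(80 * 6), 80, 6)
  ys <- drop(Xs %*% c(1.5, 0, 0, -1, 0, 0)) + rnorm(80)
  fmin <- select_by_cv(Xs, ys, seed = 2, rule = "min")
  tab <- attr(fmin, "cv_table")
  expect_equal(fmin$cv_error, min(tab$cv_error))
  expect_true(all(c("cv_error", "cv_se") %in% names(tab)))
  # the 1se choice is never denser than the min choice on the same folds
  f1se <- select_by_cv(Xs, ys, seed = 2, rule = "1se")
  expect_lte(length(f1se$support), length(fmin$support))

  # pure noise: support almost always empty
  empties <- vapply(1:60, function(s) {
    set.seed(s)
    X <- matrix(rnorm(100 * 10), 100, 10)
    y <- rnorm(100)
    length(select_by_cv(X, y, seed = s)$support) == 0
  }, logical(1))
  expect_gte(mean(empties), 0.9)

  # strong single causal variant: exactly recovered
  hits <- vapply(1:40, function(s) {
    panel <- simulate_genotype_panel(500, 10, ld_rho = 0.3, seed = 7000 + s)
    gene <- simulate_expression(panel,
                                config = sim_config("additive", 1, h2 = 0.8),
                                seed = 8000 + s)
    identical(select_by_cv(panel$dosages, gene$expression,
                           seed = s)$support, gene$causal_indices)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("stability ensemble reduces to CV selection and counts honestly", {
  inst <- make_instance(55, n = 60, p = 6)
  ens <- stability_ensemble(inst$X, inst$y, n_boot = 1, subsample_frac = 1,
                            seed = 9)
  cv <- select_by_cv(inst$X, inst$y, seed = 9)
  expect_identical(ens$support, cv$support)

  ens2 <- stability_ensemble(inst$X, inst$y, n_boot = 5,
                             subsample_frac = 0.8, freq_threshold = 0,
                             seed = 10)
  expect_true(all(ens2$frequencies >= 0 & ens2$frequencies <= 1))
  counts <- Reduce(`+`, lapply(ens2$fits, function(f)
    as.numeric(seq_len(ncol(inst$X)) %in% f$support)))
  expect_equal(unname(ens2$frequencies), counts / 5)
  # threshold 0 keeps every ever-selected variant
  expect_identical(ens2$support, which(counts > 0))
})
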