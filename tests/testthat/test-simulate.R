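test_that("genotype panels are reproducible and respect the MAF spectrum", {
  p1 <- simulate_genotype_panel(100, 20, seed = 3)
  p2 <- simulate_genotype_panel(100, 20, seed = 3)
  expect_identical(p1$dosages, p2$dosages)
  expect_true(all(p1$dosages %in% 0:2))

  narrow <- simulate_genotype_panel(4000, 30, maf_low = 0.2, maf_high = 0.3,
                                    seed = 4)
  expect_true(all(narrow$maf > 0.12 & narrow$maf < 0.38))
})

test_that("ld_rho controls adjacent-variant dosage correlation", {
  adj_cor <- function(panel) {
    cm <- cor(panel$dosages)
    mean(cm[cbind(1:(ncol(cm) - 1), 2:ncol(cm))])
  }
  free <- simulate_genotype_panel(2000, 12, ld_rho = 0, seed = 9)
  cm <- cor(free$dosages)
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.05)

  weak <- simulate_genotype_panel(2000, 12, ld_rho = 0.2, seed = 10)
  strong <- simulate_genotype_panel(2000, 12, ld_rho = 0.9, seed = 10)
  expect_gt(adj_cor(strong), adj_cor(weak))
  expect_gt(adj_cor(weak), adj_cor(free))

  expect_error(simulate_genotype_panel(10, 5, ld_rho = 1), "ld_rho")
  expect_error(simulate_genotype_panel(10, 5, maf_low = 0), "maf_low")
})

test_that("causal sets are uniform draws without replacement", {
  expect_equal(draw_causal_set(4, 4, seed = 1), 1:4)
  expect_equal(draw_causal_set(4, 0, seed = 1), integer(0))
  expect_error(draw_causal_set(3, 4), "cannot draw")

  # 10,000 draws of 2 from 4: each of the 6 unordered pairs ~ 1/6
  draws <- withr::with_seed(42, replicate(10000, paste(
    draw_causal_set(4, 2), collapse = "-")))
  freq <- table(draws) / 10000
  expect_length(freq, 6)
  se <- sqrt((1 / 6) * (5 / 6) / 10000)
  expect_true(all(abs(freq - 1 / 6) < 3 * se + 1e-9))

  region <- cis_variants(make_test_panel(matrix(0:2, 3, 5)), "g", "1",
                         3000, 1500)
  expect_true(all(draw_causal_set(region, 2, seed = 7) %in%
                  region$variant_indices))
})

test_that("genetic values follow the architecture truth tables", {
  # additive: hand example
  dos <- matrix(c(1, 2), 1, 2)
  expect_equal(genetic_values(dos, 1:2, "additive", c(0.5, -1.0)), -1.5)

  # all 9 dosage pairs for the logic architectures (carrier reading)
  grid <- as.matrix(expand.grid(x1 = 0:2, x2 = 0:2))
  het <- genetic_values(grid, 1:2, "heterogeneous", 1)
  rec <- genetic_values(grid, 1:2, "recessive", 1)
  comp <- genetic_values(grid, 1:2, "compensatory", 1)
  c1 <- grid[, 1] >= 1
  c2 <- grid[, 2] >= 1
  expect_equal(het, as.numeric(c1 | c2))
  expect_equal(rec, as.numeric(c1 & c2))
  expect_equal(comp, as.numeric(xor(c1, c2)))
  # spec'd spot checks
  expect_equal(genetic_values(rbind(c(1, 0)), 1:2, "recessive", 1), 0)
  expect_equal(genetic_values(rbind(c(1, 2)), 1:2, "recessive", 1), 1)
  expect_equal(genetic_values(rbind(c(1, 0)), 1:2, "compensatory", 1), 1)
  expect_equal(genetic_values(rbind(c(1, 1)), 1:2, "compensatory", 1), 0)

  # homozygote reading is the stricter alternative
  hom <- genetic_values(grid, 1:2, "recessive", 1,
                        carrier_mode = "homozygote")
  expect_equal(hom, as.numeric(grid[, 1] == 2 & grid[, 2] == 2))

  expect_error(genetic_values(cbind(grid, x3 = 0), 1:3, "recessive", 1),
               "exactly 2")
})

test_that("environmental variance calibration matches the h2 identity", {
  g <- c(0, 2, 4) # population variance 8/3
  expect_equal(calibrate_environmental_variance(g, 0.5), 8 / 3)
  expect_equal(calibrate_environmental_variance(g, 1), 0)
  g2 <- c(-1, 1) # population variance 1
  expect_equal(calibrate_environmental_variance(g2, 0.02), 49)
  expect_error(calibrate_environmental_variance(rep(1, 5), 0.5),
               "degenerate")
})

test_that("simulated expression is reproducible and exact at h2 = 1", {
  panel <- simulate_genotype_panel(200, 10, seed = 21)
  cfg1 <- sim_config("additive", 2, h2 = 1)
  g1 <- simulate_expression(panel, config = cfg1, seed = 5)
  expect_equal(g1$expression, g1$genetic_values) # sigma_e2 = 0
  expect_equal(g1$sigma_e2, 0)

  cfg2 <- sim_config("additive", 2, h2 = 0.3)
  a <- simulate_expression(panel, config = cfg2, seed = 6)
  b <- simulate_expression(panel, config = cfg2, seed = 6)
  expect_identical(a$expression, b$expression)
  expect_identical(a$causal_indices, b$causal_indices)
  expect_equal(a$sigma_e2, a$sigma_g2 * 0.7 / 0.3)
})

test_that("realized heritability concentrates on the target", {
  # modest replicate count here; the full four-architecture calibration is
  # exercised at scale in the acceptance suite
  ratios <- vapply(1:300, function(i) {
    panel <- simulate_genotype_panel(300, 10, seed = 1000 + i)
    g <- simulate_expression(panel, config = sim_config("additive", 2,
                                                        h2 = 0.1),
                             seed = 2000 + i)
    g$sigma_g2 / mean((g$expression - mean(g$expression))^2)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.1), 0.03)
})

test_that("logic architectures honour n_causal = 2 and redraw degeneracy", {
  expect_error(sim_config("recessive", 3), "exactly 2")
  # a panel where one variant has no ALT carriers forces redraws
  dos <- cbind(rep(0, 50), rbinom(50, 2, 0.5), rbinom(50, 2, 0.5))
  dos[1, 1] <- 0
  panel <- make_test_panel(dos)
  cfg <- sim_config("recessive", 2, h2 = 0.5, max_redraws = 50)
  g <- simulate_expression(panel, config = cfg, seed = 8)
  expect_gt(g$sigma_g2, 0)
})

test_that("simulate_study assembles a consistent multi-gene dataset", {
  study <- simulate_study(n_genes = 4, n_samples = 60, variants_per_gene = 8,
                          config = sim_config("additive", 2, h2 = 0.4),
                          seed = 99)
  expect_equal(dim(study$panel$dosages), c(60, 32))
  expect_equal(dim(study$expression), c(60, 4))
  expect_equal(nrow(study$truth), 8) # 2 causal x 4 genes
  expect_true(all(study$truth$variant_id %in%
                  study$panel$variants$variant_id))
  for (i in 1:4) {
    gn <- study$genes[[i]]
    expect_true(all(gn$causal_indices %in% gn$region$variant_indices))
    expect_true(all(gn$region$variant_indices %in% ((i - 1) * 8 + 1:8)))
  }
  # determinism, and earlier genes unchanged when the study grows
  study2 <- simulate_study(n_genes = 6, n_samples = 60,
                           variants_per_gene = 8,
                           config = sim_config("additive", 2, h2 = 0.4),
                           seed = 99)
  expect_identical(study$expression[, 1:4], study2$expression[, 1:4])
  expect_identical(study$genes[[2]]$causal_indices,
                   study2$genes[[2]]$causal_indices)
})
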