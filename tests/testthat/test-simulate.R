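test_that("simulated genotypes are Binomial(2, maf)", {
  g <- sim_genotypes(1e4, maf = 0.3, seed = 51)
  expect_true(all(g %in% 0:2))
  expect_equal(mean(g), 0.6, tolerance = 0.05)
  g5 <- sim_genotypes(1e4, maf = 0.5, seed = 52)
  expect_equal(var(g5), 0.5, tolerance = 0.05)
  expect_identical(sim_genotypes(100, 0.3, seed = 53), sim_genotypes(100, 0.3, seed = 53))
})

test_that("effect sizes hit the PVE target", {
  # pve 0.2, maf 0.3, no heterogeneity: |b| = sqrt(0.25/0.42) exactly
  b <- sim_effects(c(1, 1, 1), phi = 0, omega = 1, pve = 0.2, maf = 0.3, seed = 54)
  expect_equal(abs(b), rep(sqrt(0.25 / 0.42), 3), tolerance = 1e-12)
  expect_equal(abs(b[1]), 0.7715, tolerance = 1e-4)
  # no heterogeneity: identical effects in all active tissues
  expect_equal(b[1], b[2])
  # inactive tissues get exactly zero
  b2 <- sim_effects(c(1, 0, 1), phi = 0.3, omega = 0.6, pve = 0.2, seed = 55)
  expect_identical(b2[2], 0)
  # mean squared effect matches the target across draws
  set.seed(56)
  draws <- replicate(4000, sim_effects(1, phi = 0.5, omega = sqrt(0.75), pve = 0.2))
  expect_equal(mean(draws^2), 0.25 / 0.42, tolerance = 0.03)
  expect_error(sim_effects(1, 0, 1, pve = 1), "pve")
})

test_that("simulated expression has the requested noise structure", {
  set.seed(57)
  g <- setNames(sim_genotypes(1e4, 0.3), sprintf("i%05d", 1:1e4))
  # zero effects: per-tissue variance equals the error variance
  y0 <- sim_expression(g, c(0, 0), error_variances = c(1, 2), seed = 58)
  expect_equal(apply(y0, 1, var), c(tissue1 = 1, tissue2 = 2), tolerance = 0.06)
  # intra-individual correlation propagates to the residuals
  yc <- sim_expression(g, c(0, 0), intra_corr = 0.5, seed = 59)
  expect_equal(cor(yc[1, ], yc[2, ]), 0.5, tolerance = 0.05)
  # a strong effect is recovered by regression within 3 SE
  yb <- sim_expression(g, c(0.8, 0), error_variances = 1, seed = 60)
  fit <- fit_tissue_regression(yb[1, ], g)
  expect_lt(abs(fit$betahat - 0.8), 3 * fit$se)
  expect_error(sim_expression(g, c(0, 0), intra_corr = -2), "positive definite")
})

test_that("sim_study produces the requested design, reproducibly", {
  counts <- c("000" = 25, "111" = 10, "100" = 5)
  sc <- sim_scenario(S = 3, n = c(20, 30, 30), config_counts = counts, seed = 61)
  st <- sim_study(sc)
  expect_equal(unname(table(st$truth$config)[names(counts)]),
               unname(counts), ignore_attr = TRUE)
  expect_equal(ncol(st$datasets[[1]]$expr), 20)  # unequal sample sizes honored
  expect_equal(ncol(st$datasets[[2]]$expr), 30)
  expect_true(all(st$datasets[[1]]$samples %in% st$datasets[[2]]$samples))
  expect_equal(nrow(st$genotypes$dosages), 40)
  # inactive tissues of "100" genes have zero planted effect
  b100 <- st$truth[st$truth$config == "100", ]
  expect_true(all(b100$b2 == 0 & b100$b3 == 0))
  expect_true(all(b100$b1 != 0))
  # byte-identical reruns under the same seed
  st2 <- sim_study(sc)
  expect_identical(st$datasets[[1]]$expr, st2$datasets[[1]]$expr)
  expect_identical(st$genotypes$dosages, st2$genotypes$dosages)
})

test_that("grid-drawn effect sizes span the size set", {
  sc <- sim_scenario(S = 2, n = 80, config_counts = c("00" = 0, "11" = 400),
                     heterogeneity = 0, effect_draw = "grid", seed = 62)
  st <- sim_study(sc)
  sizes <- sort(unique(round(abs(st$truth$b1), 6)))
  expect_equal(sizes, c(0.1, 0.2, 0.4, 0.8, 1.6), tolerance = 1e-6)
})

test_that("power_config_counts splits genes between null and q-active configs", {
  cc <- power_config_counts(5, q = 2, n_genes = 1000, seed = 63)
  expect_equal(sum(cc), 1000)
  expect_equal(unname(cc["00000"]), 500)
  active <- setdiff(names(cc), "00000")
  expect_true(all(vapply(strsplit(active, ""), function(x) sum(x == "1"), 0) == 2))
})

test_that("simulated null genes yield calibrated permutation p-values", {
  # closes the loop with the significance module at reduced scale
  st <- small_study(S = 3, n = 60, n_null = 80, n_alt = 0, seed = 64)
  ps <- permutation_scan(st$datasets, st$genotypes, st$cismap, n_perm = 100,
                         seed = 65)
  expect_gte(min(ps$p_perm), 1 / 101)
  ks <- suppressWarnings(ks.test(ps$p_perm, "punif"))
  expect_gt(ks$p.value, 0.001)
})
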