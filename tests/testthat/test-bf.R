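test_that("the null grid point gives BF = 1 and zero data gives BF < 1", {
  gd <- make_gene_data(S = 3, n = 80, b = 0.3, seed = 9)
  sm <- summaries_of(gd)
  for (gam in list(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))) {
    expect_equal(bf_config_gridpoint(sm, gam, phi = 0, omega = 0), 1)
  }
  # bhat = 0 in all tissues: BF is the Occam factor, strictly below 1
  sm0 <- sm
  sm0$betahat <- 0
  sm0$bhat <- 0
  bf0 <- bf_config_gridpoint(sm0, c(1, 1, 1), phi = 0.2, omega = 0.4)
  expect_lt(bf0, 1)
  # and it decreases as the prior grows (nested-prior direction at bhat = 0)
  bf_big <- bf_config_gridpoint(sm0, c(1, 1, 1), phi = 0.4, omega = 0.8)
  expect_lt(bf_big, bf0)
})

test_that("single-tissue BF approaches the closed form at large n", {
  # bhat = 0.5, se = 0.1 (z = 5), omega = 0.4:
  # sqrt(se^2/(se^2+w^2)) * exp(z^2/2 * w^2/(se^2+w^2)) ~ 3.12e4
  summ <- tibble::tibble(tissue = "t", n = 2e6, muhat = 0, betahat = 0.5,
                         se = 0.1, sigmahat = 1, bhat = 0.5)
  closed <- sqrt(0.01 / 0.17) * exp(12.5 * 0.16 / 0.17)
  expect_equal(closed, 3.12e4, tolerance = 2e-3)
  expect_equal(bf_config_gridpoint(summ, 1, phi = 0, omega = 0.4), closed,
               tolerance = 1e-3)
})

test_that("approximate BF agrees with the numeric-integration oracle", {
  # small version of the oracle suite (the full 50-dataset run lives in the
  # acceptance tests); every instance within 5% here
  set.seed(10)
  for (rep in 1:6) {
    b <- c(0, 0.2, 0.8)[(rep %% 3) + 1]
    gd <- make_gene_data(S = 2, n = 100, b = b, sigma = c(1, 1.5), seed = 10 + rep)
    sm <- summaries_of(gd)
    phi <- c(0, 0.2, 0.3)[(rep %% 3) + 1]
    omega <- 0.4
    la <- bf_config_gridpoint(sm, c(1, 1), phi, omega, log = TRUE)
    lo <- bf_exact_oracle(gd$ys, gd$g, c(1, 1), phi, omega, log = TRUE)
    expect_lt(abs(exp(la - lo) - 1), 0.05)
  }
})

test_that("BF is scale-invariant and increases with the evidence", {
  gd <- make_gene_data(S = 2, n = 100, b = 0.5, seed = 21)
  sm <- summaries_of(gd)
  # rescaling one tissue's expression leaves the BF unchanged
  gd2 <- gd
  gd2$ys[[1]] <- 100 * gd2$ys[[1]]
  sm2 <- summaries_of(gd2)
  expect_equal(bf_config(sm, c(1, 1), build_grid(), log = TRUE),
               bf_config(sm2, c(1, 1), build_grid(), log = TRUE),
               tolerance = 1e-10)
  # monotone in |bhat| with all else fixed
  lbfs <- vapply(seq(0, 3, by = 0.25), function(z) {
    s <- sm
    s$betahat <- z * s$sigmahat
    bf_config_gridpoint(s, c(1, 1), phi = 0.1, omega = 0.4, log = TRUE)
  }, numeric(1))
  expect_true(all(diff(lbfs) > 0))
})

test_that("independent-path BF depends only on the active tissues", {
  gd <- make_gene_data(S = 3, n = 90, b = c(0.5, 0.4, 0), seed = 22)
  sm <- summaries_of(gd)
  b1 <- bf_config(sm, c(1, 1, 0), build_grid(), log = TRUE)
  sm_mod <- sm
  sm_mod$betahat[3] <- 5  # perturb an inactive tissue
  sm_mod$bhat[3] <- 5
  expect_equal(bf_config(sm_mod, c(1, 1, 0), build_grid(), log = TRUE), b1)
  # ... but with correlated residuals the inactive tissue matters
  rc <- matrix(c(1, .3, .3, .3, 1, .3, .3, .3, 1), 3, 3)
  c1 <- bf_config(sm, c(1, 1, 0), build_grid(), rcorr = rc, log = TRUE)
  c2 <- bf_config(sm_mod, c(1, 1, 0), build_grid(), rcorr = rc, log = TRUE)
  expect_false(isTRUE(all.equal(c1, c2)))
  expect_true(is.finite(c1) && is.finite(c2))
})

test_that("grid averaging is a weighted mean of grid-point BFs", {
  gd <- make_gene_data(S = 2, n = 80, b = 0.4, seed = 23)
  sm <- summaries_of(gd)
  g1 <- tibble::tibble(phi = 0.1, omega = 0.3, weight = 1)
  expect_equal(bf_config(sm, c(1, 1), g1),
               bf_config_gridpoint(sm, c(1, 1), 0.1, 0.3))
  g2 <- tibble::tibble(phi = c(0.1, 0), omega = c(0.3, 0.8), weight = c(0.5, 0.5))
  bfs <- c(bf_config_gridpoint(sm, c(1, 1), 0.1, 0.3),
           bf_config_gridpoint(sm, c(1, 1), 0, 0.8))
  expect_equal(bf_config(sm, c(1, 1), g2), mean(bfs), tolerance = 1e-12)
  expect_gte(bf_config(sm, c(1, 1), g2), min(bfs))
  expect_lte(bf_config(sm, c(1, 1), g2), max(bfs))
})

test_that("the oracle is exactly 1 at the null point and monotone in bhat", {
  gd <- make_gene_data(S = 1, n = 60, b = 0.4, seed = 24)
  expect_equal(bf_exact_oracle(gd$ys, gd$g, 1, phi = 0, omega = 0), 1)
  # monotone in the planted effect (stronger signal, larger oracle BF)
  vals <- vapply(c(0, 0.3, 0.8), function(b) {
    gdb <- make_gene_data(S = 1, n = 60, b = b, seed = 25)
    bf_exact_oracle(gdb$ys, gdb$g, 1, phi = 0.1, omega = 0.4, log = TRUE)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})
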