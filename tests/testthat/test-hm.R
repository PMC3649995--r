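# helpers building tiny bundles with known BF tables
tiny_bundle <- function(gene, bfs, L = 2) {
  # bfs: vector over configurations (same BF at every grid point)
  lbf <- array(rep(log(bfs), L), dim = c(1, length(bfs), L),
               dimnames = list(NULL, names(bfs), NULL))
  bf_bundle(gene, lbf)
}

test_that("hierarchical-model log-likelihood matches direct arithmetic", {
  cfgs <- c("10" = 2, "01" = 0.5, "11" = 8)
  b1 <- tiny_bundle("g1", cfgs)
  b2 <- tiny_bundle("g2", c("10" = 1, "01" = 1, "11" = 1))
  params <- list(pi0 = 0.6, eta = c(0.2, 0.3, 0.5), lambda = c(0.5, 0.5))
  # gene 1: avg BF = 0.2*2 + 0.3*0.5 + 0.5*8 = 4.55; gene 2: 1
  expect_equal(hm_loglik(params, list(b1, b2)),
               log(0.6 + 0.4 * 4.55) + log(0.6 + 0.4 * 1), tolerance = 1e-12)
  # pi0 = 1: relative likelihood is exactly the null's, i.e. 0
  expect_equal(hm_loglik(list(pi0 = 1, eta = c(0.2, 0.3, 0.5),
                              lambda = c(0.5, 0.5)), list(b1, b2)), 0)
  # all BFs 1: zero log-likelihood for any parameters
  expect_equal(hm_loglik(params, list(b2, b2)), 0, tolerance = 1e-12)
})

test_that("multi-SNP genes average BFs over SNPs in the likelihood", {
  lbf <- array(log(c(2, 6)), dim = c(2, 1, 1), dimnames = list(NULL, "1", NULL))
  b <- bf_bundle("g", lbf)
  params <- list(pi0 = 0.5, eta = 1, lambda = 1)
  expect_equal(hm_loglik(params, list(b, b)),
               2 * log(0.5 + 0.5 * mean(c(2, 6))), tolerance = 1e-12)
})

test_that("EM recovers parameters and increases the likelihood monotonically", {
  st <- small_study(S = 3, n = 100, n_null = 300, n_alt = 300, pve = 0.2, seed = 31)
  bun <- compute_bf_bundles(st$datasets, st$genotypes, st$cismap)
  fit <- em_fit(bun)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  # pi0 carries a small downward bias in this weak-boundary regime (see the
  # methods vignette); the configuration weight is sharp
  expect_equal(fit$pi0, 0.5, tolerance = 0.15)
  expect_equal(fit$eta$eta[fit$eta$config == "111"], 1, tolerance = 0.06)
  expect_equal(sum(fit$eta$eta), 1, tolerance = 1e-12)
  expect_equal(sum(fit$lambda$weight), 1, tolerance = 1e-12)
  # a converged fit is an EM fixed point: one more step barely moves
  one <- em_fit(bun, init = list(pi0 = fit$pi0, eta = fit$eta$eta,
                                 lambda = fit$lambda$weight), max_iter = 2L)
  expect_equal(one$pi0, fit$pi0, tolerance = 1e-4)
  expect_equal(one$eta$eta, fit$eta$eta, tolerance = 1e-3)
})

test_that("degenerate support concentrates the configuration weights", {
  set.seed(32)
  bs <- lapply(1:30, function(i) {
    tiny_bundle(paste0("g", i), c("10" = exp(rnorm(1, 4)), "01" = 0.1, "11" = 0.2))
  })
  fit <- em_fit(bs, init = list(pi0 = 0.2, eta = rep(1 / 3, 3), lambda = c(0.5, 0.5)))
  expect_gt(fit$eta$eta[1], 0.95)
})

test_that("fixed parameters stay at their initial values", {
  st <- small_study(S = 2, n = 60, n_null = 40, n_alt = 40, seed = 33)
  bun <- compute_bf_bundles(st$datasets, st$genotypes, st$cismap)
  fit <- em_fit(bun, fixed = c("pi0", "lambda"))
  expect_equal(fit$pi0, 0.9)
  expect_equal(fit$lambda$weight, rep(1 / 15, 15))
})

test_that("tidy and glance summarize a fit", {
  st <- small_study(S = 2, n = 60, n_null = 30, n_alt = 30, seed = 34)
  bun <- compute_bf_bundles(st$datasets, st$genotypes, st$cismap)
  fit <- em_fit(bun, grid = build_grid())
  td <- tidy(fit)
  expect_equal(nrow(td), 1 + 3 + 15)  # pi0, 3 configs, 15 grid points
  gl <- glance(fit)
  expect_equal(gl$n_genes, length(bun))
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("bootstrap intervals contain the estimate and collapse for identical genes", {
  set.seed(35)
  bs <- lapply(1:40, function(i) tiny_bundle(paste0("g", i), c("10" = 3, "01" = 0.5, "11" = 6)))
  fit <- em_fit(bs)
  expect_error(hm_confidence_intervals(fit, bs, n_boot = 5), "at least 20")
  ci <- hm_confidence_intervals(fit, bs, n_boot = 25, seed = 2)
  expect_true(all(ci$lower <= ci$estimate + 1e-3 & ci$estimate <= ci$upper + 1e-3))
  # identical genes: resampling changes nothing, intervals have ~zero width
  expect_lt(max(ci$upper - ci$lower), 1e-3)
})

test_that("residualizing the top SNP removes a single eQTL but not a second one", {
  set.seed(36)
  S <- 2; n <- 150; ng <- 12
  ids <- sprintf("i%03d", 1:n)
  genes <- sprintf("g%02d", 1:ng)
  snps <- paste0(rep(genes, each = 2), c("_a", "_b"))
  dos <- matrix(rbinom(2 * ng * n, 2, 0.3), 2 * ng, n, dimnames = list(snps, ids))
  cismap <- tibble::tibble(gene = rep(genes, each = 2), snp = snps)
  # genes 1..4: single eQTL at snp _a; genes 5..8: eQTLs at both; 9..12 null
  expr <- lapply(1:S, function(s) {
    E <- matrix(rnorm(ng * n), ng, n, dimnames = list(genes, ids))
    for (i in 1:4) E[i, ] <- E[i, ] + 0.8 * dos[2 * i - 1, ]
    for (i in 5:8) E[i, ] <- E[i, ] + 0.8 * dos[2 * i - 1, ] + 0.8 * dos[2 * i, ]
    E
  })
  datasets <- lapply(1:S, function(s) tissue_dataset(expr[[s]], paste0("t", s)))
  gt <- genotype_table(dos)
  bun <- compute_bf_bundles(datasets, gt, cismap)
  fit <- em_fit(bun)
  rel <- relax_single_eqtl(datasets, gt, cismap, bun, fit)
  expect_equal(length(rel$bundles), 2 * ng)
  stats <- bma_gene_stats(rel$bundles, default_weights(S), build_grid())
  art <- stats[grepl(":resid", stats$gene), ]
  one_eqtl <- art$log10_bf[match(paste0(genes[1:4], ":resid"), art$gene)]
  two_eqtl <- art$log10_bf[match(paste0(genes[5:8], ":resid"), art$gene)]
  nulls <- art$log10_bf[match(paste0(genes[9:12], ":resid"), art$gene)]
  expect_lt(median(one_eqtl), 1)       # signal removed: gene BF below 10
  expect_gt(min(two_eqtl), 2)          # second eQTL retained
  expect_lt(median(nulls), 1)          # null genes stay null
  # the top SNP identified for single-eQTL genes is the planted one
  expect_equal(rel$top_snps$snp[match(genes[1:4], rel$top_snps$gene)],
               paste0(genes[1:4], "_a"))
})
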