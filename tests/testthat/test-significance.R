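test_that("permutation p-values follow the add-one rule at the extremes", {
  gd <- make_gene_data(S = 1, n = 40, b = 0, seed = 41)
  data <- list(ys = gd$ys, g = gd$g)
  # statistic maximal on the observed labeling: y built as an exact copy of g
  data$ys[[1]] <- gd$g + 0  # perfect correlation
  stat_cor <- function(d) abs(cor(d$ys[[1]], d$g[names(d$ys[[1]])]))
  p <- permutation_pvalue(stat_cor, data, n_perm = 100, seed = 1)
  expect_equal(p, 1 / 101)
  # with "less", the same observed statistic is the least extreme
  p2 <- permutation_pvalue(stat_cor, data, n_perm = 100, seed = 1,
                           alternative = "less")
  expect_equal(p2, 1)
  expect_gte(p, 1 / 101)
})

test_that("permutation p-values are reproducible and respect the seed", {
  gd <- make_gene_data(S = 2, n = 30, b = 0.3, seed = 42)
  data <- list(ys = gd$ys, g = gd$g)
  stat <- function(d) tbt_min_p(d$ys, matrix(d$g, 1, dimnames = list("s", names(d$g))))
  p1 <- permutation_pvalue(stat, data, n_perm = 60, seed = 7, alternative = "less")
  p2 <- permutation_pvalue(stat, data, n_perm = 60, seed = 7, alternative = "less")
  expect_identical(p1, p2)
  expect_true(p1 > 0 && p1 <= 1)
})

test_that("Storey q-values estimate pi0 and agree with BH when pi0 = 1", {
  expect_equal(storey_qvalues(rep(1, 50))$qvalues, rep(1, 50))
  expect_equal(storey_qvalues(rep(1, 50))$pi0, 1)
  set.seed(43)
  p_unif <- runif(5000)
  pi0 <- storey_qvalues(p_unif)$pi0
  expect_gte(pi0, 0.9)
  # 50% strong signals: pi0 about one half
  p_mix <- c(runif(2500), rbeta(2500, 0.05, 10))
  expect_equal(storey_qvalues(p_mix)$pi0, 0.5, tolerance = 0.1)
  # with pi0 forced to 1 (small m) the q-values are Benjamini-Hochberg
  p_small <- runif(10)
  expect_warning(qs <- storey_qvalues(p_small), "fewer than 20")
  expect_equal(qs$qvalues, p.adjust(p_small, method = "BH"), tolerance = 1e-12)
  # monotone: larger p never gets a smaller q
  q <- storey_qvalues(p_unif)$qvalues
  ord <- order(p_unif)
  expect_true(all(diff(q[ord]) >= -1e-12))
})

test_that("eGene calls threshold the q-values", {
  expect_length(call_egenes(rep(1, 10), 0.05), 0)
  q <- c(a = 0.01, b = 0.04, c = 0.06)
  expect_equal(call_egenes(q, 0.05), c("a", "b"))
})

test_that("tissue-by-tissue min-p matches lm and decreases with more SNPs", {
  gd <- make_gene_data(S = 1, n = 50, b = 0.4, seed = 44)
  G1 <- matrix(gd$g, 1, dimnames = list("s1", names(gd$g)))
  got <- tbt_min_p(gd$ys, G1)
  lmp <- summary(lm(gd$ys[[1]] ~ gd$g))$coefficients[2, 4]
  expect_equal(got, lmp, tolerance = 1e-10)
  # perfect association: essentially zero
  ys_perf <- list(setNames(2 * gd$g + 1e-9 * rnorm(50), names(gd$g)))
  expect_lt(tbt_min_p(ys_perf, G1), 1e-20)
  # null data: min-p over many SNPs is stochastically smaller
  set.seed(45)
  n <- 60
  ids <- sprintf("i%03d", 1:n)
  G10 <- matrix(rbinom(10 * n, 2, 0.3), 10, n, dimnames = list(paste0("s", 1:10), ids))
  minp1 <- minp10 <- numeric(40)
  for (r in 1:40) {
    y <- list(setNames(rnorm(n), ids))
    minp1[r] <- tbt_min_p(y, G10[1, , drop = FALSE])
    minp10[r] <- tbt_min_p(y, G10)
  }
  expect_lt(mean(minp10), mean(minp1))
  # per-tissue mode returns one minimum per tissue
  gd2 <- make_gene_data(S = 3, n = 50, b = 0, seed = 46)
  expect_length(tbt_min_p(gd2$ys, G1 <- matrix(gd2$g, 1, dimnames = list("s", names(gd2$g))),
                          per_tissue = TRUE), 3)
})

test_that("the joint ANOVA F test matches the stacked linear model", {
  gd <- make_gene_data(S = 3, n = 40, b = c(0.5, 0, 0.2), seed = 47)
  got <- anova_lr_test(gd$ys, gd$g)
  # independent route: stacked lm with tissue-specific intercepts and slopes
  df <- data.frame(y = unlist(gd$ys),
                   tissue = factor(rep(1:3, each = 40)),
                   g = rep(gd$g, 3))
  a <- anova(lm(y ~ tissue, df), lm(y ~ tissue + tissue:g, df))
  expect_equal(got$statistic, a$F[2], tolerance = 1e-10)
  expect_equal(got$p_value, a$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(got$df1, 3)
  expect_error(anova_lr_test(gd$ys[1], gd$g), "at least 2")
})

test_that("overlap table tabulates presence patterns among called genes", {
  calls <- list(t1 = c("a", "b", "c"), t2 = c("a", "b", "c"), t3 = c("a", "b", "c"))
  ov <- overlap_table(calls)
  expect_equal(ov$pattern, "111")
  expect_equal(ov$prop, 1)
  dis <- overlap_table(list(t1 = "a", t2 = "b", t3 = "c"))
  expect_setequal(dis$pattern, c("100", "010", "001"))
  expect_equal(sum(dis$prop), 1)
  expect_equal(nrow(overlap_table(list(t1 = character(), t2 = character()))), 0)
})

test_that("pairwise pi1 tracks the shared fraction", {
  set.seed(48)
  expect_gt(pairwise_pi1(rbeta(200, 0.02, 10)), 0.85)
  expect_lt(pairwise_pi1(runif(500)), 0.15)
  p80 <- c(rbeta(400, 0.05, 10), runif(100))  # 80% shared
  expect_equal(pairwise_pi1(p80), 0.8, tolerance = 0.1)
  expect_error(pairwise_pi1(runif(10)), "at least 20")
})

test_that("truth-matched FDR counting picks the largest admissible set", {
  stat <- c(9, 8, 7, 6, 5)
  is_null <- c(FALSE, FALSE, TRUE, FALSE, TRUE)
  # top-2 fdp 0, top-3 fdp 1/3 > 0.05, so 2 discoveries
  expect_equal(fdr_matched_discoveries(stat, is_null, 0.05), 2)
  expect_equal(fdr_matched_discoveries(stat, is_null, 0.4), 5)
  expect_equal(fdr_matched_discoveries(stat, is_null, 0.39), 4)
  expect_equal(fdr_matched_discoveries(-stat, is_null, 0.05,
                                       larger_is_extreme = FALSE), 2)
  expect_equal(fdr_matched_discoveries(stat, rep(TRUE, 5), 0.05), 0)
})
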