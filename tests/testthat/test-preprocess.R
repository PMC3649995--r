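test_that("robust-gene filter matches direct evaluation of the rule", {
  set.seed(1)
  for (rep in 1:3) {
    e1 <- matrix(rnorm(100 * 8, mean = rep(runif(100, 0, 4), 8)), 100, 8,
                 dimnames = list(paste0("g", 1:100), paste0("i", 1:8)))
    e2 <- matrix(rnorm(100 * 6, mean = rep(runif(100, 0, 4), 6)), 100, 6,
                 dimnames = list(paste0("g", 1:100), paste0("j", 1:6)))
    got <- filter_robust_genes(list(tissue_dataset(e1, "a"), tissue_dataset(e2, "b")))
    pass1 <- rowMeans(e1) >= median(e1)
    pass2 <- rowMeans(e2) >= median(e2)
    expect_setequal(got, rownames(e1)[pass1 & pass2])
  }
})

test_that("robust-gene filter keeps the top gene and intersects across tissues", {
  e <- matrix(c(1, 2, 3), 3, 4, dimnames = list(c("a", "b", "c"), paste0("i", 1:4)))
  got <- filter_robust_genes(list(tissue_dataset(e)))
  expect_true("c" %in% got)  # the maximum-mean gene always passes
  # gene passing in one tissue only is excluded
  e2 <- e
  e2["c", ] <- -10
  got2 <- filter_robust_genes(list(tissue_dataset(e), tissue_dataset(e2)))
  expect_false("c" %in% got2)
  # disjoint gene universes error
  e3 <- e
  rownames(e3) <- c("x", "y", "z")
  expect_error(filter_robust_genes(list(tissue_dataset(e), tissue_dataset(e3))),
               "intersection")
})

test_that("PC removal projects out selected components", {
  set.seed(2)
  # dominant rank-1 structure
  u <- rnorm(40)
  v <- rnorm(30)
  X <- 10 * tcrossprod(u, v) + 0.1 * matrix(rnorm(40 * 30), 40, 30)
  dimnames(X) <- list(paste0("g", 1:40), paste0("i", 1:30))
  out <- remove_pcs(tissue_dataset(X), increment_threshold = 2.5e-5)
  expect_gte(out$n_pcs_removed, 1L)
  # residuals orthogonal to every removed PC
  Xc <- X - rowMeans(X)
  sv <- svd(Xc)
  res_c <- out$dataset$expr - rowMeans(out$dataset$expr)
  for (k in seq_len(out$n_pcs_removed)) {
    expect_lt(max(abs(res_c %*% sv$v[, k])), 1e-8)
  }
  # threshold 1 removes nothing and returns the input unchanged
  id <- remove_pcs(tissue_dataset(X), increment_threshold = 1)
  expect_identical(id$n_pcs_removed, 0L)
  expect_equal(id$dataset$expr, X)
})

test_that("PC removal equals an explicit least-squares refit", {
  set.seed(3)
  X <- matrix(rnorm(50 * 30), 50, 30,
              dimnames = list(paste0("g", 1:50), paste0("i", 1:30)))
  out <- remove_pcs(tissue_dataset(X), increment_threshold = 0.02)
  k <- out$n_pcs_removed
  expect_gt(k, 0L)
  sv <- svd(X - rowMeans(X))
  V <- sv$v[, seq_len(k), drop = FALSE]
  # regress each gene on the PCs (with intercept) and compare residuals+mean
  for (i in c(1, 25, 50)) {
    fit <- lm(X[i, ] ~ V)
    expect_equal(unname(out$dataset$expr[i, ]),
                 unname(residuals(fit) + mean(X[i, ])), tolerance = 1e-10)
  }
})

test_that("rank-normal transform maps ranks to normal quantiles", {
  expect_equal(quantile_normal_transform(c(10, 20, 30)),
               qnorm(c(0.5, 1.5, 2.5) / 3), tolerance = 1e-12)
  expect_equal(quantile_normal_transform(c(10, 20, 30))[c(1, 3)],
               c(-0.9674, 0.9674), tolerance = 1e-4)
  expect_equal(quantile_normal_transform(c(5, 9)), qnorm(c(0.25, 0.75)))
  expect_equal(quantile_normal_transform(c(5, 9))[2], 0.6745, tolerance = 1e-4)
})

test_that("rank-normal transform is monotone-invariant with mean zero", {
  set.seed(4)
  x <- rnorm(41)
  qx <- quantile_normal_transform(x)
  expect_equal(mean(qx), 0, tolerance = 1e-12)
  expect_equal(quantile_normal_transform(exp(x)), qx)  # monotone transform
  p <- sample(seq_along(x))
  expect_equal(quantile_normal_transform(x[p]), qx[p])  # matched by rank
  expect_warning(out <- quantile_normal_transform(rep(2, 5)), "degenerate")
  expect_equal(out, rep(0, 5))
})
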