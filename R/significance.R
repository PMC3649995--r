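# Gene-level significance: permutation p-values, Storey q-values, FDR calls,
# single-tissue / ANOVA baselines and pairwise sharing estimates.

# deterministic per-gene seed derived from the global seed and the gene ID,
# so permutation analyses are reproducible under any execution order
.gene_seed <- function(seed, gene) {
  h <- 0
  for (k in utf8ToInt(as.character(gene))) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Gene-level permutation p-value
#'
#' Compares an observed test statistic with its distribution under the
#' global null obtained by permuting individual labels. The same
#' permutation of individuals is applied to every tissue (implemented by
#' permuting the genotype labels once per replicate), preserving
#' intra-individual correlations between tissues. The p-value uses add-one
#' smoothing: `p = (1 + #{permuted >= observed}) / (n_perm + 1)`, with ties
#' counting as at least as extreme.
#'
#' @param stat_fn Function taking `data` and returning a scalar statistic;
#'   must be deterministic given its input.
#' @param data List with elements `ys` (list of per-tissue expression
#'   vectors, each named by individual ID) and `g` (genotype dosage vector
#'   named by individual ID, covering all individuals). `stat_fn` receives
#'   data of the same shape with `g` relabeled.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param alternative `"greater"` when large statistics are extreme (Bayes
#'   factors), `"less"` when small are (minimum p-values).
#' @return Scalar p-value in (0, 1\].
#' @export
permutation_pvalue <- function(stat_fn, data, n_perm, seed = 1L,
                               alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 1L, is.list(data), !is.null(data$g), !is.null(names(data$g)))
  obs <- stat_fn(data)
  if (!is.finite(obs)) stop("statistic not finite on observed data")
  ids <- names(data$g)
  set.seed(seed)
  hits <- 0L
  for (r in seq_len(n_perm)) {
    gp <- data$g
    names(gp) <- ids[sample.int(length(ids))]
    pd <- data
    pd$g <- gp
    s <- stat_fn(pd)
    if (!is.finite(s)) stop("statistic not finite on permuted data")
    ok <- if (alternative == "greater") s >= obs else s <= obs
    hits <- hits + as.integer(ok)
  }
  (1 + hits) / (n_perm + 1)
}

#' Storey q-values
#'
#' Estimates the null proportion `pi0` from the p-value histogram using the
#' lambda-grid smoother (`lambda = 0, 0.05, ..., 0.95`; cubic smoothing
#' spline of `pi0(lambda)` evaluated at the largest lambda, capped at 1)
#' and converts p-values to q-values by the step-wise minimum of
#' `pi0 * m * p / rank(p)`.
#'
#' @param pvalues Numeric vector of p-values in (0, 1\].
#' @return List with `qvalues` (same order as input) and `pi0`.
#' @export
storey_qvalues <- function(pvalues) {
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  m <- length(pvalues)
  if (m < 20L) {
    warning("fewer than 20 p-values; using pi0 = 1 (Benjamini-Hochberg)")
    pi0 <- 1
  } else {
    lam <- seq(0, 0.95, by = 0.05)
    pi0l <- vapply(lam, function(l) mean(pvalues > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lam, pi0l, df = 3)
    pi0 <- stats::predict(fit, x = max(lam))$y
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  ord <- order(pvalues, decreasing = TRUE)
  q <- numeric(m)
  running <- Inf
  rank_desc <- m:1
  for (i in seq_len(m)) {
    idx <- ord[i]
    running <- min(running, pi0 * m * pvalues[idx] / rank_desc[i])
    q[idx] <- min(running, 1)
  }
  list(qvalues = q, pi0 = pi0)
}

#' Call eGenes at a target FDR
#'
#' @param qvalues Numeric vector of q-values, optionally named by gene.
#' @param fdr Target false discovery rate in (0, 1).
#' @return Indices (or names, when available) of genes with `q <= fdr`.
#' @export
call_egenes <- function(qvalues, fdr = 0.05) {
  stopifnot(fdr > 0, fdr < 1)
  hit <- which(qvalues <= fdr)
  if (!is.null(names(qvalues))) names(qvalues)[hit] else hit
}

#' Tissue-by-tissue minimum-p statistic
#'
#' The baseline single-tissue test statistic: the minimum two-sided simple
#' regression p-value over all cis SNPs and (by default) all tissues.
#'
#' @param ys List of per-tissue expression vectors named by individual ID.
#' @param G Dosage matrix, SNPs x individuals, column names = individual
#'   IDs (a single SNP may be given as a named vector).
#' @param per_tissue When `TRUE`, return the per-tissue minima (vector of
#'   length S) instead of the overall minimum.
#' @return Minimum p-value (scalar, or per-tissue vector).
#' @export
tbt_min_p <- function(ys, G, per_tissue = FALSE) {
  if (!is.matrix(G)) G <- matrix(G, 1L, dimnames = list("snp", names(G)))
  stopifnot(nrow(G) >= 1L)
  minp <- vapply(ys, function(y) {
    ids <- names(y)
    stopifnot(all(ids %in% colnames(G)))
    ps <- apply(G[, ids, drop = FALSE], 1L, function(g) .ols_pvalue(y, g))
    min(ps)
  }, numeric(1))
  if (per_tissue) minp else min(minp)
}

.ols_pvalue <- function(y, g) {
  n <- length(y)
  gc <- g - mean(g); yc <- y - mean(y)
  sxx <- sum(gc^2)
  if (sxx <= 0) stop("zero genotype variance")
  sxy <- sum(gc * yc)
  rss <- sum(yc^2) - sxy^2 / sxx
  if (rss <= 0) return(0)
  tstat <- (sxy / sxx) / sqrt(rss / (n - 2) / sxx)
  2 * stats::pt(-abs(tstat), n - 2)
}

#' ANOVA / linear-regression joint test
#'
#' Joint F test across tissues assuming a common residual variance:
#' compares the model with tissue-specific intercepts and tissue-specific
#' genotype slopes against tissue-specific intercepts only. The S-df
#' numerator tests the genotype-effect block.
#'
#' @param ys List of per-tissue expression vectors (>= 2 tissues).
#' @param gs List of matching genotype dosage vectors (recycled if a single
#'   vector is given).
#' @return Tibble with `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
anova_lr_test <- function(ys, gs) {
  S <- length(ys)
  if (S < 2L) stop("need at least 2 tissues")
  if (!is.list(gs)) gs <- rep(list(gs), S)
  stopifnot(length(gs) == S)
  rss0 <- rss1 <- 0
  N <- 0L
  for (s in seq_len(S)) {
    y <- ys[[s]]; g <- gs[[s]]
    stopifnot(length(y) == length(g))
    n <- length(y)
    gc <- g - mean(g); yc <- y - mean(y)
    sxx <- sum(gc^2)
    if (sxx <= 0) stop("singular design: zero genotype variance in a tissue")
    rss0 <- rss0 + sum(yc^2)
    rss1 <- rss1 + sum(yc^2) - sum(gc * yc)^2 / sxx
    N <- N + n
  }
  df2 <- N - 2L * S
  if (df2 <= 0 || rss1 <= 0) stop("singular design")
  f <- ((rss0 - rss1) / S) / (rss1 / df2)
  tibble::tibble(statistic = f, df1 = S, df2 = df2,
                 p_value = stats::pf(f, S, df2, lower.tail = FALSE))
}

#' Overlap table of per-tissue eGene calls
#'
#' For genes called in at least one tissue, tabulates the fraction falling
#' in each presence/absence pattern across tissues. This is the
#' tissue-by-tissue view of sharing, which under-counts shared eQTLs
#' whenever per-tissue power is incomplete.
#'
#' @param calls Named list of per-tissue gene ID vectors (>= 2 tissues).
#' @return Tibble with columns `pattern` (binary string in tissue order),
#'   `n` and `prop`, sorted by decreasing `prop`.
#' @export
overlap_table <- function(calls) {
  S <- length(calls)
  if (S < 2L) stop("need calls from at least 2 tissues")
  genes <- unique(unlist(calls))
  if (length(genes) == 0L) {
    return(tibble::tibble(pattern = character(), n = integer(), prop = numeric()))
  }
  pat <- vapply(genes, function(g) {
    paste0(vapply(calls, function(cs) as.integer(g %in% cs), integer(1)),
           collapse = "")
  }, character(1))
  tb <- table(pat)
  tibble::tibble(pattern = names(tb), n = as.integer(tb),
                 prop = as.integer(tb) / length(genes)) |>
    dplyr::arrange(dplyr::desc(.data$prop))
}

#' Pairwise pi1 sharing estimate
#'
#' Given the genes called as eGenes in a first tissue (with their best
#' SNPs), estimates the proportion that are also eQTLs in a second tissue
#' as `pi1 = 1 - pi0` of the distribution of those SNPs' nominal p-values
#' in the second tissue, uncorrected for multiple comparisons. Avoids
#' thresholding in the second tissue and so partially accounts for
#' incomplete power, but only compares tissues two at a time.
#'
#' @param pvalues_b Nominal p-values in the second tissue of the best SNPs
#'   of the genes called in the first tissue (>= 20 values).
#' @return Scalar `pi1` estimate in \[0, 1\].
#' @export
pairwise_pi1 <- function(pvalues_b) {
  if (length(pvalues_b) < 20L) stop("need at least 20 called genes")
  max(0, min(1, 1 - storey_qvalues(pvalues_b)$pi0))
}

#' Discoveries at a truth-matched FDR threshold
#'
#' For simulation studies where the null status of each unit is known:
#' finds the largest set of top-ranked units whose realized false discovery
#' proportion does not exceed `fdr`, and returns its size. This is how
#' methods are compared at a matched FDR on synthetic data.
#'
#' @param stat Statistic per unit.
#' @param is_null Logical vector, `TRUE` for null units.
#' @param fdr Target false discovery proportion.
#' @param larger_is_extreme `TRUE` when large statistics indicate signal
#'   (Bayes factors), `FALSE` for p-value-like statistics.
#' @return Number of discoveries at the matched FDR.
#' @export
fdr_matched_discoveries <- function(stat, is_null, fdr = 0.05,
                                    larger_is_extreme = TRUE) {
  stopifnot(length(stat) == length(is_null))
  ord <- order(stat, decreasing = larger_is_extreme)
  fdp <- cumsum(is_null[ord]) / seq_along(ord)
  ok <- which(fdp <= fdr)
  if (length(ok) == 0L) 0L else max(ok)
}
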