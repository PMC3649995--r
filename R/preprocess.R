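#' Filter genes robustly expressed in every tissue
#'
#' A gene is considered robustly expressed in a tissue when its mean
#' expression across individuals is at least the median expression level of
#' all genes across all individuals in that tissue. Only genes passing this
#' rule in every tissue are kept, so that downstream joint analyses compare
#' like with like across tissues.
#'
#' @param datasets A list of [tissue_dataset()] objects sharing a gene
#'   universe.
#' @return Character vector of gene IDs passing the filter in all tissues.
#' @examples
#' expr <- matrix(c(1, 1, 5, 5), 2, 2, dimnames = list(c("a", "b"), c("i1", "i2")))
#' filter_robust_genes(list(tissue_dataset(expr)))
#' @export
filter_robust_genes <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  universes <- lapply(datasets, function(d) rownames(d$expr))
  common <- Reduce(intersect, universes)
  if (length(common) == 0L) stop("empty intersection of gene universes")
  keep <- common
  for (d in datasets) {
    e <- d$expr[common, , drop = FALSE]
    pass <- rowMeans(e) >= stats::median(e)
    keep <- intersect(keep, common[pass])
  }
  keep
}

#' Remove leading expression principal components
#'
#' Removes unmeasured confounders from a tissue's expression matrix by
#' principal components analysis of the gene-by-individual matrix. PCs are
#' ranked by the proportion of variance they explain, and the leading PCs
#' are retained for removal as long as each additional PC still explains at
#' least `increment_threshold` of the total variance. The selected PCs are
#' then regressed out of every gene's expression.
#'
#' @param dataset A [tissue_dataset()].
#' @param increment_threshold Fraction of total variance (in (0, 1\]) below
#'   which an additional PC is no longer removed. The default 2.5e-5
#'   corresponds to 0.0025%.
#' @return A list with `dataset` (residual expression, same shape) and
#'   `n_pcs_removed`.
#' @export
remove_pcs <- function(dataset, increment_threshold = 2.5e-5) {
  stopifnot(inherits(dataset, "tissue_dataset"))
  if (!(increment_threshold > 0 && increment_threshold <= 1)) {
    stop("increment_threshold must lie in (0, 1]")
  }
  X <- dataset$expr
  if (ncol(X) < 2L) stop("need more than one individual")
  Xc <- X - rowMeans(X)
  sv <- svd(Xc)
  prop <- sv$d^2 / sum(sv$d^2)
  rank <- sum(sv$d > max(dim(Xc)) * max(sv$d) * .Machine$double.eps)
  k <- 0L
  while (k < rank && prop[k + 1L] >= increment_threshold) k <- k + 1L
  if (k > 0L) {
    V <- sv$v[, seq_len(k), drop = FALSE]
    res <- X - (Xc %*% V) %*% t(V)
  } else {
    res <- X
  }
  dimnames(res) <- dimnames(X)
  out <- dataset
  out$expr <- res
  list(dataset = out, n_pcs_removed = k)
}

#' Rank-based inverse normal transform
#'
#' Maps values to the quantiles of a standard normal via
#' `qnorm((rank - 0.5) / n)`, with ties resolved by average rank. Applied
#' gene-wise before association testing so that the normal-error regression
#' model holds regardless of the raw expression distribution.
#'
#' @param values Numeric vector, length at least 2.
#' @return Numeric vector of normal quantiles, same length.
#' @examples
#' quantile_normal_transform(c(10, 20, 30))
#' @export
quantile_normal_transform <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2L)
  if (anyNA(values)) stop("missing values not allowed")
  n <- length(values)
  r <- rank(values, ties.method = "average")
  out <- stats::qnorm((r - 0.5) / n)
  if (all(values == values[1L])) {
    warning("all input values equal; transform is degenerate (all zeros)")
  }
  out
}
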