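#' Single-tissue eQTL regression summary
#'
#' Fits the simple linear regression `y = mu + beta * g + e` of one gene's
#' expression on one SNP's allele dosage by ordinary least squares and
#' returns the sufficient statistics used by the Bayes factor machinery.
#' The standardized slope `bhat = betahat / sigmahat` is the unit-free
#' effect-size measure: inference based on it is invariant to rescaling the
#' expression values.
#'
#' @param y Numeric vector of expression values.
#' @param g Numeric vector of genotype dosages in \[0, 2\], same length.
#'   Pairs with missing `y` or `g` are dropped.
#' @param tissue_id Optional tissue label carried into the output.
#' @return One-row tibble with columns `tissue`, `n`, `muhat`, `betahat`,
#'   `se` (standard error of `betahat`), `sigmahat` (residual SD with
#'   `n - 2` denominator) and `bhat`.
#' @examples
#' g <- c(0, 0, 1, 1, 2, 2)
#' fit_tissue_regression(c(0, 1, 1, 2, 2, 3), g)
#' @export
fit_tissue_regression <- function(y, g, tissue_id = "tissue") {
  stopifnot(length(y) == length(g))
  ok <- stats::complete.cases(y, g)
  y <- y[ok]; g <- g[ok]
  n <- length(y)
  if (n < 3L) stop("need at least 3 complete observations")
  gc <- g - mean(g)
  sxx <- sum(gc^2)
  if (sxx <= 0) stop("zero genotype variance")
  yc <- y - mean(y)
  betahat <- sum(gc * yc) / sxx
  rss <- sum((yc - betahat * gc)^2)
  if (rss <= 0) stop("degenerate perfect fit (zero residual variance)")
  sigmahat <- sqrt(rss / (n - 2))
  se <- sigmahat / sqrt(sxx)
  tibble::tibble(tissue = tissue_id, n = n,
                 muhat = mean(y) - betahat * mean(g),
                 betahat = betahat, se = se, sigmahat = sigmahat,
                 bhat = betahat / sigmahat)
}

#' Cross-tissue residual correlation
#'
#' Estimates the correlation of residual expression between tissues for
#' individuals sampled in more than one tissue, used by the
#' correlated-errors Bayes factor. Residuals should come from the null
#' (intercept-only or covariate-only) model; the pairwise correlations are
#' shrunk toward the identity, `R <- (1 - shrink) * R + shrink * I`, to
#' guarantee positive definiteness of the small-sample plug-in estimate.
#'
#' @param residuals List of named numeric vectors, one per tissue, names
#'   being individual IDs.
#' @param shrink Shrinkage weight toward the identity (default 0.05).
#' @return S x S correlation matrix (symmetric, unit diagonal, positive
#'   definite), dimnames taken from `names(residuals)` when present.
#' @export
estimate_residual_correlation <- function(residuals, shrink = 0.05) {
  S <- length(residuals)
  stopifnot(S >= 1L, shrink >= 0, shrink < 1)
  R <- diag(S)
  if (S > 1L) {
    for (i in seq_len(S - 1L)) {
      for (j in seq.int(i + 1L, S)) {
        common <- intersect(names(residuals[[i]]), names(residuals[[j]]))
        if (length(common) < 3L) {
          warning(sprintf("fewer than 3 common individuals for tissues %d and %d; correlation set to 0", i, j))
          r <- 0
        } else {
          r <- stats::cor(residuals[[i]][common], residuals[[j]][common])
          if (!is.finite(r)) r <- 0
        }
        R[i, j] <- R[j, i] <- r
      }
    }
    R <- (1 - shrink) * R + shrink * diag(S)
  }
  if (!is.null(names(residuals))) dimnames(R) <- list(names(residuals), names(residuals))
  R
}
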