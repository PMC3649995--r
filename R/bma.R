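#' Bayesian model averaging over configurations and grid
#'
#' Averages configuration- and grid-point-specific Bayes factors into the
#' single SNP-level test statistic
#' `BF = sum_gamma eta_gamma sum_l lambda_l BF[gamma, l]`, computed in log
#' space.
#'
#' @param lbf Matrix of log Bayes factors, configurations in rows and grid
#'   points in columns (as produced by the internal BF engine, or
#'   assembled from [bf_config_gridpoint()] calls).
#' @param eta Configuration prior weights: a numeric vector matching the
#'   rows of `lbf`, or a tibble from [config_weights()] (its `eta` column is
#'   used, matched by rowname when `lbf` carries config labels).
#' @param grid Grid tibble from [build_grid()] (its `weight` column is the
#'   lambda weights).
#' @param log Return the natural-log BF.
#' @return Scalar BMA Bayes factor.
#' @export
bf_bma <- function(lbf, eta, grid, log = FALSE) {
  validate_grid(grid)
  eta <- .eta_vector(eta, lbf)
  stopifnot(nrow(lbf) == length(eta), ncol(lbf) == nrow(grid))
  validate_weights(eta)
  w <- outer(base::log(eta), base::log(grid$weight), "+")
  keep <- is.finite(w)  # eta = 0 rows contribute nothing
  out <- logsumexp(lbf[keep] + w[keep])
  if (log) out else exp(out)
}

.eta_vector <- function(eta, lbf) {
  if (is.data.frame(eta)) {
    v <- eta$eta
    if (!is.null(rownames(lbf)) && all(rownames(lbf) %in% eta$config)) {
      v <- eta$eta[match(rownames(lbf), eta$config)]
    }
    v
  } else {
    as.numeric(eta)
  }
}

#' Gene-level Bayes factor
#'
#' Under the assumption of at most one cis-eQTL per gene with every SNP
#' equally likely to be the eQTL, the gene-level evidence is the arithmetic
#' mean of the SNP-level BMA Bayes factors over the `m_g` cis SNPs.
#'
#' @param snp_lbf Numeric vector of log SNP-level Bayes factors.
#' @param log Return the natural-log BF.
#' @return Scalar gene-level Bayes factor.
#' @export
gene_bf <- function(snp_lbf, log = FALSE) {
  if (length(snp_lbf) == 0L) stop("empty cis SNP set")
  out <- logsumexp(snp_lbf) - base::log(length(snp_lbf))
  if (log) out else exp(out)
}

#' Posterior configuration and tissue-activity probabilities
#'
#' Conditional on the SNP being an eQTL in at least one tissue, the
#' posterior probability of each activity configuration is proportional to
#' `eta_gamma * sum_l lambda_l BF[gamma, l]`, and the probability that the
#' eQTL is active in tissue s is the sum of the posteriors over
#' configurations with that tissue active. In production these are computed
#' with hierarchical-model weights (see [em_fit()]).
#'
#' @inheritParams bf_bma
#' @param configs Configuration matrix from [enumerate_configs()]; when
#'   `NULL`, reconstructed from the binary-string rownames of `lbf`.
#' @return List of class `config_posterior` with tibbles `configs`
#'   (`config`, `eta`, `posterior`) and `tissues` (`tissue`, `prob`).
#' @export
config_posterior <- function(lbf, eta, grid, configs = NULL) {
  validate_grid(grid)
  eta <- .eta_vector(eta, lbf)
  validate_weights(eta)
  if (is.null(configs)) {
    if (is.null(rownames(lbf))) stop("configs required when lbf has no config rownames")
    configs <- do.call(rbind, lapply(strsplit(rownames(lbf), ""), as.integer))
    rownames(configs) <- rownames(lbf)
  }
  stopifnot(nrow(configs) == nrow(lbf))
  lnum <- base::log(eta) + apply(lbf + rep(base::log(grid$weight), each = nrow(lbf)),
                                 1L, logsumexp)
  lnum[eta == 0] <- -Inf
  if (all(!is.finite(lnum))) stop("all posterior numerators are zero")
  post <- unname(exp(lnum - logsumexp(lnum)))
  tiss <- as.numeric(crossprod(configs, post))
  out <- list(
    configs = tibble::tibble(config = rownames(configs), eta = unname(eta),
                             posterior = post),
    tissues = tibble::tibble(tissue = colnames(configs) %||% paste0("tissue", seq_along(tiss)),
                             prob = tiss)
  )
  class(out) <- "config_posterior"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.config_posterior <- function(x, ...) {
  cat("<config_posterior>\n")
  top <- dplyr::arrange(x$configs, dplyr::desc(.data$posterior))
  print(utils::head(top, 5L))
  cat("tissue activity:\n")
  print(x$tissues)
  invisible(x)
}

#' @rdname config_posterior
#' @param object,x A `config_posterior` object.
#' @param ... Unused.
#' @method tidy config_posterior
#' @export
tidy.config_posterior <- function(x, ...) x$configs
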