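# Hierarchical model across genes: a gene is null with probability pi0;
# otherwise exactly one of its m_g cis SNPs is the eQTL (each equally
# likely), with activity configuration drawn with probability eta_gamma and
# prior-grid point with probability lambda_l. The likelihood is relative to
# the null (null likelihood normalized to 1), so it is a function of the
# per-SNP log Bayes factors only.

#' Bundle of log Bayes factors for one gene
#'
#' @param gene Gene ID.
#' @param lbf 3-d array of log Bayes factors, dim `(m_g, n_config, L)`
#'   (SNPs x configurations x grid points), or a matrix `(n_config, L)` for
#'   a single SNP.
#' @param snps Optional SNP IDs (length `m_g`).
#' @return Object of class `bf_bundle`.
#' @export
bf_bundle <- function(gene, lbf, snps = NULL) {
  if (is.matrix(lbf)) lbf <- array(lbf, dim = c(1L, dim(lbf)))
  stopifnot(length(dim(lbf)) == 3L, all(is.finite(lbf)), dim(lbf)[1] >= 1L)
  structure(list(gene = gene, m = dim(lbf)[1L], lbf = lbf, snps = snps),
            class = "bf_bundle")
}

# stack a list of bundles into one big flat matrix for vectorized EM
.stack_bundles <- function(bundles) {
  stopifnot(length(bundles) >= 1L)
  d <- dim(bundles[[1L]]$lbf)
  nc <- d[2L]; L <- d[3L]
  mats <- lapply(bundles, function(b) {
    stopifnot(dim(b$lbf)[2L] == nc, dim(b$lbf)[3L] == L)
    matrix(b$lbf, nrow = dim(b$lbf)[1L])  # columns ordered (gamma, l)
  })
  X <- do.call(rbind, mats)
  mg <- vapply(bundles, function(b) b$m, integer(1))
  list(X = X, gidx = rep(seq_along(bundles), mg), mg = mg, nc = nc, L = L,
       genes = vapply(bundles, function(b) as.character(b$gene), character(1)))
}

# per-gene log of the alternative-model averaged BF given log weights
.gene_alt_loglik <- function(st, leta, llambda) {
  logw <- rep(llambda, each = st$nc) + rep(leta, st$L)
  A <- st$X + rep(logw, each = nrow(st$X)) - base::log(st$mg)[st$gidx]
  rmax <- do.call(pmax, as.data.frame(A))
  gmax <- as.numeric(tapply(rmax, st$gidx, max))
  p <- exp(A - gmax[st$gidx])
  Pg <- as.numeric(rowsum(rowSums(p), st$gidx))
  list(li = gmax + base::log(Pg), p = p, Pg = Pg, gmax = gmax)
}

#' Hierarchical-model log-likelihood
#'
#' Relative log-likelihood (null likelihood normalized to 1) of the
#' hierarchical model: `sum_g log(pi0 + (1 - pi0) * gene_avg_BF_g)` where
#' `gene_avg_BF_g` averages the per-SNP BFs over SNPs (uniformly),
#' configurations (weights `eta`) and grid points (weights `lambda`).
#'
#' @param params List (or `mtqtl_hm` fit) with elements `pi0`, `eta`
#'   (numeric vector over configurations or tibble with an `eta` column) and
#'   `lambda` (numeric vector over grid points or tibble with a `weight`
#'   column).
#' @param bundles List of [bf_bundle()] objects.
#' @return Scalar log-likelihood.
#' @export
hm_loglik <- function(params, bundles) {
  st <- .stack_bundles(bundles)
  pe <- .hm_param_vectors(params, st)
  al <- .gene_alt_loglik(st, base::log(pe$eta), base::log(pe$lambda))
  sum(apply(cbind(base::log(pe$pi0), base::log(1 - pe$pi0) + al$li), 1L, logsumexp))
}

.hm_param_vectors <- function(params, st) {
  eta <- if (is.data.frame(params$eta)) params$eta$eta else params$eta
  lambda <- if (is.data.frame(params$lambda)) params$lambda$weight else params$lambda
  stopifnot(length(eta) == st$nc, length(lambda) == st$L)
  validate_weights(eta); validate_weights(lambda)
  pi0 <- params$pi0
  stopifnot(pi0 >= 0, pi0 <= 1)
  list(pi0 = pi0, eta = eta, lambda = lambda)
}

#' Fit the hierarchical model by expectation-maximization
#'
#' Maximum-likelihood estimation of the null fraction `pi0`, configuration
#' weights `eta` and grid weights `lambda` across genes. The E-step computes
#' each gene's posterior probability of harboring an eQTL and, within that,
#' the posterior over (SNP, configuration, grid point); the M-step sets
#' `pi0` to the mean null responsibility and `eta`/`lambda` proportional to
#' the summed responsibilities. The log-likelihood is non-decreasing across
#' iterations.
#'
#' @param bundles List of [bf_bundle()] objects (>= 2 genes).
#' @param init Optional initial parameters (list with `pi0`, `eta`,
#'   `lambda`); defaults to `pi0 = 0.9` with uniform `eta` and `lambda`.
#' @param tol Convergence tolerance on the relative log-likelihood change
#'   (default 1e-6).
#' @param max_iter Maximum EM iterations (default 300).
#' @param fixed Character subset of `c("pi0", "eta", "lambda")` to hold at
#'   their initial values (e.g. `fixed = "lambda"` freezes the grid weights
#'   at uniform, mimicking the default-weights analyses).
#' @param config_labels,grid Optional labels attached to the estimates.
#' @return Object of class `mtqtl_hm` with elements `pi0`, `eta` (tibble),
#'   `lambda` (tibble), `loglik`, `loglik_trace`, `converged`, `n_iter`,
#'   `n_genes`.
#' @export
em_fit <- function(bundles, init = NULL, tol = 1e-6, max_iter = 300L,
                   fixed = character(), config_labels = NULL, grid = NULL) {
  stopifnot(length(bundles) >= 2L)
  if (length(fixed) > 0L) {
    fixed <- match.arg(fixed, c("pi0", "eta", "lambda"), several.ok = TRUE)
  }
  st <- .stack_bundles(bundles)
  G <- length(bundles)
  if (is.null(init)) {
    init <- list(pi0 = 0.9, eta = rep(1 / st$nc, st$nc), lambda = rep(1 / st$L, st$L))
  }
  pe <- .hm_param_vectors(init, st)
  pi0 <- pe$pi0; eta <- pe$eta; lambda <- pe$lambda
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    al <- .gene_alt_loglik(st, base::log(eta), base::log(lambda))
    lg <- apply(cbind(base::log(pi0), base::log(1 - pi0) + al$li), 1L, logsumexp)
    ll <- sum(lg)
    if (!is.finite(ll)) stop("non-finite hierarchical-model likelihood")
    trace <- c(trace, ll)
    if (it > 1L && abs(ll - ll_old) <= tol * (1 + abs(ll))) { converged <- TRUE; break }
    if (it >= max_iter) break
    ll_old <- ll
    # E-step: gene-level alternative responsibility, then cell-level
    post_alt <- exp(base::log(1 - pi0) + al$li - lg)        # per gene
    wfac <- post_alt / al$Pg                                 # scale for cells
    csum <- colSums(al$p * wfac[st$gidx])                    # length nc*L
    cells <- matrix(csum, st$nc, st$L)
    # M-step
    if (!("pi0" %in% fixed)) pi0 <- min(max(mean(1 - post_alt), 1e-12), 1 - 1e-12)
    if (!("eta" %in% fixed)) eta <- pmax(rowSums(cells), 0) / sum(cells)
    if (!("lambda" %in% fixed)) lambda <- pmax(colSums(cells), 0) / sum(cells)
  }
  cfg_lab <- config_labels %||% dimnames(bundles[[1L]]$lbf)[[2L]] %||%
    paste0("config", seq_len(st$nc))
  lambda_tbl <- if (!is.null(grid)) {
    dplyr::mutate(tibble::as_tibble(grid), weight = lambda)
  } else {
    tibble::tibble(gridpoint = seq_len(st$L), weight = lambda)
  }
  structure(list(pi0 = pi0,
                 eta = tibble::tibble(config = cfg_lab, eta = eta),
                 lambda = lambda_tbl,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 converged = converged, n_iter = it, n_genes = G),
            class = "mtqtl_hm")
}

#' @export
print.mtqtl_hm <- function(x, ...) {
  cat(sprintf("<mtqtl_hm: %d genes, pi0 = %.3f, %s after %d EM iterations>\n",
              x$n_genes, x$pi0, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  top <- dplyr::arrange(x$eta, dplyr::desc(.data$eta))
  print(utils::head(top, 5L))
  invisible(x)
}

#' Tidy a hierarchical-model fit
#'
#' @param x A `mtqtl_hm` object from [em_fit()].
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate` (pi0, one row per
#'   configuration weight, one row per grid weight).
#' @method tidy mtqtl_hm
#' @export
tidy.mtqtl_hm <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "pi0", estimate = x$pi0),
    tibble::tibble(term = paste0("eta[", x$eta$config, "]"), estimate = x$eta$eta),
    tibble::tibble(term = paste0("lambda[", seq_len(nrow(x$lambda)), "]"),
                   estimate = x$lambda$weight)
  )
}

#' @rdname tidy.mtqtl_hm
#' @param x A `mtqtl_hm` object.
#' @return For `glance`, a one-row tibble with `pi0`, `loglik`, `n_iter`,
#'   `converged`, `n_genes`.
#' @method glance mtqtl_hm
#' @export
glance.mtqtl_hm <- function(x, ...) {
  tibble::tibble(pi0 = x$pi0, loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged, n_genes = x$n_genes)
}

#' Bootstrap confidence intervals for hierarchical-model parameters
#'
#' Percentile bootstrap over genes: gene bundles are resampled with
#' replacement and the EM refit from the point estimate; 95% percentile
#' intervals are reported for `pi0` and each configuration weight.
#'
#' @param fit A `mtqtl_hm` object from [em_fit()].
#' @param bundles The bundle list the model was fitted to.
#' @param n_boot Number of bootstrap replicates (>= 20).
#' @param seed Integer seed.
#' @param level Interval level (default 0.95).
#' @param ... Passed to [em_fit()] (e.g. `fixed`).
#' @return Tibble with columns `term`, `estimate`, `lower`, `upper`.
#' @export
hm_confidence_intervals <- function(fit, bundles, n_boot = 100L, seed = 1L,
                                    level = 0.95, ...) {
  if (n_boot < 20L) stop("n_boot must be at least 20")
  G <- length(bundles)
  init <- list(pi0 = fit$pi0, eta = fit$eta$eta, lambda = fit$lambda$weight)
  draws <- matrix(NA_real_, n_boot, 1L + nrow(fit$eta))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(G, G, replace = TRUE)
    f <- em_fit(bundles[idx], init = init, max_iter = 100L, ...)
    draws[b, ] <- c(f$pi0, f$eta$eta)
  }
  alpha <- (1 - level) / 2
  qs <- apply(draws, 2L, stats::quantile, probs = c(alpha, 1 - alpha))
  tibble::tibble(term = c("pi0", paste0("eta[", fit$eta$config, "]")),
                 estimate = c(fit$pi0, fit$eta$eta),
                 lower = qs[1L, ], upper = qs[2L, ])
}
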