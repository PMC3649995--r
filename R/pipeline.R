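# Pipeline layer: from (expression datasets, genotype table, cis map) to
# regression summaries, Bayes factor bundles, BMA scan statistics and
# permutation p-values. All heavy paths are vectorized over SNPs or
# permutations through the internal BF engine.

# per-tissue OLS sufficient statistics for a set of SNPs
# y: named expression vector; Gd: m x n dosage matrix with matching columns
.tissue_suff <- function(y, Gd) {
  ids <- names(y)
  Gd <- Gd[, ids, drop = FALSE]
  if (anyNA(Gd) || anyNA(y)) {
    out <- vapply(seq_len(nrow(Gd)), function(j) {
      fit <- fit_tissue_regression(y, Gd[j, ])
      c(fit$n, fit$betahat, fit$se, fit$sigmahat)
    }, numeric(4))
    return(list(n = out[1, ], betahat = out[2, ], se = out[3, ],
                sigmahat = out[4, ]))
  }
  n <- length(y)
  yc <- y - mean(y)
  a <- sum(yc^2)
  gs <- rowSums(Gd)
  sxx <- rowSums(Gd^2) - gs^2 / n
  if (any(sxx <= 0)) stop("zero genotype variance")
  sxy <- drop(Gd %*% yc)
  betahat <- sxy / sxx
  rss <- a - sxy^2 / sxx
  if (any(rss <= 0)) stop("degenerate perfect fit (zero residual variance)")
  sigmahat <- sqrt(rss / (n - 2))
  list(n = rep(n, nrow(Gd)), betahat = betahat, se = sigmahat / sqrt(sxx),
       sigmahat = sigmahat)
}

.check_cismap <- function(cismap) {
  stopifnot(is.data.frame(cismap), all(c("gene", "snp") %in% names(cismap)))
  cismap
}

#' Per-tissue regression summaries for all cis gene-SNP pairs
#'
#' Runs the simple regression of each gene on each of its cis SNPs in every
#' tissue and returns the tidy table of summary statistics feeding the
#' Bayes factor machinery.
#'
#' @param datasets List of [tissue_dataset()] objects.
#' @param genotypes A [genotype_table()].
#' @param cismap Data frame with columns `gene`, `snp` (see
#'   [build_cismap()]).
#' @return Tibble with columns `gene`, `snp`, `tissue`, `n`, `betahat`,
#'   `se`, `sigmahat`, `bhat`.
#' @export
compute_tissue_summaries <- function(datasets, genotypes, cismap) {
  .check_cismap(cismap)
  genes <- intersect(unique(cismap$gene), rownames(datasets[[1]]$expr))
  purrr::map_dfr(genes, function(g) {
    snps <- cismap$snp[cismap$gene == g]
    Gd <- genotypes$dosages[snps, , drop = FALSE]
    purrr::map_dfr(datasets, function(d) {
      y <- d$expr[g, ]
      sf <- .tissue_suff(y, Gd)
      tibble::tibble(gene = g, snp = snps, tissue = d$tissue_id,
                     n = unname(sf$n), betahat = unname(sf$betahat),
                     se = unname(sf$se), sigmahat = unname(sf$sigmahat),
                     bhat = unname(sf$betahat / sf$sigmahat))
    })
  })
}

#' Bayes factor bundles for all genes
#'
#' Computes, for every gene and cis SNP, the log Bayes factor of each
#' activity configuration at each grid point, packaged per gene as a
#' [bf_bundle()] for the hierarchical model and BMA statistics.
#'
#' @inheritParams compute_tissue_summaries
#' @param grid Grid tibble from [build_grid()].
#' @param error_model `"independent"` (default) or `"correlated"`; the
#'   correlated model estimates a per-gene cross-tissue residual
#'   correlation from null-model residuals (requires the same individuals
#'   in all tissues) and couples the tissues' error terms.
#' @param configs Configuration matrix (default [enumerate_configs()] for
#'   `length(datasets)` tissues).
#' @param rcorr_shrink Shrinkage toward identity for the residual
#'   correlation estimate.
#' @return Named list of [bf_bundle()] objects (one per gene with >= 1 cis
#'   SNP; genes with no SNPs are dropped with a warning).
#' @export
compute_bf_bundles <- function(datasets, genotypes, cismap,
                               grid = build_grid(),
                               error_model = c("independent", "correlated"),
                               configs = NULL, rcorr_shrink = 0.05) {
  error_model <- match.arg(error_model)
  validate_grid(grid)
  .check_cismap(cismap)
  S <- length(datasets)
  if (is.null(configs)) configs <- enumerate_configs(S)
  genes <- intersect(unique(cismap$gene), rownames(datasets[[1]]$expr))
  dropped <- setdiff(unique(cismap$gene), genes)
  if (length(dropped) > 0) {
    warning(sprintf("%d genes absent from expression data were dropped", length(dropped)))
  }
  if (error_model == "correlated") {
    idsets <- lapply(datasets, function(d) sort(d$samples))
    if (!all(vapply(idsets, identical, logical(1), idsets[[1]]))) {
      stop("correlated error model requires the same individuals in every tissue")
    }
  }
  out <- vector("list", length(genes))
  names(out) <- genes
  if (error_model == "independent") {
    # batch all gene-SNP pairs into one vectorized BF evaluation
    cis <- cismap[cismap$gene %in% genes, c("gene", "snp")]
    pair_gene <- cis$gene
    Gd_all <- genotypes$dosages[cis$snp, , drop = FALSE]
    sf <- lapply(datasets, function(d) {
      idx <- split(seq_len(nrow(cis)), pair_gene)
      res <- matrix(NA_real_, 4L, nrow(cis))
      for (g in names(idx)) {
        rows <- idx[[g]]
        s <- .tissue_suff(d$expr[g, ], Gd_all[rows, , drop = FALSE])
        res[, rows] <- rbind(s$n, s$betahat, s$se, s$sigmahat)
      }
      res
    })
    pick <- function(k) do.call(rbind, lapply(sf, function(x) x[k, ]))
    suff <- .bf_suff(n = pick(1), betahat = pick(2), se = pick(3), sigmahat = pick(4))
    lbf_all <- .lbf_array(suff, configs, grid)
    for (g in genes) {
      rows <- which(pair_gene == g)
      if (length(rows) == 0L) next
      lbf <- lbf_all[rows, , , drop = FALSE]
      dimnames(lbf) <- list(cis$snp[rows], rownames(configs), NULL)
      out[[g]] <- bf_bundle(g, lbf, snps = cis$snp[rows])
    }
    return(out[!vapply(out, is.null, logical(1))])
  }
  for (g in genes) {
    snps <- cismap$snp[cismap$gene == g]
    if (length(snps) == 0L) next
    Gd <- genotypes$dosages[snps, , drop = FALSE]
    sf <- lapply(datasets, function(d) .tissue_suff(d$expr[g, ], Gd))
    suff <- .bf_suff(
      n = do.call(rbind, lapply(sf, `[[`, "n")),
      betahat = do.call(rbind, lapply(sf, `[[`, "betahat")),
      se = do.call(rbind, lapply(sf, `[[`, "se")),
      sigmahat = do.call(rbind, lapply(sf, `[[`, "sigmahat")))
    {
      res <- lapply(datasets, function(d) {
        r <- d$expr[g, ] - mean(d$expr[g, ]); r
      })
      rcorr <- estimate_residual_correlation(res, shrink = rcorr_shrink)
      lbf <- array(0, dim = c(length(snps), nrow(configs), nrow(grid)))
      for (j in seq_along(snps)) {
        sj <- lapply(suff, function(x) x[, j, drop = FALSE])
        lbf[j, , ] <- .lbf_matrix_corr(sj, rcorr, configs, grid)
      }
    }
    dimnames(lbf) <- list(snps, rownames(configs), NULL)
    out[[g]] <- bf_bundle(g, lbf, snps = snps)
  }
  out[!vapply(out, is.null, logical(1))]
}

.weight_vectors <- function(weights, grid, configs) {
  eta <- if (is.data.frame(weights)) {
    if (!is.null(rownames(configs)) && all(rownames(configs) %in% weights$config)) {
      weights$eta[match(rownames(configs), weights$config)]
    } else weights$eta
  } else weights
  validate_weights(eta)
  list(leta = base::log(eta), llambda = base::log(grid$weight))
}

#' Gene-level BMA statistics from bundles
#'
#' Averages each gene's per-SNP Bayes factors over configurations (weights
#' `eta`), grid points (grid weights) and SNPs (uniform) into the
#' gene-level BMA Bayes factor used as the joint test statistic.
#'
#' @param bundles List of [bf_bundle()] objects.
#' @param weights Configuration weights tibble ([config_weights()]) or
#'   numeric vector; hierarchical-model fits supply their `eta` tibble.
#' @param grid Grid used to build the bundles (its `weight` column may be
#'   replaced by fitted lambda weights).
#' @return Tibble with `gene`, `m` (cis SNP count), `log10_bf`.
#' @export
bma_gene_stats <- function(bundles, weights, grid) {
  b1 <- bundles[[1]]
  cfg <- dimnames(b1$lbf)[[2]]
  configs <- structure(matrix(0L, length(cfg), 1L), dimnames = list(cfg, NULL))
  wv <- .weight_vectors(weights, grid, configs)
  purrr::map_dfr(bundles, function(b) {
    d <- dim(b$lbf)
    lw <- rep(wv$llambda, each = d[2]) + rep(wv$leta, d[3])
    A <- matrix(b$lbf, nrow = d[1]) + rep(lw, each = d[1])
    tibble::tibble(gene = as.character(b$gene), m = d[1],
                   log10_bf = (logsumexp(A) - base::log(d[1])) / base::log(10))
  })
}

#' Gene-level configuration posterior from a bundle
#'
#' Posterior over activity configurations for one gene, conditional on it
#' containing an eQTL: SNPs are averaged uniformly, grid points by the
#' lambda weights, configurations weighted by `eta`.
#'
#' @param bundle A [bf_bundle()].
#' @inheritParams bma_gene_stats
#' @return A `config_posterior` object (see [config_posterior()]).
#' @export
gene_config_posterior <- function(bundle, weights, grid) {
  d <- dim(bundle$lbf)
  # collapse SNPs (uniform) and grid (lambda) to one log BF per configuration
  lbf_cfg <- vapply(seq_len(d[2]), function(ci) {
    logsumexp(as.vector(bundle$lbf[, ci, , drop = FALSE]) +
                rep(base::log(grid$weight), each = d[1])) - base::log(d[1])
  }, numeric(1))
  eta <- if (is.data.frame(weights)) {
    weights$eta[match(dimnames(bundle$lbf)[[2]], weights$config)]
  } else weights
  lnum <- base::log(eta) + lbf_cfg
  post <- exp(lnum - logsumexp(lnum))
  configs <- do.call(rbind, lapply(strsplit(dimnames(bundle$lbf)[[2]], ""), as.integer))
  rownames(configs) <- dimnames(bundle$lbf)[[2]]
  out <- list(
    configs = tibble::tibble(config = rownames(configs), eta = eta, posterior = post),
    tissues = tibble::tibble(tissue = paste0("tissue", seq_len(ncol(configs))),
                             prob = as.numeric(crossprod(configs, post)))
  )
  class(out) <- "config_posterior"
  out
}

#' Posterior probability of each SNP being the eQTL
#'
#' Within-gene posterior over cis SNPs, conditional on the gene containing
#' exactly one eQTL.
#'
#' @inheritParams gene_config_posterior
#' @return Tibble with `snp`, `posterior`, sorted decreasing.
#' @export
snp_posterior <- function(bundle, weights, grid) {
  d <- dim(bundle$lbf)
  cfg <- dimnames(bundle$lbf)[[2]]
  eta <- if (is.data.frame(weights)) {
    weights$eta[match(cfg, weights$config)]
  } else weights
  lw <- rep(base::log(grid$weight), each = d[2]) + rep(base::log(eta), d[3])
  A <- matrix(bundle$lbf, nrow = d[1]) + rep(lw, each = d[1])
  lsnp <- apply(A, 1L, logsumexp)
  post <- exp(lsnp - logsumexp(lsnp))
  tibble::tibble(snp = bundle$snps %||% paste0("snp", seq_len(d[1])),
                 posterior = post) |>
    dplyr::arrange(dplyr::desc(.data$posterior))
}

# vectorized permutation statistics for one gene.
# Returns list(obs=..., perm=numeric(n_perm)) for the chosen statistic.
.perm_stats_gene <- function(ys, Gd, n_perm, seed, statistic, grid, wv,
                             configs, tissue_sel = NULL) {
  all_ids <- colnames(Gd)
  nid <- length(all_ids)
  set.seed(seed)
  P <- cbind(seq_len(nid), replicate(n_perm, sample.int(nid)))
  K <- n_perm + 1L
  S <- length(ys)
  sel <- tissue_sel %||% seq_len(S)
  m <- nrow(Gd)
  pos <- lapply(ys, function(y) match(names(y), all_ids))
  if (statistic == "bma") {
    snp_l <- matrix(NA_real_, m, K)
    for (j in seq_len(m)) {
      # raw sufficient statistics on the .bf_suff scale: d = centered genotype
      # SS (permutation-invariant per tissue), cc = cross-product, a = total SS
      nmat <- dmat <- cmat <- amat <- matrix(NA_real_, S, K)
      for (s in seq_len(S)) {
        y <- ys[[s]]
        yc <- y - mean(y)
        a <- sum(yc^2)
        n <- length(y)
        gmat <- matrix(Gd[j, P[pos[[s]], ]], n, K)
        gs <- colSums(gmat)
        sxx <- colSums(gmat^2) - gs^2 / n
        sxy <- drop(crossprod(yc, gmat))
        dmat[s, ] <- sxx
        cmat[s, ] <- sxy
        amat[s, ] <- a
        nmat[s, ] <- n
      }
      lbf <- .lbf_array(list(n = nmat, d = dmat, cc = cmat, a = amat),
                        configs, grid)
      lw <- rep(wv$llambda, each = nrow(configs)) + rep(wv$leta, length(wv$llambda))
      flat <- matrix(lbf, nrow = K)
      snp_l[j, ] <- apply(flat + rep(lw, each = K), 1L, logsumexp)
    }
    stat <- apply(snp_l, 2L, logsumexp) - base::log(m)
  } else {
    minp <- matrix(Inf, 1, K)
    for (j in seq_len(m)) {
      for (s in sel) {
        y <- ys[[s]]
        yc <- y - mean(y)
        a <- sum(yc^2)
        n <- length(y)
        gmat <- matrix(Gd[j, P[pos[[s]], ]], n, K)
        gs <- colSums(gmat)
        sxx <- colSums(gmat^2) - gs^2 / n
        sxy <- drop(crossprod(yc, gmat))
        t2 <- (n - 2) * sxy^2 / (sxx * a - sxy^2)
        p <- 2 * stats::pt(-sqrt(pmax(t2, 0)), n - 2)
        minp <- pmin(minp, p)
      }
    }
    stat <- drop(minp)
  }
  list(obs = stat[1L], perm = stat[-1L])
}

#' Gene-level permutation scan
#'
#' Computes, for every gene, the joint test statistic (gene-level BMA Bayes
#' factor or tissue-by-tissue minimum p-value) and its permutation p-value.
#' Individual labels are permuted identically in every tissue (the
#' genotype labels are shuffled once per replicate), preserving
#' intra-individual correlations; permutations are per gene, seeded
#' deterministically from `seed` and the gene ID.
#'
#' @inheritParams compute_tissue_summaries
#' @param statistic `"bma"` (gene BMA Bayes factor; large = extreme) or
#'   `"tbt"` (minimum regression p-value; small = extreme).
#' @param grid,weights Prior grid and configuration weights for the BMA
#'   statistic.
#' @param n_perm Number of permutations per gene.
#' @param seed Global integer seed.
#' @param tissue For `statistic = "tbt"`, restrict to one tissue index
#'   (per-tissue analysis; permutations are then specific to that tissue).
#' @return Tibble with `gene`, `m`, `stat` (log10 BMA BF, or min p) and
#'   `p_perm`.
#' @export
permutation_scan <- function(datasets, genotypes, cismap,
                             statistic = c("bma", "tbt"),
                             grid = build_grid(),
                             weights = default_weights(length(datasets)),
                             n_perm = 1000L, seed = 1L, tissue = NULL) {
  statistic <- match.arg(statistic)
  .check_cismap(cismap)
  validate_grid(grid)
  S <- length(datasets)
  configs <- enumerate_configs(S)
  wv <- .weight_vectors(weights, grid, configs)
  genes <- intersect(unique(cismap$gene), rownames(datasets[[1]]$expr))
  sel <- if (!is.null(tissue)) as.integer(tissue) else NULL
  purrr::map_dfr(genes, function(g) {
    snps <- cismap$snp[cismap$gene == g]
    Gd <- genotypes$dosages[snps, , drop = FALSE]
    ys <- lapply(datasets, function(d) d$expr[g, ])
    r <- .perm_stats_gene(ys, Gd, n_perm,
                          seed = .gene_seed(seed, g),
                          statistic = statistic, grid = grid, wv = wv,
                          configs = configs, tissue_sel = sel)
    extreme <- if (statistic == "bma") sum(r$perm >= r$obs) else sum(r$perm <= r$obs)
    tibble::tibble(gene = g, m = length(snps),
                   stat = if (statistic == "bma") r$obs / base::log(10) else r$obs,
                   p_perm = (1 + extreme) / (n_perm + 1))
  })
}

#' Relax the one-eQTL-per-gene assumption
#'
#' Identifies each gene's top SNP (largest posterior probability of being
#' the eQTL under the supplied weights), regresses its dosage out of the
#' gene's expression in every tissue, and recomputes Bayes factor bundles
#' on these residuals as a second set of "artificial" genes. Fitting the
#' hierarchical model on original plus artificial bundles allows up to two
#' independent cis-eQTLs per gene.
#'
#' @inheritParams compute_bf_bundles
#' @param bundles Round-1 bundles from [compute_bf_bundles()].
#' @param fit Round-1 hierarchical fit ([em_fit()]) or any weights/grid
#'   pair; its `eta` and `lambda` define the top-SNP posterior.
#' @return List with `bundles` (original + artificial; artificial gene IDs
#'   carry the suffix `":resid"`) and `top_snps` (tibble `gene`, `snp`).
#' @export
relax_single_eqtl <- function(datasets, genotypes, cismap, bundles, fit,
                              grid = build_grid(), ...) {
  eta <- if (inherits(fit, "mtqtl_hm")) fit$eta else fit
  lambda_grid <- if (inherits(fit, "mtqtl_hm") && "weight" %in% names(fit$lambda) &&
                     nrow(fit$lambda) == nrow(grid)) {
    dplyr::mutate(grid, weight = fit$lambda$weight)
  } else grid
  top <- purrr::map_dfr(bundles, function(b) {
    sp <- snp_posterior(b, eta, lambda_grid)
    tibble::tibble(gene = as.character(b$gene), snp = sp$snp[1L])
  })
  resid_sets <- lapply(datasets, function(d) {
    expr <- d$expr
    for (i in seq_len(nrow(top))) {
      g <- top$gene[i]
      if (!g %in% rownames(expr)) next
      y <- expr[g, ]
      gd <- genotypes$dosages[top$snp[i], d$samples]
      fitg <- fit_tissue_regression(y, gd)
      expr[g, ] <- y - fitg$betahat * gd
    }
    rownames(expr) <- paste0(rownames(expr), ":resid")
    tissue_dataset(expr, d$tissue_id)
  })
  cis2 <- dplyr::mutate(.check_cismap(cismap), gene = paste0(.data$gene, ":resid"))
  art <- compute_bf_bundles(resid_sets, genotypes, cis2, grid = grid, ...)
  list(bundles = c(bundles, art), top_snps = top)
}
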