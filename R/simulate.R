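# Synthetic multi-tissue eQTL data. The generator reproduces the study
# designs used throughout: one candidate SNP per gene, Binomial(2, maf)
# genotypes, standardized effects drawn from the two-level normal prior and
# rescaled to a target proportion of variance explained (PVE), per-tissue
# error variances, and optional intra-individual residual correlation for
# shared-individual designs.

#' Simulation scenario
#'
#' Bundles the design of a synthetic multi-tissue eQTL study.
#'
#' @param S Number of tissues.
#' @param n Per-tissue sample sizes (recycled to length S).
#' @param config_counts Named integer vector: number of genes per activity
#'   configuration, names being binary strings of length S; the all-zero
#'   string denotes null genes.
#' @param maf Minor allele frequency for Binomial(2, maf) genotypes
#'   (default 0.3).
#' @param pve Target expected proportion of expression variance explained
#'   by the eQTL in active tissues (default 0.2).
#' @param error_variances Per-tissue residual variances (recycled; default
#'   1).
#' @param heterogeneity Heterogeneity fraction `phi^2 / (phi^2 + omega^2)`
#'   of the effect prior used for active configurations (default 0.25:
#'   effects similar but not identical across active tissues).
#' @param shared_individuals When `TRUE` (default) tissues measure subsets
#'   of one individual panel; otherwise each tissue has its own
#'   individuals.
#' @param intra_corr Residual correlation between tissues for shared
#'   individuals (default 0).
#' @param effect_draw `"pve"` (default): every eQTL attains the nominal
#'   `pve` (fixed standardized magnitude). `"grid"`: each gene's total
#'   standardized effect size is drawn uniformly from `grid_sizes`, so
#'   alternatives span weak to strong; `pve` is then ignored.
#' @param grid_sizes Effect-size set for `effect_draw = "grid"` (defaults
#'   to the prior grid's size set).
#' @param seed Integer seed.
#' @return List of class `sim_scenario`.
#' @export
sim_scenario <- function(S, n, config_counts, maf = 0.3, pve = 0.2,
                         error_variances = 1, heterogeneity = 0.25,
                         shared_individuals = TRUE, intra_corr = 0,
                         effect_draw = c("pve", "grid"),
                         grid_sizes = c(0.1, 0.2, 0.4, 0.8, 1.6),
                         seed = 1L) {
  n <- rep_len(n, S)
  effect_draw <- match.arg(effect_draw)
  error_variances <- rep_len(error_variances, S)
  stopifnot(maf > 0, maf <= 0.5, pve >= 0, pve < 1,
            heterogeneity >= 0, heterogeneity <= 1,
            all(nchar(names(config_counts)) == S),
            all(config_counts >= 0), all(grid_sizes > 0),
            intra_corr > -1 / max(S - 1, 1), intra_corr < 1)
  structure(list(S = S, n = n, config_counts = config_counts, maf = maf,
                 pve = pve, error_variances = error_variances,
                 heterogeneity = heterogeneity,
                 shared_individuals = shared_individuals,
                 intra_corr = intra_corr, effect_draw = effect_draw,
                 grid_sizes = grid_sizes, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate genotype dosages
#'
#' i.i.d. Binomial(2, maf) dosages: Hardy-Weinberg genotypes at the given
#' minor allele frequency.
#'
#' @param n Number of individuals.
#' @param maf Minor allele frequency.
#' @param seed Optional integer seed.
#' @return Integer vector of dosages in \{0, 1, 2\}.
#' @export
sim_genotypes <- function(n, maf = 0.3, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(n, 2L, maf)
}

#' Simulate standardized eQTL effects for one gene
#'
#' Standardized effects for the active tissues of `gamma` (zero elsewhere)
#' are built as a shared mean plus between-tissue jitter, scaled so that
#' the expected squared standardized effect equals the PVE target
#' `b*^2 = pve / ((1 - pve) * Var(g))` with `Var(g) = 2 maf (1 - maf)`:
#' the shared mean is `bbar = +/- b* * omega / sqrt(phi^2 + omega^2)`
#' (random sign, deterministic magnitude so every simulated eQTL attains
#' the nominal PVE) and `b_s ~ N(bbar, phi^2 * b*^2 / (phi^2 + omega^2))`.
#' With `phi = 0` (no heterogeneity) all active effects equal `+/- b*`.
#'
#' @param gamma Binary activity vector.
#' @param phi,omega Shape of the effect prior; only the heterogeneity
#'   ratio `phi^2 / (phi^2 + omega^2)` matters (the total scale is set by
#'   `pve`).
#' @param pve Target expected proportion of variance explained.
#' @param maf Minor allele frequency of the simulated SNP.
#' @param seed Optional integer seed.
#' @return Numeric vector of standardized effects, one per tissue.
#' @export
sim_effects <- function(gamma, phi, omega, pve, maf = 0.3, seed = NULL) {
  if (pve >= 1) stop("pve must be < 1")
  stopifnot(phi >= 0, omega >= 0, phi + omega > 0)
  if (!is.null(seed)) set.seed(seed)
  gamma <- as.integer(gamma)
  S <- length(gamma)
  varg <- 2 * maf * (1 - maf)
  bstar <- sqrt(pve / ((1 - pve) * varg))
  tot <- sqrt(phi^2 + omega^2)
  bbar <- sample(c(-1, 1), 1L) * bstar * omega / tot
  b <- stats::rnorm(S, bbar, bstar * phi / tot)
  b * gamma
}

#' Simulate expression for one gene across tissues
#'
#' `y_s = mu_s + b_s * sigma_s * g + e_s` with residual vectors drawn
#' i.i.d. across individuals from an S-variate normal with per-tissue
#' variances `error_variances` and constant cross-tissue correlation
#' `intra_corr` (shared-individual designs).
#'
#' @param g Dosage vector (one value per individual).
#' @param effects Standardized effects `b_s`, one per tissue.
#' @param error_variances Per-tissue residual variances (recycled).
#' @param intra_corr Cross-tissue residual correlation.
#' @param mu Per-tissue intercepts (default 0).
#' @param seed Optional integer seed.
#' @return Matrix S x n of expression values (tissues in rows).
#' @export
sim_expression <- function(g, effects, error_variances = 1, intra_corr = 0,
                           mu = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- length(effects)
  n <- length(g)
  sig <- sqrt(rep_len(error_variances, S))
  mu <- rep_len(mu, S)
  R <- matrix(intra_corr, S, S); diag(R) <- 1
  Sigma <- R * tcrossprod(sig)
  cS <- tryCatch(chol(Sigma), error = function(e) stop("residual correlation matrix not positive definite"))
  eps <- t(cS) %*% matrix(stats::rnorm(S * n), S, n)
  out <- mu + (effects * sig) %o% g + eps
  rownames(out) <- paste0("tissue", seq_len(S))
  colnames(out) <- names(g)
  out
}

#' Simulate a complete multi-tissue eQTL study
#'
#' Generates one candidate SNP per gene under a [sim_scenario()]: genotypes
#' for the individual panel, per-tissue expression matrices, and a truth
#' table recording each gene's activity configuration. Covers both the
#' power-study design (eQTLs active in exactly q of S tissues) and the
#' sharing-recovery design (a fixed set of active configurations plus null
#' genes, possibly with unequal per-tissue sample sizes).
#'
#' @param scenario A [sim_scenario()].
#' @return List with `datasets` (list of [tissue_dataset()]), `genotypes`
#'   (a [genotype_table()]; SNP `snp_<gene>` in row for each gene),
#'   `cismap` (tibble gene/snp pairing, one SNP per gene), `truth` (tibble
#'   with `gene`, `snp`, `config`, `q`, and the per-tissue standardized
#'   effects as columns `b1...bS`) and `scenario`.
#' @export
sim_study <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  S <- scenario$S
  cc <- scenario$config_counts
  G <- sum(cc)
  if (G < 1L) stop("no genes requested")
  if (scenario$shared_individuals) {
    nind <- max(scenario$n)
    ids <- sprintf("ind%03d", seq_len(nind))
    tissue_ids <- lapply(scenario$n, function(ns) ids[seq_len(ns)])
  } else {
    offs <- cumsum(c(0, scenario$n))
    ids <- sprintf("ind%03d", seq_len(sum(scenario$n)))
    tissue_ids <- lapply(seq_len(S), function(s) ids[(offs[s] + 1):offs[s + 1]])
  }
  nind <- length(ids)
  configs <- rep(names(cc), cc)
  configs <- configs[sample.int(G)]  # shuffle gene order
  genes <- sprintf("gene%04d", seq_len(G))
  snps <- paste0("snp_", genes)
  dos <- matrix(stats::rbinom(G * nind, 2L, scenario$maf), G, nind,
                dimnames = list(snps, ids))
  # guard monomorphic SNPs (possible at small n): redraw
  mono <- which(apply(dos, 1L, function(x) stats::var(x) == 0))
  while (length(mono) > 0L) {
    dos[mono, ] <- stats::rbinom(length(mono) * nind, 2L, scenario$maf)
    mono <- which(apply(dos, 1L, function(x) stats::var(x) == 0))
  }
  gp <- .het_gridpoint(scenario$heterogeneity)
  varg <- 2 * scenario$maf * (1 - scenario$maf)
  B <- matrix(0, G, S)
  for (i in seq_len(G)) {
    gam <- as.integer(strsplit(configs[i], "")[[1]])
    if (sum(gam) > 0L) {
      pve_i <- if (scenario$effect_draw == "grid") {
        size <- sample(scenario$grid_sizes, 1L)
        size^2 * varg / (1 + size^2 * varg)
      } else {
        scenario$pve
      }
      B[i, ] <- sim_effects(gam, phi = gp$phi, omega = gp$omega,
                            pve = pve_i, maf = scenario$maf)
    }
  }
  sig <- sqrt(scenario$error_variances)
  R <- matrix(scenario$intra_corr, S, S); diag(R) <- 1
  cR <- chol(R)
  datasets <- vector("list", S)
  eps <- array(stats::rnorm(G * nind * S), dim = c(S, G * nind))
  eps <- crossprod(cR, eps)  # correlate across tissues
  for (s in seq_len(S)) {
    E <- matrix(eps[s, ], G, nind) * sig[s]
    expr <- B[, s] * sig[s] * dos + E
    dimnames(expr) <- list(genes, ids)
    datasets[[s]] <- tissue_dataset(expr[, tissue_ids[[s]], drop = FALSE],
                                    tissue_id = paste0("tissue", s))
  }
  gt <- genotype_table(dos, snps = tibble::tibble(
    snp = snps, chrom = paste0("chr", seq_len(G)), pos = rep(1e6, G)))
  truth <- tibble::tibble(gene = genes, snp = snps, config = configs,
                          q = vapply(strsplit(configs, ""),
                                     function(x) sum(x == "1"), numeric(1)))
  truth <- dplyr::bind_cols(truth, tibble::as_tibble(
    stats::setNames(as.data.frame(B), paste0("b", seq_len(S)))))
  cismap <- tibble::tibble(gene = genes, snp = snps)
  list(datasets = datasets, genotypes = gt, cismap = cismap,
       truth = truth, scenario = scenario)
}

.het_gridpoint <- function(het) {
  list(phi = sqrt(het), omega = sqrt(1 - het))
}

#' Genes-per-configuration table for the power-study design
#'
#' Helper building `config_counts` for the design "half the genes null, the
#' other half with an eQTL active in exactly q tissues" (active tissues
#' drawn uniformly among the `choose(S, q)` possibilities).
#'
#' @param S Number of tissues.
#' @param q Number of active tissues for alternative genes.
#' @param n_genes Total genes.
#' @param frac_null Fraction of null genes (default 0.5).
#' @param seed Integer seed for assigning configurations.
#' @return Named integer vector usable as `config_counts`.
#' @export
power_config_counts <- function(S, q, n_genes, frac_null = 0.5, seed = 1L) {
  stopifnot(q >= 1, q <= S)
  set.seed(seed)
  n_null <- round(n_genes * frac_null)
  n_alt <- n_genes - n_null
  cfg <- enumerate_configs(S)
  labs <- rownames(cfg)[rowSums(cfg) == q]
  pick <- table(sample(labs, n_alt, replace = TRUE))
  counts <- c(stats::setNames(n_null, strrep("0", S)),
              stats::setNames(as.integer(pick), names(pick)))
  counts[counts > 0]
}
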