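# mtqtl — joint mapping of cis-eQTLs across multiple tissues

`mtqtl` is an R package for mapping expression quantitative trait loci
(eQTLs) **jointly** across several tissues or cell types, for studies that
measure gene expression in multiple conditions (often on overlapping
individuals) and want both more power to *detect* eQTLs and an honest
answer to *in which tissues* each eQTL is active.

Analyzing tissues one at a time wastes the information shared eQTLs carry
and — because per-tissue power is incomplete — systematically overstates
tissue specificity: a shared eQTL that clears the threshold in one tissue
and narrowly misses in another looks "tissue-specific". `mtqtl` instead:

* models each gene–SNP pair per tissue with the simple regression
  `y_s = mu_s + beta_s g + e_s`, working with standardized effects
  `b_s = beta_s / sigma_s` so inference is invariant to expression units;
* represents each sharing hypothesis as a binary **configuration**
  `gamma` over tissues and computes an approximate **Bayes factor**
  `BF_{gamma,l}` against the global null under a two-level normal prior
  `b_s ~ N(bbar, phi^2)`, `bbar ~ N(0, omega^2)` on a grid of
  `(phi, omega)` scales (with an optional intra-individual residual
  correlation model for shared donors);
* averages the BFs over configurations, grid and cis SNPs (**Bayesian
  model averaging**) into a gene-level detection statistic,
  `BF_gene = m^-1 sum_j sum_gamma eta_gamma sum_l lambda_l BF_{j,gamma,l}`,
  calibrated by permuting individual labels identically across tissues and
  converted to FDR calls via Storey q-values;
* fits a **hierarchical model** across genes by EM to estimate the null
  fraction `pi0`, the configuration frequencies `eta` (the sharing
  pattern, free of thresholding artifacts) and the grid weights `lambda`,
  which then power per-gene configuration and tissue-activity posteriors;
* ships baselines (tissue-by-tissue minimum-p, pooled-variance ANOVA/LR F
  test, pairwise pi1 sharing) and a synthetic-data generator reproducing
  the power and sharing-recovery study designs.

## Worked example

```r
library(mtqtl)

# simulate 3 tissues measured on the same 80 individuals: 150 genes,
# 50 with an eQTL shared by all tissues, 10 specific to tissue 1 (PVE 20%)
scenario <- sim_scenario(S = 3, n = 80,
                         config_counts = c("000" = 90, "111" = 50, "100" = 10),
                         pve = 0.2, intra_corr = 0.2, seed = 1)
study <- sim_study(scenario)

# configuration x grid Bayes factors for every gene-SNP pair
bundles <- compute_bf_bundles(study$datasets, study$genotypes, study$cismap,
                              error_model = "correlated")

# gene-level BMA statistics with permutation significance and q-values
scan <- permutation_scan(study$datasets, study$genotypes, study$cismap,
                         statistic = "bma", n_perm = 500, seed = 1)
scan$q <- storey_qvalues(scan$p_perm)$qvalues
egenes <- call_egenes(setNames(scan$q, scan$gene), fdr = 0.05)
length(egenes)
#> [1] 57

# hierarchical model: how are eQTLs shared across tissues?
fit <- em_fit(bundles, grid = build_grid())
fit
#> <mtqtl_hm: 150 genes, pi0 = 0.425, converged after 100 EM iterations>
#> # A tibble: 5 x 2
#>   config    eta
#>   <chr>   <dbl>
#> 1 111    0.816
#> 2 110    0.0730
#> 3 100    0.0625
#> 4 101    0.0377
#> 5 011    0.0110
```

57 of the 150 genes are called as eGenes at FDR 0.05, and the estimated
configuration weights put ~82% of eQTLs in the all-tissue configuration
`111` — close to the planted 50/60 ≈ 83% — with most of the rest on
tissue-1-containing patterns, reflecting the 10 tissue-1-specific genes.
`pi0` is the estimated fraction of genes with no eQTL (see the methods
vignette for its small-sample caveat). For a single gene:

```r
post <- gene_config_posterior(bundles[[egenes[1]]], fit$eta,
                              dplyr::mutate(build_grid(), weight = fit$lambda$weight))
post
#> <config_posterior>
#> # A tibble: 5 x 3
#>   config    eta  posterior
#>   <chr>   <dbl>      <dbl>
#> 1 111    0.816  0.861
#> 2 110    0.0730 0.139
#> ...
#> tissue activity:
#>   tissue   prob
#> 1 tissue1 1.000
#> 2 tissue2 1.000
#> 3 tissue3 0.861
```

This gene is an eQTL with certainty in tissues 1 and 2 and with posterior
probability 0.86 in tissue 3 (tissue-activity probabilities sum the
configuration posteriors, so they stay informative even when the exact
configuration is uncertain). `tidy()`, `glance()` and `autoplot()` methods
summarize fits and posteriors; real data come in through
`read_genotypes()` (VCF or dosage TSV), `read_expression()` (TSV + BED)
and `build_cismap()` (1 Mb cis window around the TSS). A command-line
interface wrapping the same functions lives at `inst/cli/mtqtl.R`
(subcommands `simulate`, `bf`, `hm`, `perm`, `tbt`, `report`).

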