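---
title: "Joint multi-tissue eQTL mapping with mtqtl: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint multi-tissue eQTL mapping with mtqtl: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtqtl)
```

## The problem

An expression quantitative trait locus (eQTL) is a genetic variant
associated with a gene's expression level. When expression is measured in
several tissues or cell types, two questions arise together: *does this
gene have an eQTL in any tissue?* (detection), and *in which tissues is it
active?* (tissue specificity). Analyzing each tissue separately wastes
power on shared eQTLs and, worse, systematically overstates tissue
specificity: a shared eQTL that clears the significance threshold in one
tissue and narrowly misses it in another looks "tissue-specific" purely
because per-tissue power is incomplete.

`mtqtl` implements a joint Bayesian framework that addresses both
questions. Its components are:

1. **Per-tissue regression summaries.** For each gene--SNP pair and tissue
   $s$, the simple linear model
   $y_{si} = \mu_s + \beta_s g_i + \epsilon_{si}$,
   $\epsilon_{si} \sim N(0, \sigma_s^2)$, with genotype dosage
   $g_i \in [0,2]$. Effect sizes are standardized,
   $b_s = \beta_s / \sigma_s$, so all inference is invariant to the units
   and scale of each tissue's expression measurements.

2. **Configurations.** A binary vector $\gamma \in \{0,1\}^S$ records in
   which tissues the eQTL is active; each nonzero $\gamma$ is one
   alternative hypothesis and the all-zero vector is the global null.

3. **A two-level effect prior.** Given $\gamma$, the active standardized
   effects share a mean, $b_s \sim N(\bar b, \phi^2)$ with
   $\bar b \sim N(0, \omega^2)$; $\omega$ sets the typical effect size and
   $\phi/\sqrt{\phi^2+\omega^2}$ the heterogeneity across active tissues
   ($\phi = 0$ is the fixed-effects model). A fixed grid of
   $(\phi, \omega)$ values with weights $\lambda_l$ spans effect sizes and
   heterogeneity levels.

4. **Configuration Bayes factors.** $BF_{\gamma,l}$ compares "eQTL with
   configuration $\gamma$, prior scale $(\phi_l, \omega_l)$" against the
   global null, with diffuse priors on the nuisance intercepts and residual
   variances.

5. **Bayesian model averaging (BMA).** The detection statistic averages
   BFs over configurations (prior weights $\eta_\gamma$), grid points
   ($\lambda_l$) and, at the gene level, cis SNPs (uniform, under an
   at-most-one-eQTL-per-gene assumption). Significance is assessed by
   permuting individual labels -- identically in every tissue, so
   intra-individual correlations are preserved -- and converting gene-level
   p-values to Storey q-values.

6. **A hierarchical model across genes.** Treating $(\pi_0, \eta,
   \lambda)$ -- the fraction of genes with no eQTL, the configuration
   frequencies, and the grid weights -- as unknowns, the marginal
   likelihood of gene $g$ is
   $\pi_0 + (1-\pi_0)\, m_g^{-1} \sum_j \sum_\gamma \eta_\gamma
   \sum_l \lambda_l BF_{gj\gamma l}$, multiplied across genes and
   maximized by EM. The estimated $\eta$ measures eQTL sharing *without
   thresholding*, which is what lets it see past incomplete power; the
   fitted weights also sharpen the per-gene posteriors
   $P(\gamma \mid \text{data, eQTL})$ and the per-tissue activity
   probabilities obtained by summing them.

## The Bayes factor realization

With independent individuals the BF factorizes over tissues after
integrating the intercept (flat prior) and the effect vector (normal
prior). Writing $d_s$ for the centered genotype sum of squares, $c_s$ for
the genotype--expression cross-product and $a_s$ for the total expression
sum of squares, the remaining integral over the residual precisions has an
exact closed form tissue-by-tissue. For a single tissue the BF is exactly

$$BF = (1 + d\,w^2)^{-1/2} \left(1 - \rho^2 \frac{d w^2}{1 + d w^2}\right)^{-(n-1)/2},$$

with $w^2$ the prior variance and $\rho$ the sample correlation -- the
*score statistic* form: expanding the second factor gives
$\exp(z^2 r / 2)$ with $z^2 = (n-1)\rho^2$. `bf_config_gridpoint()`
combines these exact per-tissue factors with Sherman--Morrison algebra for
the diagonal-plus-rank-one prior and a tilted plug-in for the cross-tissue
variance coupling. Accuracy is anchored to `bf_exact_oracle()`, an
independent numeric-integration route (Gauss--Hermite over the effects,
adaptive quadrature over each residual precision): on two-tissue, n = 100
pairs spanning null to strong effects the median relative error is well
below 1% (`bf_oracle_agreement()`), against roughly 13% for the naive
multivariate-normal density ratio on t-statistic summaries, which is why
that simpler form is not used.

When all tissues measure the same individuals, residuals may correlate
across tissues. The correlated path estimates a per-gene cross-tissue
correlation matrix from null-model residuals, shrinks it toward the
identity (`(1-0.05) R + 0.05 I`, guaranteeing positive definiteness of the
n = 75-scale plug-in), and uses the multivariate normal density ratio with
error covariance $V_{st} = r_{st}\,se_s\,se_t$ on score-scale summaries.
The exact variance-integration trick does not extend to coupled residuals,
so this path is a coarser approximation; it is the one exercised by the
sharing study below, where mis-modelling intra-individual correlation
(fitting the independent model to correlated data) visibly corrupts the
estimated null fraction.

Everything is computed in log space (BFs exceed $10^{300}$ in
strong-signal simulations) and vectorized over SNPs or permutations, so a
2,000-pair scan or a 200-permutation-per-gene analysis runs in seconds.

## Tunable parameters

* **Grid** (`build_grid()`): total effect sizes
  $\{0.1, 0.2, 0.4, 0.8, 1.6\}$ (unitless, standardized scale) crossed
  with heterogeneity fractions $\{0, 1/4, 1/2\}$ ("default", 15 points) or
  $\{0, 1/4, 1/2, 3/4, 1\}$ ("lite", 25 points); equal weights. The sizes
  span sub-percent to >50% PVE at common allele frequencies; the default
  grid assumes eQTLs shared between tissues have similar effects, while the
  lite grid compensates for its restricted configuration set by allowing
  extreme heterogeneity. Both sets are configurable.
* **Configuration weights** (`config_weights()`): "default" spreads mass
  $1/(S\binom{S}{q})$ over all $2^S - 1$ configurations (enumeration is
  capped at S = 20; beyond that only "lite" is practical); "lite" puts 0.5
  on the consistent configuration and $0.5/S$ on each singleton, i.e. only
  $S+1$ terms. Production posterior reports should use the
  hierarchical-model estimates.
* **Cis window** (`build_cismap()`): 1 Mb around the TSS, inclusive at
  exactly 1 Mb.
* **Permutations**: default 10,000 per gene (`permutation_scan()`);
  simulation studies in this package use 100--1,000. The add-one estimator
  `(1 + #extreme)/(n_perm + 1)` keeps p-values valid and strictly
  positive; per-gene seeds are hashed from the global seed and the gene ID
  so results do not depend on execution order.
* **EM** (`em_fit()`): starts at $\pi_0 = 0.9$ with uniform $\eta$ and
  $\lambda$ (the "default" prior, away from boundaries), stops when the
  relative log-likelihood change drops below $10^{-6}$ or at 300
  iterations; `fixed = "lambda"` freezes the grid weights at uniform to
  mimic default-weight analyses. The log-likelihood trace is monotone (a
  strict EM guarantee, asserted in the tests).
* **Confidence intervals** (`hm_confidence_intervals()`): percentile
  bootstrap over genes, refitting from the point estimate. A bootstrap was
  chosen for model-agnostic validity; interval widths are therefore not
  comparable with profile-likelihood intervals.

## The synthetic-data generator

`sim_study()` generates one candidate SNP per gene: Binomial(2, maf)
genotypes (maf 0.3), per-configuration standardized effects, per-tissue
error variances, and optional constant intra-individual residual
correlation for shared-individual designs. Two effect-size regimes are
supported:

* `effect_draw = "pve"` (default): every eQTL attains the nominal
  proportion of variance explained. The shared mean has fixed magnitude
  $b^{*}\,\omega/\sqrt{\phi^2+\omega^2}$ with random sign, where
  $b^{*2} = \text{pve}/((1-\text{pve})\,\mathrm{Var}(g))$, and per-tissue
  jitter has SD $b^{*}\phi/\sqrt{\phi^2+\omega^2}$, so
  $E[b_s^2] = b^{*2}$ exactly and the magnitude is deterministic when
  heterogeneity is 0 (at pve 0.2, maf 0.3: $|b^{*}| \approx 0.7715$). A
  fully random $N(0, b^{*2})$ draw was rejected because it makes half the
  "alternative" genes effectively null, which destroys the interpretability
  of power and recovery studies.
* `effect_draw = "grid"`: each gene's total effect size is drawn uniformly
  from the grid's size set, so alternatives span weak to strong. The power
  study uses this regime: at the fixed pve-0.2 magnitude with n = 100 all
  methods detect essentially every q = 5 eQTL and the comparison
  degenerates into ties.

Default heterogeneity for shared eQTLs is fraction 1/4 (similar but not
identical effects). Intercepts are zero (irrelevant after centering).

What the generator does **not** emulate: linkage disequilibrium between
cis SNPs (each SNP is drawn independently, so multi-SNP fine-mapping
behavior on real data is not tested), more than two causal eQTLs per gene,
expression-level-dependent measurement noise, population structure, or
batch confounding beyond what the PC-removal utilities would handle.
Passing tests therefore demonstrate correctness of the machinery and the
qualitative phenomena (power gains, incomplete-power artifacts), not
performance on any particular real dataset.

## The validation experiments

Five experiment functions reproduce the framework's headline behaviors at
desk scale; `scripts/acceptance.R` runs all of them and the test suite
asserts their outcomes.

* `bf_oracle_agreement()` -- 50 two-tissue pairs, n = 100: median relative
  error of the analytic BF against numeric integration, required < 5%.
* `em_recovery_study()` -- five tissues (n = 60 in tissue 1, 100
  elsewhere), eQTLs planted in 8 configurations (five singletons, tissues
  1--2, tissues 3--5, all five) with 200 genes each plus 200 nulls,
  grid-drawn effect sizes: every $\hat\eta$ within $\pm 0.03$ of 1/8 and
  $\hat\pi_0$ within $\pm 0.05$ of 1/9. Under a fixed single-PVE magnitude
  the null fraction is practically unidentifiable in this design -- the
  smallest grid size's near-unity BFs absorb the null genes and
  $\hat\pi_0$ collapses while $\hat\eta$ is unaffected -- so the recovery
  study, like the power study, spans effect sizes.
* `power_study()` -- five tissues, n = 100, 2,000 pairs (half null, half
  active in all five), grid-drawn effect sizes: discoveries at
  truth-matched FDR 0.05. BMA with default weights beats the
  tissue-by-tissue minimum-p baseline, and beats the pooled-variance
  ANOVA/LR F test when per-tissue error variances are drawn from
  $\{1, 1.5, 2\}$ (ANOVA both mis-weights tissues and, unlike the BF,
  cannot exploit effect consistency).
* `calibration_study()` -- 500 null genes, 200 permutations: p-values pass
  a Kolmogorov--Smirnov uniformity test at $\alpha = 0.01$; the ANOVA F
  test holds its 5% level within $\pm 1\%$ under the equal-variance null.
* `sharing_study()` -- the incomplete-power contrast. Three tissues on the
  same 75 individuals (residual correlation 0.3), 1,800 genes per dataset,
  30% of genes carrying an eQTL at PVE 20% with 88.3% of eQTLs consistent
  across all three tissues and the remainder spread over partial
  configurations. The hierarchical model with correlated-residual BFs is
  fit on three replicate datasets and the consistent-configuration weight
  averaged (recovery is reported as a replicate mean because the
  single-dataset estimator has sampling spread of about $\pm 0.05$ at 540
  eQTL genes); per-tissue permutation calls (1,000 permutations -- 200
  would leave the p-value floor of 1/201 exactly at the q = 0.05 calling
  boundary at this gene count, an artifact of resolution rather than
  power) at FDR 0.05 give the naive overlap view. The model-based estimate
  lands near the true 0.88 while the fraction of called genes shared by
  all three tissues stays far below 0.5 -- the thresholding artifact that
  makes overlap analyses overstate tissue specificity.

The 30% eQTL fraction and n = 75 mirror a three-cell-type panel of
moderate size; per-tissue detection power is then roughly one half, which
is exactly the regime where the contrast between model-based and
overlap-based sharing is scientifically interesting.

## Numerical choices and degenerate inputs

* Rank-normal transform: $\Phi^{-1}((\text{rank} - 0.5)/n)$, average ranks
  for ties; an all-constant vector maps to zeros with a warning.
* PC selection: proportions of variance from squared singular values of
  the row-centered gene-by-individual matrix; leading PCs are removed
  while each additional PC still explains at least the increment threshold
  (default 0.0025%), capped at the matrix rank.
* Perfect fits ($\hat\sigma = 0$) and monomorphic SNPs are errors, never
  infinite BFs; regressions use complete cases per tissue with n - 2
  residual degrees of freedom.
* The correlated-residual path requires every tissue to observe the same
  individuals and errs otherwise; pairs of tissues with fewer than 3
  common individuals get correlation 0 with a warning.
* Posterior and likelihood accumulation uses log-sum-exp throughout;
  configuration posteriors are conditional on "eQTL present" (the null
  term is excluded from the normalization).
* Ties between observed and permuted statistics count as "at least as
  extreme" (conservative).
* Artificial residualized genes from `relax_single_eqtl()` enter the
  refitted likelihood as independent genes -- an approximation, since they
  share individuals with their parent genes.

## Known limitations

* The hierarchical model's $\hat\pi_0$ is biased downward in
  weak-signal, high-$\pi_0$ regimes (the null/weak-alternative boundary is
  only softly identified at n = 75; the fitted likelihood genuinely
  exceeds the truth's, so this is a property of the estimator, not of the
  optimizer). The configuration weights -- the quantity of scientific
  interest -- remain accurate in the validated designs; treat $\hat\pi_0$
  as a nuisance parameter at small sample sizes.
* Full configuration enumeration is exponential in S; above ~10 tissues
  only the lite statistic is practical, and the hierarchical model's
  per-configuration parameterization becomes statistically fragile well
  before S = 20.
* The correlated-residual BF is a plug-in approximation; its accuracy is
  not covered by the numeric oracle (which handles independent tissues).
* Bootstrap confidence intervals refit the EM up to 100 iterations per
  replicate from the point estimate; for large panels this is the slowest
  step and the intervals inherit any estimator bias.
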