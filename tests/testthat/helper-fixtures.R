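# Shared fixture builders. Everything is generated in code under fixed seeds.

# one gene's worth of data: S tissues, common individuals, optional effect
make_gene_data <- function(S = 2, n = 100, b = 0, maf = 0.3, sigma = 1,
                           intra = 0, seed = 1) {
  set.seed(seed)
  g <- stats::rbinom(n, 2, maf)
  while (stats::var(g) == 0) g <- stats::rbinom(n, 2, maf)
  names(g) <- sprintf("i%03d", seq_len(n))
  sig <- rep_len(sigma, S)
  R <- matrix(intra, S, S); diag(R) <- 1
  eps <- t(chol(R)) %*% matrix(stats::rnorm(S * n), S, n)
  b <- rep_len(b, S)
  ys <- lapply(seq_len(S), function(s) {
    y <- b[s] * sig[s] * g + sig[s] * eps[s, ]
    names(y) <- names(g)
    y
  })
  list(g = g, ys = ys)
}

summaries_of <- function(gd) {
  dplyr::bind_rows(lapply(seq_along(gd$ys), function(s) {
    fit_tissue_regression(gd$ys[[s]], gd$g, tissue_id = paste0("t", s))
  }))
}

# small complete study for pipeline tests
small_study <- function(S = 3, n = 50, n_null = 30, n_alt = 20, pve = 0.2,
                        seed = 42, ...) {
  counts <- stats::setNames(c(n_null, n_alt), c(strrep("0", S), strrep("1", S)))
  sim_study(sim_scenario(S = S, n = n, config_counts = counts, pve = pve,
                         seed = seed, ...))
}

write_test_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampA\tsampB",
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1",
    "chr1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/0\t./.",
    "chr1\t300\trs3\tG\tA,C\t.\tPASS\t.\tGT\t0/1\t0/2"
  ), path)
  path
}

write_test_bed <- function(path, rows) {
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}
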