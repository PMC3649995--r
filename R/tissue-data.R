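#' Per-tissue expression dataset
#'
#' Container for one tissue's expression data: a gene-by-individual matrix
#' plus sample identifiers. Expression units are arbitrary; all downstream
#' inference operates on standardized effect sizes and is invariant to
#' per-tissue rescaling.
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene IDs),
#'   individuals in columns (colnames = sample IDs).
#' @param tissue_id Character scalar naming the tissue.
#' @return An object of class `tissue_dataset`: a list with elements
#'   `tissue_id`, `samples` and `expr`.
#' @examples
#' expr <- matrix(rnorm(20), 4, 5,
#'                dimnames = list(paste0("g", 1:4), paste0("i", 1:5)))
#' td <- tissue_dataset(expr, "liver")
#' @export
tissue_dataset <- function(expr, tissue_id = "tissue") {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr))) rownames(expr) <- paste0("gene", seq_len(nrow(expr)))
  if (is.null(colnames(expr))) colnames(expr) <- paste0("ind", seq_len(ncol(expr)))
  if (anyDuplicated(rownames(expr))) stop("duplicated gene IDs")
  if (anyDuplicated(colnames(expr))) stop("duplicated sample IDs")
  if (!all(is.finite(expr))) stop("expression values must be finite")
  if (ncol(expr) < 3L) stop("need at least 3 individuals")
  structure(list(tissue_id = tissue_id, samples = colnames(expr), expr = expr),
            class = "tissue_dataset")
}

#' @export
print.tissue_dataset <- function(x, ...) {
  cat(sprintf("<tissue_dataset '%s': %d genes x %d individuals>\n",
              x$tissue_id, nrow(x$expr), ncol(x$expr)))
  invisible(x)
}

#' Genotype dosage table
#'
#' @param dosages Numeric matrix, SNPs in rows (rownames = SNP IDs),
#'   individuals in columns; values in \[0, 2\] (allele dosages).
#' @param snps A data frame with columns `snp`, `chrom`, `pos` (1-based);
#'   defaults to placeholder coordinates when omitted.
#' @return An object of class `genotype_table` with elements `snps`
#'   (a tibble) and `dosages`.
#' @export
genotype_table <- function(dosages, snps = NULL) {
  stopifnot(is.matrix(dosages), is.numeric(dosages))
  if (is.null(rownames(dosages))) rownames(dosages) <- paste0("snp", seq_len(nrow(dosages)))
  if (anyDuplicated(rownames(dosages))) stop("duplicated SNP IDs")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  if (is.null(snps)) {
    snps <- tibble::tibble(snp = rownames(dosages), chrom = "chrUn",
                           pos = seq_len(nrow(dosages)))
  } else {
    snps <- tibble::as_tibble(snps)
    stopifnot(all(c("snp", "chrom", "pos") %in% names(snps)))
    if (anyDuplicated(snps$snp)) stop("duplicated SNP IDs")
    if (any(snps$pos < 1)) stop("positions must be positive integers")
    snps <- snps[match(rownames(dosages), snps$snp), ]
  }
  structure(list(snps = snps, dosages = dosages), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table: %d SNPs x %d individuals>\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}
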