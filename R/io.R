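# Readers and writers for the standard interchange formats: VCF or dosage
# TSV genotypes, per-tissue expression TSVs with BED gene coordinates, TSV
# result tables and a key-value document for hierarchical-model parameters.

#' Read genotypes from VCF or a dosage table
#'
#' For VCF input, dosages are taken from the `DS` FORMAT field when
#' present, otherwise computed as the count of ALT alleles in `GT`
#' (missing genotypes become `NA` and are dropped pair-wise downstream);
#' multi-allelic records are skipped with a warning. Dosage-table input is
#' a TSV with columns `snp`, `chrom`, `pos` followed by one column per
#' sample.
#'
#' @param path File path.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi)) {
      warning(sprintf("skipping %d multi-allelic site(s)", sum(multi)))
    }
    keep <- !multi
    fmt <- v@gt[, 1L]
    dos <- if (all(grepl("DS", fmt))) {
      suppressWarnings(apply(vcfR::extract.gt(v, element = "DS"), 2L, as.numeric))
    } else {
      gt <- vcfR::extract.gt(v, element = "GT")
      apply(gt, 2L, function(col) {
        vapply(col, function(x) {
          if (is.na(x) || grepl("\\.", x)) return(NA_real_)
          sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0)
        }, numeric(1))
      })
    }
    dos <- matrix(dos, nrow = nrow(fix),
                  dimnames = list(NULL, colnames(v@gt)[-1L]))
    ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                  paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
    rownames(dos) <- ids
    snps <- tibble::tibble(snp = ids[keep], chrom = fix[keep, "CHROM"],
                           pos = as.integer(fix[keep, "POS"]))
    genotype_table(dos[keep, , drop = FALSE], snps = snps)
  } else {
    tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    stopifnot(all(c("snp", "chrom", "pos") %in% names(tb)))
    samp <- setdiff(names(tb), c("snp", "chrom", "pos"))
    dos <- as.matrix(tb[, samp])
    rownames(dos) <- tb$snp
    genotype_table(dos, snps = tb[, c("snp", "chrom", "pos")])
  }
}

#' Write a genotype table as a dosage TSV
#'
#' @param genotypes A [genotype_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  tb <- dplyr::bind_cols(genotypes$snps,
                         tibble::as_tibble(genotypes$dosages))
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}

#' Read per-tissue expression matrices with gene coordinates
#'
#' Expression files are TSVs with a `gene` column followed by one column
#' per sample. Gene coordinates come from a BED file (0-based half-open;
#' columns chrom, start, end, name, score, strand): the transcription
#' start site is the BED start for + strand genes and the BED end for -
#' strand genes (both reported 1-based).
#'
#' @param paths Named character vector of expression file paths (names =
#'   tissue IDs).
#' @param bed_path BED file of gene coordinates.
#' @return List with `datasets` (list of [tissue_dataset()]) and `coords`
#'   (tibble `gene`, `chrom`, `tss`, `strand`).
#' @export
read_expression <- function(paths, bed_path) {
  if (is.null(names(paths))) names(paths) <- paste0("tissue", seq_along(paths))
  datasets <- purrr::imap(paths, function(p, tid) {
    tb <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    stopifnot("gene" %in% names(tb))
    if (anyDuplicated(tb$gene)) stop("duplicated gene IDs in ", p)
    m <- as.matrix(tb[, setdiff(names(tb), "gene")])
    rownames(m) <- tb$gene
    tissue_dataset(m, tid)
  })
  bed <- readr::read_tsv(bed_path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  stopifnot(ncol(bed) >= 4L)
  strand <- if (ncol(bed) >= 6L) bed[[6L]] else rep("+", nrow(bed))
  coords <- tibble::tibble(
    gene = bed[[4L]], chrom = bed[[1L]],
    tss = ifelse(strand == "-", as.integer(bed[[3L]]), as.integer(bed[[2L]]) + 1L),
    strand = strand)
  list(datasets = unname(datasets), coords = coords)
}

#' Pair genes with their cis candidate SNPs
#'
#' A SNP belongs to a gene's cis candidate region when it lies on the same
#' chromosome within `window` bases of the transcription start site
#' (inclusive at exactly `window`).
#'
#' @param coords Tibble with `gene`, `chrom`, `tss` (1-based) as returned
#'   by [read_expression()].
#' @param genotypes A [genotype_table()].
#' @param window Cis window half-width in bases (default 1 Mb).
#' @return Tibble with columns `gene`, `snp`, `distance` (signed
#'   `pos - tss`); genes with no cis SNP are absent.
#' @export
build_cismap <- function(coords, genotypes, window = 1e6) {
  stopifnot(all(c("gene", "chrom", "tss") %in% names(coords)))
  snps <- genotypes$snps
  purrr::map_dfr(seq_len(nrow(coords)), function(i) {
    hit <- snps$chrom == coords$chrom[i] &
      abs(snps$pos - coords$tss[i]) <= window
    if (!any(hit)) return(NULL)
    tibble::tibble(gene = coords$gene[i], snp = snps$snp[hit],
                   distance = snps$pos[hit] - coords$tss[i])
  })
}

#' Write hierarchical-model parameters as a key-value document
#'
#' One `key<TAB>value` pair per line: `pi0`, `eta:<config>` for every
#' configuration, `lambda:<l>` for every grid point, plus convergence
#' metadata. Values are written with full precision so that re-reading is
#' lossless.
#'
#' @param fit A `mtqtl_hm` object from [em_fit()].
#' @param path Output path.
#' @param ci Optional interval tibble from [hm_confidence_intervals()];
#'   adds `ci_lower:` / `ci_upper:` lines.
#' @return `path`, invisibly.
#' @export
write_hm_params <- function(fit, path, ci = NULL) {
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    paste0("pi0\t", num(fit$pi0)),
    paste0("eta:", fit$eta$config, "\t", num(fit$eta$eta)),
    paste0("lambda:", seq_len(nrow(fit$lambda)), "\t", num(fit$lambda$weight)),
    paste0("loglik\t", num(fit$loglik)),
    paste0("n_iter\t", fit$n_iter),
    paste0("converged\t", tolower(as.character(fit$converged)))
  )
  if (!is.null(ci)) {
    lines <- c(lines,
               paste0("ci_lower:", ci$term, "\t", num(ci$lower)),
               paste0("ci_upper:", ci$term, "\t", num(ci$upper)))
  }
  writeLines(lines, path)
  invisible(path)
}
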