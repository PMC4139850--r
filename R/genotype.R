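#' Genotype matrix container
#'
#' Bundles an additive-coded sample-by-SNP genotype matrix with per-SNP
#' metadata. Genotypes are minor-allele counts 0/1/2 with `NA` for missing
#' calls; rows are samples, columns are SNPs.
#'
#' @param geno numeric matrix, samples x SNPs, entries in \{0, 1, 2, NA\}.
#'   Row names are sample ids (generated as `S0001`... if absent), column
#'   names SNP ids (taken from `snp_info` if absent).
#' @param snp_info data frame with one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `allele1`, `allele2` (allele2 is the counted, minor allele). A default
#'   frame is synthesised when omitted.
#' @return An object of class `genotype_matrix`: a list with elements `geno`
#'   and `snp_info`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 1), 2, 2))
#' n_samples(g); n_snps(g); snp_maf(g)
#' @export
genotype_matrix <- function(geno, snp_info = NULL) {
  if (!is.matrix(geno)) stopf("`geno` must be a matrix")
  storage.mode(geno) <- "double"
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stopf("genotype codes must be 0, 1, 2 or NA")
  n <- nrow(geno); p <- ncol(geno)
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("S%04d", seq_len(n))
  if (is.null(snp_info)) {
    ids <- colnames(geno) %||% sprintf("snp%05d", seq_len(p))
    snp_info <- data.frame(snp_id = ids,
                           chrom = rep(1L, p),
                           pos = seq_len(p),
                           allele1 = "A", allele2 = "C",
                           stringsAsFactors = FALSE)
  }
  need <- c("snp_id", "chrom", "pos", "allele1", "allele2")
  miss <- setdiff(need, names(snp_info))
  if (length(miss))
    stopf("snp_info lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(snp_info) != p)
    stopf("snp_info has %d rows but geno has %d SNPs", nrow(snp_info), p)
  if (anyDuplicated(snp_info$snp_id)) stopf("duplicated SNP ids")
  colnames(geno) <- snp_info$snp_id
  structure(list(geno = geno, snp_info = snp_info),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs, %.2f%% missing\n",
              nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`
#' @export
n_samples <- function(x) nrow(x$geno)

#' @rdname genotype_matrix
#' @export
n_snps <- function(x) ncol(x$geno)

#' @rdname genotype_matrix
#' @export
sample_ids <- function(x) rownames(x$geno)

#' Per-SNP minor allele frequency over non-missing calls
#' @param x a `genotype_matrix`
#' @return named numeric vector of MAFs (folded to be at most 0.5)
#' @export
snp_maf <- function(x) {
  f <- colMeans(x$geno, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Per-SNP fraction of missing calls
#' @param x a `genotype_matrix`
#' @export
snp_missing_rate <- function(x) colMeans(is.na(x$geno))

#' Per-sample fraction of missing calls
#' @param x a `genotype_matrix`
#' @export
sample_missing_rate <- function(x) rowMeans(is.na(x$geno))

#' Per-sample heterozygosity (fraction of non-missing calls equal to 1)
#' @param x a `genotype_matrix`
#' @export
sample_het_rate <- function(x) {
  rowMeans(x$geno == 1, na.rm = TRUE)
}

#' Subset a genotype matrix by samples and/or SNPs
#' @param x a `genotype_matrix`
#' @param samples,snps character ids or logical/integer indices; `NULL` keeps all
#' @return a `genotype_matrix`
#' @export
subset_genotypes <- function(x, samples = NULL, snps = NULL) {
  g <- x$geno; info <- x$snp_info
  if (!is.null(samples)) {
    if (is.character(samples)) {
      miss <- setdiff(samples, rownames(g))
      if (length(miss))
        stopf("unknown sample id(s): %s", paste(utils::head(miss, 5), collapse = ", "))
    }
    g <- g[samples, , drop = FALSE]
  }
  if (!is.null(snps)) {
    if (is.character(snps)) {
      miss <- setdiff(snps, info$snp_id)
      if (length(miss))
        stopf("unknown SNP id(s): %s", paste(utils::head(miss, 5), collapse = ", "))
      snps <- match(snps, info$snp_id)
    }
    g <- g[, snps, drop = FALSE]
    info <- info[snps, , drop = FALSE]
  }
  genotype_matrix(g, info)
}

# Per-SNP genotype counts (n0, n1, n2) over non-missing calls.
genotype_counts <- function(x) {
  g <- x$geno
  cbind(n0 = colSums(g == 0, na.rm = TRUE),
        n1 = colSums(g == 1, na.rm = TRUE),
        n2 = colSums(g == 2, na.rm = TRUE))
}
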