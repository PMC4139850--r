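#' Write genotypes as PLINK text (.ped/.map)
#'
#' `.map` columns: chromosome, SNP id, genetic distance (0), 1-based
#' position. `.ped` columns: family id, individual id, paternal and maternal
#' ids (0), sex (1 = male, 2 = female, 0 = unknown), phenotype (-9 when
#' absent), then two allele characters per SNP. Dosage `d` is written as `d`
#' copies of `allele2` and `2 - d` copies of `allele1`; missing calls become
#' `0 0`.
#'
#' @param geno a [genotype_matrix()].
#' @param prefix output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @param pheno optional phenotype frame supplying `sex` (1 = male) and `pa`.
#' @return `prefix`, invisibly.
#' @export
write_plink_text <- function(geno, prefix, pheno = NULL) {
  info <- geno$snp_info
  utils::write.table(data.frame(info$chrom, info$snp_id, 0L, info$pos),
                     paste0(prefix, ".map"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  g <- geno$geno
  n <- nrow(g); p <- ncol(g)
  a1 <- matrix(rep(info$allele1, each = n), n, p)
  a2 <- matrix(rep(info$allele2, each = n), n, p)
  first <- ifelse(is.na(g), "0", ifelse(g >= 1, a2, a1))
  second <- ifelse(is.na(g), "0", ifelse(g == 2, a2, a1))
  gcols <- matrix(paste(first, second), n, p)
  ids <- rownames(g)
  sex <- rep(0L, n); pa <- rep(-9, n)
  if (!is.null(pheno)) {
    at <- match(ids, pheno$sample_id)
    if ("sex" %in% names(pheno))
      sex <- ifelse(is.na(at), 0L, ifelse(pheno$sex[at] == 1, 1L, 2L))
    if ("pa" %in% names(pheno))
      pa <- ifelse(is.na(at), -9, pheno$pa[at])
  }
  ped <- cbind(ids, ids, 0L, 0L, sex, pa, gcols)
  utils::write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK text (.ped/.map) into a genotype matrix
#'
#' Biallelic loci are converted to additive minor-allele counts; `0 0`
#' genotypes become missing. The minor allele is the less frequent of the
#' two observed alleles in this cohort; at exactly equal frequencies the
#' alphabetically later allele is counted, which makes write-then-read an
#' identity on complete data.
#'
#' @param prefix path prefix of `<prefix>.ped` and `<prefix>.map`.
#' @return list with `geno` (a [genotype_matrix()]) and `samples` (data
#'   frame `sample_id`, `sex` where 1 = male, 0 = female, NA unknown, and
#'   `phenotype`, NA when coded -9).
#' @export
read_plink_text <- function(prefix) {
  map_path <- paste0(prefix, ".map"); ped_path <- paste0(prefix, ".ped")
  for (f in c(map_path, ped_path))
    if (!file.exists(f)) stopf("missing file: %s", f)
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos"),
                           stringsAsFactors = FALSE)
  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  p <- nrow(map)
  if (ncol(ped) != 6L + 2L * p)
    stopf(".ped has %d genotype columns but .map lists %d SNPs",
          ncol(ped) - 6L, p)
  n <- nrow(ped)
  g <- matrix(NA_real_, n, p)
  a1c <- character(p); a2c <- character(p)
  for (j in seq_len(p)) {
    x1 <- ped[[6L + 2L * j - 1L]]
    x2 <- ped[[6L + 2L * j]]
    obs <- x1 != "0" & x2 != "0"
    alleles <- sort(unique(c(x1[obs], x2[obs])))
    if (length(alleles) > 2L)
      stopf("SNP %s has more than two alleles: %s", map$snp_id[j],
            paste(alleles, collapse = ", "))
    if (length(alleles) == 0L) alleles <- c("A", "C")
    if (length(alleles) == 1L) {           # monomorphic: zero minor alleles
      g[obs, j] <- 0
      a1c[j] <- alleles; a2c[j] <- alleles
      next
    }
    cnt2 <- sum(x1[obs] == alleles[2L]) + sum(x2[obs] == alleles[2L])
    tot <- 2L * sum(obs)
    # count the minor allele; tie -> alphabetically later allele
    minor <- if (cnt2 <= tot - cnt2) alleles[2L] else alleles[1L]
    major <- setdiff(alleles, minor)
    g[obs, j] <- (x1[obs] == minor) + (x2[obs] == minor)
    a1c[j] <- major[1L]; a2c[j] <- minor
  }
  rownames(g) <- ped[[2L]]
  info <- data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                     allele1 = a1c, allele2 = a2c, stringsAsFactors = FALSE)
  sex_raw <- as.integer(ped[[5L]])
  pa_raw <- suppressWarnings(as.numeric(ped[[6L]]))
  samples <- data.frame(sample_id = ped[[2L]],
                        sex = ifelse(sex_raw == 1L, 1L,
                                     ifelse(sex_raw == 2L, 0L, NA_integer_)),
                        phenotype = ifelse(pa_raw == -9, NA_real_, pa_raw),
                        stringsAsFactors = FALSE)
  list(geno = genotype_matrix(g, info), samples = samples)
}

#' Read an additive-coded genotype TSV
#'
#' Fast-path input: a tab-separated matrix with a header of SNP ids, a
#' `sample_id` first column, and entries 0/1/2 or NA.
#'
#' @param path TSV path.
#' @return a [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path) {
  df <- read_tsv_file(path, check.names = FALSE)
  if (names(df)[1L] != "sample_id") stopf("first column must be `sample_id`")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample_id
  genotype_matrix(m)
}

#' Write an additive-coded genotype TSV
#' @param geno a [genotype_matrix()].
#' @param path output TSV path.
#' @export
write_genotype_tsv <- function(geno, path) {
  df <- data.frame(sample_id = sample_ids(geno), geno$geno,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}
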