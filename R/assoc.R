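#' Single-SNP covariate-adjusted association scan
#'
#' For every SNP fits `pa ~ intercept + g + sex + age + area + bmi` by least
#' squares and reports the Wald t-test for the genotype coefficient. The
#' genotype is additive minor-allele dosage; columns whose coded-allele
#' frequency exceeds 0.5 in this cohort are flipped (`g <- 2 - g`) so that
#' betas are always per minor allele. Computation residualises the phenotype
#' and all genotype columns on the covariates once (Frisch-Waugh-Lovell), so
#' the per-SNP statistics equal the full multiple-regression fit exactly.
#'
#' @param geno a complete [genotype_matrix()] (run [impute_missing()] first).
#' @param pheno phenotype frame with `sample_id`, `pa` and the covariates
#'   `sex`, `age`, `area`, `bmi`.
#' @return data frame of class `assoc_table`: one row per SNP with `snp_id`,
#'   `chrom`, `pos`, `beta`, `se`, `t`, `p_value`, `maf`, `n_used`,
#'   `flipped`, `flag` (`"ok"` or `"monomorphic"`; monomorphic SNPs get
#'   `beta = 0`, `p_value = 1`).
#' @export
single_snp_scan <- function(geno, pheno) {
  g <- geno$geno
  if (anyNA(g))
    stopf("genotypes contain missing calls; run impute_missing() first")
  ids <- sample_ids(geno)
  at <- match(ids, pheno$sample_id)
  if (anyNA(at))
    stopf("phenotype frame lacks sample(s): %s",
          paste(utils::head(ids[is.na(at)], 5), collapse = ", "))
  ph <- pheno[at, , drop = FALSE]
  y <- ph$pa
  if (anyNA(y)) stopf("phenotype contains missing values")
  n <- length(y)
  cm <- covariate_matrix(ph)
  design <- cbind(intercept = 1, cm)
  k <- ncol(design)                       # covariates + intercept
  df <- n - k - 1L                        # residual df of the full model
  if (df < 1L) stopf("too few samples (%d) for the covariate model", n)

  freq <- colMeans(g) / 2
  flip <- freq > 0.5
  if (any(flip)) g[, flip] <- 2 - g[, flip]
  maf <- pmin(freq, 1 - freq)

  qrd <- qr(design)
  y_res <- qr.resid(qrd, y)
  g_res <- qr.resid(qrd, g)
  gss <- colSums(g_res^2)
  num <- colSums(g_res * y_res)
  yss <- sum(y_res^2)

  mono <- gss < n * 1e-12
  beta <- ifelse(mono, 0, num / gss)
  rss <- pmax(yss - beta * num, 0)
  se <- sqrt(rss / df / gss)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  beta[mono] <- 0; se[mono] <- NA_real_; tval[mono] <- 0; p[mono] <- 1

  out <- data.frame(snp_id = geno$snp_info$snp_id,
                    chrom = geno$snp_info$chrom,
                    pos = geno$snp_info$pos,
                    beta = beta, se = se, t = tval, p_value = p,
                    maf = unname(maf), n_used = n,
                    flipped = unname(flip),
                    flag = ifelse(mono, "monomorphic", "ok"),
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

# Deterministic scan ordering: p ascending, then |t| descending, then id.
assoc_order <- function(assoc) {
  order(assoc$p_value, -abs(assoc$t), assoc$snp_id)
}

#' Top-K screening of the association scan
#'
#' Returns, for each requested depth K, the K SNPs with smallest scan
#' p-values. Ties at the boundary are broken by `|t|` descending and then by
#' SNP id, so the sets are deterministic and nested across depths.
#'
#' @param assoc an `assoc_table` from [single_snp_scan()].
#' @param depths integer vector of screen depths.
#' @return named list (one element per depth, in increasing order) of
#'   character vectors of SNP ids, each ordered by ascending p-value.
#' @export
screen_top_k <- function(assoc, depths) {
  depths <- sort(unique(as.integer(depths)))
  if (any(depths < 1L)) stopf("screen depths must be positive")
  if (max(depths) > nrow(assoc))
    stopf("screen depth %d exceeds the %d tested SNPs", max(depths), nrow(assoc))
  ranked <- assoc$snp_id[assoc_order(assoc)]
  sets <- lapply(depths, function(k) ranked[seq_len(k)])
  names(sets) <- as.character(depths)
  sets
}

#' Export Manhattan-plot data
#'
#' Writes (or returns) a table of chromosome, position and `-log10(p)` per
#' SNP, with genome-wide and suggestive thresholds recorded as attributes
#' and appended to the file header. Rows without position metadata are
#' dropped with a message.
#'
#' @param assoc an `assoc_table`.
#' @param path optional output TSV path.
#' @param genomewide,suggestive reference p-value thresholds.
#' @return data frame `chrom`, `pos`, `snp_id`, `neglog10_p` (invisibly when
#'   `path` is given).
#' @export
manhattan_export <- function(assoc, path = NULL,
                             genomewide = 1e-5, suggestive = 1e-4) {
  keep <- !is.na(assoc$chrom) & !is.na(assoc$pos)
  if (any(!keep))
    message(sprintf("dropping %d SNP(s) without position metadata", sum(!keep)))
  df <- data.frame(chrom = assoc$chrom[keep], pos = assoc$pos[keep],
                   snp_id = assoc$snp_id[keep],
                   neglog10_p = -log10(assoc$p_value[keep]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  attr(df, "genomewide_line") <- -log10(genomewide)
  attr(df, "suggestive_line") <- -log10(suggestive)
  if (!is.null(path)) {
    con <- file(path, "w")
    writeLines(sprintf("# genomewide_line=%g suggestive_line=%g",
                       -log10(genomewide), -log10(suggestive)), con)
    close(con)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, col.names = TRUE,
                                        append = TRUE))
    return(invisible(df))
  }
  df
}
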