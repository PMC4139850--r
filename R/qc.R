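#' Quality-control thresholds
#'
#' Defaults follow common GWAS practice for cohort-scale panels: samples are
#' removed at >4% missing calls, >30% heterozygosity, reported/inferred sex
#' mismatch, a disease-exclusion flag, or mean pairwise identity-by-state
#' above 0.80; markers at >5% missing calls, MAF < 0.01, or a Hardy-Weinberg
#' exact p-value below 1e-6.
#'
#' @param sample_missing_max max per-sample missing-call fraction.
#' @param sample_het_max max per-sample heterozygosity.
#' @param ibs_max max pairwise IBS before a pair is treated as related.
#' @param marker_missing_max max per-marker missing-call fraction.
#' @param maf_min minimum minor allele frequency.
#' @param hwe_p_min minimum HWE exact p-value.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_missing_max = 0.04,
                          sample_het_max = 0.30,
                          ibs_max = 0.80,
                          marker_missing_max = 0.05,
                          maf_min = 0.01,
                          hwe_p_min = 1e-6) {
  for (nm in c("sample_missing_max", "sample_het_max", "ibs_max",
               "marker_missing_max", "maf_min", "hwe_p_min"))
    check_fraction(get(nm), nm, 0, 1, lo_open = TRUE, hi_open = TRUE)
  structure(list(sample_missing_max = sample_missing_max,
                 sample_het_max = sample_het_max,
                 ibs_max = ibs_max,
                 marker_missing_max = marker_missing_max,
                 maf_min = maf_min,
                 hwe_p_min = hwe_p_min),
            class = "qc_thresholds")
}

new_qc_report <- function() {
  structure(data.frame(filter = character(), threshold = character(),
                       n_removed = integer(), removed_ids = character(),
                       stringsAsFactors = FALSE),
            class = c("qc_report", "data.frame"))
}

add_qc_stage <- function(report, filter, threshold, removed) {
  row <- data.frame(filter = filter, threshold = as.character(threshold),
                    n_removed = length(removed),
                    removed_ids = paste(removed, collapse = ","),
                    stringsAsFactors = FALSE)
  structure(rbind(as.data.frame(report), row),
            class = c("qc_report", "data.frame"))
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  df <- as.data.frame(x)[, c("filter", "threshold", "n_removed")]
  print(df, row.names = FALSE)
  cat(sprintf("total removed: %d\n", sum(x$n_removed)))
  invisible(x)
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided exact p-value conditioning on the observed allele counts: over
#' all heterozygote counts compatible with the allele counts, the
#' probabilities of all configurations no more probable than the observed
#' one are summed. Monomorphic markers return 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major hom, het, minor hom).
#' @return exact p-value in `(0, 1]`.
#' @examples
#' hwe_exact_test(25, 50, 25)   # near 1: most probable configuration
#' hwe_exact_test(50, 0, 50)    # extreme heterozygote deficit
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != floor(counts)))
    stopf("genotype counts must be nonnegative integers")
  n <- sum(counts)
  if (n == 0) stopf("total genotype count must be > 0")
  n_a <- 2 * n_aa + n_Aa           # minor-ish allele count as given
  rare <- min(n_a, 2L * n - n_a)
  if (rare == 0) return(1)
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  # log P(h | n, rare) up to a constant: multinomial coefficient times 2^h
  logp <- lgamma(n + 1) -
    lgamma((rare - hets) / 2 + 1) -
    lgamma(hets + 1) -
    lgamma(n - (rare + hets) / 2 + 1) +
    hets * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- match(n_Aa, hets)
  if (is.na(obs)) stopf("heterozygote count incompatible with allele counts")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-10)]))
}

#' Pairwise identity-by-state between two samples
#'
#' Mean over shared non-missing SNPs of `(2 - |g_i - g_j|) / 2`.
#'
#' @param geno a [genotype_matrix()].
#' @param pair character vector of two sample ids (or integer indices).
#' @return IBS fraction in `[0, 1]`, or `NA` (with a warning) when the pair
#'   shares no non-missing calls.
#' @export
pairwise_ibs <- function(geno, pair) {
  if (length(pair) != 2L) stopf("`pair` must identify two samples")
  g1 <- geno$geno[pair[[1L]], ]
  g2 <- geno$geno[pair[[2L]], ]
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) {
    warnf("samples share no non-missing calls; IBS undefined")
    return(NA_real_)
  }
  mean((2 - abs(g1[ok] - g2[ok])) / 2)
}

# Full IBS matrix via indicator-matrix products; O(n^2 p) in BLAS.
ibs_matrix <- function(geno) {
  g <- geno$geno
  obs <- !is.na(g)
  i0 <- (g == 0) & obs; i1 <- (g == 1) & obs; i2 <- (g == 2) & obs
  storage.mode(i0) <- storage.mode(i1) <- storage.mode(i2) <- "double"
  storage.mode(obs) <- "double"
  d01 <- i0 %*% t(i1); d12 <- i1 %*% t(i2); d02 <- i0 %*% t(i2)
  totdiff <- d01 + t(d01) + d12 + t(d12) + 2 * (d02 + t(d02))
  shared <- obs %*% t(obs)
  ibs <- 1 - totdiff / (2 * shared)
  ibs[shared == 0] <- NA_real_
  dimnames(ibs) <- list(rownames(g), rownames(g))
  ibs
}

#' Sample quality control
#'
#' Applies the sample filters in a fixed order — missingness, heterozygosity,
#' sex inconsistency, disease-exclusion flag, relatedness — removing each
#' sample at the first stage it fails, so per-stage counts are sequential
#' and disjoint.
#'
#' The sex check compares `meta$reported_sex` against a genotype-inferred
#' `meta$inferred_sex` column supplied by the caller (autosome-only data
#' cannot infer sex); if either column is absent the stage is skipped with a
#' warning. The disease stage removes samples with `meta$exclude_flag`
#' `TRUE` and is skipped silently when the column is absent. Relatedness
#' flags pairs with IBS above `thr$ibs_max` and removes, from each flagged
#' pair, the member with higher missingness (ties broken by lexicographic
#' sample id), repeating until no flagged pair remains.
#'
#' @param geno a [genotype_matrix()].
#' @param meta data frame with `sample_id` and optional `reported_sex`,
#'   `inferred_sex`, `exclude_flag` columns covering every sample.
#' @param thr a [qc_thresholds()].
#' @return list with `geno` (filtered) and `report` (a `qc_report`).
#' @export
sample_qc <- function(geno, meta, thr = qc_thresholds()) {
  ids <- sample_ids(geno)
  orphan <- setdiff(ids, meta$sample_id)
  if (length(orphan))
    stopf("samples absent from `meta`: %s",
          paste(utils::head(orphan, 5), collapse = ", "))
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  report <- new_qc_report()
  keep <- ids

  miss <- sample_missing_rate(geno)
  rm1 <- keep[miss[keep] > thr$sample_missing_max]
  keep <- setdiff(keep, rm1)
  report <- add_qc_stage(report, "sample_missingness",
                         sprintf("> %g", thr$sample_missing_max), rm1)

  het <- sample_het_rate(geno)
  rm2 <- keep[het[keep] > thr$sample_het_max]
  keep <- setdiff(keep, rm2)
  report <- add_qc_stage(report, "heterozygosity",
                         sprintf("> %g", thr$sample_het_max), rm2)

  if (all(c("reported_sex", "inferred_sex") %in% names(meta))) {
    sx <- meta[match(keep, meta$sample_id), ]
    rm3 <- keep[!is.na(sx$reported_sex) & !is.na(sx$inferred_sex) &
                  sx$reported_sex != sx$inferred_sex]
  } else {
    warnf("no reported_sex/inferred_sex columns; sex-consistency stage skipped")
    rm3 <- character(0)
  }
  keep <- setdiff(keep, rm3)
  report <- add_qc_stage(report, "sex_inconsistency", "mismatch", rm3)

  rm4 <- if ("exclude_flag" %in% names(meta)) {
    fx <- meta[match(keep, meta$sample_id), ]
    keep[!is.na(fx$exclude_flag) & fx$exclude_flag]
  } else character(0)
  keep <- setdiff(keep, rm4)
  report <- add_qc_stage(report, "disease_exclusion", "flagged", rm4)

  rm5 <- character(0)
  if (length(keep) > 1L) {
    sub <- subset_genotypes(geno, samples = keep)
    ibs <- ibs_matrix(sub)
    missk <- sample_missing_rate(sub)
    repeat {
      ibs_active <- ibs
      ibs_active[upper.tri(ibs_active, diag = TRUE)] <- NA_real_
      flagged <- which(ibs_active > thr$ibs_max, arr.ind = TRUE)
      if (!nrow(flagged)) break
      a <- rownames(ibs)[flagged[1L, "row"]]
      b <- colnames(ibs)[flagged[1L, "col"]]
      drop <- if (missk[a] > missk[b]) a
      else if (missk[b] > missk[a]) b
      else max(a, b)          # tie: lexicographically later id dropped
      rm5 <- c(rm5, drop)
      at <- match(drop, rownames(ibs))
      ibs <- ibs[-at, -at, drop = FALSE]
    }
  }
  keep <- setdiff(keep, rm5)
  report <- add_qc_stage(report, "relatedness",
                         sprintf("IBS > %g", thr$ibs_max), rm5)

  list(geno = subset_genotypes(geno, samples = keep), report = report)
}

#' Marker quality control
#'
#' Removes markers in a fixed order — call rate, minor allele frequency,
#' Hardy-Weinberg exact test — each computed over the post-sample-QC cohort
#' and over non-missing calls. Counts are of the first failing stage.
#'
#' @param geno a [genotype_matrix()] (after [sample_qc()]).
#' @param thr a [qc_thresholds()].
#' @return list with `geno` (filtered) and `report` (a `qc_report`).
#' @export
marker_qc <- function(geno, thr = qc_thresholds()) {
  report <- new_qc_report()
  ids <- geno$snp_info$snp_id
  keep <- ids

  miss <- snp_missing_rate(geno)
  rm1 <- keep[miss[match(keep, ids)] > thr$marker_missing_max]
  keep <- setdiff(keep, rm1)
  report <- add_qc_stage(report, "marker_missingness",
                         sprintf("> %g", thr$marker_missing_max), rm1)

  maf <- snp_maf(geno)
  rm2 <- keep[maf[match(keep, ids)] < thr$maf_min]
  keep <- setdiff(keep, rm2)
  report <- add_qc_stage(report, "maf", sprintf("< %g", thr$maf_min), rm2)

  cnt <- genotype_counts(geno)
  hwe_p <- vapply(match(keep, ids), function(j)
    hwe_exact_test(cnt[j, "n0"], cnt[j, "n1"], cnt[j, "n2"]), numeric(1))
  rm3 <- keep[hwe_p < thr$hwe_p_min]
  keep <- setdiff(keep, rm3)
  report <- add_qc_stage(report, "hwe", sprintf("p < %g", thr$hwe_p_min), rm3)

  list(geno = subset_genotypes(geno, snps = keep), report = report)
}

#' Replace missing genotype calls by the per-SNP modal genotype
#'
#' Downstream joint modelling needs complete additive codes; missing calls
#' are filled with the most frequent observed genotype of the SNP, ties
#' broken toward the lower code.
#'
#' @param geno a [genotype_matrix()].
#' @return a complete [genotype_matrix()].
#' @export
impute_missing <- function(geno) {
  g <- geno$geno
  if (!anyNA(g)) return(geno)
  cnt <- genotype_counts(geno)
  all_missing <- rowSums(cnt) == 0
  if (any(all_missing))
    stopf("SNP(s) with all calls missing cannot be imputed: %s",
          paste(utils::head(geno$snp_info$snp_id[all_missing], 5), collapse = ", "))
  mode_code <- max.col(cnt, ties.method = "first") - 1L
  for (j in which(colSums(is.na(g)) > 0)) {
    g[is.na(g[, j]), j] <- mode_code[j]
  }
  genotype_matrix(g, geno$snp_info)
}
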