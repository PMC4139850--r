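#' Adjusted R-squared of a joint SNP + covariate model
#'
#' Fits `pa ~ intercept + SNPs + sex + age + area + bmi` by OLS and returns
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)` with `p` the number of
#' non-intercept predictors actually fitted. Collinear columns are dropped
#' (with a warning) and `p` reduced accordingly.
#'
#' @param geno_subset dosage matrix or [genotype_matrix()]; may have zero
#'   columns for the covariate-only baseline.
#' @param pheno phenotype frame.
#' @return adjusted R-squared, with attributes `r2` (unadjusted), `p`
#'   (predictors fitted) and `n`.
#' @export
adjusted_r2 <- function(geno_subset, pheno) {
  g <- as_snp_matrix(geno_subset)
  ph <- align_pheno(g, pheno)
  y <- ph$pa
  x <- cbind(g, covariate_matrix(ph))
  n <- length(y)
  if (n <= ncol(x) + 1L)
    stopf("design (%d predictors + intercept) needs more than %d samples",
          ncol(x), n)
  qrd <- qr(cbind(1, x))
  if (qrd$rank < ncol(x) + 1L)
    warnf("dropping %d collinear column(s) from the design",
          ncol(x) + 1L - qrd$rank)
  p <- qrd$rank - 1L
  res <- qr.resid(qrd, y)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(adj, r2 = r2, p = p, n = n)
}

#' Adjusted-R-squared curves: multi-stage vs single-marker rankings
#'
#' Ranks candidate SNPs two ways — by descending bootstrap selection
#' stability at the deepest screen (ties: larger `|effect_size|`, then SNP
#' id) over that screen's jointly identified set, and by ascending
#' single-SNP p-value over the same screened pool — and, for each requested
#' panel size, fits the joint OLS model (always including covariates) and
#' records unadjusted and adjusted R-squared.
#'
#' @param selection a `selection_result` from [multi_stage_select()].
#' @param assoc the `assoc_table` used for screening.
#' @param geno complete [genotype_matrix()].
#' @param pheno phenotype frame.
#' @param sizes integer panel sizes; sizes exceeding a ranking's pool are
#'   truncated with a message. Size 0 gives the covariate-only baseline for
#'   both curves.
#' @param holdout_frac fraction of samples held out for honest prediction;
#'   0 (the default) evaluates in-sample, mirroring the descriptive use of
#'   these curves. With a holdout, models are fitted on the training split
#'   and `r2` is the out-of-sample R-squared on the held-out samples
#'   (`adjusted_r2` is reported equal to it: no dimension penalty is needed
#'   out of sample).
#' @param holdout_seed seed for the holdout split.
#' @return data frame of class `r2_curve`: `source` (`"multi_stage"` or
#'   `"single_marker"`), `n_snps`, `r2`, `adjusted_r2`.
#' @export
build_r2_curves <- function(selection, assoc, geno, pheno,
                            sizes = c(0, 5, 10, 20, 50),
                            holdout_frac = 0, holdout_seed = 1L) {
  depths <- names(selection$nonzero)
  deepest <- depths[length(depths)]
  bt <- selection$bss_table
  bt <- bt[bt$depth == as.integer(deepest), , drop = FALSE]

  cand <- bt[bt$snp_id %in% selection$nonzero[[deepest]], , drop = FALSE]
  ms_rank <- cand$snp_id[order(-cand$bss, -abs(cand$effect_size), cand$snp_id)]

  pool <- screen_top_k(assoc, as.integer(deepest))[[1L]]
  sub <- assoc[match(pool, assoc$snp_id), , drop = FALSE]
  sm_rank <- sub$snp_id[order(sub$p_value, -abs(sub$t), sub$snp_id)]

  check_fraction(holdout_frac, "holdout_frac", 0, 1, hi_open = TRUE)
  split <- NULL
  if (holdout_frac > 0) {
    set.seed(derive_seed(holdout_seed, 4L))
    n <- n_samples(geno)
    test <- sort(sample.int(n, max(2L, round(holdout_frac * n))))
    split <- list(train = setdiff(seq_len(n), test), test = test)
  }

  sizes <- sort(unique(as.integer(sizes)))
  rows <- list()
  for (src in c("multi_stage", "single_marker")) {
    ranking <- if (src == "multi_stage") ms_rank else sm_rank
    sz <- sizes
    if (max(sz) > length(ranking)) {
      message(sprintf("%s: truncating sizes above the %d available SNPs",
                      src, length(ranking)))
      sz <- unique(pmin(sz, length(ranking)))
    }
    for (s in sz) {
      gsub <- subset_genotypes(geno,
                               snps = if (s > 0) ranking[seq_len(s)] else integer(0))
      if (is.null(split)) {
        a <- adjusted_r2(gsub$geno, pheno)
        r2 <- attr(a, "r2"); ar2 <- as.numeric(a)
      } else {
        r2 <- ar2 <- holdout_r2(gsub$geno, pheno, split)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(source = src, n_snps = s, r2 = r2, adjusted_r2 = ar2,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("r2_curve", "data.frame")
  out
}

# Out-of-sample R^2: OLS on the training split, scored on the holdout
# against the holdout phenotype mean.
holdout_r2 <- function(g, pheno, split) {
  ph <- align_pheno(g, pheno)
  x <- cbind(1, g, covariate_matrix(ph))
  y <- ph$pa
  fit <- stats::lm.fit(x[split$train, , drop = FALSE], y[split$train])
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  pred <- drop(x[split$test, , drop = FALSE] %*% cf)
  yt <- y[split$test]
  1 - sum((yt - pred)^2) / sum((yt - mean(yt))^2)
}
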