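#' Configuration for multi-stage elastic-net selection
#'
#' @param alpha elastic-net mixing parameter in `(0, 1]` (1 = lasso); the
#'   default 0.5 balances sparsity against the grouping of correlated SNPs.
#' @param nfolds cross-validation folds for tuning lambda on the full
#'   screened data (used by the CV tuning rules).
#' @param B number of bootstrap resamples for the selection-stability score;
#'   BSS granularity is `1/B`.
#' @param bss_threshold minimum BSS for final selection (default 0.95).
#' @param screen_depths top-K depths for the screening stage.
#' @param lambda_choice how the penalty is tuned on the full screened data:
#'   `"retention"` (default) takes the largest lambda on the glmnet path at
#'   which at least `retention_frac` of the screened SNPs carry nonzero
#'   coefficients — the liberal joint-identification regime in which the
#'   stability score, not the penalty, does the pruning; `"min"` and `"1se"`
#'   use k-fold cross-validation (prediction-optimal and one-SE sparser).
#' @param retention_frac target nonzero fraction for the `"retention"` rule.
#' @param retune_lambda re-tune lambda inside every bootstrap resample
#'   instead of holding the full-data lambda fixed (slower; default `FALSE`,
#'   so stability is measured for one fixed selection rule).
#' @param bss_rule `"all"` (default) requires BSS at or above the threshold
#'   at every screen depth; `"deepest"` only at the deepest screen.
#' @param seed integer seed controlling fold assignment and resampling.
#' @return list of class `en_config`.
#' @export
en_config <- function(alpha = 0.5, nfolds = 5L, B = 100L,
                      bss_threshold = 0.95,
                      screen_depths = c(1000L, 2000L, 3000L, 4000L),
                      lambda_choice = c("retention", "min", "1se"),
                      retention_frac = 0.6,
                      retune_lambda = FALSE,
                      bss_rule = c("all", "deepest"),
                      seed = 1L) {
  check_fraction(alpha, "alpha", 0, 1, lo_open = TRUE)
  check_fraction(bss_threshold, "bss_threshold", 0, 1, lo_open = TRUE)
  check_fraction(retention_frac, "retention_frac", 0, 1, lo_open = TRUE)
  structure(list(alpha = alpha,
                 nfolds = check_count(nfolds, "nfolds", min = 3L),
                 B = check_count(B, "B"),
                 bss_threshold = bss_threshold,
                 screen_depths = sort(unique(as.integer(screen_depths))),
                 lambda_choice = match.arg(lambda_choice),
                 retention_frac = retention_frac,
                 retune_lambda = isTRUE(retune_lambda),
                 bss_rule = match.arg(bss_rule),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "en_config")
}

as_snp_matrix <- function(geno_subset) {
  if (inherits(geno_subset, "genotype_matrix")) geno_subset$geno else
    as.matrix(geno_subset)
}

# Fit glmnet at one target lambda, approaching it along a decreasing path
# for numerical stability; coefficients are read off exactly at the target.
# lambda = 0 is the unpenalized limit, computed exactly by least squares
# (coordinate descent converges too slowly there for tight tolerances).
glmnet_at_lambda <- function(x, y, alpha, penalty.factor, lambda,
                             thresh = 1e-10) {
  if (lambda == 0) {
    cf <- stats::lm.fit(cbind(1, x), y)$coefficients
    cf[is.na(cf)] <- 0
    out <- matrix(cf, ncol = 1,
                  dimnames = list(c("(Intercept)", colnames(x)), "s0"))
    return(out)
  }
  lseq <- lambda * c(8, 4, 2, 1)
  fit <- glmnet::glmnet(x, y, alpha = alpha, penalty.factor = penalty.factor,
                        lambda = lseq, standardize = TRUE,
                        thresh = thresh, maxit = 1e6)
  stats::coef(fit, s = lambda)
}

#' Elastic-net fit of SNPs plus unpenalized covariates
#'
#' Minimises `(1/2n) RSS + lambda * (alpha * sum|b_j| + (1-alpha)/2 *
#' sum b_j^2)` over the SNP coefficients, with the covariates `sex`, `age`,
#' `area`, `bmi` always in the model and never penalized. SNP columns are
#' standardized internally; coefficients are reported on the original
#' scale. Unless `lambda` is supplied, it is tuned by k-fold
#' cross-validation on the full data.
#'
#' @param geno_subset a [genotype_matrix()] or plain dosage matrix (complete,
#'   samples x SNPs).
#' @param pheno phenotype frame with `pa` and covariates, rows matching the
#'   genotype rows (matched by `sample_id` when names are available).
#' @param config an [en_config()].
#' @param lambda optional fixed penalty (0 gives the OLS limit when p < n).
#' @return list of class `en_fit`: `lambda`, `alpha`, `intercept`,
#'   `beta_snp` (named, original scale), `beta_covar`, `nonzero` (SNP ids
#'   with nonzero coefficients), `n`, `p`.
#' @export
fit_elastic_net <- function(geno_subset, pheno, config = en_config(),
                            lambda = NULL) {
  g <- as_snp_matrix(geno_subset)
  ph <- align_pheno(g, pheno)
  y <- ph$pa
  n <- length(y)
  if (stats::var(y) == 0) stopf("phenotype is constant; nothing to fit")
  if (is.null(lambda) && config$lambda_choice != "retention" &&
      n < 3L * config$nfolds)
    stopf("cross-validation needs at least 3 samples per fold (n = %d, folds = %d)",
          n, config$nfolds)
  cm <- covariate_matrix(ph)
  if (is.null(colnames(g))) colnames(g) <- sprintf("snp%d", seq_len(ncol(g)))
  x <- cbind(g, cm)
  pf <- c(rep(1, ncol(g)), rep(0, ncol(cm)))

  if (is.null(lambda) && config$lambda_choice == "retention") {
    fit <- glmnet::glmnet(x, y, alpha = config$alpha, penalty.factor = pf,
                          nlambda = 100L)
    frac <- Matrix::colMeans(fit$beta[seq_len(ncol(g)), , drop = FALSE] != 0)
    j <- which(frac >= config$retention_frac)[1L]
    if (is.na(j)) j <- length(fit$lambda)
    lambda <- fit$lambda[j]
    cf <- stats::coef(fit, s = lambda)
  } else if (is.null(lambda)) {
    set.seed(derive_seed(config$seed, 10L))
    foldid <- sample(rep(seq_len(config$nfolds), length.out = n))
    cv <- glmnet::cv.glmnet(x, y, alpha = config$alpha, penalty.factor = pf,
                            foldid = foldid, standardize = TRUE)
    lambda <- if (config$lambda_choice == "min") cv$lambda.min else cv$lambda.1se
    cf <- stats::coef(cv, s = lambda)
  } else {
    cf <- glmnet_at_lambda(x, y, config$alpha, pf, lambda)
  }
  cf <- drop(as.matrix(cf))
  beta_snp <- cf[colnames(g)]
  beta_covar <- cf[colnames(cm)]
  structure(list(lambda = as.numeric(lambda), alpha = config$alpha,
                 intercept = unname(cf[1L]),
                 beta_snp = beta_snp, beta_covar = beta_covar,
                 nonzero = names(beta_snp)[beta_snp != 0],
                 n = n, p = ncol(g)),
            class = "en_fit")
}

#' @export
print.en_fit <- function(x, ...) {
  cat(sprintf("<en_fit> n=%d p=%d alpha=%g lambda=%.5g nonzero=%d\n",
              x$n, x$p, x$alpha, x$lambda, length(x$nonzero)))
  invisible(x)
}

align_pheno <- function(g, pheno) {
  if (!is.null(rownames(g)) && all(rownames(g) %in% pheno$sample_id))
    return(pheno[match(rownames(g), pheno$sample_id), , drop = FALSE])
  if (nrow(pheno) != nrow(g))
    stopf("phenotype rows (%d) do not match genotype rows (%d)",
          nrow(pheno), nrow(g))
  pheno
}

#' Bootstrap selection stability (BSS) per SNP
#'
#' Draws `B` bootstrap resamples of the samples (with replacement, size n),
#' refits the elastic net on each at the full-data lambda (or re-tunes when
#' `config$retune_lambda`), and scores each SNP by the fraction of resamples
#' in which its coefficient is nonzero. A resample whose fit fails is
#' redrawn once, then counted as selecting nothing, with a warning.
#'
#' @param geno_subset complete dosage matrix or [genotype_matrix()].
#' @param pheno phenotype frame.
#' @param config an [en_config()].
#' @param full_fit optional precomputed [fit_elastic_net()] result on the
#'   full data (computed here when omitted).
#' @param seed_offset integer mixed into the resampling seed so that
#'   independent depths use independent resamples.
#' @return data frame of class `bss_table`: one row per SNP with `snp_id`,
#'   `selected_full`, `effect_size` (full-data coefficient), `bss`,
#'   `n_boot`.
#' @export
bootstrap_bss <- function(geno_subset, pheno, config = en_config(),
                          full_fit = NULL, seed_offset = 0L) {
  g <- as_snp_matrix(geno_subset)
  ph <- align_pheno(g, pheno)
  if (is.null(full_fit)) full_fit <- fit_elastic_net(g, ph, config)
  y <- ph$pa
  cm <- covariate_matrix(ph)
  if (is.null(colnames(g))) colnames(g) <- names(full_fit$beta_snp)
  x <- cbind(g, cm)
  pf <- c(rep(1, ncol(g)), rep(0, ncol(cm)))
  n <- nrow(x); p <- ncol(g)

  set.seed(derive_seed(config$seed, 100L + seed_offset))
  counts <- integer(p)
  one_fit <- function(idx) {
    if (config$retune_lambda) {
      cv <- glmnet::cv.glmnet(x[idx, , drop = FALSE], y[idx],
                              alpha = config$alpha, penalty.factor = pf,
                              nfolds = config$nfolds)
      drop(as.matrix(stats::coef(cv, s = cv$lambda.min)))[2:(p + 1L)]
    } else {
      # selection patterns stabilise at loose tolerance; the refit only
      # needs the nonzero pattern, not tight coefficients
      drop(as.matrix(glmnet_at_lambda(x[idx, , drop = FALSE], y[idx],
                                      config$alpha, pf, full_fit$lambda,
                                      thresh = 1e-7)))[2:(p + 1L)]
    }
  }
  for (b in seq_len(config$B)) {
    idx <- sample.int(n, n, replace = TRUE)
    bcf <- tryCatch(one_fit(idx), error = function(e) NULL)
    if (is.null(bcf)) {              # one redraw, then count as non-selecting
      idx <- sample.int(n, n, replace = TRUE)
      bcf <- tryCatch(one_fit(idx), error = function(e) {
        warnf("bootstrap fit %d failed twice; counted as selecting no SNP", b)
        numeric(p)
      })
    }
    counts <- counts + (bcf != 0)
  }
  out <- data.frame(snp_id = colnames(g),
                    selected_full = unname(full_fit$beta_snp != 0),
                    effect_size = unname(full_fit$beta_snp),
                    bss = counts / config$B,
                    n_boot = config$B,
                    stringsAsFactors = FALSE)
  class(out) <- c("bss_table", "data.frame")
  out
}

#' Multi-stage joint SNP identification
#'
#' Implements the full multi-stage procedure: (1) screen the association
#' scan at each configured depth K; (2) fit the elastic net on each screened
#' set and record its nonzero SNPs; (3) score every screened SNP by
#' bootstrap selection stability; (4) intersect the nonzero sets across all
#' depths ("common set"); (5) keep common-set SNPs whose BSS reaches
#' `bss_threshold` (at every depth, or only the deepest, per
#' `config$bss_rule`); (6) report per-SNP p-values from one joint multiple
#' regression of the phenotype on all final SNPs plus covariates.
#'
#' @param assoc an `assoc_table` from [single_snp_scan()].
#' @param geno complete [genotype_matrix()] covering the screened SNPs.
#' @param pheno phenotype frame.
#' @param config an [en_config()].
#' @return object of class `selection_result`: list with `table` (one row
#'   per final SNP: `snp_id`, `effect_size` and `bss` at the deepest
#'   screen, `p_value` from the joint regression, sorted by ascending p),
#'   `bss_table` (rows for every screened SNP at every depth, with
#'   `in_common_set`), `nonzero` (per-depth nonzero SNP id lists), `common`
#'   (the intersection), and `counts` (screened / jointly identified /
#'   common / final).
#' @export
multi_stage_select <- function(assoc, geno, pheno, config = en_config()) {
  screens <- screen_top_k(assoc, config$screen_depths)
  depths <- as.integer(names(screens))
  fits <- vector("list", length(depths))
  bss_tabs <- vector("list", length(depths))
  nonzero <- vector("list", length(depths))
  names(fits) <- names(bss_tabs) <- names(nonzero) <- names(screens)

  for (i in seq_along(depths)) {
    sub <- subset_genotypes(geno, snps = screens[[i]])
    fits[[i]] <- fit_elastic_net(sub, pheno, config)
    bt <- bootstrap_bss(sub, pheno, config, full_fit = fits[[i]],
                        seed_offset = i)
    bt$depth <- depths[i]
    bss_tabs[[i]] <- bt
    nonzero[[i]] <- fits[[i]]$nonzero
  }
  common <- Reduce(intersect, nonzero)
  if (!length(common)) message("empty cross-depth intersection; no SNP selected")

  bss_all <- do.call(rbind, bss_tabs)
  bss_all$in_common_set <- bss_all$snp_id %in% common
  deepest <- bss_tabs[[length(depths)]]

  pass_bss <- if (config$bss_rule == "all") {
    ok <- vapply(common, function(s) {
      all(vapply(bss_tabs, function(bt)
        bt$bss[match(s, bt$snp_id)] >= config$bss_threshold, logical(1)))
    }, logical(1))
    common[ok]
  } else {
    common[deepest$bss[match(common, deepest$snp_id)] >= config$bss_threshold]
  }

  if (length(pass_bss)) {
    gm <- subset_genotypes(geno, snps = pass_bss)
    ph <- align_pheno(gm$geno, pheno)
    dat <- data.frame(pa = ph$pa, gm$geno, covariate_matrix(ph),
                      check.names = FALSE)
    fit <- stats::lm(pa ~ ., data = dat)
    sm <- summary(fit)$coefficients
    pj <- sm[match(make.names(pass_bss), rownames(sm)), "Pr(>|t|)"]
    at <- match(pass_bss, deepest$snp_id)
    tab <- data.frame(snp_id = pass_bss,
                      effect_size = deepest$effect_size[at],
                      bss = deepest$bss[at],
                      p_value = unname(pj),
                      stringsAsFactors = FALSE)
    tab <- tab[order(tab$p_value, tab$snp_id), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(snp_id = character(), effect_size = numeric(),
                      bss = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  }
  structure(list(table = tab,
                 bss_table = bss_all,
                 nonzero = nonzero,
                 common = common,
                 counts = list(screened = depths,
                               jointly_identified = unname(lengths(nonzero)),
                               common = length(common),
                               final = nrow(tab)),
                 config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>\n")
  cat(sprintf("  screened depths: %s\n", paste(x$counts$screened, collapse = ", ")))
  cat(sprintf("  jointly identified: %s\n",
              paste(x$counts$jointly_identified, collapse = ", ")))
  cat(sprintf("  common set: %d, final (BSS >= %g): %d\n",
              x$counts$common, x$config$bss_threshold, x$counts$final))
  invisible(x)
}
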