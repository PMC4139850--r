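make_en_cohort <- function(n = 150, p = 20, seed = 5) {
  co <- make_cohort(n = n, p = p, n_causal = 3, h2 = 0.05, seed = seed,
                    missing_rate = 0)
  co$geno <- impute_missing(co$geno)
  co
}

test_that("the unpenalized limit reproduces OLS", {
  co <- make_en_cohort()
  fit <- fit_elastic_net(co$geno, co$pheno, en_config(seed = 1), lambda = 0)
  X <- cbind(co$geno$geno, as.matrix(co$pheno[, c("sex", "age", "area", "bmi")]))
  ols <- coef(lm(co$pheno$pa ~ X))
  expect_lt(max(abs(fit$beta_snp - ols[2:21])), 1e-6)
  expect_lt(max(abs(fit$beta_covar - ols[22:25])), 1e-6)
  expect_lt(abs(fit$intercept - ols[1]), 1e-6)
})

test_that("a huge penalty zeroes every SNP but keeps covariates fitted", {
  co <- make_en_cohort()
  fit <- fit_elastic_net(co$geno, co$pheno, en_config(seed = 1), lambda = 1e9)
  expect_true(all(fit$beta_snp == 0))
  expect_equal(length(fit$nonzero), 0L)
  covfit <- coef(lm(pa ~ sex + age + area + bmi, data = co$pheno))
  expect_equal(unname(fit$beta_covar), unname(covfit[-1]), tolerance = 1e-4)
})

test_that("the elastic net groups duplicated causal columns", {
  set.seed(21)
  n <- 200
  g <- rbinom(n, 2, 0.3)
  G <- cbind(dup1 = g, dup2 = g, noise = rbinom(n, 2, 0.3))
  ph <- null_pheno(n, seed = 22)
  ph$pa <- 500 + 120 * g + rnorm(n, 0, 100)
  cfg <- en_config(alpha = 0.5, seed = 23, lambda_choice = "min")
  lam <- 20
  en <- fit_elastic_net(G, ph, cfg, lambda = lam)
  expect_gt(abs(en$beta_snp["dup1"]), 0)
  expect_gt(abs(en$beta_snp["dup2"]), 0)
  # with exactly duplicated columns the EN solution splits the weight evenly
  expect_equal(en$beta_snp[["dup1"]], en$beta_snp[["dup2"]], tolerance = 1e-3)
})

test_that("returned coefficients are a local optimum of the EN objective", {
  co <- make_en_cohort()
  cfg <- en_config(seed = 3, lambda_choice = "min")
  lam <- 50
  fit <- fit_elastic_net(co$geno, co$pheno, cfg, lambda = lam)
  Xr <- cbind(co$geno$geno,
              as.matrix(co$pheno[, c("sex", "age", "area", "bmi")]))
  X <- cbind(1, Xr)
  y <- co$pheno$pa
  # evaluate the objective in the internally standardized coordinates the
  # solver works in (x columns and y scaled to unit variance, penalty
  # factors rescaled to sum to the number of variables)
  sy <- sqrt(mean((y - mean(y))^2))
  sds <- apply(Xr, 2, function(v) sqrt(mean((v - mean(v))^2)))
  pf <- c(rep(1, n_snps(co$geno)), rep(0, 4))
  pfe <- pf * length(pf) / sum(pf)
  objective <- function(beta_all) {
    r <- (y - X %*% beta_all) / sy
    bs <- beta_all[-1] * sds / sy
    mean(r^2) / 2 + lam / sy * sum(pfe * (0.5 * abs(bs) + 0.25 * bs^2))
  }
  b0 <- c(fit$intercept, fit$beta_snp, fit$beta_covar)
  base <- objective(b0)
  expect_lte(base, objective(numeric(length(b0))))
  set.seed(4)
  for (i in 1:100) {
    expect_lt(base, objective(b0 + rnorm(length(b0), 0, 1e-3)) + 1e-8)
  }
})

test_that("degenerate inputs are rejected", {
  co <- make_en_cohort()
  ph <- co$pheno; ph$pa <- 1
  expect_error(fit_elastic_net(co$geno, ph, en_config()), "constant")
  expect_error(
    fit_elastic_net(co$geno$geno[1:10, ], co$pheno[1:10, ],
                    en_config(nfolds = 5, lambda_choice = "min")),
    "3 samples per fold")
})

test_that("BSS is an exact selection fraction with the right granularity", {
  co <- make_en_cohort(n = 120, p = 10)
  cfg1 <- en_config(B = 1, seed = 9)
  b1 <- bootstrap_bss(co$geno, co$pheno, cfg1)
  expect_true(all(b1$bss %in% c(0, 1)))
  cfg <- en_config(B = 20, seed = 9)
  b <- bootstrap_bss(co$geno, co$pheno, cfg)
  expect_true(all(b$bss >= 0 & b$bss <= 1))
  expect_true(all(abs(b$bss * 20 - round(b$bss * 20)) < 1e-12))
  # determinism under a fixed seed
  b2 <- bootstrap_bss(co$geno, co$pheno, cfg)
  expect_identical(b, b2)
})

test_that("an overwhelming signal is always selected; pure noise rarely", {
  set.seed(31)
  n <- 300
  g_strong <- rbinom(n, 2, 0.4)
  ph <- null_pheno(n, seed = 32)
  ph$pa <- 1000 + 400 * g_strong + rnorm(n, 0, sqrt(var(400 * g_strong)))
  G <- cbind(strong = g_strong,
             matrix(rbinom(n * 9, 2, 0.3), n, 9,
                    dimnames = list(NULL, paste0("noise", 1:9))))
  b <- bootstrap_bss(G, ph, en_config(B = 50, seed = 33))
  expect_equal(b$bss[b$snp_id == "strong"], 1.0)

  # noise SNPs orthogonal to the phenotype, sitting next to real signal so
  # that the penalty is tuned to that signal, are rarely selected
  mean_noise <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 150
    gs <- rbinom(n, 2, 0.4)
    Gn <- cbind(signal = gs,
                matrix(rbinom(n * 5, 2, 0.3), n, 5,
                       dimnames = list(NULL, paste0("n", 1:5))))
    phn <- null_pheno(n, seed = 100 + s)
    phn$pa <- 1000 + 300 * gs + rnorm(n, 0, 300)
    bn <- bootstrap_bss(Gn, phn, en_config(B = 20, seed = s,
                                           lambda_choice = "1se"))
    mean(bn$bss[bn$snp_id != "signal"])
  }, numeric(1))
  expect_lt(mean(mean_noise), 0.2)
})

test_that("multi-stage selection composes screening, EN, BSS and intersection", {
  co <- make_cohort(n = 400, p = 300, n_causal = 4, h2 = 0.04, seed = 51,
                    missing_rate = 0)
  g <- impute_missing(co$geno)
  a <- single_snp_scan(g, co$pheno)
  cfg <- en_config(screen_depths = c(40, 80, 150), B = 25, seed = 52)
  sel <- multi_stage_select(a, g, co$pheno, cfg)

  # common-set property: final within every depth's nonzero set
  for (d in names(sel$nonzero))
    expect_true(all(sel$table$snp_id %in% sel$nonzero[[d]]))
  expect_true(all(sel$table$snp_id %in% sel$common))
  # BSS bookkeeping: every final SNP reaches the threshold at every depth
  for (s in sel$table$snp_id) {
    bt <- sel$bss_table[sel$bss_table$snp_id == s, ]
    expect_true(all(bt$bss >= 0.95))
  }
  # accounting is internally consistent
  expect_equal(sel$counts$jointly_identified, unname(lengths(sel$nonzero)))
  expect_lte(sel$counts$final, sel$counts$common)
  expect_true(all(sel$counts$common <= sel$counts$jointly_identified))
  # joint p-values are valid probabilities
  expect_true(all(sel$table$p_value > 0 & sel$table$p_value <= 1))

  # determinism of the whole procedure
  sel2 <- multi_stage_select(a, g, co$pheno, cfg)
  expect_identical(sel$table, sel2$table)
  expect_identical(sel$bss_table, sel2$bss_table)

  # most causal SNPs should be recovered in this easy regime
  expect_gte(sum(co$truth$causal_snp_ids %in% sel$table$snp_id), 2)
})

test_that("a single depth makes the common set that depth's nonzero set", {
  co <- make_cohort(n = 200, p = 60, n_causal = 2, h2 = 0.05, seed = 55,
                    missing_rate = 0)
  g <- impute_missing(co$geno)
  a <- single_snp_scan(g, co$pheno)
  cfg <- en_config(screen_depths = 30, B = 10, seed = 56)
  sel <- multi_stage_select(a, g, co$pheno, cfg)
  expect_setequal(sel$common, sel$nonzero[["30"]])
})

test_that("raising the BSS threshold never enlarges the final set", {
  co <- make_cohort(n = 200, p = 60, n_causal = 2, h2 = 0.05, seed = 57,
                    missing_rate = 0)
  g <- impute_missing(co$geno)
  a <- single_snp_scan(g, co$pheno)
  sets <- lapply(c(0.5, 0.8, 1.0), function(thr) {
    cfg <- en_config(screen_depths = c(30, 50), B = 10, seed = 58,
                     bss_threshold = thr)
    multi_stage_select(a, g, co$pheno, cfg)$table$snp_id
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
  # a strict threshold of 1.0 excludes anything at bss 0.9
  cfg <- en_config(screen_depths = c(30, 50), B = 10, seed = 58,
                   bss_threshold = 1.0)
  sel <- multi_stage_select(a, g, co$pheno, cfg)
  bt <- sel$bss_table[sel$bss_table$snp_id %in% sel$table$snp_id, ]
  expect_true(all(bt$bss == 1))
})
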