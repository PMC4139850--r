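test_that("configuration invariants are enforced", {
  expect_error(sim_config(100, 10, n_causal = 11), "n_causal")
  expect_error(sim_config(100, 10, maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(100, 10, within_block_rho = 1), "within_block_rho")
  expect_error(sim_config(100, 100, n_causal = 60, h2_per_causal = 0.02),
               "heritability")
  expect_error(sim_config(100, 10, missing_rate = 1), "missing_rate")
})

test_that("genotype generation hits target MAF and missingness", {
  cfg <- sim_config(5000, 40, maf_range = c(0.3, 0.3), missing_rate = 0,
                    n_causal = 0, seed = 7)
  g <- simulate_genotypes(cfg)
  expect_false(anyNA(g$geno))
  maf <- colMeans(g$geno) / 2
  # binomial sampling: SE of a MAF estimate at n=5000 is ~0.0046, so every
  # SNP should land within +/-0.02 of 0.30
  expect_true(all(abs(maf - 0.3) < 0.02))

  cfg2 <- sim_config(500, 100, missing_rate = 0.05, n_causal = 0, seed = 7)
  g2 <- simulate_genotypes(cfg2)
  expect_gt(mean(is.na(g2$geno)), 0.03)
  expect_lt(mean(is.na(g2$geno)), 0.07)
})

test_that("zero within-block correlation gives independent SNPs", {
  cfg <- sim_config(2000, 30, within_block_rho = 0, missing_rate = 0,
                    n_causal = 0, seed = 11)
  g <- simulate_genotypes(cfg)
  cors <- cor(g$geno[, 1:10])
  off <- cors[upper.tri(cors)]
  expect_lt(abs(mean(off)), 0.05)
})

test_that("within-block correlation is present and blocks are independent", {
  cfg <- sim_config(2000, 20, within_block_rho = 0.5, block_size = 10,
                    missing_rate = 0, n_causal = 0, seed = 13)
  g <- simulate_genotypes(cfg)
  cc <- cor(g$geno)
  within <- cc[1:10, 1:10][upper.tri(diag(10))]
  between <- cc[1:10, 11:20]
  expect_gt(mean(within), 0.15)
  expect_lt(abs(mean(between)), 0.05)
})

test_that("generator output is deterministic given the config", {
  cfg <- sim_config(100, 50, seed = 5, n_causal = 2, h2_per_causal = 0.02)
  g1 <- simulate_genotypes(cfg); g2 <- simulate_genotypes(cfg)
  expect_identical(g1$geno, g2$geno)
  p1 <- simulate_covariates_and_phenotype(g1, cfg)
  p2 <- simulate_covariates_and_phenotype(g2, cfg)
  expect_identical(p1$pheno, p2$pheno)
  expect_identical(p1$truth, p2$truth)
})

test_that("genotypes are Hardy-Weinberg consistent (uniform exact p-values)", {
  # independent SNPs: the KS check needs independent p-values
  cfg <- sim_config(2000, 1000, within_block_rho = 0, missing_rate = 0,
                    n_causal = 0, seed = 17)
  g <- simulate_genotypes(cfg)
  cnt <- cbind(colSums(g$geno == 0), colSums(g$geno == 1), colSums(g$geno == 2))
  pv <- vapply(seq_len(nrow(cnt)), function(j)
    hwe_exact_test(cnt[j, 1], cnt[j, 2], cnt[j, 3]), numeric(1))
  # exact conditional p-values are discrete and conservative; subtracting a
  # uniform share of the observed configuration's probability makes them
  # exactly Uniform(0,1) under the null, which the KS test can then assess
  atom <- vapply(seq_len(nrow(cnt)), function(j)
    hwe_obs_prob(cnt[j, 1], cnt[j, 2], cnt[j, 3]), numeric(1))
  set.seed(1)
  pv_r <- pv - runif(length(pv)) * atom
  ks <- suppressWarnings(ks.test(pv_r, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("phenotype mean matches the configured baseline without effects", {
  cfg <- sim_config(5000, 10, n_causal = 0, missing_rate = 0,
                    covariate_effects = c(sex = 0, age = 0, area = 0, bmi = 0),
                    intercept = 1332, noise_sd = 871, seed = 23)
  g <- simulate_genotypes(cfg)
  ph <- simulate_covariates_and_phenotype(g, cfg)$pheno
  se <- 871 / sqrt(5000)
  expect_lt(abs(mean(ph$pa) - 1332), 3 * se)
  expect_lt(abs(sd(ph$pa) - 871), 3 * se)
})

test_that("single-SNP regression recovers a causal effect", {
  cfg <- sim_config(5000, 20, n_causal = 1, h2_per_causal = 0.01,
                    missing_rate = 0, seed = 29)
  g <- simulate_genotypes(cfg)
  cp <- simulate_covariates_and_phenotype(g, cfg)
  j <- match(cp$truth$causal_snp_ids, g$snp_info$snp_id)
  fit <- summary(lm(cp$pheno$pa ~ g$geno[, j]))
  est <- fit$coefficients[2, ]
  expect_lt(abs(est["Estimate"] - cp$truth$causal_betas), 3 * est["Std. Error"])
})

test_that("noiseless phenotype without effects is constant", {
  cfg <- sim_config(50, 10, n_causal = 0, noise_sd = 0, missing_rate = 0,
                    covariate_effects = c(sex = 0, age = 0, area = 0, bmi = 0),
                    intercept = 1000, seed = 31)
  g <- simulate_genotypes(cfg)
  ph <- simulate_covariates_and_phenotype(g, cfg)$pheno
  expect_equal(ph$pa, rep(1000, 50))
})

test_that("variance accounting: full-model R2 matches configured shares", {
  cfg <- sim_config(5000, 100, n_causal = 10, h2_per_causal = 0.01,
                    missing_rate = 0, seed = 37)
  g <- simulate_genotypes(cfg)
  cp <- simulate_covariates_and_phenotype(g, cfg)
  ph <- cp$pheno
  cov_lin <- with(ph, 67 * sex + 640 * area)
  h2_tot <- 0.10
  total <- (var(cov_lin) + cfg$noise_sd^2) / (1 - h2_tot)
  expected_r2 <- 1 - cfg$noise_sd^2 / total
  G <- g$geno[, match(cp$truth$causal_snp_ids, g$snp_info$snp_id)]
  fit <- summary(lm(ph$pa ~ G + ph$sex + ph$age + ph$area + ph$bmi))
  expect_lt(abs(fit$r.squared - expected_r2), 0.03)
})

test_that("questionnaire inversion round-trips the phenotype", {
  cfg <- sim_config(200, 10, n_causal = 0, family = "lognormal", seed = 41)
  g <- simulate_genotypes(cfg)
  ph <- simulate_covariates_and_phenotype(g, cfg)$pheno
  met <- met_assignment()
  act <- simulate_questionnaire(ph, met, seed = 3)
  back <- suppressWarnings(compute_total_pa(act, met))
  expect_equal(back$pa, ph$pa, tolerance = 1e-12)

  # rounding to whole minutes keeps the round trip within one minute x MET sum
  actr <- simulate_questionnaire(ph, met, seed = 3, round_minutes = TRUE)
  backr <- suppressWarnings(compute_total_pa(actr, met))
  expect_lt(max(abs(backr$pa - ph$pa)), 0.5 * sum(met_assignment()))

  # determinism and the zero/negative edge cases
  expect_identical(act, simulate_questionnaire(ph, met, seed = 3))
  z <- data.frame(sample_id = "z", pa = 0)
  expect_equal(unlist(simulate_questionnaire(z, met, seed = 1)[, -1]),
               c(stable = 0, sitting = 0, low = 0, medium = 0, high = 0))
  expect_error(simulate_questionnaire(data.frame(sample_id = "n", pa = -5), met),
               "negative phenotype")
})

test_that("lognormal family yields positive right-skewed phenotypes", {
  cfg <- sim_config(2000, 10, n_causal = 0, family = "lognormal", seed = 43)
  g <- simulate_genotypes(cfg)
  ph <- simulate_covariates_and_phenotype(g, cfg)$pheno
  expect_true(all(ph$pa > 0))
  expect_gt(mean((ph$pa - mean(ph$pa))^3) / sd(ph$pa)^3, 0.5)
})
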