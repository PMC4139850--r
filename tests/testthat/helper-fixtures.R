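# Small cohorts built in code for unit tests.

make_cohort <- function(n = 300, p = 50, n_causal = 0, h2 = 0.01, seed = 42,
                        missing_rate = 0, rho = 0.3, ...) {
  cfg <- sim_config(n_samples = n, n_snps = p, n_causal = n_causal,
                    h2_per_causal = h2, missing_rate = missing_rate,
                    within_block_rho = rho, seed = seed, ...)
  geno <- simulate_genotypes(cfg)
  cp <- simulate_covariates_and_phenotype(geno, cfg)
  list(config = cfg, geno = geno, pheno = cp$pheno, truth = cp$truth)
}

# Hand-built genotype matrix from explicit codes.
geno_from_codes <- function(codes, sample_ids = NULL) {
  m <- as.matrix(codes)
  if (!is.null(sample_ids)) rownames(m) <- sample_ids
  genotype_matrix(m)
}

# Null phenotype frame with covariates independent of everything.
null_pheno <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%04d", seq_len(n)),
             pa = rnorm(n, 1332, 871),
             sex = rbinom(n, 1, 0.5), age = runif(n, 40, 69),
             area = rbinom(n, 1, 0.5), bmi = rnorm(n, 24, 3),
             stringsAsFactors = FALSE)
}
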