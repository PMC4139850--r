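#' Configuration for the synthetic cohort generator
#'
#' Describes a synthetic genotyped cohort: LD-blocked biallelic SNPs, a
#' quantitative physical-activity phenotype in MET·min/day driven by
#' covariates plus a sparse set of additive causal SNPs, and a missing-call
#' rate. Defaults emulate a two-area middle-aged cohort with overall
#' phenotype mean near 1332 and SD near 871 MET·min/day: a modest sex effect,
#' a large rural/urban area effect, and noise chosen so the marginal SD lands
#' near the target once the covariate and genetic shares are added.
#'
#' @param n_samples,n_snps cohort dimensions.
#' @param block_size SNPs per LD block.
#' @param within_block_rho exchangeable latent correlation within a block,
#'   in `[0, 1)`.
#' @param maf_range `(low, high)` in `(0, 0.5]`; per-SNP MAFs are drawn
#'   log-uniformly from this interval (an array-like decreasing spectrum).
#' @param n_causal number of causal SNPs (`<= n_snps`).
#' @param h2_per_causal fraction of total phenotype variance contributed by
#'   each causal SNP; `n_causal * h2_per_causal` must be `< 1`.
#' @param covariate_effects named vector `c(sex=, age=, area=, bmi=)` of
#'   effects on MET·min/day per unit covariate.
#' @param intercept baseline MET·min/day.
#' @param noise_sd residual SD in MET·min/day.
#' @param missing_rate fraction of genotype calls set missing, in `[0, 1)`.
#' @param family `"gaussian"` for additive Gaussian noise (default) or
#'   `"lognormal"` for multiplicative noise guaranteeing a positive,
#'   right-skewed phenotype.
#' @param seed integer seed; all generator output is deterministic given the
#'   full configuration.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples, n_snps,
                       block_size = 10L,
                       within_block_rho = 0.3,
                       maf_range = c(0.05, 0.5),
                       n_causal = 10L,
                       h2_per_causal = 0.005,
                       covariate_effects = c(sex = 67, age = 0, area = 640, bmi = 0),
                       intercept = 978.5,
                       noise_sd = 786,
                       missing_rate = 0.02,
                       family = c("gaussian", "lognormal"),
                       seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples")
  n_snps <- check_count(n_snps, "n_snps")
  block_size <- check_count(block_size, "block_size")
  n_causal <- check_count(n_causal, "n_causal", min = 0L)
  if (n_causal > n_snps) stopf("n_causal (%d) exceeds n_snps (%d)", n_causal, n_snps)
  check_fraction(within_block_rho, "within_block_rho", 0, 1, hi_open = TRUE)
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2])
    stopf("maf_range must be (low, high) with low <= high")
  check_fraction(maf_range[1], "maf_range[1]", 0, 0.5, lo_open = TRUE)
  check_fraction(maf_range[2], "maf_range[2]", 0, 0.5, lo_open = TRUE)
  check_fraction(h2_per_causal, "h2_per_causal", 0, 1, hi_open = TRUE)
  if (n_causal * h2_per_causal >= 1)
    stopf("total causal heritability n_causal * h2_per_causal = %g must be < 1",
          n_causal * h2_per_causal)
  check_fraction(missing_rate, "missing_rate", 0, 1, hi_open = TRUE)
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  miss <- setdiff(covariate_names(), names(covariate_effects))
  if (length(miss))
    stopf("covariate_effects lacks: %s", paste(miss, collapse = ", "))
  structure(list(n_samples = n_samples, n_snps = n_snps,
                 block_size = block_size,
                 within_block_rho = within_block_rho,
                 maf_range = as.numeric(maf_range),
                 n_causal = n_causal, h2_per_causal = h2_per_causal,
                 covariate_effects = covariate_effects[covariate_names()],
                 intercept = intercept, noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 family = match.arg(family),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "sim_config")
}

#' Simulate LD-blocked genotypes
#'
#' Genotypes are generated from a latent-Gaussian threshold model: each of
#' the two haplotypes of a sample carries, per LD block, a shared standard
#' normal block factor mixed with an independent residual (exchangeable
#' correlation `within_block_rho`), and the latent value is thresholded at
#' the per-SNP MAF quantile to give an allele indicator. Because the two
#' haplotypes are independent, genotype frequencies are Hardy-Weinberg
#' consistent by construction. Missing calls are inserted uniformly at
#' `missing_rate`.
#'
#' The complete (pre-missingness) matrix is retained in attribute
#' `"complete"` so that simulation truth can be checked in tests; downstream
#' analysis code never reads it.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()] with SNPs spread over chromosomes 1-22,
#'   one LD block never spanning two chromosomes.
#' @export
simulate_genotypes <- function(config) {
  if (!inherits(config, "sim_config")) stopf("`config` must be a sim_config")
  set.seed(derive_seed(config$seed, 0L))
  n <- config$n_samples; p <- config$n_snps
  rho <- config$within_block_rho
  block <- rep(seq_len(ceiling(p / config$block_size)),
               each = config$block_size, length.out = p)
  # log-uniform MAF spectrum: approximates the decreasing site-frequency
  # spectrum of genotyping arrays, keeping mean per-sample heterozygosity
  # (~0.28) and mean unrelated-pair IBS (~0.75) in the range real panels show
  mafs <- exp(stats::runif(p, log(config$maf_range[1]), log(config$maf_range[2])))
  thr <- stats::qnorm(mafs)
  alleles <- vector("list", 2L)
  for (h in 1:2) {
    z <- matrix(stats::rnorm(n * p), n, p)
    if (rho > 0) {
      u <- matrix(stats::rnorm(n * max(block)), n)
      z <- sqrt(rho) * u[, block] + sqrt(1 - rho) * z
    }
    alleles[[h]] <- z < rep(thr, each = n)
  }
  g <- alleles[[1L]] + alleles[[2L]]
  storage.mode(g) <- "double"
  rownames(g) <- sprintf("S%05d", seq_len(n))
  n_blocks <- max(block)
  chrom <- ((block - 1L) %% 22L) + 1L
  info <- data.frame(snp_id = sprintf("snp%05d", seq_len(p)),
                     chrom = chrom,
                     pos = 1000L * seq_len(p),
                     allele1 = "A", allele2 = "C",
                     block = block,
                     stringsAsFactors = FALSE)
  complete <- g
  if (config$missing_rate > 0) {
    drop <- stats::runif(n * p) < config$missing_rate
    g[drop] <- NA_real_
  }
  out <- genotype_matrix(g, info)
  attr(out, "complete") <- complete
  attr(out, "target_maf") <- mafs
  out
}

#' Simulate covariates, causal effects and the PA phenotype
#'
#' Covariates: sex ~ Bernoulli(0.5) (1 = male), age ~ Uniform(40, 69),
#' area ~ Bernoulli(0.5) (1 = rural), BMI ~ Normal(24, 3). Causal SNPs are
#' drawn among non-monomorphic SNPs and their effects scaled so that each
#' contributes `h2_per_causal` of the total phenotype variance, where the
#' total is the covariate-plus-noise variance inflated by
#' `1 / (1 - n_causal * h2_per_causal)`. Effect signs are random.
#'
#' With `family = "gaussian"` the phenotype is the linear predictor plus
#' Gaussian noise and can be negative in noisy configurations; with
#' `family = "lognormal"` the noise is multiplicative,
#' `pa = mu * exp(sigma * Z - sigma^2 / 2)`, with `sigma` chosen so the
#' conditional SD approximates `noise_sd`, giving a positive right-skewed
#' phenotype suitable for questionnaire inversion.
#'
#' @param geno a [genotype_matrix()] from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return list with `pheno` (data frame `sample_id`, `pa`, `sex`, `age`,
#'   `area`, `bmi`) and `truth` (list `causal_snp_ids`, `causal_betas`,
#'   `generator_seed`).
#' @export
simulate_covariates_and_phenotype <- function(geno, config) {
  if (!inherits(config, "sim_config")) stopf("`config` must be a sim_config")
  n <- n_samples(geno)
  if (n == 0L) stopf("empty genotype matrix")
  set.seed(derive_seed(config$seed, 1L))
  sex <- stats::rbinom(n, 1L, 0.5)
  age <- stats::runif(n, 40, 69)
  area <- stats::rbinom(n, 1L, 0.5)
  bmi <- stats::rnorm(n, 24, 3)
  ce <- config$covariate_effects
  cov_lin <- ce[["sex"]] * sex + ce[["age"]] * age +
    ce[["area"]] * area + ce[["bmi"]] * bmi

  gc <- attr(geno, "complete") %||% geno$geno
  poly <- which(apply(gc, 2L, stats::var) > 0)
  if (config$n_causal > length(poly))
    stopf("only %d non-monomorphic SNPs available for %d causal draws",
          length(poly), config$n_causal)
  # causal SNPs are drawn from distinct LD blocks (when enough blocks exist)
  # so that their variance contributions are additive
  causal <- integer(0)
  if (config$n_causal > 0) {
    blocks <- geno$snp_info$block
    if (!is.null(blocks) && length(unique(blocks[poly])) >= config$n_causal) {
      bsel <- sample(unique(blocks[poly]), config$n_causal)
      causal <- sort(vapply(bsel, function(b) {
        cand <- poly[blocks[poly] == b]
        if (length(cand) == 1L) cand else sample(cand, 1L)
      }, numeric(1)))
    } else {
      causal <- sort(sample(poly, config$n_causal))
    }
  }

  h2_tot <- config$n_causal * config$h2_per_causal
  base_var <- stats::var(cov_lin) + config$noise_sd^2
  total_var <- if (h2_tot > 0) base_var / (1 - h2_tot) else base_var
  betas <- numeric(0)
  genetic <- 0
  if (length(causal)) {
    gvar <- apply(gc[, causal, drop = FALSE], 2L, stats::var)
    betas <- sqrt(config$h2_per_causal * total_var / gvar) *
      sample(c(-1, 1), length(causal), replace = TRUE)
    genetic <- drop(gc[, causal, drop = FALSE] %*% betas)
  }
  mu <- config$intercept + cov_lin + genetic
  if (config$family == "gaussian") {
    pa <- mu + stats::rnorm(n, 0, config$noise_sd)
  } else {
    if (any(mu <= 0))
      stopf("lognormal family requires a positive linear predictor for all samples")
    sigma <- sqrt(log1p((config$noise_sd / mean(mu))^2))
    pa <- mu * exp(stats::rnorm(n, -sigma^2 / 2, sigma))
  }
  pheno <- data.frame(sample_id = sample_ids(geno), pa = pa,
                      sex = sex, age = age, area = area, bmi = bmi,
                      stringsAsFactors = FALSE)
  truth <- list(causal_snp_ids = geno$snp_info$snp_id[causal],
                causal_betas = unname(betas),
                generator_seed = config$seed)
  list(pheno = pheno, truth = truth)
}

#' Simulate questionnaire duration records consistent with a phenotype
#'
#' Inverts the MET phenotype: for each sample the total PA value is split
#' into five nonnegative MET·min shares by a random Dirichlet(1,...,1) draw
#' and each share converted to minutes by dividing by the category MET
#' intensity, so that the MET-weighted sum of durations reproduces the
#' phenotype exactly (up to floating point, or up to rounding when
#' `round_minutes = TRUE`).
#'
#' @param pheno phenotype frame with `sample_id` and nonnegative `pa`.
#' @param met a [met_assignment()].
#' @param seed integer seed.
#' @param round_minutes round durations to whole minutes (breaks the exact
#'   round trip by at most `2.5 * sum(met)` MET·min).
#' @return data frame `sample_id` plus one duration column (min/day) per
#'   category.
#' @export
simulate_questionnaire <- function(pheno, met = met_assignment(), seed = 1L,
                                   round_minutes = FALSE) {
  met <- validate_met(met)
  if (any(pheno$pa < 0))
    stopf("negative phenotype value(s) cannot be decomposed into durations (e.g. sample %s)",
          pheno$sample_id[which(pheno$pa < 0)[1L]])
  set.seed(derive_seed(seed, 2L))
  n <- nrow(pheno); k <- length(met)
  w <- matrix(stats::rgamma(n * k, shape = 1), n, k)
  w <- w / rowSums(w)
  dur <- (w * pheno$pa) / rep(met, each = n)
  if (round_minutes) dur <- round(dur)
  colnames(dur) <- names(met)
  cbind(data.frame(sample_id = pheno$sample_id, stringsAsFactors = FALSE),
        as.data.frame(dur))
}

#' Simulate a SNP-to-gene map and pathway database
#'
#' Synthetic annotation plumbing for end-to-end runs: SNPs are assigned to
#' genes in genomic order (a minority get a two-gene annotation, mirroring
#' intergenic SNPs flanked by two genes), and pathways are random gene sets
#' over the mappable universe.
#'
#' @param snp_ids character vector of SNP ids.
#' @param snps_per_gene average number of SNPs mapping to one gene.
#' @param n_pathways number of pathways.
#' @param pathway_size genes per pathway.
#' @param seed integer seed.
#' @return list with `gene_map` (data frame `snp_id`, `genes`, `location`)
#'   and `pathways` (a [pathway_db()]).
#' @export
simulate_annotation <- function(snp_ids, snps_per_gene = 4L,
                                n_pathways = 20L, pathway_size = 15L,
                                seed = 1L) {
  set.seed(derive_seed(seed, 3L))
  p <- length(snp_ids)
  n_genes <- max(2L, ceiling(p / snps_per_gene))
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  idx <- sort(rep(seq_len(n_genes), length.out = p))
  primary <- genes[idx]
  second <- stats::runif(p) < 0.1
  gene_str <- ifelse(second & idx < n_genes,
                     paste(primary, genes[pmin(idx + 1L, n_genes)], sep = ","),
                     primary)
  loc <- sample(c("intronic", "intergenic", "utr-variant-3-prime",
                  "nonsynonymous", "upstream", "downstream"),
                p, replace = TRUE,
                prob = c(0.35, 0.45, 0.05, 0.03, 0.06, 0.06))
  gene_map <- data.frame(snp_id = snp_ids, genes = gene_str, location = loc,
                         stringsAsFactors = FALSE)
  sets <- lapply(seq_len(n_pathways),
                 function(i) sample(genes, min(pathway_size, n_genes)))
  names(sets) <- sprintf("PATH%03d", seq_len(n_pathways))
  list(gene_map = gene_map, pathways = pathway_db(sets, universe = genes))
}
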