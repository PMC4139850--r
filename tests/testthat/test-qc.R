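test_that("HWE exact test matches the enumeration oracle exhaustively", {
  # all genotype-count triples with total <= 30 (the acceptance suite pushes
  # this to 50); agreement must be to numerical precision
  for (n in 1:30) {
    for (nAA in 0:n) {
      for (nAa in 0:(n - nAA)) {
        naa <- n - nAA - nAa
        expect_equal(hwe_exact_test(nAA, nAa, naa),
                     hwe_enum_oracle(nAA, nAa, naa),
                     tolerance = 1e-12,
                     label = sprintf("hwe(%d,%d,%d)", nAA, nAa, naa))
      }
    }
  }
})

test_that("HWE edge cases behave", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)           # monomorphic
  p_bal <- hwe_exact_test(25, 50, 25)
  expect_gte(p_bal, hwe_enum_oracle(25, 50, 25))       # most probable config
  expect_gt(p_bal, 0.5)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)           # het deficit
  expect_error(hwe_exact_test(-1, 0, 5), "nonnegative")
  expect_error(hwe_exact_test(0, 0, 0), "> 0")
})

test_that("pairwise IBS matches hand arithmetic and is symmetric", {
  g <- geno_from_codes(rbind(a = c(0, 1, 2), b = c(1, 1, 1), c = c(0, 1, 2),
                             d = c(2, 1, 0)))
  expect_equal(pairwise_ibs(g, c("a", "b")), (0.5 + 1 + 0.5) / 3)
  expect_equal(pairwise_ibs(g, c("a", "b")), pairwise_ibs(g, c("b", "a")))
  expect_equal(pairwise_ibs(g, c("a", "c")), 1)
  g2 <- geno_from_codes(rbind(a = c(0, 2), b = c(2, 0)))
  expect_equal(pairwise_ibs(g2, c("a", "b")), 0)
  gna <- geno_from_codes(rbind(a = c(NA, 1), b = c(1, NA)))
  expect_warning(v <- pairwise_ibs(gna, c("a", "b")), "no non-missing")
  expect_true(is.na(v))
})

test_that("the IBS matrix agrees with the pairwise definition under missingness", {
  set.seed(5)
  m <- matrix(sample(c(0, 1, 2, NA), 60, replace = TRUE), 6, 10)
  m[1, ] <- c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0)   # guarantee overlap
  g <- geno_from_codes(m, sample_ids = letters[1:6])
  im <- stabselgwas:::ibs_matrix(g)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(im[i, j],
                 suppressWarnings(pairwise_ibs(g, c(letters[i], letters[j]))))
  }
})

test_that("mode imputation fills missing calls with documented tie-break", {
  g <- geno_from_codes(cbind(c(0, 0, 2, NA), c(2, 2, 0, NA), c(0, 0, 2, 2)))
  out <- impute_missing(g)
  expect_equal(unname(out$geno[4, ]), c(0, 2, 2))
  expect_false(anyNA(out$geno))
  # tie between modes -> lower genotype code
  gt <- geno_from_codes(cbind(c(0, 2, NA, NA)))
  expect_equal(unname(impute_missing(gt)$geno[3, ]), 0)
  # complete input is returned unchanged
  gi <- geno_from_codes(cbind(c(0, 1), c(2, 1)))
  expect_identical(impute_missing(gi)$geno, gi$geno)
  gall <- geno_from_codes(cbind(c(NA, NA), c(0, 1)))
  expect_error(impute_missing(gall), "all calls missing")
})

test_that("sample QC applies filters sequentially and reports them", {
  # controlled cohort: binomial genotypes at MAF 0.3 (baseline het ~0.42,
  # IBS between unrelated pairs ~0.67, both far from the custom thresholds)
  set.seed(101)
  n <- 40; p <- 200
  g <- matrix(rbinom(n * p, 2, 0.3), n, p,
              dimnames = list(sprintf("S%04d", 1:n), NULL))
  g[1, 1:10] <- NA          # 5% missing (> 4%)
  g[3, ] <- g[2, ]          # duplicate pair -> IBS = 1
  g[4, ] <- 1               # heterozygosity 1.0
  gm <- genotype_matrix(g)
  sex <- rbinom(n, 1, 0.5)
  meta <- data.frame(sample_id = rownames(g),
                     reported_sex = sex, inferred_sex = sex)
  meta$inferred_sex[5] <- 1 - meta$inferred_sex[5]   # sex mismatch sample 5
  thr <- qc_thresholds(sample_het_max = 0.6)
  res <- sample_qc(gm, meta, thr)
  rep <- as.data.frame(res$report)
  expect_equal(rep$filter, c("sample_missingness", "heterozygosity",
                             "sex_inconsistency", "disease_exclusion",
                             "relatedness"))
  expect_equal(rep$removed_ids[1], "S0001")
  expect_equal(rep$removed_ids[2], "S0004")
  expect_equal(rep$removed_ids[3], "S0005")
  # duplicates: exactly one of the identical pair dropped at relatedness
  expect_equal(rep$n_removed[5], 1L)
  expect_true(rep$removed_ids[5] %in% c("S0002", "S0003"))
  expect_equal(n_samples(res$geno), 40 - 4)

  # a clean cohort loses nobody, and QC is idempotent
  res2 <- sample_qc(res$geno, meta, thr)
  expect_equal(sum(res2$report$n_removed), 0L)
})

test_that("disease-exclusion flags remove samples at their own stage", {
  set.seed(11)
  g <- matrix(rbinom(20 * 100, 2, 0.3), 20, 100,
              dimnames = list(sprintf("S%04d", 1:20), NULL))
  meta <- data.frame(sample_id = rownames(g),
                     exclude_flag = c(TRUE, rep(FALSE, 19)))
  res <- suppressWarnings(sample_qc(genotype_matrix(g), meta,
                                    qc_thresholds(sample_het_max = 0.6)))
  rep <- as.data.frame(res$report)
  expect_equal(rep$n_removed[rep$filter == "disease_exclusion"], 1L)
  expect_equal(rep$removed_ids[rep$filter == "disease_exclusion"], "S0001")
})

test_that("sample QC validates ids and skips sex stage without columns", {
  co <- make_cohort(n = 10, p = 20, seed = 7)
  expect_error(sample_qc(co$geno, data.frame(sample_id = "nope")), "absent")
  expect_warning(sample_qc(co$geno, data.frame(sample_id = sample_ids(co$geno))),
                 "sex-consistency stage skipped")
})

test_that("marker QC removes failing SNPs at the right stages", {
  set.seed(8)
  n <- 200
  g <- matrix(rbinom(n * 4, 2, 0.3), n, 4)
  g[seq_len(0.06 * n), 2] <- NA               # 6% missing > 5%
  g[, 3] <- rbinom(n, 2, 0.004)               # MAF below 0.01
  g[, 4] <- rep(c(0, 2), each = n / 2)        # extreme HWE violation
  gm <- genotype_matrix(g)
  res <- marker_qc(gm, qc_thresholds())
  rep <- as.data.frame(res$report)
  expect_equal(rep$filter, c("marker_missingness", "maf", "hwe"))
  expect_equal(rep$n_removed, c(1L, 1L, 1L))
  expect_equal(n_snps(res$geno), 1L)
  # idempotent on its own output
  res2 <- marker_qc(res$geno, qc_thresholds())
  expect_equal(sum(res2$report$n_removed), 0L)
})
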