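# Independent oracles used to check the package's statistics from scratch.

# Full-model OLS via normal equations: returns beta, se, t, p for the
# genotype column of pa ~ 1 + g + sex + age + area + bmi.
ols_snp_oracle <- function(g, pheno) {
  X <- cbind(1, g, pheno$sex, pheno$age, pheno$area, pheno$bmi)
  XtX <- t(X) %*% X
  bhat <- solve(XtX, t(X) %*% pheno$pa)
  res <- pheno$pa - X %*% bhat
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  vc <- s2 * solve(XtX)
  se <- sqrt(vc[2, 2])
  tv <- bhat[2] / se
  list(beta = bhat[2], se = se, t = tv, p = 2 * pt(-abs(tv), df))
}

# HWE exact p by brute-force enumeration over all heterozygote counts
# compatible with the allele counts; probabilities from the exact
# multinomial/hypergeometric formula, no recursion shared with the package.
hwe_enum_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hs <- seq(0L, min(nA, 2L * n - nA))
  hs <- hs[(nA - hs) %% 2L == 0L]
  logp <- vapply(hs, function(h) {
    aa <- (nA - h) / 2
    bb <- n - h - aa
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp)
  obs <- pr[match(nAa, hs)]
  sum(pr[pr <= obs * (1 + 1e-10)])
}

# Probability of the observed heterozygote count itself under the exact
# conditional HWE distribution (used to de-discretise p-values: for an exact
# conditional test, p - U * P(obs) is exactly Uniform(0,1)).
hwe_obs_prob <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hs <- seq(0L, min(nA, 2L * n - nA))
  hs <- hs[(nA - hs) %% 2L == 0L]
  logp <- vapply(hs, function(h) {
    aa <- (nA - h) / 2
    bb <- n - h - aa
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  }, numeric(1))
  exp(logp[match(nAa, hs)])
}

# Hypergeometric upper tail P(X >= k) by direct summation of the pmf.
hyper_tail_oracle <- function(k, K, n, N) {
  xs <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# Adjusted R^2 oracle from an explicit lm fit.
adj_r2_oracle <- function(y, X) {
  fit <- lm(y ~ X)
  summary(fit)$adj.r.squared
}
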