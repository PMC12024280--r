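test_that("founder genotypes follow the configured allele-frequency law", {
  f <- simulate_founders(63, 50, seed = 1)
  expect_equal(nrow(f$X), 126)          # two parents per family
  expect_equal(length(unique(f$family)), 63)
  expect_error(simulate_founders(0, 10), "positive")

  # point mass at p = 0.5: Hardy-Weinberg heterozygote share ~ 1/2
  f2 <- simulate_founders(1, 4000, maf_range = 0.5, seed = 2)
  expect_true(all(f2$X %in% 0:2))
  expect_lt(abs(mean(f2$X == 1) - 0.5), 0.04)

  # law of large numbers: mean genotype at p = 0.3 is 0.6 +- 0.01
  f3 <- simulate_founders(50, 10000, maf_range = 0.3, seed = 3)
  expect_lt(abs(mean(f3$X) - 0.6), 0.01)
})

test_that("gene dropping is Mendelian and preserves family structure", {
  # both parents homozygous reference: offspring all zero
  X0 <- matrix(0L, 2, 5, dimnames = list(c("p1", "p2"), NULL))
  fnd0 <- genotypes(X0, family = c("F1", "F1"))
  off0 <- drop_offspring(fnd0, 6, seed = 1)
  expect_true(all(off0$X == 0))
  expect_equal(nrow(off0$X), 6)

  # both parents heterozygous: offspring genotypes ~ (1/4, 1/2, 1/4)
  X1 <- matrix(1L, 2, 4000)
  fnd1 <- genotypes(X1, family = c("F1", "F1"))
  off1 <- drop_offspring(fnd1, 1, seed = 2)
  frq <- tabulate(off1$X + 1L, 3) / 4000
  expect_lt(max(abs(frq - c(0.25, 0.5, 0.25))), 0.03)

  # unpaired founders rejected
  X3 <- matrix(1L, 3, 5)
  fnd3 <- genotypes(X3, family = rep("F1", 3))
  expect_error(drop_offspring(fnd3, 2), class = "mtgblup_error_unpaired")

  # offspring allele frequencies are unbiased for founder frequencies
  fnd <- simulate_founders(63, 1000, seed = 4)
  off <- drop_offspring(fnd, 20, seed = 5)
  pf <- allele_frequencies(fnd)
  po <- allele_frequencies(off)
  expect_lt(abs(mean(po - pf)), 0.002)
  expect_gt(cor(po, pf), 0.98)
})

test_that("simulated breeding values have the configured covariance structure", {
  # zero genetic covariance: breeding values exactly zero
  cfg0 <- sim_config(n_families = 10, offspring_per_family = 6, n_snps = 100,
                     traits = c("T1", "T2"), trait_means = c(0, 0),
                     trait_sds = c(1, 1), h2 = c(0, 0),
                     genetic_cor = diag(2), missing_rate = 0,
                     n_retained = NULL, survival_rates = c(A = 1, B = 1))
  fnd <- simulate_founders(10, 100, seed = 1)
  off <- drop_offspring(fnd, 6, seed = 2)
  s0 <- simulate_phenotypes(off, cfg0, seed = 3)
  expect_true(all(s0$truth$tbv_T1 == 0))
  expect_true(all(s0$truth$tbv_T2 == 0))
  # phenotypic covariance falls back to the residual covariance
  expect_lt(abs(cov(s0$pheno$T1, s0$pheno$T2)), 0.3)

  # h2 = 0.16: cov(y, u) / var(y) recovers it at n = 1260
  cfg <- sim_config(traits = c("T1", "T2"), trait_means = c(0, 0),
                    trait_sds = c(1, 1), h2 = c(0.16, 0.20),
                    genetic_cor = matrix(c(1, 0.783, 0.783, 1), 2),
                    n_snps = 800, missing_rate = 0, n_retained = NULL,
                    survival_rates = c(A = 1, B = 1),
                    fixed_effects = list(sex = c(0, 0), group = c(0, 0),
                                         interaction = c(0, 0)))
  fnd <- simulate_founders(63, 800, seed = 6)
  off <- drop_offspring(fnd, 20, seed = 7)
  sp <- simulate_phenotypes(off, cfg, seed = 8)
  h2_real <- cov(sp$pheno$T1, sp$truth$tbv_T1) / var(sp$pheno$T1)
  expect_lt(abs(h2_real - 0.16), 0.03)
  # genetic correlation of the true breeding values
  expect_lt(abs(cor(sp$truth$tbv_T1, sp$truth$tbv_T2) - 0.783), 0.05)

  # a non-PSD covariance is rejected with an explicit condition
  expect_error(
    sim_config(traits = c("T1", "T2"), trait_means = c(0, 0),
               trait_sds = c(1, 1), h2 = c(0.2, 0.2),
               genetic_cor = matrix(c(1, 1.2, 1.2, 1), 2)),
    class = "mtgblup_error_not_psd")
})

test_that("attrition thins at the stated group rates and then uniformly", {
  ph <- tibble::tibble(id = sprintf("i%04d", 1:1260),
                       family = rep(sprintf("F%03d", 1:63), each = 20),
                       group = factor(rep(c("A", "B"), each = 630)))
  # identity when nothing is dropped
  keep_all <- apply_attrition(ph, c(A = 1, B = 1), n_retained = NULL, seed = 1)
  expect_equal(keep_all$id, ph$id)

  # reference rates on a 630/630 split leave about 1010 survivors
  surv <- vapply(1:20, function(s) {
    nrow(apply_attrition(ph, c(A = 0.8329, B = 0.7694), NULL, seed = s))
  }, 0)
  expect_lt(abs(mean(surv) - 1010), 15)

  # binomial spread at rate one half
  ph2 <- tibble::tibble(id = as.character(1:1000), family = "F", group = factor("A"))
  n50 <- nrow(apply_attrition(ph2, c(A = 0.5), NULL, seed = 3))
  expect_lt(abs(n50 - 500), 64)   # 4 binomial SDs

  expect_error(apply_attrition(ph2, c(A = 0.1), n_retained = 900, seed = 1),
               class = "mtgblup_error_attrition")
})

test_that("the end-to-end generator is reproducible and keeps MY in range", {
  cfg <- sim_config(n_families = 15, offspring_per_family = 8, n_snps = 200,
                    n_retained = 90)
  a <- simulate_shrimp(cfg, seed = 5)
  b <- simulate_shrimp(cfg, seed = 5)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$genotypes$X, b$genotypes$X)
  expect_identical(a$truth, b$truth)
  expect_true(all(a$pheno$MY > 0 & a$pheno$MY < 100))
  expect_equal(nrow(a$pheno), 90)
  # survival bookkeeping sums to the stocked totals
  expect_equal(sum(a$survival$stocked), 15 * 8)
  c2 <- simulate_shrimp(cfg, seed = 6)
  expect_false(identical(a$pheno$BW, c2$pheno$BW))
})
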