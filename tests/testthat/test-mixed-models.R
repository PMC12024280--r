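test_that("design matrices use treatment coding, stacked trait-major", {
  ph <- tibble::tibble(
    id = sprintf("i%02d", 1:10),
    sex = factor(rep(c("F", "M"), 5)),
    group = factor(rep(c("A", "B"), each = 5)),
    T1 = rnorm(10), T2 = rnorm(10)
  )
  G <- diag(10) + 0.01
  grm <- structure(list(G = G, freqs = 0.5, denominator = 1, ridge = 0,
                        ids = ph$id), class = "grm")
  d1 <- build_design(ph, grm, "T1")
  expect_equal(ncol(d1$X), 4)            # intercept + sex + group + interaction
  expect_equal(qr(d1$X)$rank, 4)         # brute-force rank check
  d2 <- build_design(ph, grm, c("T1", "T2"))
  expect_equal(dim(d2$X), c(20, 8))
  expect_equal(d2$trait, rep(1:2, each = 10))
  # block structure: trait-1 rows have zero trait-2 columns
  expect_true(all(d2$X[1:10, 5:8] == 0))
  expect_true(all(d2$X[11:20, 1:4] == 0))

  # masked records are flagged, never dropped
  ph$T1[3] <- NA
  dm <- build_design(ph, grm, c("T1", "T2"))
  expect_equal(sum(dm$masked), 1)
  expect_equal(length(dm$y), 20)

  expect_error(build_design(ph, grm, c("T1", "T1")), "distinct")
  expect_error(build_design(ph, grm, "T3"), "not in")
  ph2 <- ph
  ph2$sex[1] <- NA
  expect_error(build_design(ph2, grm, "T1"), "missing levels")
})

test_that("the restricted likelihood matches direct dense algebra", {
  # hand-built 3 x 3 case
  y3 <- c(1.2, -0.4, 2.2)
  G3 <- diag(3)
  ph3 <- tibble::tibble(id = c("a", "b", "c"), y = y3)
  g3 <- structure(list(G = G3, freqs = 0.5, denominator = 1, ridge = 0,
                       ids = ph3$id), class = "grm")
  d3 <- build_design(ph3, g3, "y", fixed = ~ 1)
  vc3 <- list(sigma_a = matrix(0.5), sigma_e = matrix(1.5))
  ll <- reml_loglik(vc3, d3, g3)
  V3 <- 0.5 * G3 + 1.5 * diag(3)
  X3 <- matrix(1, 3, 1)
  Vi3 <- solve(V3)
  P3 <- Vi3 - Vi3 %*% X3 %*% solve(t(X3) %*% Vi3 %*% X3) %*% t(X3) %*% Vi3
  hand <- -0.5 * (determinant(V3)$modulus +
                    determinant(t(X3) %*% Vi3 %*% X3)$modulus +
                    drop(t(y3) %*% P3 %*% y3))
  expect_equal(ll, as.numeric(hand), tolerance = 1e-10)

  # independence factorisation: with zero covariances the bivariate
  # likelihood is the sum of the single-trait likelihoods
  pop <- small_population(seed = 2, n_families = 8, offspring = 6,
                          n_snps = 150)
  dd <- build_design(pop$pheno, pop$grm, c("T1", "T2"))
  d1 <- build_design(pop$pheno, pop$grm, "T1")
  d2 <- build_design(pop$pheno, pop$grm, "T2")
  vc_b <- list(sigma_a = diag(c(0.6, 0.9)), sigma_e = diag(c(2.5, 3.1)))
  ll_b <- reml_loglik(vc_b, dd, pop$grm)
  ll_1 <- reml_loglik(list(sigma_a = matrix(0.6), sigma_e = matrix(2.5)),
                      d1, pop$grm)
  ll_2 <- reml_loglik(list(sigma_a = matrix(0.9), sigma_e = matrix(3.1)),
                      d2, pop$grm)
  expect_equal(ll_b, ll_1 + ll_2, tolerance = 1e-8)
})

test_that("AI-REML agrees with the eigendecomposition oracle (single trait)", {
  pop <- small_population(seed = 3, n_families = 15, offspring = 8,
                          n_snps = 250)
  fit <- fit_gblup(pop$pheno, pop$grm, "T1")
  X <- model.matrix(~ sex + group + sex:group, pop$pheno)
  Gm <- as.matrix(pop$grm)[pop$pheno$id, pop$pheno$id]
  orc <- oracle_reml_1trait(pop$pheno$T1, X, Gm)
  expect_lt(abs(fit$loglik - orc$loglik), 1e-4)
  expect_lt(abs(heritability(fit)$h2 - orc$h2), 1e-3)
  expect_true(fit$converged)
  # likelihood ascent along the accepted trace
  expect_true(all(diff(fit$trace$loglik) >= -1e-10))
})

test_that("REML is scale-equivariant and order-invariant", {
  pop <- small_population(seed = 4, n_families = 10, offspring = 8,
                          n_snps = 200)
  fit <- fit_gblup(pop$pheno, pop$grm, c("T1", "T2"))
  ph_s <- pop$pheno
  ph_s$T1 <- 3 * ph_s$T1
  fit_s <- fit_gblup(ph_s, pop$grm, c("T1", "T2"))
  # variance components scale by c^2, h2 and rg are invariant
  expect_equal(fit_s$vc$sigma_a[1, 1] / fit$vc$sigma_a[1, 1], 9,
               tolerance = 1e-2)
  expect_equal(heritability(fit_s)$h2, heritability(fit)$h2,
               tolerance = 1e-3)
  expect_equal(genetic_correlation(fit_s)$rg, genetic_correlation(fit)$rg,
               tolerance = 1e-3)

  # permuting individuals (phenotypes and G rows together) changes nothing
  perm <- sample(nrow(pop$pheno))
  fit_p <- fit_gblup(pop$pheno[perm, ], pop$grm, c("T1", "T2"))
  expect_equal(fit_p$loglik, fit$loglik, tolerance = 1e-6)
  expect_equal(fit_p$vc$sigma_a, fit$vc$sigma_a, tolerance = 1e-4)
})

test_that("a zero genetic variance is pinned at the boundary and flagged", {
  cfg <- sim_config(n_families = 10, offspring_per_family = 8, n_snps = 150,
                    traits = c("T1", "T2"), trait_means = c(0, 0),
                    trait_sds = c(1, 1), h2 = c(0, 0), genetic_cor = diag(2),
                    missing_rate = 0, n_retained = NULL,
                    survival_rates = c(A = 1, B = 1))
  sim <- simulate_shrimp(cfg, seed = 5)
  grm <- build_grm(sim$genotypes, ridge = 1e-3)
  fit <- fit_gblup(sim$pheno, grm, "T1")
  expect_lt(fit$vc$sigma_a[1, 1], 0.05)
  se_tab <- standard_errors(fit)
  expect_true(se_tab$boundary[se_tab$component == "sigma_a[T1,T1]"])
  expect_true(is.na(se_tab$se[se_tab$component == "sigma_a[T1,T1]"]))
})

test_that("fixing covariances reduces the bivariate model to two STGMs", {
  pop <- small_population(seed = 6, n_families = 10, offspring = 8,
                          n_snps = 200)
  fit_b <- fit_gblup(pop$pheno, pop$grm, c("T1", "T2"), fix_cov = TRUE)
  fit_1 <- fit_gblup(pop$pheno, pop$grm, "T1")
  fit_2 <- fit_gblup(pop$pheno, pop$grm, "T2")
  expect_equal(fit_b$vc$sigma_a[1, 2], 0)
  expect_equal(fit_b$vc$sigma_a[1, 1], fit_1$vc$sigma_a[1, 1],
               tolerance = 1e-3)
  expect_equal(fit_b$vc$sigma_e[2, 2], fit_2$vc$sigma_e[1, 1],
               tolerance = 1e-3)
  expect_equal(fit_b$loglik, fit_1$loglik + fit_2$loglik, tolerance = 1e-5)
})

test_that("MME solutions equal GLS + BLUP and respect no-information cases", {
  # identity relationships: GEBV is the ridge-shrunk centred record
  n <- 12
  ph <- tibble::tibble(id = sprintf("i%02d", 1:n), y = rnorm(n, 5))
  grm_i <- structure(list(G = diag(n), freqs = 0.5, denominator = 1,
                          ridge = 0, ids = ph$id), class = "grm")
  des <- build_design(ph, grm_i, "y", fixed = ~ 1)
  vc <- list(sigma_a = matrix(2), sigma_e = matrix(3))
  sol <- solve_mme(des, grm_i, vc)
  lam <- 3 / 2
  # with G = I and an intercept, u = (y - mu) / (1 + lambda) at the GLS mu
  mu <- sol$fixed$estimate[1]
  expect_equal(sol$gebv$gebv, (ph$y - mu) / (1 + lam), tolerance = 1e-8)

  # a masked individual unrelated to everyone gets GEBV zero
  ph$y[1] <- NA
  des_m <- build_design(ph, grm_i, "y", fixed = ~ 1)
  sol_m <- solve_mme(des_m, grm_i, vc)
  expect_equal(sol_m$gebv$gebv[1], 0)

  # dense-inversion GLS/BLUP oracle on a two-trait fixture with masking
  pop <- small_population(seed = 7, n_families = 8, offspring = 7,
                          n_snps = 200, ridge = 1e-3)
  ph2 <- pop$pheno
  ph2$T1[1:10] <- NA
  vc2 <- list(sigma_a = matrix(c(0.7, 0.4, 0.4, 1.1), 2),
              sigma_e = matrix(c(2.8, 1.1, 1.1, 3.5), 2))
  des2 <- build_design(ph2, pop$grm, c("T1", "T2"))
  sol2 <- solve_mme(des2, pop$grm, vc2)
  orc <- oracle_gls_blup(ph2, pop$grm, c("T1", "T2"), vc2)
  expect_lt(max(abs(sol2$fixed$estimate - orc$b)), 1e-8)
  expect_lt(max(abs(sol2$gebv$gebv - orc$u)), 1e-8)
})

test_that("AI standard errors behave like an information quantity", {
  pop_a <- small_population(seed = 8, n_families = 8, offspring = 6,
                            n_snps = 200)
  pop_b <- small_population(seed = 8, n_families = 32, offspring = 6,
                            n_snps = 200)
  fit_a <- fit_gblup(pop_a$pheno, pop_a$grm, "T1")
  fit_b <- fit_gblup(pop_b$pheno, pop_b$grm, "T1")
  se_a <- standard_errors(fit_a)$se
  se_b <- standard_errors(fit_b)$se
  # quadrupling the families roughly halves the SE
  expect_lt(se_b[2], se_a[2])
  expect_gt(se_a[2] / se_b[2], 1.3)

  # masking a third of the records removes information: SEs grow
  ph_m <- pop_a$pheno
  ph_m$T1[seq(1, nrow(ph_m), by = 3)] <- NA
  fit_m <- fit_gblup(ph_m, pop_a$grm, "T1")
  expect_gt(standard_errors(fit_m)$se[2], se_a[2])

  # the reported covariance is the inverse of an independently recomputed
  # average-information matrix at the estimates
  des <- build_design(pop_a$pheno, pop_a$grm, "T1")
  obs <- !is.na(des$y)
  Gm <- as.matrix(pop_a$grm)[pop_a$pheno$id, pop_a$pheno$id]
  V <- fit_a$vc$sigma_a[1, 1] * Gm + fit_a$vc$sigma_e[1, 1] * diag(nrow(Gm))
  X <- des$X
  Vi <- solve(V)
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi
  y <- des$y
  Py <- P %*% y
  Fa <- Gm %*% Py
  Fe <- Py
  AI <- 0.5 * matrix(c(t(Fa) %*% P %*% Fa, t(Fa) %*% P %*% Fe,
                       t(Fe) %*% P %*% Fa, t(Fe) %*% P %*% Fe), 2, 2)
  expect_equal(unname(fit_a$ai_cov), solve(AI), tolerance = 1e-4)
})
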