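test_that("fold partitions are balanced, exhaustive and reproducible", {
  ids10 <- sprintf("i%02d", 1:10)
  f <- make_folds(ids10, 5, seed = 1)
  expect_equal(sort(as.integer(table(f$fold))), rep(2L, 5))
  expect_setequal(f$id, ids10)

  ids899 <- sprintf("i%04d", 1:899)
  f899 <- make_folds(ids899, 5, seed = 2)
  expect_equal(sort(as.integer(table(f899$fold))), c(179L, rep(180L, 4)))

  expect_identical(make_folds(ids899, 5, seed = 3),
                   make_folds(ids899, 5, seed = 3))
  expect_false(identical(make_folds(ids899, 5, seed = 3)$fold,
                         make_folds(ids899, 5, seed = 4)$fold))
  expect_error(make_folds(ids10, 1), "at least 2")
  expect_error(make_folds(ids10, 11), "exceed")

  # sizes differ by at most one across random shapes
  set.seed(5)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    k <- sample(2:10, 1)
    sz <- table(make_folds(as.character(1:n), k)$fold)
    expect_lte(max(sz) - min(sz), 1)
  }
})

test_that("CV1 keeps auxiliary phenotypes, CV2 removes them", {
  ph <- tibble::tibble(id = sprintf("i%02d", 1:20),
                       T1 = rnorm(20), T2 = rnorm(20))
  val <- ph$id[1:5]
  m1 <- mask_validation(ph, val, "cv1", "T1", "T2")
  expect_equal(sum(is.na(m1$T1)), 5)
  expect_equal(sum(is.na(m1$T2)), 0)
  m2 <- mask_validation(ph, val, "cv2", "T1", "T2")
  expect_equal(sum(is.na(m2$T1)), 5)
  expect_equal(sum(is.na(m2$T2)), 5)
  # single-trait CV2: validation individuals keep no phenotype rows
  m3 <- mask_validation(ph, val, "cv2", "T1")
  expect_equal(sum(is.na(m3$T1)), 5)
  # training rows untouched
  expect_equal(m2$T1[6:20], ph$T1[6:20])
  # masked-count bookkeeping: fold size x traits masked
  expect_equal(sum(is.na(m1)) , 5)
  expect_equal(sum(is.na(m2)) , 10)

  expect_error(mask_validation(ph, val, "cv1", "T1"), "auxiliary")
  expect_error(mask_validation(ph, val, "cv2", "T9"), "not a phenotype")
})

test_that("accuracy and bias match their textbook definitions", {
  set.seed(6)
  x <- rnorm(10)
  expect_equal(cv_accuracy(x, x), 1)
  expect_equal(cv_accuracy(x, -x), -1)
  g <- rnorm(10)
  # hand-summation Pearson correlation
  n <- 10
  num <- sum(x * g) - n * mean(x) * mean(g)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(g^2) - n * mean(g)^2))
  expect_equal(cv_accuracy(x, g), num / den)

  expect_equal(cv_bias(g, g), 1)
  expect_equal(cv_bias(2 * g + 3, g), 2)
  # normal-equations slope
  expect_equal(cv_bias(x, g),
               (sum(x * g) - n * mean(x) * mean(g)) /
                 (sum(g^2) - n * mean(g)^2))
  # shifting the GEBVs changes neither metric (intercept absorbs it)
  expect_equal(cv_accuracy(x, g + 5), cv_accuracy(x, g))
  expect_equal(cv_bias(x, g + 5), cv_bias(x, g))

  expect_warning(a0 <- cv_accuracy(rep(1, 5), rnorm(5)), "zero variance")
  expect_true(is.na(a0))
  expect_warning(b0 <- cv_bias(rnorm(5), rep(2, 5)), "zero variance")
  expect_true(is.na(b0))
  expect_error(cv_accuracy(1:2, 1:2), "at least 3")
})

test_that("relative improvement is the percentage gain over the baseline", {
  expect_equal(relative_improvement(0.4, 0.4), 0)
  expect_equal(relative_improvement(0.3, 0.2), 50)
  expect_error(relative_improvement(0.3, 0), "positive")
})

test_that("run_cv produces per-fold metrics and is seed-reproducible", {
  pop <- small_population(seed = 9, n_families = 14, offspring = 8,
                          n_snps = 250, rg = 0.6)
  cv <- run_cv(pop$pheno, pop$grm, "T1", auxiliary = "T2", strategy = "cv1",
               k = 3, repeats = 2, seed = 11, tol = 1e-5, max_iter = 40)
  expect_s3_class(cv, "gblup_cv")
  expect_equal(nrow(cv$folds), 6)
  expect_true(all(abs(cv$folds$accuracy) <= 1))
  expect_true(is.finite(cv$accuracy))
  cv_again <- run_cv(pop$pheno, pop$grm, "T1", auxiliary = "T2",
                     strategy = "cv1", k = 3, repeats = 2, seed = 11,
                     tol = 1e-5, max_iter = 40)
  expect_identical(cv$folds, cv_again$folds)

  # fixed-component mode skips re-estimation and still scores folds
  vc <- list(sigma_a = matrix(c(0.6, 0.3, 0.3, 0.8), 2),
             sigma_e = matrix(c(3.4, 1.5, 1.5, 3.2), 2))
  cv_fix <- run_cv(pop$pheno, pop$grm, "T1", auxiliary = "T2",
                   strategy = "cv2", k = 3, repeats = 1, seed = 11, vc = vc)
  expect_equal(nrow(cv_fix$folds), 3)
  expect_false(cv_fix$reestimated)

  g1 <- glance(cv)
  expect_equal(g1$strategy, "CV1")
  expect_equal(g1$accuracy, mean(cv$folds$accuracy[cv$folds$converged]))
})

test_that("single-trait accuracy respects the heritability bound and CV1
           inflates bias under a near-unit genetic correlation", {
  # quantitative-genetics bound: accuracy of phenotype-GEBV correlation is
  # limited by sqrt(h2), checked loosely
  pop <- small_population(seed = 12, n_families = 18, offspring = 8,
                          n_snps = 250, rg = 0.5)
  cv_st <- run_cv(pop$pheno, pop$grm, "T1", k = 3, repeats = 1, seed = 4,
                  tol = 1e-5, max_iter = 50)
  expect_lt(cv_st$accuracy, sqrt(0.16) + 0.1)

  # with the auxiliary trait retained (CV1) and rg ~ 1, the regression of
  # phenotype on GEBV steepens relative to CV2 (compressed GEBV spread)
  slopes <- vapply(1:4, function(s) {
    pop2 <- small_population(seed = 20 + s, n_families = 25, offspring = 10,
                             n_snps = 300, rg = 0.95)
    c1 <- run_cv(pop2$pheno, pop2$grm, "T1", auxiliary = "T2",
                 strategy = "cv1", k = 3, repeats = 1, seed = s,
                 tol = 1e-5, max_iter = 50)
    c2 <- run_cv(pop2$pheno, pop2$grm, "T1", auxiliary = "T2",
                 strategy = "cv2", k = 3, repeats = 1, seed = s,
                 tol = 1e-5, max_iter = 50)
    c(c1$bias, c2$bias)
  }, numeric(2))
  expect_gt(mean(slopes[1, ]), mean(slopes[2, ]))
})
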