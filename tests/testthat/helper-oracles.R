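# shared fixtures and independent oracles for the test suite

# small simulated population: genotypes + phenotypes + GRM, sized for speed
small_population <- function(seed = 1, n_families = 12, offspring = 8,
                             n_snps = 300, traits = c("T1", "T2"),
                             h2 = c(0.16, 0.20), rg = 0.5,
                             missing_rate = 0, ridge = 1e-3,
                             fixed_effects = NULL) {
  cfg <- sim_config(
    n_families = n_families, offspring_per_family = offspring,
    n_snps = n_snps, traits = traits,
    trait_means = rep(10, length(traits)), trait_sds = rep(2, length(traits)),
    h2 = h2,
    genetic_cor = matrix(c(1, rg, rg, 1), 2)[seq_along(traits), seq_along(traits),
                                             drop = FALSE],
    missing_rate = missing_rate, n_retained = NULL,
    survival_rates = c(A = 1, B = 1),
    fixed_effects = fixed_effects
  )
  sim <- simulate_shrimp(cfg, seed = seed)
  geno <- if (missing_rate > 0) impute_missing(sim$genotypes) else sim$genotypes
  list(sim = sim, pheno = sim$pheno, truth = sim$truth,
       grm = build_grm(geno, ridge = ridge))
}

# independent single-trait REML solver: eigendecomposition of G reduces the
# problem to a 1-D profile likelihood over the variance ratio
oracle_reml_1trait <- function(y, X, G) {
  ee <- eigen(G, symmetric = TRUE)
  ys <- crossprod(ee$vectors, y)
  Xs <- crossprod(ee$vectors, X)
  d <- ee$values
  N <- length(y)
  p <- qr(X)$rank
  prof <- function(lambda) {
    w <- lambda * d + 1
    XtWX <- crossprod(Xs / w, Xs)
    b <- solve(XtWX, crossprod(Xs / w, ys))
    r <- ys - Xs %*% b
    S <- sum(r^2 / w)
    se <- S / (N - p)
    -0.5 * (N * log(se) + sum(log(w)) +
              (determinant(XtWX, logarithm = TRUE)$modulus - p * log(se)) +
              S / se)
  }
  opt <- optimize(prof, c(1e-8, 200), maximum = TRUE, tol = 1e-10)
  opt <- optimize(prof, c(opt$maximum / 2, opt$maximum * 2),
                  maximum = TRUE, tol = 1e-12)
  lam <- opt$maximum
  w <- lam * d + 1
  XtWX <- crossprod(Xs / w, Xs)
  b <- solve(XtWX, crossprod(Xs / w, ys))
  se <- sum((ys - Xs %*% b)^2 / w) / (N - p)
  list(loglik = opt$objective, sigma_a = lam * se, sigma_e = se,
       h2 = lam / (1 + lam))
}

# independent bivariate REML maximiser: repeated Nelder-Mead on the packed
# components, rescaled by the phenotypic variances
oracle_reml_2trait <- function(pheno, grm, traits, fixed = ~ sex + group + sex:group,
                               restarts = 4) {
  design <- build_design(pheno, grm, traits, fixed)
  obj <- function(th) {
    if (th[1] <= 0 || th[3] <= 0 || th[2]^2 >= th[1] * th[3]) return(1e10)
    if (th[4] <= 0 || th[6] <= 0 || th[5]^2 >= th[4] * th[6]) return(1e10)
    vc <- list(sigma_a = matrix(c(th[1], th[2], th[2], th[3]), 2),
               sigma_e = matrix(c(th[4], th[5], th[5], th[6]), 2))
    tryCatch(-reml_loglik(vc, design, grm), error = function(e) 1e10)
  }
  v1 <- var(pheno[[traits[1]]], na.rm = TRUE)
  v2 <- var(pheno[[traits[2]]], na.rm = TRUE)
  start <- c(v1 / 2, 0.1 * sqrt(v1 * v2), v2 / 2,
             v1 / 2, 0.1 * sqrt(v1 * v2), v2 / 2)
  o <- optim(start, obj, method = "Nelder-Mead",
             control = list(maxit = 20000, reltol = 1e-15,
                            parscale = abs(start)))
  for (i in seq_len(restarts)) {
    o <- optim(o$par, obj, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-15,
                              parscale = abs(start)))
  }
  list(loglik = -o$value, par = o$par)
}

# direct generalised-least-squares + BLUP solution through dense inversion
# of the observed-record covariance (textbook formulas)
oracle_gls_blup <- function(pheno, grm, traits, vc,
                            fixed = ~ sex + group + sex:group) {
  design <- build_design(pheno, grm, traits, fixed)
  obs <- !is.na(design$y)
  Gsub <- as.matrix(grm)[design$ids, design$ids]
  to <- design$trait[obs]
  io <- design$ind[obs]
  V <- vc$sigma_a[to, to] * Gsub[io, io] + vc$sigma_e[to, to] * outer(io, io, "==")
  Xo <- design$X[obs, , drop = FALSE]
  keep <- sort(qr(Xo)$pivot[seq_len(qr(Xo)$rank)])
  Xo <- Xo[, keep, drop = FALSE]
  yo <- design$y[obs]
  Vi <- solve(V)
  b <- solve(t(Xo) %*% Vi %*% Xo, t(Xo) %*% Vi %*% yo)
  resid <- yo - Xo %*% b
  ng <- length(grm$ids)
  t <- design$t
  gidx <- match(design$ids, grm$ids)
  Gfull <- as.matrix(grm)
  Cuy <- matrix(0, t * ng, sum(obs))
  for (a in seq_len(t)) {
    Cuy[(a - 1) * ng + seq_len(ng), ] <-
      Gfull[, gidx[io], drop = FALSE] * rep(vc$sigma_a[a, to], each = ng)
  }
  list(b = drop(b), u = drop(Cuy %*% Vi %*% resid))
}
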