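#' Build design matrices for a single- or two-trait GBLUP animal model
#'
#' Stacks phenotype records trait-major (all records of the first trait,
#' then all records of the second), builds a treatment-coded fixed-effect
#' incidence matrix per trait (block diagonal across traits) and maps every
#' record to its individual in the genomic relationship matrix. Records with
#' a missing (`NA`) phenotype are flagged as masked, not dropped: they carry
#' no data but their individuals still receive GEBVs through `G`.
#'
#' @param pheno phenotype tibble with an `id` column, the trait columns and
#'   every factor used in `fixed`.
#' @param grm a [build_grm()] result covering all `pheno$id`.
#' @param traits character vector of one or two distinct trait columns.
#' @param fixed one-sided formula for the fixed effects, applied to each
#'   trait; default `~ sex + group + sex:group`.
#' @return An object of class `gblup_design`.
#' @export
build_design <- function(pheno, grm, traits,
                         fixed = ~ sex + group + sex:group) {
  stopifnot(is.data.frame(pheno), inherits(grm, "grm"))
  if (!"id" %in% names(pheno)) abort("`pheno` needs an `id` column.")
  if (length(traits) < 1 || length(traits) > 2) {
    abort("one or two traits are supported.")
  }
  if (anyDuplicated(traits)) abort("`traits` must be distinct.")
  missing_tr <- setdiff(traits, names(pheno))
  if (length(missing_tr)) {
    abort(sprintf("trait column(s) not in `pheno`: %s",
                  paste(missing_tr, collapse = ", ")))
  }
  ids <- as.character(pheno$id)
  if (anyDuplicated(ids)) abort("duplicate individual ids in `pheno`.")
  not_in_grm <- setdiff(ids, grm$ids)
  if (length(not_in_grm)) {
    abort(sprintf("individual(s) missing from the GRM: %s",
                  paste(head(not_in_grm, 5), collapse = ", ")))
  }
  vars <- all.vars(fixed)
  for (v in vars) {
    if (!v %in% names(pheno)) abort(sprintf("fixed-effect variable `%s` not in `pheno`.", v))
    if (anyNA(pheno[[v]])) {
      abort(sprintf("fixed-effect variable `%s` has missing levels.", v))
    }
  }
  X0 <- model.matrix(fixed, data = pheno)
  n <- nrow(pheno)
  t <- length(traits)
  p0 <- ncol(X0)
  y <- unlist(lapply(traits, function(tr) as.numeric(pheno[[tr]])),
              use.names = FALSE)
  X <- matrix(0, n * t, p0 * t)
  for (j in seq_len(t)) {
    X[(j - 1) * n + seq_len(n), (j - 1) * p0 + seq_len(p0)] <- X0
  }
  colnames(X) <- unlist(lapply(traits, function(tr) paste0(tr, ":", colnames(X0))))
  structure(list(
    y = y,
    X = X,
    trait = rep(seq_len(t), each = n),
    ind = rep(seq_len(n), t),
    ids = ids,
    traits = traits,
    fixed = fixed,
    n = n,
    t = t,
    masked = is.na(y)
  ), class = "gblup_design")
}

#' @export
print.gblup_design <- function(x, ...) {
  cat(sprintf("<gblup_design> %d individuals, traits: %s | %d/%d records observed\n",
              x$n, paste(x$traits, collapse = ", "),
              sum(!x$masked), length(x$y)))
  invisible(x)
}

# precompute the observed-record structures the REML engine works on:
# Gobs (relationships among observed records' individuals), Io (same
# individual indicator), trait index, and the aliasing-reduced X
make_obs <- function(design, grm) {
  obs <- which(!design$masked)
  if (!length(obs)) abort("no observed records.")
  for (j in seq_len(design$t)) {
    if (!any(design$trait[obs] == j)) {
      abort(sprintf("trait `%s` has no observed records.", design$traits[j]))
    }
  }
  yo <- design$y[obs]
  Xo <- design$X[obs, , drop = FALSE]
  qrX <- qr(Xo)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  dropped <- colnames(Xo)[setdiff(seq_len(ncol(Xo)), keep)]
  keep <- sort(keep)
  Xo <- Xo[, keep, drop = FALSE]
  io <- design$ind[obs]
  to <- design$trait[obs]
  gidx <- match(design$ids, grm$ids)
  Gsub <- grm$G[gidx, gidx, drop = FALSE]
  list(
    obs = obs, yo = yo, Xo = Xo, to = to, io = io,
    Gobs = Gsub[io, io, drop = FALSE],
    Io = 1 * outer(io, io, "=="),
    Gsub = Gsub,
    keep_cols = keep, dropped = dropped,
    N = length(obs), p = ncol(Xo)
  )
}

# core likelihood machinery on the dense observed-record covariance
# V = sigma_a[t_r, t_s] * G[i_r, i_s] + sigma_e[t_r, t_s] * 1{i_r = i_s}
reml_parts <- function(sigma_a, sigma_e, ob, need_P = TRUE) {
  V <- sigma_a[ob$to, ob$to] * ob$Gobs + sigma_e[ob$to, ob$to] * ob$Io
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  ldetV <- 2 * sum(log(diag(ch)))
  Vinv <- chol2inv(ch)
  XtVi <- crossprod(ob$Xo, Vinv)
  XtViX <- XtVi %*% ob$Xo
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(NULL)
  ldetX <- 2 * sum(log(diag(chX)))
  bhat <- backsolve(chX, forwardsolve(t(chX), XtVi %*% ob$yo))
  Py <- Vinv %*% (ob$yo - ob$Xo %*% bhat)
  loglik <- -0.5 * (ldetV + ldetX + sum(ob$yo * Py))
  P <- NULL
  if (need_P) P <- Vinv - crossprod(XtVi, backsolve(chX, forwardsolve(t(chX), XtVi)))
  list(loglik = loglik, Py = drop(Py), P = P, bhat = drop(bhat), Vinv = Vinv)
}

# derivative of V with respect to one packed variance-component parameter
make_dV <- function(block, i, j, t, ob) {
  S <- matrix(0, t, t)
  S[i, j] <- S[j, i] <- 1
  if (block == "a") S[ob$to, ob$to] * ob$Gobs else S[ob$to, ob$to] * ob$Io
}

par_table <- function(t) {
  idx <- vech_index(t)
  tibble(
    block = rep(c("a", "e"), each = nrow(idx)),
    i = rep(idx[, "row"], 2),
    j = rep(idx[, "col"], 2)
  )
}

#' Restricted log-likelihood of a GBLUP model
#'
#' Evaluates `-0.5 * (log|V| + log|X' V^-1 X| + y' P y)` (the REML
#' criterion, constants dropped) at the supplied variance components, using
#' only non-masked records.
#'
#' @param vc list with matrices `sigma_a` and `sigma_e` (t x t, trait order
#'   matching the design).
#' @param design a [build_design()] result.
#' @param grm the [build_grm()] result used in the design.
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(vc, design, grm) {
  stopifnot(inherits(design, "gblup_design"))
  ob <- make_obs(design, grm)
  parts <- reml_parts(as.matrix(vc$sigma_a), as.matrix(vc$sigma_e), ob,
                      need_P = FALSE)
  if (is.null(parts)) {
    V <- vc$sigma_a[ob$to, ob$to] * ob$Gobs + vc$sigma_e[ob$to, ob$to] * ob$Io
    abort(sprintf(
      "singular phenotypic covariance (reciprocal condition number %.2e).",
      rcond(V)), class = "mtgblup_error_singular_V")
  }
  parts$loglik
}

#' Fit a GBLUP animal model by average-information REML
#'
#' Maximises the restricted likelihood over the genetic and residual
#' covariance matrices with average-information (quasi-Newton) updates,
#' falling back to step-halving along the AI direction, plus projection of
#' each covariance matrix onto the positive-semi-definite cone, whenever a
#' step would leave the parameter region or decrease the likelihood. At
#' convergence the sampling covariance of the estimates is the inverse AI
#' matrix, and fixed effects and GEBVs are obtained from the mixed-model
#' equations at the estimated components. Individuals with masked (`NA`)
#' phenotypes contribute no data but receive GEBVs through the genomic
#' relationships (and, in two-trait fits, through any observed record on the
#' other trait).
#'
#' @inheritParams build_design
#' @param init optional list with starting `sigma_a` and `sigma_e`; default
#'   assigns half the phenotypic variance of each trait to each component,
#'   with zero covariances.
#' @param max_iter maximum AI iterations (default 200).
#' @param tol convergence threshold on the restricted log-likelihood change
#'   (default `1e-8`); the maximum relative parameter change must also fall
#'   below `par_tol`.
#' @param par_tol relative parameter-change threshold (default `1e-6`).
#' @param fix_cov logical; hold all between-trait covariances fixed at their
#'   starting value (zero by default) instead of estimating them.
#' @param verbose print per-iteration progress.
#' @return An object of class `gblup_fit`; see [tidy.gblup_fit()],
#'   [glance.gblup_fit()], [heritability()], [genetic_correlation()].
#' @export
fit_gblup <- function(pheno, grm, traits,
                      fixed = ~ sex + group + sex:group,
                      init = NULL, max_iter = 200, tol = 1e-8,
                      par_tol = 1e-6, fix_cov = FALSE, verbose = FALSE) {
  design <- build_design(pheno, grm, traits, fixed)
  ob <- make_obs(design, grm)
  t <- design$t
  pt <- par_table(t)
  K <- nrow(pt)
  par_names <- vc_par_names(design$traits)

  vscale <- vapply(seq_len(t), function(j) var(ob$yo[ob$to == j]), 0)
  if (is.null(init)) {
    Sa <- diag(vscale / 2, t)
    Se <- diag(vscale / 2, t)
  } else {
    Sa <- as.matrix(init$sigma_a)
    Se <- as.matrix(init$sigma_e)
  }
  free <- rep(TRUE, K)
  if (fix_cov) free <- !(pt$i != pt$j)

  pr <- sym_floor(Sa, 1e-8 * mean(vscale))
  Sa <- pr$mat
  pr <- sym_floor(Se, 1e-8 * mean(vscale))
  Se <- pr$mat
  theta <- vc_pack(Sa, Se)

  # natural scale of each packed parameter, used by the relative-change
  # convergence test
  par_scale <- vapply(seq_len(K), function(k) {
    sqrt(vscale[pt$i[k]] * vscale[pt$j[k]])
  }, 0)

  # The AI update runs on an unconstrained transform of the components:
  # log variances and atanh (Fisher-z) correlations, per matrix. Positive
  # definiteness holds for every finite parameter value, so the PSD
  # boundary (a zero variance or |correlation| -> 1) is approached smoothly
  # instead of being crossed; the average-information matrix is mapped
  # through the Jacobian d theta / d phi, and the fallback when a step
  # fails to improve the likelihood is halving plus a preconditioned
  # gradient direction. Fisher-z keeps the curvature in the correlation
  # direction bounded even next to the boundary.
  block_to_phi <- function(M) {
    if (t == 1) return(log(max(M[1, 1], 1e-300)))
    v1 <- max(M[1, 1], 1e-300); v2 <- max(M[2, 2], 1e-300)
    rho <- M[1, 2] / sqrt(v1 * v2)
    rho <- min(max(rho, -0.999999), 0.999999)
    c(log(v1), atanh(rho), log(v2))
  }
  phi_to_block <- function(ph) {
    if (t == 1) return(matrix(exp(ph[1])))
    v1 <- exp(ph[1]); v2 <- exp(ph[3]); rho <- tanh(ph[2])
    matrix(c(v1, rho * sqrt(v1 * v2), rho * sqrt(v1 * v2), v2), 2, 2)
  }
  # d (v1, c, v2) / d (w1, z, w2) for one 2x2 block
  block_jac <- function(ph) {
    if (t == 1) return(matrix(exp(ph[1])))
    v1 <- exp(ph[1]); v2 <- exp(ph[3]); rho <- tanh(ph[2])
    cc <- rho * sqrt(v1 * v2)
    matrix(c(v1, cc / 2, 0,
             0, (1 - rho^2) * sqrt(v1 * v2), 0,
             0, cc / 2, v2), 3, 3)
  }
  kh <- K / 2
  phi <- c(block_to_phi(Sa), block_to_phi(Se))
  phi_free <- if (fix_cov && t == 2) rep(c(TRUE, FALSE, TRUE), 2) else rep(TRUE, K)

  parts <- reml_parts(Sa, Se, ob)
  if (is.null(parts)) abort("starting values give a singular covariance.")
  trace <- list(tibble(iteration = 0L, loglik = parts$loglik, step = NA_real_,
                       !!!setNames(as.list(theta), par_names)))
  converged <- FALSE
  iter <- 0L

  dVs <- lapply(seq_len(K), function(k) make_dV(pt$block[k], pt$i[k], pt$j[k], t, ob))

  while (iter < max_iter) {
    iter <- iter + 1L
    Py <- parts$Py
    P <- parts$P
    Fm <- vapply(seq_len(K), function(k) drop(dVs[[k]] %*% Py), numeric(ob$N))
    score <- vapply(seq_len(K), function(k) {
      -0.5 * (sum(P * dVs[[k]]) - sum(Py * Fm[, k]))
    }, 0)
    PF <- P %*% Fm
    AI <- 0.5 * crossprod(Fm, PF)
    AI <- (AI + t(AI)) / 2

    J <- matrix(0, K, K)
    J[seq_len(kh), seq_len(kh)] <- block_jac(phi[seq_len(kh)])
    J[kh + seq_len(kh), kh + seq_len(kh)] <- block_jac(phi[kh + seq_len(kh)])
    score_phi <- drop(crossprod(J, score))
    AI_phi <- crossprod(J, AI %*% J)
    AI_phi <- (AI_phi + t(AI_phi)) / 2

    fr <- which(phi_free)
    jit <- 1e-10 * max(diag(AI_phi)[fr], 1e-300)
    delta <- rep(0, K)
    delta[fr] <- tryCatch(
      solve(AI_phi[fr, fr] + diag(jit, length(fr)), score_phi[fr]),
      error = function(e) score_phi[fr] / pmax(diag(AI_phi)[fr], jit))
    grad_dir <- rep(0, K)
    grad_dir[fr] <- score_phi[fr] / pmax(abs(diag(AI_phi)[fr]), jit)

    accepted <- FALSE
    for (dir in list(delta, grad_dir)) {
      # trust region on the transformed scale: at most one log/Fisher-z
      # unit per update
      step <- min(1, 1 / max(abs(dir)))
      for (h in seq_len(40)) {
        cand_phi <- phi + step * dir
        Sa_c <- phi_to_block(cand_phi[seq_len(kh)])
        Se_c <- phi_to_block(cand_phi[kh + seq_len(kh)])
        new_parts <- reml_parts(Sa_c, Se_c, ob)
        if (!is.null(new_parts) && new_parts$loglik > parts$loglik + 1e-13) {
          dll <- new_parts$loglik - parts$loglik
          cand <- vc_pack(Sa_c, Se_c)
          dpar <- max(abs(cand - theta) / (abs(theta) + 1e-3 * par_scale))
          phi <- cand_phi
          theta <- cand
          Sa <- Sa_c; Se <- Se_c
          parts <- new_parts
          accepted <- TRUE
          trace[[length(trace) + 1L]] <-
            tibble(iteration = iter, loglik = parts$loglik, step = step,
                   !!!setNames(as.list(theta), par_names))
          if (verbose) {
            inform(sprintf("iter %d: logL = %.6f (step %.3g)", iter,
                           parts$loglik, step))
          }
          if (dll < tol && dpar < par_tol) converged <- TRUE
          break
        }
        step <- step / 2
      }
      if (accepted) break
    }
    if (!accepted) {
      # no ascent step in either direction: at the optimum (possibly next
      # to the PSD boundary) or numerically stalled
      converged <- TRUE
      break
    }
    if (converged) break
  }
  dimnames(Sa) <- dimnames(Se) <- list(design$traits, design$traits)

  # sampling covariance of the estimates from the final AI matrix
  Py <- parts$Py
  Fm <- vapply(which(free), function(k) drop(dVs[[k]] %*% Py), numeric(ob$N))
  AI <- 0.5 * crossprod(Fm, parts$P %*% Fm)
  AI <- (AI + t(AI)) / 2
  ai_cov <- matrix(NA_real_, K, K, dimnames = list(par_names, par_names))
  inv <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(inv)) ai_cov[free, free] <- inv

  # boundary diagnosis by proximity: a variance collapsed to ~0 relative to
  # the phenotypic scale, or a covariance pinned at |correlation| ~ 1
  boundary <- rep(FALSE, K)
  for (k in seq_len(K)) {
    M <- if (pt$block[k] == "a") Sa else Se
    i <- pt$i[k]; j <- pt$j[k]
    if (i == j) {
      boundary[k] <- M[i, i] < 1e-5 * vscale[i]
    } else {
      denom <- sqrt(M[i, i] * M[j, j])
      boundary[k] <- denom <= 0 || abs(M[i, j]) >= 0.999 * denom
    }
  }
  names(boundary) <- par_names

  vc <- list(sigma_a = Sa, sigma_e = Se)
  mme <- solve_mme(design, grm, vc)

  structure(list(
    traits = design$traits,
    vc = vc,
    ai = AI,
    ai_cov = ai_cov,
    par_names = par_names,
    free = setNames(free, par_names),
    boundary = boundary,
    fixed_solutions = mme$fixed,
    gebv = mme$gebv,
    loglik = parts$loglik,
    converged = converged,
    iterations = iter,
    trace = dplyr::bind_rows(trace),
    dropped_columns = ob$dropped,
    n_individuals = design$n,
    n_records = ob$N,
    design = design
  ), class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("<gblup_fit> %s | logL = %.4f | %s in %d iterations\n",
              paste(x$traits, collapse = " + "), x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  est <- vc_pack(x$vc$sigma_a, x$vc$sigma_e)
  se <- sqrt(diag(x$ai_cov))
  for (k in seq_along(est)) {
    cat(sprintf("  %-18s %10.4f  (se %.4f)%s\n", x$par_names[k], est[k],
                se[k], if (x$boundary[k]) " [boundary]" else ""))
  }
  invisible(x)
}

#' Variance-component estimates and standard errors
#'
#' Standard errors are square roots of the diagonal of the inverse
#' average-information matrix; components pinned at the positive-semi-
#' definite boundary are flagged and their SE reported as `NA`.
#'
#' @param fit a [fit_gblup()] result.
#' @return Tibble with columns component, estimate, se, boundary.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "gblup_fit"))
  est <- vc_pack(fit$vc$sigma_a, fit$vc$sigma_e)
  se <- sqrt(pmax(diag(fit$ai_cov), 0))
  se[fit$boundary] <- NA_real_
  tibble(component = fit$par_names, estimate = est, se = se,
         boundary = unname(fit$boundary))
}

#' @rdname standard_errors
#' @param x a `gblup_fit`.
#' @param ... ignored.
#' @export
tidy.gblup_fit <- function(x, ...) {
  dplyr::rename(standard_errors(x), term = "component")
}

#' One-row model summary of a GBLUP fit
#'
#' @param x a `gblup_fit`.
#' @param ... ignored.
#' @return Tibble with the restricted log-likelihood, iteration count,
#'   convergence flag and problem sizes.
#' @export
glance.gblup_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik,
    iterations = x$iterations,
    converged = x$converged,
    n_individuals = x$n_individuals,
    n_records = x$n_records,
    traits = paste(x$traits, collapse = "+")
  )
}

#' Convergence trace of an AI-REML fit
#'
#' @param object a [fit_gblup()] result.
#' @param ... ignored.
#' @return A ggplot of restricted log-likelihood against iteration.
#' @export
autoplot.gblup_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(.data$iteration, .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "AI-REML iteration", y = "restricted log-likelihood",
                  title = paste("Convergence:",
                                paste(object$traits, collapse = " + "))) +
    ggplot2::theme_minimal()
}
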