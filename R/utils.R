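# internal numerical helpers

# symmetric eigen-floor: project a symmetric matrix onto the cone of matrices
# with smallest eigenvalue >= floor; returns the matrix plus a flag saying
# whether any eigenvalue was clamped
sym_floor <- function(M, floor = 0) {
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  clamped <- any(ee$values < floor)
  if (clamped) {
    vals <- pmax(ee$values, floor)
    M <- ee$vectors %*% (vals * t(ee$vectors))
    M <- (M + t(M)) / 2
  }
  list(mat = M, clamped = clamped)
}

is_psd <- function(M, tol = 1e-8) {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev[1] <= 0 || ev[length(ev)] >= -tol * max(abs(ev[1]), 1)
}

check_covariance <- function(M, name) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    abort(sprintf("`%s` must be a square matrix.", name))
  }
  if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M)))) {
    abort(sprintf("`%s` must be symmetric.", name))
  }
  if (!is_psd(M)) {
    abort(sprintf("`%s` must be positive semi-definite.", name),
          class = "mtgblup_error_not_psd")
  }
  invisible((M + t(M)) / 2)
}

# half-vectorisation order used for variance-component parameter vectors:
# column-major lower triangle, genetic block first, then residual block
vech_index <- function(t) {
  idx <- which(lower.tri(matrix(0, t, t), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}

vc_pack <- function(sigma_a, sigma_e) {
  t <- nrow(sigma_a)
  idx <- vech_index(t)
  c(sigma_a[idx], sigma_e[idx])
}

vc_unpack <- function(theta, t, traits = NULL) {
  idx <- vech_index(t)
  k <- nrow(idx)
  Sa <- matrix(0, t, t)
  Se <- matrix(0, t, t)
  Sa[idx] <- theta[seq_len(k)]
  Se[idx] <- theta[k + seq_len(k)]
  Sa <- Sa + t(Sa) - diag(diag(Sa), t)
  Se <- Se + t(Se) - diag(diag(Se), t)
  if (!is.null(traits)) {
    dimnames(Sa) <- dimnames(Se) <- list(traits, traits)
  }
  list(sigma_a = Sa, sigma_e = Se)
}

vc_par_names <- function(traits) {
  t <- length(traits)
  idx <- vech_index(t)
  nm <- function(block) {
    sprintf("%s[%s,%s]", block, traits[idx[, "row"]], traits[idx[, "col"]])
  }
  c(nm("sigma_a"), nm("sigma_e"))
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(seed)
}

# draw n iid rows from N(0, Sigma); Sigma may be positive semi-definite
rmvn <- function(n, Sigma) {
  t <- nrow(Sigma)
  ee <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  L <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), t)
  matrix(rnorm(n * t), n, t) %*% t(L)
}
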