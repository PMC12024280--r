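#' Solve Henderson's mixed-model equations at given variance components
#'
#' Builds and solves the mixed-model equations for the stacked (trait-major)
#' model with random-effect covariance `sigma_a %x% G` and residual
#' covariance `sigma_e %x% I` on observed records. GEBVs are returned for
#' every individual in the GRM, including individuals whose records are all
#' masked: information reaches them through their genomic relationships and,
#' in two-trait fits, through observed records on the other trait.
#'
#' @param design a [build_design()] result.
#' @param grm the [build_grm()] result used in the design.
#' @param vc list with positive-definite `sigma_a` and `sigma_e`.
#' @return List with `fixed` (tibble: trait, term, estimate) and `gebv`
#'   (tibble: id, trait, gebv).
#' @export
solve_mme <- function(design, grm, vc) {
  stopifnot(inherits(design, "gblup_design"), inherits(grm, "grm"))
  t <- design$t
  Sa <- as.matrix(vc$sigma_a)
  Se <- as.matrix(vc$sigma_e)
  ob <- make_obs(design, grm)
  n_g <- length(grm$ids)
  gidx_of_record <- match(design$ids, grm$ids)[ob$io]

  # residual precision, block diagonal by individual over its observed traits
  N <- ob$N
  Rinv <- matrix(0, N, N)
  recs_by_ind <- split(seq_len(N), ob$io)
  for (recs in recs_by_ind) {
    tr <- ob$to[recs]
    Rinv[recs, recs] <- solve(Se[tr, tr, drop = FALSE])
  }

  q <- t * n_g
  Z <- matrix(0, N, q)
  Z[cbind(seq_len(N), (ob$to - 1L) * n_g + gidx_of_record)] <- 1

  Ginv <- tryCatch(chol2inv(chol(grm$G)), error = function(e) {
    abort("the genomic relationship matrix block is singular; increase `ridge`.",
          class = "mtgblup_error_singular_G")
  })
  # a genetic covariance pinned on the PSD boundary (e.g. correlation 1) is
  # jittered minimally so the MME precision block exists
  ea <- eigen((Sa + t(Sa)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ea) < 1e-8 * max(ea)) {
    Sa <- sym_floor(Sa, 1e-8 * max(ea, 0) + 1e-300)$mat
  }
  Sainv <- tryCatch(solve(Sa), error = function(e) {
    abort("the genetic covariance block `sigma_a` is singular.",
          class = "mtgblup_error_singular_sigma_a")
  })

  W <- cbind(ob$Xo, Z)
  RiW <- Rinv %*% W
  C <- crossprod(W, RiW)
  ui <- ob$p + seq_len(q)
  C[ui, ui] <- C[ui, ui] + kronecker(Sainv, Ginv)
  rhs <- crossprod(RiW, ob$yo)
  chC <- tryCatch(chol(C), error = function(e) {
    abort("singular mixed-model coefficient matrix (fixed-effect block).",
          class = "mtgblup_error_singular_C")
  })
  sol <- drop(backsolve(chC, forwardsolve(t(chC), rhs)))

  b <- sol[seq_len(ob$p)]
  terms <- colnames(ob$Xo)
  fixed <- tibble(
    trait = sub(":.*$", "", terms),
    term = sub("^[^:]*:", "", terms),
    estimate = unname(b)
  )
  u <- matrix(sol[ui], n_g, t)
  gebv <- tibble(
    id = rep(grm$ids, t),
    trait = rep(design$traits, each = n_g),
    gebv = as.vector(u)
  )
  list(fixed = fixed, gebv = gebv)
}
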