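#' Narrow-sense heritability from a fitted GBLUP model
#'
#' `h2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)` per trait, with a delta-method
#' standard error from the inverse average-information matrix (analytic
#' gradient, the standard variance-function prediction of REML software).
#' Standard errors are suppressed (`NA`) for traits whose variance estimate
#' sits on the parameter boundary.
#'
#' @param fit a [fit_gblup()] result.
#' @return Tibble with columns trait, h2, se.
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "gblup_fit"))
  t <- length(fit$traits)
  pt <- par_table(t)
  purrr::map_dfr(seq_len(t), function(j) {
    va <- fit$vc$sigma_a[j, j]
    ve <- fit$vc$sigma_e[j, j]
    tot <- va + ve
    if (tot <= 0) abort("zero total variance; heritability undefined.")
    h2 <- va / tot
    ka <- which(pt$block == "a" & pt$i == j & pt$j == j)
    ke <- which(pt$block == "e" & pt$i == j & pt$j == j)
    se <- NA_real_
    if (!fit$boundary[ka] && !fit$boundary[ke] &&
        !anyNA(fit$ai_cov[c(ka, ke), c(ka, ke)])) {
      g <- c(ve, -va) / tot^2            # d h2 / d (va, ve)
      se <- sqrt(max(drop(g %*% fit$ai_cov[c(ka, ke), c(ka, ke)] %*% g), 0))
    }
    tibble(trait = fit$traits[j], h2 = h2, se = se)
  })
}

#' Genetic correlation from a fitted two-trait GBLUP model
#'
#' `rg = cov_g(x, y) / (sigma_g(x) * sigma_g(y))` with a delta-method
#' standard error from the inverse AI matrix. Undefined (returned as `NA`
#' with a warning) when either genetic variance is zero or on the boundary.
#'
#' @param fit a two-trait [fit_gblup()] result.
#' @return Tibble with columns trait_x, trait_y, rg, se.
#' @export
genetic_correlation <- function(fit) {
  stopifnot(inherits(fit, "gblup_fit"))
  t <- length(fit$traits)
  if (t < 2) abort("genetic correlations require a two-trait fit.")
  pt <- par_table(t)
  v1 <- fit$vc$sigma_a[1, 1]
  v2 <- fit$vc$sigma_a[2, 2]
  cg <- fit$vc$sigma_a[1, 2]
  k1 <- which(pt$block == "a" & pt$i == 1 & pt$j == 1)
  k2 <- which(pt$block == "a" & pt$i == 2 & pt$j == 2)
  kc <- which(pt$block == "a" & pt$i == 2 & pt$j == 1)
  if (v1 <= 0 || v2 <= 0 || fit$boundary[k1] || fit$boundary[k2]) {
    warn("a genetic variance is zero or on the boundary; rg undefined.")
    return(tibble(trait_x = fit$traits[1], trait_y = fit$traits[2],
                  rg = NA_real_, se = NA_real_))
  }
  rg <- cg / sqrt(v1 * v2)
  se <- NA_real_
  ks <- c(k1, kc, k2)                     # order: v1, cov, v2
  if (!anyNA(fit$ai_cov[ks, ks])) {
    g <- c(-rg / (2 * v1), 1 / sqrt(v1 * v2), -rg / (2 * v2))
    se <- sqrt(max(drop(g %*% fit$ai_cov[ks, ks] %*% g), 0))
  }
  tibble(trait_x = fit$traits[1], trait_y = fit$traits[2], rg = rg, se = se)
}

#' Z-score test of an estimate against a theoretical value
#'
#' `z = (estimate - null) / se`, with significance flagged at the two fixed
#' thresholds `|z| >= 1.96` (p < 0.05) and `|z| >= 2.58` (p < 0.01). Both
#' null values used in practice (0 for "different from zero", 1 for
#' "different from one", e.g. for genetic correlations) are supported.
#'
#' @param estimate,se numeric vectors (se must be positive).
#' @param null theoretical value(s) tested against (default 0).
#' @return Tibble with estimate, se, null, z, sig_0.05, sig_0.01.
#' @export
z_test <- function(estimate, se, null = 0) {
  if (any(!is.finite(se) | se <= 0)) abort("`se` must be positive.")
  z <- (estimate - null) / se
  tibble(estimate = estimate, se = se, null = null, z = z,
         sig_0.05 = abs(z) >= 1.96, sig_0.01 = abs(z) >= 2.58)
}
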