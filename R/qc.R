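#' Per-SNP alternative allele frequencies
#'
#' `p_i` is the sum of dosages at SNP `i` divided by twice the number of
#' non-missing calls; missing calls are excluded from the denominator, never
#' counted as reference.
#'
#' @param geno a [genotypes] object or a dosage matrix.
#' @return Named numeric vector of frequencies, one per SNP.
#' @export
allele_frequencies <- function(geno) {
  X <- if (inherits(geno, "genotypes")) geno$X else geno
  n_called <- colSums(!is.na(X))
  if (any(n_called == 0)) {
    abort(sprintf("SNP(s) with no called genotypes: %s",
                  paste(head(colnames(X)[n_called == 0], 5), collapse = ", ")))
  }
  colSums(X, na.rm = TRUE) / (2 * n_called)
}

#' Quality-control filtering of genotypes
#'
#' Applies the three marker-panel filters in a fixed, logged order:
#' individuals by call rate first, then SNPs by call rate, then SNPs by minor
#' allele frequency (frequencies computed on non-missing calls of the
#' retained individuals). Defaults mirror array QC practice for the design:
#' individual call rate >= 80%, SNP call rate >= 90%, MAF strictly > 5%.
#'
#' @param geno a [genotypes] object.
#' @param ind_call_rate_min minimum individual call rate (kept when `>=`).
#' @param snp_call_rate_min minimum SNP call rate (kept when `>=`).
#' @param maf_min minor-allele-frequency threshold (kept when strictly `>`).
#' @return A list with `genotypes` (filtered) and `report`, a `qc_report`
#'   holding the removed individuals/SNPs with reasons, the thresholds, the
#'   filter order and the post-filter (pre-imputation) overall call rate.
#' @export
filter_genotypes <- function(geno, ind_call_rate_min = 0.80,
                             snp_call_rate_min = 0.90, maf_min = 0.05) {
  stopifnot(inherits(geno, "genotypes"))
  X <- geno$X
  if (!length(X)) abort("empty genotype matrix.")

  ind_cr <- rowMeans(!is.na(X))
  keep_ind <- ind_cr >= ind_call_rate_min
  individuals_removed <- tibble(
    id = rownames(X)[!keep_ind],
    reason = "individual call rate",
    value = ind_cr[!keep_ind]
  )
  if (!any(keep_ind)) {
    abort("all individuals removed by the call-rate filter.",
          class = "mtgblup_error_all_individuals_removed")
  }
  X <- X[keep_ind, , drop = FALSE]

  snp_cr <- colMeans(!is.na(X))
  keep_cr <- snp_cr >= snp_call_rate_min
  snps_removed <- tibble(
    snp = colnames(X)[!keep_cr],
    reason = "SNP call rate",
    value = snp_cr[!keep_cr]
  )
  X2 <- X[, keep_cr, drop = FALSE]

  if (ncol(X2)) {
    p <- allele_frequencies(X2)
    maf <- pmin(p, 1 - p)
    keep_maf <- maf > maf_min
    snps_removed <- dplyr::bind_rows(snps_removed, tibble(
      snp = colnames(X2)[!keep_maf],
      reason = "MAF",
      value = maf[!keep_maf]
    ))
    X2 <- X2[, keep_maf, drop = FALSE]
  }
  if (!ncol(X2)) {
    abort("all SNPs removed by the QC filters.",
          class = "mtgblup_error_all_snps_removed")
  }

  out <- genotypes(X2, family = geno$family[keep_ind], dosage = geno$dosage)
  report <- structure(list(
    individuals_removed = individuals_removed,
    snps_removed = snps_removed,
    thresholds = c(ind_call_rate_min = ind_call_rate_min,
                   snp_call_rate_min = snp_call_rate_min,
                   maf_min = maf_min),
    order = c("individual call rate", "SNP call rate", "MAF"),
    n_individuals = c(before = nrow(geno$X), after = nrow(X2)),
    n_snps = c(before = ncol(geno$X), after = ncol(X2)),
    overall_call_rate = mean(!is.na(X2))
  ), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  individuals: %d -> %d (removed %d)\n",
              x$n_individuals["before"], x$n_individuals["after"],
              nrow(x$individuals_removed)))
  cat(sprintf("  SNPs: %d -> %d (removed %d: %d call rate, %d MAF)\n",
              x$n_snps["before"], x$n_snps["after"], nrow(x$snps_removed),
              sum(x$snps_removed$reason == "SNP call rate"),
              sum(x$snps_removed$reason == "MAF")))
  cat(sprintf("  post-filter call rate: %.2f%%\n", 100 * x$overall_call_rate))
  invisible(x)
}

#' Tidy view of QC removals
#'
#' @param x a `qc_report`.
#' @param ... ignored.
#' @return Tibble with columns unit, id, reason, value.
#' @export
tidy.qc_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$individuals_removed, unit = "individual",
                  id = .data$id),
    dplyr::mutate(dplyr::rename(x$snps_removed, id = "snp"), unit = "snp")
  )[, c("unit", "id", "reason", "value")]
}

#' Mean-dosage imputation of missing genotype calls
#'
#' Replaces each missing call by `2 * p_i`, the SNP mean dosage over
#' non-missing calls. Intended for use after [filter_genotypes()]; the
#' result is a real-valued dosage matrix and preserves per-SNP allele
#' frequencies exactly.
#'
#' @param geno a [genotypes] object.
#' @return A complete [genotypes] object with `dosage = TRUE`.
#' @export
impute_missing <- function(geno) {
  stopifnot(inherits(geno, "genotypes"))
  X <- geno$X
  if (!anyNA(X)) {
    geno$dosage <- TRUE
    return(geno)
  }
  p <- allele_frequencies(geno)  # errors on all-missing SNPs
  miss <- which(is.na(X), arr.ind = TRUE)
  X[miss] <- 2 * p[miss[, "col"]]
  genotypes(X, family = geno$family, dosage = TRUE)
}

#' VanRaden genomic relationship matrix
#'
#' Centers each SNP column by twice its allele frequency and scales the
#' cross-product by `2 * sum(p_i * (1 - p_i))`:
#' `G = Z Z' / (2 * sum(p_i * (1 - p_i)))`, with `Z` the centered dosage
#' matrix. A small ridge is added to the diagonal so that `G` is invertible
#' for REML and the mixed-model equations.
#'
#' @param geno complete [genotypes] object (run [impute_missing()] first if
#'   calls are missing).
#' @param freqs optional externally supplied allele frequencies; defaults to
#'   the frequencies observed in the current sample.
#' @param ridge constant added to the diagonal (default `1e-6`).
#' @return An object of class `grm`: the `n x n` matrix plus the
#'   frequencies, denominator and ridge used.
#' @export
build_grm <- function(geno, freqs = NULL, ridge = 1e-6) {
  stopifnot(inherits(geno, "genotypes"))
  X <- geno$X
  if (anyNA(X)) abort("genotypes contain missing calls; run impute_missing() first.")
  p <- freqs %||% allele_frequencies(geno)
  if (length(p) != ncol(X)) abort("`freqs` must have one entry per SNP.")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) {
    abort("zero denominator: every SNP is monomorphic.",
          class = "mtgblup_error_monomorphic")
  }
  Z <- sweep(X, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  diag(G) <- diag(G) + ridge
  structure(list(G = G, freqs = p, denominator = denom, ridge = ridge,
                 ids = rownames(X)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d individuals | denominator %.2f | ridge %.1e\n",
              nrow(x$G), x$denominator, x$ridge))
  cat(sprintf("  mean diagonal %.3f | mean off-diagonal %.4f\n",
              mean(diag(x$G)),
              (sum(x$G) - sum(diag(x$G))) / (nrow(x$G)^2 - nrow(x$G))))
  invisible(x)
}

#' @export
as.matrix.grm <- function(x, ...) x$G

#' @export
dim.grm <- function(x) dim(x$G)

#' Relationship heatmap for a genomic relationship matrix
#'
#' @param object a [build_grm()] result.
#' @param max_n downsample to at most this many individuals for plotting.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.grm <- function(object, max_n = 400, ...) {
  G <- object$G
  if (nrow(G) > max_n) {
    keep <- sort(sample.int(nrow(G), max_n))
    G <- G[keep, keep]
  }
  df <- tidyr::expand_grid(row = seq_len(nrow(G)), col = seq_len(ncol(G)))
  df$value <- G[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "G") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Genomic relationship matrix") +
    ggplot2::theme_minimal()
}
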