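#' Genotype matrix container
#'
#' Holds an individuals-by-SNPs dosage matrix coded 0/1/2 (counts of the
#' alternative allele) with `NA` for missing calls, together with individual
#' ids, SNP ids and, optionally, the full-sib family of each individual.
#' After [impute_missing()] the codes become real-valued dosages in `[0, 2]`.
#'
#' @param X integer or numeric matrix, individuals in rows, SNPs in columns.
#'   Row names are individual ids, column names SNP ids (generated when
#'   absent). Values must lie in `[0, 2]` or be `NA`.
#' @param family optional character/factor vector of family ids, one per row.
#' @param dosage logical; `TRUE` once values are continuous imputed dosages.
#' @return An object of class `genotypes`.
#' @export
genotypes <- function(X, family = NULL, dosage = FALSE) {
  if (!is.matrix(X)) abort("`X` must be a matrix.")
  if (is.null(rownames(X))) rownames(X) <- sprintf("ind%04d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("snp%05d", seq_len(ncol(X)))
  if (anyDuplicated(rownames(X))) abort("duplicate individual ids.")
  if (anyDuplicated(colnames(X))) abort("duplicate SNP ids.")
  vals <- X[!is.na(X)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 2)) {
    abort("genotype codes must lie in [0, 2] or be NA.")
  }
  if (!dosage && length(vals) && any(vals != round(vals))) {
    abort("non-integer codes require `dosage = TRUE`.")
  }
  if (!is.null(family)) {
    if (length(family) != nrow(X)) abort("`family` must have one entry per individual.")
    family <- as.character(family)
  }
  structure(list(X = X, family = family, dosage = dosage),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("<genotypes> %d individuals x %d SNPs (%s)\n",
              nrow(x$X), ncol(x$X),
              if (x$dosage) "imputed dosages" else "0/1/2 calls"))
  miss <- mean(is.na(x$X))
  cat(sprintf("  missing calls: %.2f%%", 100 * miss))
  if (!is.null(x$family)) {
    cat(sprintf(" | %d families", length(unique(x$family))))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.matrix.genotypes <- function(x, ...) x$X

#' @export
dim.genotypes <- function(x) dim(x$X)

#' Subset a genotype matrix by individual id
#'
#' @param geno a [genotypes] object.
#' @param ids individual ids to keep, in the requested order.
#' @return A [genotypes] object restricted to `ids`.
#' @export
subset_individuals <- function(geno, ids) {
  stopifnot(inherits(geno, "genotypes"))
  missing_ids <- setdiff(ids, rownames(geno$X))
  if (length(missing_ids)) {
    abort(sprintf("ids not present in genotypes: %s",
                  paste(head(missing_ids, 5), collapse = ", ")))
  }
  keep <- match(ids, rownames(geno$X))
  genotypes(geno$X[keep, , drop = FALSE],
            family = geno$family[keep],
            dosage = geno$dosage)
}
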