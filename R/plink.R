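#' Write genotypes as PLINK text (.ped/.map)
#'
#' Genotype codes are emitted as allele pairs with `A` the reference and `B`
#' the alternative allele (0 -> `A A`, 1 -> `A B`, 2 -> `B B`), missing calls
#' as `0 0` (the PLINK convention). The .map file places every SNP on
#' chromosome 1 at its column index.
#'
#' @param geno a [genotypes] object with integer 0/1/2 calls.
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return The two paths, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "genotypes"))
  if (geno$dosage) abort("imputed dosages cannot be written as .ped calls.")
  X <- geno$X
  code <- c(`0` = "A A", `1` = "A B", `2` = "B B")
  alleles <- matrix("0 0", nrow(X), ncol(X))
  ok <- !is.na(X)
  alleles[ok] <- code[as.character(X[ok])]
  fam <- geno$family %||% rep("0", nrow(X))
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  lines <- paste(fam, rownames(X), 0, 0, 0, -9,
                 apply(alleles, 1, paste, collapse = " "))
  writeLines(lines, ped_path)
  writeLines(paste(1, colnames(X), 0, seq_len(ncol(X)), sep = "\t"), map_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read genotypes from PLINK text (.ped/.map)
#'
#' The minor allele of each SNP is determined from the data (ties broken
#' towards the lexicographically larger allele, so `A`/`B` files written by
#' [write_plink()] round-trip exactly when the alternative allele frequency
#' is at most 0.5) and counted into 0/1/2 dosages; `0` alleles are missing.
#'
#' @param ped_path,map_path paths to the .ped and .map files.
#' @return A [genotypes] object; family ids are taken from the first .ped
#'   column.
#' @export
read_plink <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_fields <- strsplit(trimws(map_lines), "\\s+")
  bad <- which(lengths(map_fields) < 4)
  if (length(bad)) {
    abort(sprintf("malformed .map line %d: expected 4 fields.", bad[1]))
  }
  snp_ids <- vapply(map_fields, `[[`, "", 2)
  m <- length(snp_ids)

  ped_lines <- readLines(ped_path)
  n <- length(ped_lines)
  if (!n) abort("empty .ped file.")
  ids <- character(n)
  fam <- character(n)
  a1 <- matrix(NA_character_, n, m)
  a2 <- matrix(NA_character_, n, m)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(ped_lines[i]), "\\s+")[[1]]
    if (length(f) != 6 + 2 * m) {
      abort(sprintf("malformed .ped line %d: %d fields, expected %d.",
                    i, length(f), 6 + 2 * m))
    }
    fam[i] <- f[1]
    ids[i] <- f[2]
    g <- f[-(1:6)]
    a1[i, ] <- g[seq(1, 2 * m, by = 2)]
    a2[i, ] <- g[seq(2, 2 * m, by = 2)]
  }
  X <- matrix(NA_integer_, n, m, dimnames = list(ids, snp_ids))
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    present <- setdiff(unique(al), "0")
    if (length(present) > 2) {
      abort(sprintf("SNP `%s` has more than two alleles: %s.", snp_ids[j],
                    paste(sort(present), collapse = "/")))
    }
    if (!length(present)) next
    miss0 <- a1[, j] == "0" | a2[, j] == "0"
    if (length(present) == 1) {
      # the minor allele is unobserved: dosage 0 everywhere called
      X[!miss0, j] <- 0L
      next
    }
    counts <- table(factor(al[al != "0"], levels = sort(present)))
    # minor allele; ties go to the lexicographically larger allele
    minor <- names(counts)[which(counts == min(counts))]
    minor <- minor[length(minor)]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    X[, j] <- (a1[, j] == minor) + (a2[, j] == minor)
    X[miss, j] <- NA_integer_
  }
  genotypes(X, family = if (any(fam != "0")) fam else NULL)
}

#' Write and read the phenotype CSV dialect
#'
#' Columns: id, family, sex, tank, group, BW_g, BL_cm, AL_cm, MW_g, MY_pct
#' (trait columns present only when the corresponding internal trait
#' exists). `read_pheno()` restores the internal column names and factor
#' codings.
#'
#' @param pheno phenotype tibble.
#' @param path CSV path.
#' @return `write_pheno()` the path invisibly; `read_pheno()` a tibble.
#' @export
write_pheno <- function(pheno, path) {
  unit_map <- c(BW = "BW_g", BL = "BL_cm", AL = "AL_cm", MW = "MW_g",
                MY = "MY_pct")
  out <- pheno
  for (tr in names(unit_map)) {
    if (tr %in% names(out)) {
      names(out)[names(out) == tr] <- unit_map[[tr]]
    }
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_pheno
#' @export
read_pheno <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  unit_map <- c(BW_g = "BW", BL_cm = "BL", AL_cm = "AL", MW_g = "MW",
                MY_pct = "MY")
  for (cn in names(unit_map)) {
    if (cn %in% names(out)) names(out)[names(out) == cn] <- unit_map[[cn]]
  }
  for (fc in intersect(c("sex", "tank", "group"), names(out))) {
    out[[fc]] <- factor(out[[fc]])
  }
  out$id <- as.character(out$id)
  out
}
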