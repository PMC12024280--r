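#' Default trait parameters for the shrimp family design
#'
#' Mean, phenotypic SD and narrow-sense heritability for the four directly
#' simulated traits (body weight BW in g, body length BL in cm, abdominal
#' segment length AL in cm, net meat weight MW in g), and the genetic
#' correlation matrix among them, at the values reported for a 63-family
#' *Penaeus vannamei* meat-yield experiment. Meat yield (MY, %) is not
#' simulated directly: it is derived as `MW / BW * 100` so that the ratio
#' definition is preserved.
#'
#' @return A list with elements `traits` (tibble: trait, mean, sd, h2) and
#'   `genetic_cor` (4x4 correlation matrix).
#' @export
shrimp_trait_defaults <- function() {
  traits <- tibble(
    trait = c("BW", "BL", "AL", "MW"),
    mean  = c(27.29, 13.04, 7.50, 13.81),
    sd    = c(4.45, 0.75, 0.47, 2.41),
    h2    = c(0.158, 0.133, 0.101, 0.197)
  )
  rg <- matrix(c(
    1.000, 0.935, 0.811, 0.978,
    0.935, 1.000, 0.924, 0.915,
    0.811, 0.924, 1.000, 0.735,
    0.978, 0.915, 0.735, 1.000
  ), 4, 4, dimnames = list(traits$trait, traits$trait))
  list(traits = traits, genetic_cor = rg)
}

#' Simulation configuration for a full-sib family design
#'
#' Describes the population the generator emulates: `n_families` full-sib
#' families of `offspring_per_family` offspring genotyped at `n_snps`
#' unlinked biallelic SNPs, multivariate polygenic traits with genetic
#' covariance `sigma_a` and residual covariance `sigma_e`, fixed effects of
#' sex, tank group and their interaction, group-specific survival, and a
#' final uniform thinning to `n_retained` analysed individuals. Defaults
#' reproduce the 63-family design: 63 x 20 = 1260 stocked, survival 83.29% /
#' 76.94% in the two tank groups, 899 retained.
#'
#' @param n_families number of full-sib families (default 63).
#' @param offspring_per_family offspring genotyped per family (default 20).
#' @param n_snps number of simulated SNPs (desk default 1000).
#' @param traits character vector naming the directly simulated traits; must
#'   be a subset of the rows of `shrimp_trait_defaults()$traits` unless
#'   `trait_means`/`trait_sds`/`h2` are all supplied.
#' @param trait_means,trait_sds,h2 per-trait mean, phenotypic SD and
#'   heritability; defaults taken from [shrimp_trait_defaults()].
#' @param genetic_cor genetic correlation matrix among `traits`.
#' @param residual_cor residual correlation matrix; defaults to
#'   `genetic_cor` (the only correlation structure reported for the design).
#' @param sigma_a,sigma_e optional explicit genetic/residual covariance
#'   matrices, overriding the h2/SD/correlation parameterisation.
#' @param fixed_effects list with numeric vectors `sex`, `group`,
#'   `interaction` (one entry per trait, trait units): the effect of male vs
#'   female, tank group B (low light) vs A, and their interaction. Defaults:
#'   -0.3, -0.2 and +0.05 phenotypic SD respectively.
#' @param maf_range founder allele-frequency law: length-2 range for a
#'   uniform draw, or a single value for a point mass.
#' @param missing_rate fraction of genotype calls set missing at random in
#'   the emitted genotypes (array-like missingness; default 0.02).
#' @param survival_rates named survival probabilities per tank group,
#'   default `c(A = 0.8329, B = 0.7694)`.
#' @param n_retained analysed individuals after outlier exclusion (default
#'   899); set `NULL` to keep all survivors.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_families = 63,
                       offspring_per_family = 20,
                       n_snps = 1000,
                       traits = c("BW", "BL", "AL", "MW"),
                       trait_means = NULL,
                       trait_sds = NULL,
                       h2 = NULL,
                       genetic_cor = NULL,
                       residual_cor = NULL,
                       sigma_a = NULL,
                       sigma_e = NULL,
                       fixed_effects = NULL,
                       maf_range = c(0.05, 0.5),
                       missing_rate = 0.02,
                       survival_rates = c(A = 0.8329, B = 0.7694),
                       n_retained = 899) {
  if (n_families < 1 || offspring_per_family < 1 || n_snps < 1) {
    abort("design dimensions must be positive.")
  }
  defaults <- shrimp_trait_defaults()
  t <- length(traits)
  if (anyDuplicated(traits)) abort("`traits` must be distinct.")

  pick <- function(user, col) {
    if (!is.null(user)) {
      stopifnot(length(user) == t)
      return(user)
    }
    if (!all(traits %in% defaults$traits$trait)) {
      abort("non-default trait names need explicit trait_means/trait_sds/h2.")
    }
    defaults$traits[[col]][match(traits, defaults$traits$trait)]
  }
  trait_means <- pick(trait_means, "mean")
  trait_sds <- pick(trait_sds, "sd")
  h2 <- pick(h2, "h2")
  if (any(h2 < 0 | h2 > 1)) abort("`h2` must lie in [0, 1].")

  if (is.null(genetic_cor)) {
    if (all(traits %in% rownames(defaults$genetic_cor))) {
      genetic_cor <- defaults$genetic_cor[traits, traits, drop = FALSE]
    } else {
      genetic_cor <- diag(t)
    }
  }
  if (is.null(residual_cor)) residual_cor <- genetic_cor

  if (is.null(sigma_a)) {
    sa <- sqrt(h2) * trait_sds
    sigma_a <- genetic_cor * tcrossprod(sa)
  }
  if (is.null(sigma_e)) {
    se <- sqrt(1 - h2) * trait_sds
    sigma_e <- residual_cor * tcrossprod(se)
  }
  dimnames(sigma_a) <- dimnames(sigma_e) <- list(traits, traits)
  sigma_a <- check_covariance(sigma_a, "sigma_a")
  sigma_e <- check_covariance(sigma_e, "sigma_e")

  if (is.null(fixed_effects)) {
    fixed_effects <- list(sex = -0.3 * trait_sds,
                          group = -0.2 * trait_sds,
                          interaction = 0.05 * trait_sds)
  }
  stopifnot(all(c("sex", "group", "interaction") %in% names(fixed_effects)),
            all(lengths(fixed_effects[c("sex", "group", "interaction")]) == t))

  if (any(survival_rates <= 0 | survival_rates > 1)) {
    abort("`survival_rates` must lie in (0, 1].")
  }
  n_total <- n_families * offspring_per_family
  if (!is.null(n_retained) && n_retained > n_total) {
    abort("`n_retained` cannot exceed n_families * offspring_per_family.")
  }
  if (length(maf_range) == 1) maf_range <- rep(maf_range, 2)
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must be in [0, 1).")

  structure(list(
    n_families = n_families,
    offspring_per_family = offspring_per_family,
    n_snps = n_snps,
    traits = traits,
    trait_means = setNames(trait_means, traits),
    trait_sds = setNames(trait_sds, traits),
    sigma_a = sigma_a,
    sigma_e = sigma_e,
    fixed_effects = fixed_effects,
    maf_range = maf_range,
    missing_rate = missing_rate,
    survival_rates = survival_rates,
    n_retained = n_retained
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d families x %d offspring, %d SNPs, traits: %s\n",
              x$n_families, x$offspring_per_family, x$n_snps,
              paste(x$traits, collapse = ", ")))
  cat(sprintf("  survival: %s | retained: %s\n",
              paste(sprintf("%s=%.2f%%", names(x$survival_rates),
                            100 * x$survival_rates), collapse = " "),
              x$n_retained %||% "all survivors"))
  invisible(x)
}

#' Simulate founder genotypes
#'
#' Draws two unrelated parents per family with SNP genotypes sampled
#' independently as Binomial(2, p_i), where the founder allele frequencies
#' p_i follow the configured law (clipped to `[0.01, 0.99]`).
#'
#' @param n_families number of families (2 founders each).
#' @param n_snps number of SNPs.
#' @param maf_range length-2 range for uniform founder frequencies, or a
#'   single value for a point mass.
#' @param seed optional integer seed.
#' @return A [genotypes] object of `2 * n_families` founders with the drawn
#'   frequencies in attribute `founder_freq`.
#' @export
simulate_founders <- function(n_families = 63, n_snps = 1000,
                              maf_range = c(0.05, 0.5), seed = NULL) {
  if (n_families < 1 || n_snps < 1) abort("dimensions must be positive.")
  set_seed_if(seed)
  if (length(maf_range) == 1) maf_range <- rep(maf_range, 2)
  p <- pmin(pmax(runif(n_snps, maf_range[1], maf_range[2]), 0.01), 0.99)
  n <- 2L * n_families
  X <- matrix(rbinom(n * n_snps, 2L, rep(p, each = n)), n, n_snps)
  fam <- rep(sprintf("F%03d", seq_len(n_families)), each = 2)
  rownames(X) <- paste0(fam, "_P", rep(1:2, n_families))
  colnames(X) <- sprintf("snp%05d", seq_len(n_snps))
  out <- genotypes(X, family = fam)
  attr(out, "founder_freq") <- p
  out
}

#' Drop full-sib offspring from paired founders
#'
#' Mendelian gene dropping: each offspring receives, per SNP, one allele
#' sampled uniformly from each parent, giving full-sib families whose
#' expected genomic relationship is 0.5.
#'
#' @param founders a [genotypes] object with exactly two complete parents per
#'   family (as from [simulate_founders()]).
#' @param offspring_per_family offspring sampled per family.
#' @param seed optional integer seed.
#' @return A [genotypes] object of offspring with family ids.
#' @export
drop_offspring <- function(founders, offspring_per_family = 20, seed = NULL) {
  stopifnot(inherits(founders, "genotypes"))
  if (offspring_per_family < 1) abort("`offspring_per_family` must be positive.")
  if (is.null(founders$family)) abort("founders must carry family ids.")
  if (anyNA(founders$X)) abort("founder genotypes must be complete.")
  fam_sizes <- table(founders$family)
  if (any(fam_sizes != 2)) {
    abort("each family must have exactly two founders (unpaired founders).",
          class = "mtgblup_error_unpaired")
  }
  set_seed_if(seed)
  fams <- unique(founders$family)
  ord <- order(match(founders$family, fams))
  Xf <- founders$X[ord, , drop = FALSE]
  p1 <- seq(1, nrow(Xf), by = 2)
  k <- offspring_per_family
  G1 <- Xf[rep(p1, each = k), , drop = FALSE]
  G2 <- Xf[rep(p1 + 1, each = k), , drop = FALSE]
  O <- matrix(rbinom(length(G1), 1L, G1 / 2) + rbinom(length(G2), 1L, G2 / 2),
              nrow(G1), ncol(G1))
  fam <- rep(fams, each = k)
  rownames(O) <- paste0(fam, "_", sprintf("%02d", rep(seq_len(k), length(fams))))
  colnames(O) <- colnames(Xf)
  genotypes(O, family = fam)
}

# block families into six tanks (two light-intensity groups of three tanks),
# 10-11 families per tank for the 63-family design
assign_tanks <- function(families) {
  fams <- unique(families)
  n_tanks <- 6L
  if (length(fams) == 63L) {
    sizes <- c(10L, 11L, 11L, 10L, 11L, 10L)  # the reference 63-family layout
  } else {
    sizes <- rep(length(fams) %/% n_tanks, n_tanks)
    extra <- length(fams) %% n_tanks
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    if (any(sizes == 0L)) {
      sizes <- rep(1L, n_tanks)  # degenerate tiny designs: round-robin
      tanks <- c("A1", "A2", "A3", "B1", "B2", "B3")[
        rep_len(seq_len(n_tanks), length(fams))]
      return(setNames(tanks, fams))
    }
  }
  tank_of <- rep(seq_len(n_tanks), times = sizes)
  tanks <- c("A1", "A2", "A3", "B1", "B2", "B3")[tank_of]
  setNames(tanks, fams)
}

#' Simulate phenotypes on a genotyped population
#'
#' Generates multivariate polygenic trait values under the animal model
#' `y = Xb + Zu + e`. Per-SNP allele-substitution effects are drawn
#' multivariate normal with covariance `sigma_a / d`, where
#' `d = 2 * sum(p * (1 - p))` is the same denominator used by the VanRaden
#' genomic relationship matrix, so that breeding values have covariance
#' `sigma_a` on the G scale in expectation. Fixed effects of sex (Bernoulli
#' 0.5), tank group (families blocked into six tanks, three per group) and
#' their interaction are added, residuals are multivariate normal with
#' covariance `sigma_e`, and meat yield `MY = MW / BW * 100` is derived when
#' both MW and BW are simulated.
#'
#' @param geno complete [genotypes] object (offspring).
#' @param config a [sim_config].
#' @param seed optional integer seed.
#' @return A list of class `sim_phenotypes` with elements `pheno` (tibble:
#'   id, family, sex, tank, group, one column per trait, MY when derivable)
#'   and `truth` (tibble of per-individual true breeding values `tbv_*`),
#'   plus the per-SNP effect matrix `snp_effects`.
#' @export
simulate_phenotypes <- function(geno, config, seed = NULL) {
  stopifnot(inherits(geno, "genotypes"), inherits(config, "sim_config"))
  if (anyNA(geno$X)) abort("genotypes must be complete to simulate phenotypes.")
  traits <- config$traits
  t <- length(traits)
  check_covariance(config$sigma_a, "sigma_a")
  check_covariance(config$sigma_e, "sigma_e")
  set_seed_if(seed)

  n <- nrow(geno$X)
  m <- ncol(geno$X)
  p <- colMeans(geno$X) / 2
  d <- 2 * sum(p * (1 - p))
  if (d <= 0) abort("all SNPs are monomorphic; cannot scale genetic effects.")
  W <- sweep(geno$X, 2, 2 * p)

  beta <- rmvn(m, config$sigma_a / d)            # m x t SNP effects
  u <- W %*% beta                                # true breeding values
  e <- rmvn(n, config$sigma_e)

  sex <- sample(c("F", "M"), n, replace = TRUE)
  fam <- geno$family %||% rep("F000", n)
  tank <- assign_tanks(fam)[fam]
  group <- substr(tank, 1, 1)

  fe <- config$fixed_effects
  Xb <- outer(sex == "M", fe$sex) +
    outer(group == "B", fe$group) +
    outer(sex == "M" & group == "B", fe$interaction)

  Y <- matrix(rep(config$trait_means, each = n), n, t) + Xb + u + e
  colnames(Y) <- traits

  pheno <- tibble(
    id = rownames(geno$X),
    family = fam,
    sex = factor(sex, levels = c("F", "M")),
    tank = factor(tank, levels = c("A1", "A2", "A3", "B1", "B2", "B3")),
    group = factor(group, levels = c("A", "B"))
  )
  pheno <- dplyr::bind_cols(pheno, as_tibble(Y))
  if (all(c("MW", "BW") %in% traits)) {
    pheno$MY <- compute_my(pheno$MW, pheno$BW)
  }
  truth <- tibble(id = rownames(geno$X))
  colnames(u) <- paste0("tbv_", traits)
  truth <- dplyr::bind_cols(truth, as_tibble(u))

  structure(list(pheno = pheno, truth = truth, snp_effects = beta),
            class = "sim_phenotypes")
}

#' Apply tank-group survival and uniform thinning
#'
#' Drops individuals independently per tank group at the configured survival
#' rates, then thins the survivors uniformly at random to `n_retained`
#' (emulating the exclusion of a small number of abnormal records, which is
#' missing-at-random with respect to phenotype).
#'
#' @param pheno phenotype tibble with a `group` column.
#' @param survival_rates named per-group survival probabilities.
#' @param n_retained final number of analysed individuals (`NULL` keeps all
#'   survivors).
#' @param seed optional integer seed.
#' @return The retained subset of `pheno`, with a `survival` attribute: a
#'   per-tank tibble of stocked/harvested counts.
#' @export
apply_attrition <- function(pheno, survival_rates = c(A = 0.8329, B = 0.7694),
                            n_retained = NULL, seed = NULL) {
  stopifnot(is.data.frame(pheno), "group" %in% names(pheno))
  if (any(survival_rates <= 0 | survival_rates > 1)) {
    abort("`survival_rates` must lie in (0, 1].")
  }
  set_seed_if(seed)
  rate <- survival_rates[as.character(pheno$group)]
  if (anyNA(rate)) abort("every group needs a survival rate.")
  alive <- rbinom(nrow(pheno), 1L, rate) == 1L
  survivors <- pheno[alive, , drop = FALSE]
  if (!is.null(n_retained)) {
    if (n_retained > nrow(survivors)) {
      abort(sprintf("`n_retained` (%d) exceeds the %d survivors.",
                    n_retained, nrow(survivors)),
            class = "mtgblup_error_attrition")
    }
    keep <- sort(sample.int(nrow(survivors), n_retained))
    survivors <- survivors[keep, , drop = FALSE]
  }
  if ("tank" %in% names(pheno)) {
    stocked <- dplyr::count(pheno, .data$tank, name = "stocked")
    harvested <- dplyr::count(pheno[alive, , drop = FALSE], .data$tank,
                              name = "harvested")
    surv <- dplyr::left_join(stocked, harvested, by = "tank")
    surv$harvested[is.na(surv$harvested)] <- 0L
    surv$group <- substr(as.character(surv$tank), 1, 1)
    n_fam <- tapply(pheno$family, pheno$tank, function(f) length(unique(f)))
    surv$families <- as.integer(n_fam[as.character(surv$tank)])
    attr(survivors, "survival") <-
      surv[, c("tank", "group", "families", "stocked", "harvested")]
  }
  survivors
}

#' Simulate a complete analysed population
#'
#' End-to-end generator: founders, Mendelian gene dropping, phenotypes,
#' attrition/thinning, and random genotype missingness, with all randomness
#' driven by sub-seeds derived from `seed`.
#'
#' @param config a [sim_config].
#' @param seed integer seed (kept below 2^31 after sub-stream derivation).
#' @return A list of class `sim_population`: `genotypes` (retained
#'   individuals, with `missing_rate` calls set `NA`), `pheno`, `truth`
#'   (retained individuals), `survival` (per-tank counts) and `config`.
#' @export
simulate_shrimp <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sub <- function(k) if (is.null(seed)) NULL else (as.integer(seed) * 7L + k) %% 2147483629L
  founders <- simulate_founders(config$n_families, config$n_snps,
                                config$maf_range, seed = sub(1L))
  off <- drop_offspring(founders, config$offspring_per_family, seed = sub(2L))
  sim <- simulate_phenotypes(off, config, seed = sub(3L))
  retained <- apply_attrition(sim$pheno, config$survival_rates,
                              config$n_retained, seed = sub(4L))
  geno <- subset_individuals(off, retained$id)
  if (config$missing_rate > 0) {
    set_seed_if(sub(5L))
    drop <- runif(length(geno$X)) < config$missing_rate
    geno$X[drop] <- NA
  }
  structure(list(
    genotypes = geno,
    pheno = retained,
    truth = sim$truth[match(retained$id, sim$truth$id), , drop = FALSE],
    survival = attr(retained, "survival"),
    config = config
  ), class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> %d retained individuals, %d SNPs, traits: %s\n",
              nrow(x$pheno), ncol(x$genotypes$X),
              paste(setdiff(names(x$pheno),
                            c("id", "family", "sex", "tank", "group")),
                    collapse = ", ")))
  invisible(x)
}
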