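#' Random k-fold partition of individuals
#'
#' Uniform random partition into `k` folds whose sizes differ by at most
#' one; deterministic under `seed`.
#'
#' @param ids individual ids.
#' @param k number of folds (default 5).
#' @param seed optional integer seed.
#' @return Tibble with columns id, fold.
#' @export
make_folds <- function(ids, k = 5, seed = NULL) {
  n <- length(ids)
  if (k < 2) abort("`k` must be at least 2.")
  if (k > n) abort("`k` cannot exceed the number of individuals.")
  set_seed_if(seed)
  shuffled <- sample(ids)
  tibble(id = shuffled, fold = rep_len(seq_len(k), n))[order(match(shuffled, ids)), ]
}

#' Mask validation phenotypes under the CV1 or CV2 strategy
#'
#' CV1 masks only the target trait of the validation individuals, keeping
#' their auxiliary-trait records available to the model; CV2 masks both
#' traits, removing all phenotypic information on the validation set.
#' Training records are untouched.
#'
#' @param pheno phenotype tibble with an `id` column.
#' @param val_ids ids of the validation individuals.
#' @param strategy `"cv1"` or `"cv2"`.
#' @param target target trait column.
#' @param auxiliary auxiliary trait column (required for CV1; optional for
#'   CV2 single-trait runs).
#' @return `pheno` with the masked entries set to `NA`.
#' @export
mask_validation <- function(pheno, val_ids, strategy = c("cv1", "cv2"),
                            target, auxiliary = NULL) {
  strategy <- match.arg(strategy)
  if (!target %in% names(pheno)) {
    abort(sprintf("target trait `%s` is not a phenotype column.", target))
  }
  if (!is.null(auxiliary) && !auxiliary %in% names(pheno)) {
    abort(sprintf("auxiliary trait `%s` is not a phenotype column.", auxiliary))
  }
  if (strategy == "cv1" && is.null(auxiliary)) {
    abort("CV1 requires an auxiliary trait to retain.")
  }
  val <- pheno$id %in% val_ids
  pheno[[target]][val] <- NA_real_
  if (strategy == "cv2" && !is.null(auxiliary)) {
    pheno[[auxiliary]][val] <- NA_real_
  }
  pheno
}

#' Prediction accuracy: Pearson correlation of phenotype and GEBV
#'
#' Computed on validation individuals only, between the raw observed
#' phenotype and the predicted GEBV.
#'
#' @param observed,gebv numeric vectors over the same individuals.
#' @return Pearson correlation, or `NA` (with a warning) when either vector
#'   has zero variance.
#' @export
cv_accuracy <- function(observed, gebv) {
  ok <- complete.cases(observed, gebv)
  if (sum(ok) < 3) abort("need at least 3 validation individuals.")
  if (sd(observed[ok]) == 0 || sd(gebv[ok]) == 0) {
    warn("zero variance in observed phenotypes or GEBVs; accuracy undefined.")
    return(NA_real_)
  }
  cor(observed[ok], gebv[ok])
}

#' Prediction bias: regression slope of phenotype on GEBV
#'
#' Ordinary least-squares slope (intercept included) of the observed
#' phenotype on the GEBV in the validation set; 1 indicates an unbiased
#' prediction, values below 1 overdispersed GEBVs.
#'
#' @inheritParams cv_accuracy
#' @return The slope, or `NA` (with a warning) when the GEBVs have zero
#'   variance.
#' @export
cv_bias <- function(observed, gebv) {
  ok <- complete.cases(observed, gebv)
  if (sum(ok) < 3) abort("need at least 3 validation individuals.")
  if (var(gebv[ok]) == 0) {
    warn("zero variance in GEBVs; bias undefined.")
    return(NA_real_)
  }
  cov(observed[ok], gebv[ok]) / var(gebv[ok])
}

#' k-fold CV1/CV2 cross-validation of genomic prediction
#'
#' For each fold (and repeat), masks the validation phenotypes according to
#' the strategy, refits the model on the masked data (variance components
#' re-estimated inside every training fold by default, the leakage-free
#' choice), solves the mixed-model equations, and scores accuracy
#' ([cv_accuracy()]) and bias ([cv_bias()]) of the target-trait GEBVs on the
#' fold's validation individuals. Repeats are independent partitions.
#'
#' @param pheno phenotype tibble.
#' @param grm a [build_grm()] result.
#' @param target target trait column.
#' @param auxiliary auxiliary trait column for two-trait models (`NULL` for
#'   a single-trait run).
#' @param strategy `"cv1"` (auxiliary phenotypes retained in validation) or
#'   `"cv2"`; single-trait runs are CV2 by construction.
#' @param k folds (default 5).
#' @param repeats independent repetitions of the whole partition (default 5).
#' @param seed integer seed driving every partition.
#' @param vc optional variance components (list `sigma_a`, `sigma_e`) to fix
#'   instead of re-estimating per fold.
#' @param fixed fixed-effect formula, as in [fit_gblup()].
#' @param max_iter,tol,par_tol REML controls for the per-fold fits (defaults
#'   looser than [fit_gblup()] since per-fold components are nuisance
#'   estimates).
#' @return An object of class `gblup_cv` with per-fold results and averages.
#' @export
run_cv <- function(pheno, grm, target, auxiliary = NULL,
                   strategy = if (is.null(auxiliary)) "cv2" else "cv1",
                   k = 5, repeats = 5, seed = NULL, vc = NULL,
                   fixed = ~ sex + group + sex:group,
                   max_iter = 100, tol = 1e-6, par_tol = 1e-3) {
  strategy <- tolower(strategy)
  if (!strategy %in% c("cv1", "cv2")) abort("`strategy` must be cv1 or cv2.")
  if (strategy == "cv1" && is.null(auxiliary)) {
    abort("CV1 requires an auxiliary trait.")
  }
  traits <- c(target, auxiliary)
  label <- paste(traits, collapse = "-")

  fold_rows <- list()
  for (r in seq_len(repeats)) {
    rep_seed <- if (is.null(seed)) NULL else (as.integer(seed) * 131L + r) %% 2147483629L
    folds <- make_folds(pheno$id, k, seed = rep_seed)
    for (f in seq_len(k)) {
      val_ids <- folds$id[folds$fold == f]
      masked <- mask_validation(pheno, val_ids, strategy, target, auxiliary)
      res <- tryCatch({
        if (is.null(vc)) {
          fit <- fit_gblup(masked, grm, traits, fixed = fixed,
                           max_iter = max_iter, tol = tol, par_tol = par_tol)
          gebv <- fit$gebv
          conv <- fit$converged
        } else {
          design <- build_design(masked, grm, traits, fixed)
          gebv <- solve_mme(design, grm, vc)$gebv
          conv <- TRUE
        }
        g <- gebv$gebv[gebv$trait == target][match(val_ids,
                                                   gebv$id[gebv$trait == target])]
        obs_y <- pheno[[target]][match(val_ids, pheno$id)]
        list(accuracy = cv_accuracy(obs_y, g),
             bias = cv_bias(obs_y, g),
             converged = conv)
      }, error = function(e) {
        warn(sprintf("fold %d (repeat %d) failed: %s", f, r, conditionMessage(e)))
        list(accuracy = NA_real_, bias = NA_real_, converged = FALSE)
      })
      if (!res$converged) {
        warn(sprintf("fold %d (repeat %d) did not converge; excluded.", f, r))
      }
      fold_rows[[length(fold_rows) + 1L]] <- tibble(
        rep = r, fold = f, n_val = length(val_ids),
        accuracy = res$accuracy, bias = res$bias, converged = res$converged
      )
    }
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  use <- folds_tbl$converged & !is.na(folds_tbl$accuracy)
  structure(list(
    model = label,
    target = target,
    auxiliary = auxiliary,
    strategy = toupper(strategy),
    k = k,
    repeats = repeats,
    folds = folds_tbl,
    accuracy = mean(folds_tbl$accuracy[use]),
    bias = mean(folds_tbl$bias[use & !is.na(folds_tbl$bias)]),
    n_excluded = sum(!use),
    reestimated = is.null(vc)
  ), class = "gblup_cv")
}

#' @export
print.gblup_cv <- function(x, ...) {
  cat(sprintf("<gblup_cv> %s (%s), %d-fold x %d repeats\n",
              x$model, x$strategy, x$k, x$repeats))
  cat(sprintf("  accuracy %.3f | bias %.3f%s\n", x$accuracy, x$bias,
              if (x$n_excluded) sprintf(" | %d folds excluded", x$n_excluded) else ""))
  invisible(x)
}

#' @rdname run_cv
#' @param x a `gblup_cv` object.
#' @param ... ignored.
#' @export
tidy.gblup_cv <- function(x, ...) {
  dplyr::mutate(x$folds, model = x$model, strategy = x$strategy,
                .before = 1)
}

#' @rdname run_cv
#' @export
glance.gblup_cv <- function(x, ...) {
  tibble(model = x$model, strategy = x$strategy, target = x$target,
         accuracy = x$accuracy, bias = x$bias,
         sd_accuracy = sd(x$folds$accuracy, na.rm = TRUE),
         n_folds = nrow(x$folds), n_excluded = x$n_excluded)
}

#' Per-fold accuracy and bias of a cross-validation run
#'
#' @param object a [run_cv()] result.
#' @param ... ignored.
#' @return A ggplot showing per-fold accuracies and biases with their means.
#' @export
autoplot.gblup_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$folds, c("accuracy", "bias"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s (%s): per-fold metrics", object$model,
                                  object$strategy)) +
    ggplot2::theme_minimal()
}

#' Relative improvement of a model over a baseline accuracy
#'
#' `100 * (acc_model - acc_baseline) / acc_baseline`, the percentage gain of
#' a multi-trait model over the single-trait baseline.
#'
#' @param acc_model,acc_baseline accuracies (baseline must be positive).
#' @return Percent improvement (vectorised).
#' @export
relative_improvement <- function(acc_model, acc_baseline) {
  if (any(acc_baseline <= 0)) abort("baseline accuracy must be positive.")
  100 * (acc_model - acc_baseline) / acc_baseline
}
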