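#' Meat yield from net meat weight and body weight
#'
#' `MY = MW / BW * 100`, the abdominal-muscle percentage of body weight.
#'
#' @param mw net meat weight (g).
#' @param bw body weight (g); must be strictly positive.
#' @return Meat yield in percent (vectorised).
#' @export
compute_my <- function(mw, bw) {
  if (any(!is.finite(bw) | bw <= 0)) abort("`bw` must be strictly positive.")
  mw / bw * 100
}

#' Descriptive statistics of a trait vector
#'
#' Mean, maximum, minimum, sample standard deviation (n - 1 denominator, the
#' spreadsheet convention) and coefficient of variation `100 * sd / mean`.
#'
#' @param x numeric vector with at least two non-missing values.
#' @return One-row tibble: n, mean, max, min, sd, cv.
#' @export
summary_stats <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) abort("need at least two values.")
  m <- mean(x)
  s <- sd(x)
  cv <- if (m == 0) {
    warn("zero mean; CV undefined.")
    NA_real_
  } else {
    100 * s / m
  }
  tibble(n = length(x), mean = m, max = max(x), min = min(x), sd = s, cv = cv)
}

#' Trait-by-trait descriptive table
#'
#' @param pheno phenotype tibble.
#' @param traits trait columns to summarise; default all of MY, MW, BW, BL,
#'   AL present in `pheno`.
#' @return Tibble with one row per trait.
#' @export
trait_summary <- function(pheno, traits = intersect(c("MY", "MW", "BW", "BL", "AL"),
                                                    names(pheno))) {
  purrr::map_dfr(traits, function(tr) {
    dplyr::mutate(summary_stats(pheno[[tr]]), trait = tr, .before = 1)
  })
}

#' Survival summary over tanks and tank groups
#'
#' Per-tank survival rates (`100 * harvested / stocked`), unweighted group
#' means across tanks, and the overall rate pooled over all tanks.
#'
#' @param records tibble with columns tank, group, stocked, harvested (and
#'   optionally families).
#' @return A list of class `survival_summary` with tibbles `tanks` and
#'   `groups`, plus `overall` (rate, stocked, harvested).
#' @export
survival_summary <- function(records) {
  stopifnot(all(c("tank", "group", "stocked", "harvested") %in% names(records)))
  if (any(records$stocked <= 0)) abort("`stocked` must be positive.")
  if (any(records$harvested > records$stocked)) {
    abort("`harvested` cannot exceed `stocked`.")
  }
  tanks <- dplyr::mutate(records, rate = 100 * .data$harvested / .data$stocked)
  groups <- dplyr::summarise(dplyr::group_by(tanks, .data$group),
                             n_tanks = dplyr::n(),
                             stocked = sum(.data$stocked),
                             harvested = sum(.data$harvested),
                             mean_rate = mean(.data$rate),
                             .groups = "drop")
  structure(list(
    tanks = tanks,
    groups = groups,
    overall = c(rate = 100 * sum(records$harvested) / sum(records$stocked),
                stocked = sum(records$stocked),
                harvested = sum(records$harvested))
  ), class = "survival_summary")
}

#' @export
print.survival_summary <- function(x, ...) {
  cat("<survival_summary>\n")
  for (i in seq_len(nrow(x$groups))) {
    g <- x$groups[i, ]
    cat(sprintf("  group %s: %.2f%% mean over %d tanks (%d/%d)\n",
                g$group, g$mean_rate, g$n_tanks, g$harvested, g$stocked))
  }
  cat(sprintf("  overall: %.2f%% (%d/%d)\n", x$overall["rate"],
              x$overall["harvested"], x$overall["stocked"]))
  invisible(x)
}

#' Two-sample t-test of survival rates between tank groups
#'
#' Compares the per-tank survival rates of the two groups (each group must
#' contribute at least two tanks). The pooled-variance test is the default;
#' the Welch variant is available.
#'
#' @param records as in [survival_summary()], for exactly two groups.
#' @param var_equal pooled-variance test when `TRUE` (default), Welch
#'   otherwise.
#' @return Tibble with statistic, df, p_value, method.
#' @export
survival_t_test <- function(records, var_equal = TRUE) {
  tanks <- survival_summary(records)$tanks
  grp <- split(tanks$rate, tanks$group)
  if (length(grp) != 2) abort("exactly two groups are required.")
  if (any(lengths(grp) < 2)) {
    abort("each group needs at least two tanks for a t-test.")
  }
  method <- if (var_equal) "pooled" else "welch"
  if (sd(grp[[1]]) == 0 && sd(grp[[2]]) == 0 &&
      mean(grp[[1]]) == mean(grp[[2]])) {
    # degenerate case: identical rates everywhere
    return(tibble(statistic = 0, df = sum(lengths(grp)) - 2, p_value = 1,
                  method = method))
  }
  tt <- stats::t.test(grp[[1]], grp[[2]], var.equal = var_equal)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, method = method)
}
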