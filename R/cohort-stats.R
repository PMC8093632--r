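# Two-step balanced bootstrap for cohort medians, CI-overlap significance,
# and CI-normalised effect sizes.

#' One balanced resample of a cohort
#'
#' With `N` the cohort's total sample count and `k` its animals, draws
#' `ceiling(N / k)` values with replacement from each animal, concatenates,
#' and truncates uniformly at random to exactly `N` values. Every animal
#' therefore contributes equally in expectation, regardless of how many
#' samples it originally supplied.
#'
#' @param cohort Named list of per-animal numeric value vectors (all
#'   non-empty and finite).
#' @return Numeric vector of length `N`.
#' @export
balanced_resample <- function(cohort) {
  k <- length(cohort)
  if (k < 1) stop("cohort must contain at least one animal")
  sizes <- lengths(cohort)
  if (any(sizes == 0)) stop("empty animal sample in cohort")
  N <- sum(sizes)
  m <- ceiling(N / k)
  pooled <- unlist(lapply(cohort, function(v)
    v[sample.int(length(v), m, replace = TRUE)]), use.names = FALSE)
  if (length(pooled) > N)
    pooled <- pooled[sample.int(length(pooled), N)]
  pooled
}

#' Balanced-bootstrap median with percentile confidence intervals
#'
#' `B` balanced resamples yield `B` medians; the point estimate is the
#' median of those medians and the confidence intervals are their
#' percentile intervals (2.5/97.5% and 0.5/99.5%). Deterministic under a
#' fixed seed.
#'
#' @param cohort Named list of per-animal numeric vectors.
#' @param B Number of bootstrap replicates (>= 100; 10000 in the reference
#'   protocol).
#' @param seed Integer seed.
#' @param parameter,units Labels carried into the estimate.
#' @return A `cohort_estimate` list: `parameter`, `units`, `median`,
#'   `ci95`, `ci99`, `n_total`, `n_animals`, `B`.
#' @export
bootstrap_median_ci <- function(cohort, B = 10000, seed = 1,
                                parameter = "value", units = "") {
  if (!is.numeric(B) || B < 100) stop("B must be at least 100")
  if (length(cohort) < 1) stop("cohort must contain at least one animal")
  vals <- unlist(cohort, use.names = FALSE)
  if (any(!is.finite(vals))) stop("cohort values must be finite")
  withr::with_seed(as.integer(seed), {
    meds <- vapply(seq_len(B), function(b)
      stats::median(balanced_resample(cohort)), numeric(1))
  })
  est <- structure(list(parameter = parameter, units = units,
                        median = stats::median(meds),
                        ci95 = unname(stats::quantile(meds, c(0.025, 0.975),
                                                      type = 7)),
                        ci99 = unname(stats::quantile(meds, c(0.005, 0.995),
                                                      type = 7)),
                        n_total = length(vals),
                        n_animals = length(cohort), B = as.integer(B)),
                   class = "cohort_estimate")
  est
}

#' @export
print.cohort_estimate <- function(x, ...) {
  cat(sprintf("<cohort_estimate> %s: median %.4g %s, 95%% CI [%.4g, %.4g], 99%% CI [%.4g, %.4g] (n=%d, %d animals, B=%d)\n",
              x$parameter, x$median, x$units, x$ci95[1], x$ci95[2],
              x$ci99[1], x$ci99[2], x$n_total, x$n_animals, x$B))
  invisible(x)
}

#' Compare two cohort estimates
#'
#' Pairwise significance by CI overlap: significant at the 5% level when
#' the two 95% intervals are disjoint, at the 1% level when the 99%
#' intervals are disjoint. Intervals sharing an endpoint count as
#' overlapping (closed intervals, conservative). The effect size is the
#' absolute difference between cohort medians divided by the mean of the
#' two 95% CI widths (`denominator = "halfwidth"` divides by the mean
#' half-width instead).
#'
#' @param a,b `cohort_estimate` objects for the same parameter and units.
#' @param denominator `"width"` (default) or `"halfwidth"`.
#' @param label Optional label (e.g. the leg id) carried into summaries.
#' @return A `cohort_comparison` list: `parameter`, `label`,
#'   `median_a`, `median_b`, `significant_95`, `significant_99`,
#'   `effect_size`, `direction` (sign of `median_b - median_a`).
#' @export
compare_cohorts <- function(a, b, denominator = c("width", "halfwidth"),
                            label = NULL) {
  stopifnot(inherits(a, "cohort_estimate"), inherits(b, "cohort_estimate"))
  denominator <- match.arg(denominator)
  if (!identical(a$parameter, b$parameter) || !identical(a$units, b$units))
    stop(sprintf("cannot compare '%s' [%s] with '%s' [%s]",
                 a$parameter, a$units, b$parameter, b$units))
  disjoint <- function(ia, ib) ia[2] < ib[1] || ib[2] < ia[1]
  sig95 <- disjoint(a$ci95, b$ci95)
  sig99 <- disjoint(a$ci99, b$ci99)
  wa <- a$ci95[2] - a$ci95[1]
  wb <- b$ci95[2] - b$ci95[1]
  den <- mean(c(wa, wb))
  if (denominator == "halfwidth") den <- den / 2
  dmed <- b$median - a$median
  # degenerate (zero-width) intervals: a nonzero shift against zero spread
  # is reported as an infinite effect, not a float-noise quotient
  es <- if (dmed == 0) 0
  else if (den < sqrt(.Machine$double.eps) * max(1, abs(dmed))) Inf
  else abs(dmed) / den
  structure(list(parameter = a$parameter, units = a$units, label = label,
                 median_a = a$median, median_b = b$median,
                 significant_95 = sig95, significant_99 = sig99,
                 effect_size = es, direction = sign(dmed)),
            class = "cohort_comparison")
}

#' Tabulate lesion effects across legs and parameters
#'
#' Formats a set of pairwise comparisons (cohort A = sham, cohort B =
#' lesion) as an effect table: one row per parameter, one column per label
#' (leg), each cell showing a direction arrow (single arrow when only the
#' 95% CIs are disjoint, double when the 99% CIs are too) followed by the
#' effect size; non-significant cells are blank.
#'
#' @param comparisons List of `cohort_comparison` objects with `label` set.
#' @param digits Effect-size digits.
#' @return Character data frame, parameters x labels.
#' @export
summarize_lesion_effects <- function(comparisons, digits = 2) {
  if (length(comparisons) == 0)
    return(data.frame())
  for (cmp in comparisons)
    stopifnot(inherits(cmp, "cohort_comparison"))
  pars <- unique(vapply(comparisons, function(x) x$parameter, character(1)))
  labs <- unique(vapply(comparisons, function(x)
    x$label %||% "all", character(1)))
  tab <- matrix("", length(pars), length(labs),
                dimnames = list(pars, labs))
  for (cmp in comparisons) {
    cell <- ""
    if (cmp$significant_95 && cmp$direction != 0) {
      arrow <- if (cmp$direction > 0) "↑" else "↓"
      if (cmp$significant_99) arrow <- paste0(arrow, arrow)
      cell <- paste(arrow, format(round(cmp$effect_size, digits)))
    }
    tab[cmp$parameter, cmp$label %||% "all"] <- cell
  }
  as.data.frame(tab, stringsAsFactors = FALSE)
}
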