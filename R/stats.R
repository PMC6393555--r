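# Cohort-level inference: paired sign-flip Monte-Carlo permutation tests for
# hemispheric differences, Bonferroni adjustment, robust summaries.

#' Paired sample of left/right hemisphere values
#'
#' Pairs one value per subject and hemisphere (typically assortativity
#' coefficients). Subjects with an undefined value on either side are
#' excluded, with the exclusion count recorded.
#'
#' @param left_values,right_values Numeric vectors, one value per subject
#'   (`NA` = undefined).
#' @param subjects Optional subject ids.
#' @return An object of class `paired_sample` with elements `subjects`,
#'   `left`, `right`, `n_excluded`.
#' @export
paired_sample <- function(left_values, right_values, subjects = NULL) {
  if (length(left_values) != length(right_values))
    stop("left and right value vectors must have equal length")
  if (is.null(subjects)) subjects <- seq_along(left_values)
  ok <- !is.na(left_values) & !is.na(right_values)
  structure(list(subjects = subjects[ok],
                 left = as.numeric(left_values[ok]),
                 right = as.numeric(right_values[ok]),
                 n_excluded = sum(!ok)),
            class = "paired_sample")
}

#' Paired sign-flip Monte-Carlo permutation test
#'
#' Tests whether the median paired difference (left minus right) differs from
#' zero. The observed statistic is `T = median(left - right)`; the null
#' distribution is approximated by conditional Monte Carlo over the `2^n`
#' equally likely sign assignments, flipping each subject's difference
#' independently with probability 1/2. The two-tailed p-value uses the
#' add-one correction `p = (1 + #{|T_perm| >= |T_obs|}) / (1 + B)`, so finite
#' Monte Carlo never reports p = 0.
#'
#' @param sample A `paired_sample` with at least 2 usable pairs.
#' @param n_permutations Monte-Carlo draws (default 10000).
#' @param seed Integer seed.
#' @param statistic `"median"` (default) or `"mean"` of the paired
#'   differences.
#' @return An object of class `permutation_result`: `observed_stat`,
#'   `p_value`, `p_adjusted` (`NA` until adjusted), `n_permutations`, `n_pairs`,
#'   `seed`, `degenerate` (all differences zero).
#' @export
paired_permutation_test <- function(sample, n_permutations = 10000L, seed = 1L,
                                    statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(sample, "paired_sample"))
  d <- sample$left - sample$right
  n <- length(d)
  if (n < 2) stop("need at least 2 usable pairs")
  stat_fun <- if (statistic == "median") stats::median else mean
  t_obs <- stat_fun(d)
  if (all(d == 0)) {
    return(structure(list(observed_stat = 0, p_value = 1, p_adjusted = NA_real_,
                          n_permutations = as.integer(n_permutations),
                          n_pairs = n, seed = as.integer(seed),
                          statistic = statistic, degenerate = TRUE),
                     class = "permutation_result"))
  }
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                  nrow = n_permutations)
  flipped <- signs * rep(d, each = n_permutations)
  t_perm <- if (statistic == "median") {
    apply(flipped, 1, stats::median)
  } else {
    rowMeans(flipped)
  }
  p <- (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (1 + n_permutations)
  structure(list(observed_stat = t_obs, p_value = min(1, p),
                 p_adjusted = NA_real_,
                 n_permutations = as.integer(n_permutations),
                 n_pairs = n, seed = as.integer(seed),
                 statistic = statistic, degenerate = FALSE),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s diff = %.4g, p = %.4g (%d pairs, %d perms)%s\n",
              x$statistic, x$observed_stat, x$p_value, x$n_pairs,
              x$n_permutations,
              if (isTRUE(x$degenerate)) " [degenerate: all differences zero]" else ""))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the family size and clips at 1; order is
#' preserved. The family is the set of tests run together in one pipeline
#' invocation.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bonferroni_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  pmin(1, p_values * length(p_values))
}

#' Robust cohort summary
#'
#' Median and raw median absolute deviation (MAD, about the median, no
#' consistency constant) of a vector of per-subject values; undefined values
#' (`NA`) are excluded and counted.
#'
#' @param values Numeric vector (may contain `NA` for undefined subjects).
#' @return A list: `median`, `mad`, `n_used`, `n_undefined`.
#' @export
cohort_summary <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("no defined values to summarize")
  med <- stats::median(v)
  list(median = med, mad = stats::median(abs(v - med)),
       n_used = length(v), n_undefined = sum(is.na(values)))
}
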