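#' Compare two groups of quantum-dot measurements
#'
#' Two-sided Wilcoxon rank-sum test (brightness and blinking-ratio
#' distributions are typically skewed, so a rank test is preferred over a
#' t-test), with the usual significance-star convention and the two effect
#' summaries used for reporting: the relative difference of means
#' `100 (mean_a - mean_b) / mean_b` (a "decrease of 40%" when -40) and the
#' ratio of means `100 mean_a / mean_b` (an "increase to 403%" when 403).
#'
#' @param a,b Numeric measurement vectors, each with at least 2 values.
#' @return An object of class `group_comparison`: `p_value`, `stars` (one of
#'   `ns, *, **, ***, ****` at thresholds 0.05, 0.01, 0.001, 0.0001),
#'   `effect_pct` (relative difference of means, %), `ratio_pct` (ratio of
#'   means, %), `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @examples
#' compare_groups(rnorm(20, 10), rnorm(20, 12))
#' @export
compare_groups <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  structure(list(p_value = p, stars = significance_stars(p),
                 effect_pct = relative_difference_pct(mean(a), mean(b)),
                 ratio_pct = ratio_of_means_pct(mean(a), mean(b)),
                 mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Rank-sum comparison: mean %.4g (n=%d) vs %.4g (n=%d)\n",
              x$mean_a, x$n_a, x$mean_b, x$n_b))
  cat(sprintf("  p = %.3g (%s)\n", x$p_value, x$stars))
  cat(sprintf("  relative difference of means: %+.1f%%  (ratio %.0f%%)\n",
              x$effect_pct, x$ratio_pct))
  invisible(x)
}

#' Significance stars for a p-value
#'
#' Thresholds 0.05, 0.01, 0.001, 0.0001 mapping to `*` through `****`,
#' `ns` otherwise.
#'
#' @param p A p-value.
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
significance_stars <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Relative difference of two means, in percent
#'
#' `100 (mean_a - mean_b) / mean_b`: negative values read as a decrease.
#'
#' @param mean_a,mean_b Group means (`mean_b != 0`).
#' @return Percent relative difference.
#' @examples
#' relative_difference_pct(0.44, 0.74)  # about -40.5: a 40% decrease
#' @export
relative_difference_pct <- function(mean_a, mean_b) {
  if (mean_b == 0) stop("`mean_b` must be nonzero", call. = FALSE)
  100 * (mean_a - mean_b) / mean_b
}

#' Ratio of two means, in percent
#'
#' `100 mean_a / mean_b`, the "increase to X%" form.
#'
#' @param mean_a,mean_b Group means (`mean_b != 0`).
#' @return Percent ratio.
#' @examples
#' ratio_of_means_pct(826, 205)  # about 403
#' @export
ratio_of_means_pct <- function(mean_a, mean_b) {
  if (mean_b == 0) stop("`mean_b` must be nonzero", call. = FALSE)
  100 * mean_a / mean_b
}
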