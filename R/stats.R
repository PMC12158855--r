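# Pairwise statistical comparison of per-frame metrics across conditions.

#' Pairwise comparison of condition groups with Bonferroni correction
#'
#' Two-sample t-tests (pooled-variance Student by default; Welch with
#' `var_equal = FALSE`) for every pair of conditions, Bonferroni-adjusted
#' over the family of all pairs, with confidence intervals for the mean
#' differences. A degenerate pair (both groups zero-variance with identical
#' means) is reported with p = 1 and flagged.
#'
#' Per-frame trajectory values are autocorrelated; the default replicates
#' the direct frame-wise test. `block` > 1 thins each group to every
#' `block`-th value as a simple decorrelation, clearly recorded in the
#' output attribute.
#'
#' @param groups Named list of numeric vectors, or a data frame with
#'   `condition` and `value` columns.
#' @param var_equal Pooled (Student) vs Welch.
#' @param conf_level Confidence level for the intervals.
#' @param alpha Significance level applied to adjusted p-values.
#' @param block Optional thinning stride (1 = use every frame).
#' @return A `comparison_table` tibble: `group1`, `group2`, `estimate`,
#'   `conf_low`, `conf_high`, `p_value`, `p_adjusted`, `significant`,
#'   `degenerate`.
#' @export
pairwise_compare <- function(groups, var_equal = TRUE, conf_level = 0.95,
                             alpha = 0.05, block = 1L) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$condition)
  }
  if (length(groups) < 2L) abort("need at least two groups to compare")
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    abort("each group needs at least 2 values")
  }
  if (block > 1L) {
    groups <- lapply(groups, function(v) v[seq(1, length(v), by = block)])
  }
  pairs <- utils::combn(names(groups), 2)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(k) {
    a <- groups[[pairs[1, k]]]; b <- groups[[pairs[2, k]]]
    degenerate <- sd(a) == 0 && sd(b) == 0
    if (degenerate && mean(a) == mean(b)) {
      tibble(group1 = pairs[1, k], group2 = pairs[2, k],
             estimate = 0, conf_low = 0, conf_high = 0,
             p_value = 1, degenerate = TRUE)
    } else {
      tt <- t.test(a, b, var.equal = var_equal, conf.level = conf_level)
      tibble(group1 = pairs[1, k], group2 = pairs[2, k],
             estimate = unname(diff(rev(tt$estimate))),
             conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
             p_value = tt$p.value, degenerate = FALSE)
    }
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "bonferroni")
  out$significant <- out$p_adjusted < alpha
  out <- out[, c("group1", "group2", "estimate", "conf_low", "conf_high",
                 "p_value", "p_adjusted", "significant", "degenerate")]
  structure(out, class = c("comparison_table", class(tibble())),
            var_equal = var_equal, conf_level = conf_level, alpha = alpha,
            n_comparisons = n_pairs, block = block)
}
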