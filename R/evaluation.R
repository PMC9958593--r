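#' Paired before/after comparison of accuracies
#'
#' Computes per-pair differences (`after - before`), their mean and sample
#' standard deviation (n-1), the count of strict improvements, the two-sided
#' paired t statistic with `df = n - 1`, and the Shapiro-Wilk normality p
#' value of the differences.
#'
#' @param before,after numeric accuracy vectors (%) of equal length >= 3.
#' @return list with `n`, `mean_before`, `mean_after`, `sd_before`,
#'   `sd_after`, `mean_diff`, `sd_diff`, `n_improved`, `t_stat`, `df`,
#'   `p_value`, `sw_p_value`.
#' @export
paired_comparison <- function(before, after) {
  if (length(before) != length(after)) {
    stopf("before (%d) and after (%d) must have equal length",
          length(before), length(after))
  }
  n <- length(before)
  if (n < 3) stopf("need at least 3 pairs, got %d", n)
  d <- after - before
  sd_d <- sd(d)
  if (sd_d == 0) stopf("zero-variance differences: paired t undefined")
  t_stat <- mean(d) / (sd_d / sqrt(n))
  list(n = n,
       mean_before = mean(before), mean_after = mean(after),
       sd_before = sd(before), sd_after = sd(after),
       mean_diff = mean(d), sd_diff = sd_d,
       n_improved = sum(d > 0),
       t_stat = t_stat, df = n - 1L,
       p_value = 2 * pt(-abs(t_stat), n - 1),
       sw_p_value = shapiro.test(d)$p.value)
}

#' Summary row of a per-subject before/after accuracy table
#'
#' Means and sample standard deviations of both accuracy columns and of
#' their differences, plus the strict-improvement count — the shape of the
#' packaged table's average row.
#'
#' @param table data.frame with columns `before` and `after` (%).
#' @return list with `mean_before`, `sd_before`, `mean_after`, `sd_after`,
#'   `mean_diff`, `sd_diff`, `n_improved`.
#' @export
summarize_table7 <- function(table = load_table7_fixture()) {
  d <- table$after - table$before
  list(mean_before = mean(table$before), sd_before = sd(table$before),
       mean_after = mean(table$after), sd_after = sd(table$after),
       mean_diff = mean(d), sd_diff = sd(d), n_improved = sum(d > 0))
}
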