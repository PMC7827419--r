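#' Two-sample Student's t-test on per-line values
#'
#' Pooled-variance (Student's) two-sided t-test, the classical test for
#' comparing small per-group means such as mutation densities or
#' recombination counts over three lines per condition.  Welch's
#' unequal-variance test is available behind `welch = TRUE`.  Degenerate
#' inputs are handled explicitly: zero pooled variance with equal means
#' gives `t = 0, p = 1`; zero variance with unequal means is flagged
#' `degenerate` (the statistic is unbounded).
#'
#' @param x,y Numeric vectors, each of length at least 2.
#' @param welch Use Welch's correction instead of pooling (default
#'   `FALSE`).
#' @return List: `statistic` (t), `df`, `p.value`, `degenerate`.
#' @examples
#' two_sample_ttest(c(10, 12, 14), c(20, 22, 24))
#' @export
two_sample_ttest <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least two values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, df = length(x) + length(y) - 2,
                  p.value = 1, degenerate = FALSE))
    return(list(statistic = NA_real_,
                df = length(x) + length(y) - 2,
                p.value = NA_real_, degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, degenerate = FALSE)
}

#' Pearson chi-square test on a groups-by-categories spectrum table
#'
#' Tests homogeneity of substitution-category composition across groups
#' on raw counts (never percentages).  Groups with zero total are
#' excluded with a warning; a warning is also raised when any expected
#' count falls below 5, where the chi-square approximation weakens.
#'
#' @param counts Matrix of counts, categories x groups (e.g.
#'   `spectrum_table()$counts`).
#' @return List: `statistic` (chi-square), `df`, `p.value`, `expected`.
#' @examples
#' spectrum_chisq(cbind(a = c(20, 10), b = c(10, 20)))
#' @export
spectrum_chisq <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least two groups")
  tot <- colSums(counts)
  if (any(tot == 0)) {
    warning("excluding group(s) with zero total: ",
            paste(colnames(counts)[tot == 0], collapse = ", "))
    counts <- counts[, tot > 0, drop = FALSE]
    if (ncol(counts) < 2) stop("fewer than two non-empty groups remain")
  }
  # drop all-zero categories: they contribute no information and break
  # the expected-count computation
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ht$expected < 5))
    warning("expected count below 5; chi-square approximation may be poor")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, expected = ht$expected)
}

#' Category-wise chi-square tests (each category against the rest)
#'
#' For every substitution category, tests a 2 x groups table of
#' (this category, all others) across groups — one way of asking which
#' individual category differs in composition between irradiated
#' tissues.  The full-table homogeneity test is [spectrum_chisq()].
#'
#' @param counts Matrix of counts, categories x groups.
#' @return Data frame `category`, `statistic`, `df`, `p.value`.
#' @export
spectrum_chisq_by_category <- function(counts) {
  counts <- as.matrix(counts)
  out <- lapply(rownames(counts), function(cat) {
    tab <- rbind(counts[cat, ], colSums(counts) - counts[cat, ])
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(category = cat, statistic = unname(ht$statistic),
               df = unname(ht$parameter), p.value = ht$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-group mean, standard error and n
#'
#' @param values Numeric per-line values.
#' @param group Parallel group labels.
#' @return Data frame `group`, `n`, `mean`, `se` (`NA` when `n < 2`).
#' @export
group_summary <- function(values, group) {
  stopifnot(length(values) == length(group))
  lv <- unique(group)
  out <- lapply(lv, function(g) {
    v <- values[group == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               se = if (length(v) >= 2) stats::sd(v) / sqrt(length(v))
                    else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' All pairwise Student's t-tests between groups
#'
#' No multiple-testing correction is applied by default, matching the
#' convention of reporting each pairwise comparison at nominal alpha;
#' set `bonferroni = TRUE` to adjust.
#'
#' @param values,group As in [group_summary()].
#' @param welch Passed to [two_sample_ttest()].
#' @param bonferroni Adjust p-values by the number of comparisons.
#' @return Data frame `group1`, `group2`, `statistic`, `df`, `p.value`,
#'   `degenerate`.
#' @export
pairwise_ttests <- function(values, group, welch = FALSE,
                            bonferroni = FALSE) {
  lv <- unique(group)
  if (length(lv) < 2) stop("need at least two groups")
  pairs <- utils::combn(lv, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    ht <- two_sample_ttest(values[group == g1], values[group == g2],
                           welch = welch)
    data.frame(group1 = g1, group2 = g2, statistic = ht$statistic,
               df = ht$df, p.value = ht$p.value,
               degenerate = ht$degenerate, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (bonferroni)
    res$p.value <- pmin(1, res$p.value * nrow(res))
  res
}
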