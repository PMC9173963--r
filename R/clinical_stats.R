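# Contingency and diagnostic-accuracy statistics for clinical evaluation
# tables: sensitivity/specificity/accuracy from a confusion matrix, Pearson
# chi-square homogeneity, the two-sided Fisher exact test for small 2x2
# tables, and exact recovery of integer counts from percentages printed to
# two decimals.

# Round half away from zero (printed clinical percentages use this
# convention, unlike R's banker rounding).
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5) / p
}

#' Diagnostic performance of a binary classifier
#'
#' Sensitivity `100 * tp / (tp + fn)`, specificity `100 * tn / (tn + fp)`,
#' and accuracy `100 * (tp + tn) / total`, reported in percent to two
#' decimals.
#'
#' @param tp,fp,tn,fn nonnegative integer counts.
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy` (%).
#' @export
diagnostic_performance <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (tp + fn == 0 || tn + fp == 0) {
    stop("both a positive and a negative margin are required", call. = FALSE)
  }
  round_half_away(c(
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy    = 100 * (tp + tn) / sum(counts)
  ), 2)
}

check_count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("table entries must be nonnegative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("table must have a positive grand total", call. = FALSE)
  counts
}

#' Pearson chi-square test of homogeneity
#'
#' `sum((O - E)^2 / E)` with expected counts from the row/column margins, no
#' continuity correction, `df = (r - 1)(c - 1)`, upper-tail p-value.
#'
#' @param counts r x c matrix of nonnegative integer counts.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_homogeneity <- function(counts) {
  counts <- check_count_table(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) {
    stop("all expected counts must be positive", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = unname(ct$expected))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value obtained by summing, over the hypergeometric distribution
#' of the top-left cell given the margins, the probabilities of all tables
#' at most as probable as the observed one.
#'
#' @param counts 2 x 2 matrix of nonnegative integer counts.
#' @return The two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(counts) {
  counts <- check_count_table(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("table must be 2 x 2", call. = FALSE)
  stats::fisher.test(counts)$p.value
}

#' Recover integer counts from printed percentages
#'
#' Finds the integer composition of `n` whose percentages, rounded half away
#' from zero to two decimals, reproduce the printed values.  The search is
#' exhaustive; if no composition or more than one matches, an error reports
#' the ambiguity, so a returned vector is guaranteed unique.
#'
#' @param percentages printed percentages (two decimals), near-summing to 100.
#' @param n group size.
#' @return Integer vector summing to `n`.
#' @export
counts_from_percentages <- function(percentages, n) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (abs(sum(percentages) - 100) > 0.05 * length(percentages)) {
    stop("percentages must approximately sum to 100", call. = FALSE)
  }
  cand <- lapply(percentages, function(p) {
    k <- 0:n
    k[round_half_away(100 * k / n, 2) == round_half_away(p, 2)]
  })
  if (any(lengths(cand) == 0)) {
    stop("no integer count reproduces the printed percentages", call. = FALSE)
  }
  combos <- as.matrix(expand.grid(cand))
  hits <- combos[rowSums(combos) == n, , drop = FALSE]
  if (nrow(hits) == 0) {
    stop("no composition of n reproduces the printed percentages", call. = FALSE)
  }
  if (nrow(hits) > 1) {
    stop("percentages are ambiguous: multiple compositions match", call. = FALSE)
  }
  as.integer(hits[1, ])
}

#' Welch two-sample t test
#'
#' Thin wrapper for mean comparisons of measurement data between two groups
#' (unequal variances).
#'
#' @param x,y numeric vectors.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
welch_t <- function(x, y) {
  tt <- stats::t.test(x, y)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
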