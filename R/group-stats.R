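# Group-level inference: one-sample and paired t-tests on per-subject
# change statistics, Bonferroni family-wise correction, and rating-item
# correlation screens. The t and correlation machinery is stats::t.test /
# stats::cor.test; this module fixes the conventions (two-tailed, n - 1 df,
# paired within-subject contrast) and the result container.

new_test_result <- function(measure, estimate, t, p, n, df,
                            alpha_corrected) {
  structure(list(measure = measure, estimate = estimate, t = t, p = p,
                 n = n, df = df, alpha_corrected = alpha_corrected,
                 significant = p < alpha_corrected),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat("<test_result> ", x$measure, ": t(", x$df, ") = ", signif(x$t, 4),
      ", p = ", signif(x$p, 4), ", n = ", x$n,
      if (x$significant) " *" else "",
      "  [alpha = ", signif(x$alpha_corrected, 4), "]\n", sep = "")
  invisible(x)
}

#' One-sample two-tailed t-test
#'
#' Classical one-sample t-test of the mean against `null_mean` with
#' `n - 1` degrees of freedom, two-tailed — the test applied to per-subject
#' percent-change values against zero.
#'
#' @param values numeric vector, n >= 2, non-degenerate.
#' @param null_mean null-hypothesis mean (default 0).
#' @param alpha_corrected per-test significance threshold (e.g. a
#'   [bonferroni_threshold()]).
#' @param measure label carried into the result.
#' @return a `test_result` with fields `estimate` (sample mean), `t`, `p`,
#'   `n`, `df`, `alpha_corrected`, `significant`.
#' @export
one_sample_t <- function(values, null_mean = 0, alpha_corrected = 0.05,
                         measure = "one_sample") {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values")
  if (stats::sd(values) == 0)
    stop("degenerate sample: zero variance")
  ht <- stats::t.test(values, mu = null_mean, alternative = "two.sided")
  new_test_result(measure, unname(ht$estimate), unname(ht$statistic),
                  ht$p.value, length(values), unname(ht$parameter),
                  alpha_corrected)
}

#' Bonferroni-corrected per-test threshold
#'
#' `alpha_family / m_tests`. The companion display value rounds to 3
#' decimals, reproducing thresholds as conventionally printed (0.05/9 is
#' displayed as 0.006, 0.05/23 as 0.002); the full-precision value is what
#' significance decisions use.
#'
#' @param alpha_family family-wise alpha in (0, 1).
#' @param m_tests number of tests in the family (>= 1).
#' @return list with `threshold` (full precision) and `display` (rounded to
#'   3 decimals).
#' @export
bonferroni_threshold <- function(alpha_family, m_tests) {
  if (alpha_family <= 0 || alpha_family >= 1)
    stop("alpha_family must lie in (0, 1)")
  m_tests <- stopifnot_count(m_tests, "m_tests", min = 1L)
  thr <- alpha_family / m_tests
  list(threshold = thr, display = display_threshold(thr))
}

#' Paired condition contrast of change scores
#'
#' Two-tailed t-test of drug-arm vs. placebo-arm per-subject change scores:
#' paired (default, for a within-subject design) on the per-subject
#' differences, or unpaired Welch otherwise.
#'
#' @param drug_changes,placebo_changes numeric vectors of per-subject change
#'   scores; equal length required when paired.
#' @param paired within-subject pairing (default `TRUE`).
#' @param alpha_corrected per-test threshold.
#' @param measure label carried into the result.
#' @return a `test_result`; `estimate` is the mean (paired) difference.
#' @export
condition_contrast <- function(drug_changes, placebo_changes,
                               paired = TRUE, alpha_corrected = 0.05,
                               measure = "condition_contrast") {
  drug_changes <- as.numeric(drug_changes)
  placebo_changes <- as.numeric(placebo_changes)
  if (paired && length(drug_changes) != length(placebo_changes))
    stop("paired contrast needs equal-length change vectors (",
         length(drug_changes), " vs ", length(placebo_changes), ")")
  if (length(drug_changes) < 2L) stop("need at least 2 subjects")
  if (paired) {
    d <- drug_changes - placebo_changes
    if (stats::sd(d) == 0) {
      if (mean(d) != 0)
        stop("degenerate contrast: constant nonzero difference")
      # identical change vectors: no evidence of a difference
      return(new_test_result(measure, 0, 0, 1, length(d),
                             length(d) - 1L, alpha_corrected))
    }
  }
  ht <- stats::t.test(drug_changes, placebo_changes, paired = paired,
                      alternative = "two.sided")
  new_test_result(measure, unname(ht$estimate)[1L], unname(ht$statistic),
                  ht$p.value, length(drug_changes), unname(ht$parameter),
                  alpha_corrected)
}

#' Correlate a neural change score against subjective rating items
#'
#' Per-item Pearson correlation of one per-subject neural change score
#' against each of m rating items, with two-tailed p-values and Bonferroni
#' significance at `alpha_family / m`. A constant item yields `NA` results
#' for that item only.
#'
#' @param neural_change_scores numeric vector, one value per subject
#'   (n >= 3).
#' @param rating_items matrix or data.frame, subjects x items.
#' @param alpha_family family-wise alpha (default 0.05).
#' @return data.frame with one row per item: `item`, `r`, `r_squared`, `p`,
#'   `significant`; the Bonferroni threshold is attached as attribute
#'   `"alpha_corrected"`.
#' @export
rating_correlation <- function(neural_change_scores, rating_items,
                               alpha_family = 0.05) {
  scores <- as.numeric(neural_change_scores)
  items <- as.matrix(rating_items)
  if (length(scores) < 3L) stop("need at least 3 subjects")
  if (nrow(items) != length(scores))
    stop("rating_items must have one row per subject")
  if (stats::sd(scores) == 0)
    stop("neural change scores are constant; correlations undefined")
  m <- ncol(items)
  thr <- bonferroni_threshold(alpha_family, m)$threshold
  item_names <- colnames(items)
  if (is.null(item_names)) item_names <- sprintf("item_%02d", seq_len(m))
  res <- lapply(seq_len(m), function(j) {
    if (stats::sd(items[, j]) == 0)
      return(data.frame(item = item_names[j], r = NA_real_,
                        r_squared = NA_real_, p = NA_real_,
                        significant = NA))
    ht <- stats::cor.test(scores, items[, j])
    r <- unname(ht$estimate)
    data.frame(item = item_names[j], r = r, r_squared = r^2,
               p = ht$p.value, significant = ht$p.value < thr)
  })
  out <- do.call(rbind, res)
  attr(out, "alpha_corrected") <- thr
  out
}
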