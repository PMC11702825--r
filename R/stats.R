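#' Normality-routed two-group comparison
#'
#' The comparison rule used for every biomarker: Shapiro-Wilk normality
#' tests on both samples; if both p-values exceed `normality_alpha` a
#' two-sided two-sample t test is applied (Welch by default), otherwise the
#' Wilcoxon rank-sum test. The Wilcoxon test uses exact enumeration when
#' both samples have at most 20 observations and no ties, and the
#' continuity-corrected normal approximation otherwise. No multiple-testing
#' correction is applied; raw p-values are reported per comparison.
#'
#' Constant samples (for which the Shapiro-Wilk statistic is undefined) are
#' handled explicitly: two identical constant groups compare as a null
#' result (`test = "degenerate"`, p = 1); a single constant sample routes
#' to the rank-sum test.
#'
#' @param sample_a,sample_b Numeric vectors (each n >= 3; the Shapiro-Wilk
#'   test is undefined below that).
#' @param normality_alpha Normality threshold (default 0.05).
#' @param var_equal Assume equal variances in the t route (default FALSE).
#' @return Object of class `group_comparison`: list with group summaries,
#'   both Shapiro-Wilk p-values, `test` (`"t"`, `"wilcoxon"` or
#'   `"degenerate"`), the test `statistic` and `p_value`, and the sample
#'   sizes.
#' @export
compare_groups <- function(sample_a, sample_b, normality_alpha = 0.05,
                           var_equal = FALSE) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (length(sample_a) < 3L || length(sample_b) < 3L)
    stop("each sample needs at least 3 finite observations")
  base <- list(
    mean_a = mean(sample_a), sd_a = stats::sd(sample_a), n_a = length(sample_a),
    mean_b = mean(sample_b), sd_b = stats::sd(sample_b), n_b = length(sample_b),
    normality_alpha = normality_alpha)
  if (stats::sd(c(sample_a, sample_b)) == 0) {
    return(structure(c(base, list(shapiro_p_a = NA_real_,
                                  shapiro_p_b = NA_real_,
                                  test = "degenerate",
                                  statistic = NA_real_, p_value = 1)),
                     class = "group_comparison"))
  }
  sw_p <- function(x) {
    if (stats::sd(x) == 0) return(0)  # constant: certainly not Gaussian
    stats::shapiro.test(x)$p.value
  }
  sw_a <- sw_p(sample_a)
  sw_b <- sw_p(sample_b)
  use_t <- sw_a > normality_alpha && sw_b > normality_alpha
  if (use_t) {
    ht <- stats::t.test(sample_a, sample_b, var.equal = var_equal)
    test <- "t"
  } else {
    exact <- max(length(sample_a), length(sample_b)) <= 20L &&
      !anyDuplicated(c(sample_a, sample_b))
    ht <- suppressWarnings(
      stats::wilcox.test(sample_a, sample_b, exact = exact, correct = TRUE))
    test <- "wilcoxon"
  }
  structure(c(base, list(shapiro_p_a = sw_a, shapiro_p_b = sw_b,
                         test = test, statistic = unname(ht$statistic),
                         p_value = ht$p.value)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test: p = %.4g  (A: %.3f +/- %.3f, n=%d; B: %.3f +/- %.3f, n=%d)\n",
              x$test, x$p_value, x$mean_a, x$sd_a, x$n_a,
              x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("  Shapiro-Wilk p: %.3g / %.3g (threshold %.2f)\n",
              x$shapiro_p_a, x$shapiro_p_b, x$normality_alpha))
  invisible(x)
}

#' Compare two groups across a table of biomarkers
#'
#' Applies [compare_groups()] per biomarker column (optionally within
#' regions), producing a tidy comparison table.
#'
#' @param records Data frame of per-eye biomarker values.
#' @param group_col Name of the two-level grouping column.
#' @param value_cols Biomarker columns (default: all numeric columns).
#' @param region_col Optional region column to stratify by.
#' @return Data frame with one row per biomarker (x region).
#' @export
compare_biomarker_table <- function(records, group_col = "cohort",
                                    value_cols = NULL, region_col = NULL) {
  groups <- unique(records[[group_col]])
  if (length(groups) != 2L) stop("group column must have exactly two levels")
  if (is.null(value_cols))
    value_cols <- names(records)[vapply(records, is.numeric, logical(1))]
  strata <- if (is.null(region_col)) list(`all` = records)
  else split(records, records[[region_col]])
  rows <- list()
  for (rg in names(strata)) {
    df <- strata[[rg]]
    for (vc in value_cols) {
      a <- df[[vc]][df[[group_col]] == groups[1]]
      b <- df[[vc]][df[[group_col]] == groups[2]]
      cmp <- compare_groups(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, biomarker = vc,
        mean_a = cmp$mean_a, sd_a = cmp$sd_a, n_a = cmp$n_a,
        mean_b = cmp$mean_b, sd_b = cmp$sd_b, n_b = cmp$n_b,
        test = cmp$test, p_value = cmp$p_value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlation screen
#'
#' Pearson correlations over complete cases for every pair of biomarker
#' columns, flagging moderate-to-strong associations as `r > 0.3` on the
#' signed coefficient exactly as reported clinically — strong negative
#' correlations are reported but never flagged (see `note` column).
#' Pairs with a zero-variance member or fewer than 3 complete pairs yield
#' `NA` with an explanatory note.
#'
#' @param records Data frame of biomarker values.
#' @param value_cols Columns to correlate (default: all numeric columns).
#' @param flag_threshold Signed-r threshold for the moderate flag.
#' @return Data frame with `var1`, `var2`, `r`, `n`, `flagged_moderate`,
#'   `note`.
#' @export
correlation_screen <- function(records, value_cols = NULL,
                               flag_threshold = 0.3) {
  if (is.null(value_cols))
    value_cols <- names(records)[vapply(records, is.numeric, logical(1))]
  if (length(value_cols) < 2L) stop("need at least two columns to correlate")
  rows <- list()
  for (i in seq_len(length(value_cols) - 1L)) {
    for (j in (i + 1L):length(value_cols)) {
      x <- records[[value_cols[i]]]
      y <- records[[value_cols[j]]]
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      note <- ""
      if (n < 3L) {
        r <- NA_real_
        note <- "fewer than 3 complete pairs"
      } else if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        r <- NA_real_
        note <- "zero variance: correlation undefined"
      } else {
        r <- stats::cor(x[ok], y[ok])
        if (r < -flag_threshold) note <- "negative association (never flagged)"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        var1 = value_cols[i], var2 = value_cols[j], r = r, n = n,
        flagged_moderate = !is.na(r) && r > flag_threshold, note = note)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
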