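# Cohort summary statistics: 2x2 chi-square tests with Yates continuity
# correction for the categorical rows (site, sex) and pooled-variance
# two-sample t tests for the continuous rows (age, education, MMSE).

#' Yates-corrected chi-square for a 2x2 table
#'
#' The continuity correction is clamped, `max(|O - E| - 0.5, 0)`, so a table
#' with observed equal to expected gives exactly 0 (this is the correction
#' used by [stats::chisq.test()], which performs the computation here).
#'
#' @param tab 2x2 matrix of counts (groups in columns or rows; symmetric).
#' @return List with `statistic`, `df`, `p`.
#' @export
chi2_yates <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square test undefined: zero marginal in the contingency table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Two-sample t test from summary statistics
#'
#' Pooled-variance form by default (`var_equal = TRUE`); Welch is available
#' since the source table does not state which was used.
#'
#' @param n1,m1,s1 Size, mean, SD of group 1.
#' @param n2,m2,s2 Size, mean, SD of group 2.
#' @param var_equal Pooled (`TRUE`) or Welch (`FALSE`).
#' @return List with `statistic`, `df`, `p` (two-sided).
#' @export
t_from_summary <- function(n1, m1, s1, n2, m2, s2, var_equal = TRUE) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  if (var_equal) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- s1^2 / n1 + s2^2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  }
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Group-comparison statistics for a cohort
#'
#' Reproduces the summary-table tests: chi-square (Yates) for site and sex,
#' pooled two-sample t for age, education and MMSE.  Accepts either a cohort
#' table or printed summaries.
#'
#' @param table An `nf_cohort` data.frame; or `NULL` when `categorical` /
#'   `continuous` summaries are given directly.
#' @param categorical Named list of 2x2 matrices (variable -> counts).
#' @param continuous Named list of 6-vectors `(n1, mean1, sd1, n2, mean2, sd2)`.
#' @param var_equal Pooled (default) or Welch t.
#' @return Data frame with columns `variable`, `test`, `statistic`, `df`, `p`;
#'   statistics rounded to 2 decimals in the `statistic_2dp` column.
#' @export
cohort_stats <- function(table = NULL, categorical = NULL, continuous = NULL,
                         var_equal = TRUE) {
  rows <- list()
  if (!is.null(table)) {
    stopifnot(is.data.frame(table))
    g <- factor(table$group, levels = c("HC", "MCI"))
    categorical <- c(categorical, list(
      site = table(factor(table$site, levels = c("CBU", "CTB")), g),
      sex = table(factor(table$sex, levels = c("M", "F")), g)))
    mk <- function(v) {
      x1 <- table[[v]][g == "HC"]; x2 <- table[[v]][g == "MCI"]
      c(length(x1), mean(x1), stats::sd(x1), length(x2), mean(x2), stats::sd(x2))
    }
    continuous <- c(continuous, list(age = mk("age"), education = mk("education"),
                                     mmse = mk("mmse")))
  }
  for (v in names(categorical)) {
    r <- chi2_yates(categorical[[v]])
    rows[[length(rows) + 1]] <- data.frame(variable = v, test = "chi2_yates",
                                           statistic = r$statistic, df = r$df,
                                           p = r$p)
  }
  for (v in names(continuous)) {
    s <- continuous[[v]]
    r <- t_from_summary(s[1], s[2], s[3], s[4], s[5], s[6],
                        var_equal = var_equal)
    rows[[length(rows) + 1]] <- data.frame(variable = v, test = "t_two_sample",
                                           statistic = r$statistic, df = r$df,
                                           p = r$p)
  }
  out <- do.call(rbind, rows)
  out$statistic_2dp <- round(out$statistic, 2)
  out
}

#' Paired t test with Bonferroni correction
#'
#' Paired t on fold-wise metric differences with `p_adjusted = min(1, m * p)`.
#' All-zero differences return `p = 1`; zero-variance nonzero differences are
#' flagged degenerate.
#'
#' @param metric_a,metric_b Per-fold metric values (equal length >= 2).
#' @param m Number of comparisons in the family.
#' @return List with `t`, `df`, `p_raw`, `p_adjusted`, `degenerate`.
#' @export
paired_ttest_bonferroni <- function(metric_a, metric_b, m = 1) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 2,
            m >= 1)
  d <- metric_a - metric_b
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, df = n - 1, p_raw = 1, p_adjusted = 1,
                  degenerate = FALSE))
    return(list(t = sign(d[1]) * Inf, df = n - 1, p_raw = 0, p_adjusted = 0,
                degenerate = TRUE))
  }
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  p <- 2 * stats::pt(-abs(t), n - 1)
  list(t = t, df = n - 1, p_raw = p, p_adjusted = min(1, m * p),
       degenerate = FALSE)
}
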