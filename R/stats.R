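#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t-test computed from group sizes, means and SDs:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided Student-t p-value.  Operating on
#' summaries lets published group tables be re-analysed directly.
#'
#' @param n1,mean1,sd1 First group: size, mean, SD.
#' @param n2,mean2,sd2 Second group.
#' @return List with `t`, `df`, `p`.
#' @examples
#' welch_t(38, 64.68, 13.56, 25, 59.28, 12.26)
#' @export
welch_t <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (v1 + v2 == 0) stop("zero variance in both groups")
  tval <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Pearson chi-square statistic for a 2x2 table
#'
#' No continuity correction is applied: the uncorrected statistic is the
#' convention that reproduces the published group comparisons this
#' package mirrors, and it is the statistic resampled by [simulate_p()].
#'
#' @param table 2x2 matrix of non-negative counts, or the four counts
#'   `a, b, c, d` (row-wise).
#' @param b,c,d Remaining counts when `table` is given as scalar `a`.
#' @return The chi-square statistic (scalar).
#' @examples
#' chisq_2x2(matrix(c(0, 38, 6, 19), 2, byrow = TRUE))
#' @export
chisq_2x2 <- function(table, b = NULL, c = NULL, d = NULL) {
  if (!is.matrix(table)) table <- matrix(c(table, b, c, d), 2, byrow = TRUE)
  stopifnot(all(dim(table) == 2), all(table >= 0),
            all(table == round(table)))
  if (sum(table) == 0) stop("empty table")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0))
    stop("zero marginal row or column")
  e <- outer(rs, cs) / sum(table)
  sum((table - e)^2 / e)
}

#' Monte-Carlo p-value for a 2x2 table with fixed margins
#'
#' Resamples tables from the fixed-margins null (label permutation,
#' via `r2dtable`) and returns
#' `p = (1 + #\{chi-square >= observed\}) / (1 + n_reshuffles)`, the
#' add-one estimator that cannot return 0.
#'
#' @param table 2x2 count matrix.
#' @param n_reshuffles Number of resampled tables (default 10000).
#' @param seed Integer seed; the p-value is deterministic given it.
#' @return Monte-Carlo p-value.
#' @export
simulate_p <- function(table, n_reshuffles = 10000, seed = 1) {
  stopifnot(all(dim(table) == 2))
  obs <- chisq_2x2(table)
  set.seed(seed)
  sim <- stats::r2dtable(n_reshuffles, rowSums(table), colSums(table))
  stat <- vapply(sim, chisq_2x2, numeric(1))
  (1 + sum(stat >= obs - 1e-12)) / (1 + n_reshuffles)
}

.fmt_msd <- function(x) sprintf("%.2f (%.2f)", mean(x), stats::sd(x))

#' Two-group demographic comparison report
#'
#' Summarises the cohort per group (n; mean/SD of age, MADRS-SIGMA and
#' NIHSS; yes/no counts for sex, depression history, antidepressant use
#' and any reported symptom items present) and attaches the matching
#' test to each row: Welch t for continuous rows, uncorrected chi-square
#' with a Monte-Carlo p for count rows.
#'
#' @param cohort A `cohort_table`.
#' @param n_reshuffles Reshuffles for the Monte-Carlo chi-square p.
#' @param seed Seed for the Monte-Carlo p.
#' @return A `cohort_report` data frame: variable, low, high, test,
#'   statistic, df, p.
#' @export
cohort_report <- function(cohort, n_reshuffles = 10000, seed = 1) {
  lo <- cohort[cohort$group == "low", ]
  hi <- cohort[cohort$group == "high", ]
  if (nrow(lo) < 2 || nrow(hi) < 2)
    stop("each group needs at least 2 subjects for the group comparisons")
  rows <- list(data.frame(variable = "n", low = as.character(nrow(lo)),
                          high = as.character(nrow(hi)), test = "",
                          statistic = NA_real_, df = NA_real_,
                          p = NA_real_))
  cont_row <- function(label, col) {
    m1 <- mean(lo[[col]]); m2 <- mean(hi[[col]])
    s1 <- stats::sd(lo[[col]]); s2 <- stats::sd(hi[[col]])
    w <- if (s1 + s2 == 0) {
      # degenerate constant groups: identical means are a null result,
      # different means an unambiguous (infinite-t) one
      if (m1 == m2) list(t = 0, df = NA_real_, p = 1)
      else list(t = sign(m1 - m2) * Inf, df = NA_real_, p = 0)
    } else welch_t(nrow(lo), m1, s1, nrow(hi), m2, s2)
    data.frame(variable = label, low = .fmt_msd(lo[[col]]),
               high = .fmt_msd(hi[[col]]), test = "welch_t",
               statistic = w$t, df = w$df, p = w$p)
  }
  count_row <- function(label, flag_lo, flag_hi) {
    tab <- matrix(c(sum(flag_lo), sum(!flag_lo),
                    sum(flag_hi), sum(!flag_hi)), 2, byrow = TRUE)
    fmt <- function(f) sprintf("%d/%d (%.1f%%)", sum(f), sum(!f),
                               100 * mean(f))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      return(data.frame(variable = label, low = fmt(flag_lo),
                        high = fmt(flag_hi), test = "chisq",
                        statistic = 0, df = 1, p = 1))
    data.frame(variable = label, low = fmt(flag_lo), high = fmt(flag_hi),
               test = "chisq", statistic = chisq_2x2(tab), df = 1,
               p = simulate_p(tab, n_reshuffles, seed))
  }
  rows <- c(rows, list(
    cont_row("age", "age"),
    count_row("sex_female", lo$sex == "female", hi$sex == "female"),
    cont_row("madrs_total", "madrs_total"),
    count_row("history_depression", lo$history_depression,
              hi$history_depression),
    count_row("antidepressant", lo$antidepressant, hi$antidepressant)))
  for (col in intersect(.cohort_optional_cols, names(cohort)))
    if (!anyNA(cohort[[col]]))
      rows <- c(rows, list(count_row(col, lo[[col]], hi[[col]])))
  rows <- c(rows, list(cont_row("nihss", "nihss")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_report", "data.frame")
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  y <- as.data.frame(x)
  y$statistic <- ifelse(is.na(y$statistic), "",
                        sprintf("%.2f", y$statistic))
  y$df <- ifelse(is.na(y$df), "", sprintf("%.2f", y$df))
  y$p <- ifelse(is.na(y$p), "", sprintf("%.4f", y$p))
  print(y, right = FALSE, row.names = FALSE)
  invisible(x)
}

#' Write a cohort report as TSV
#'
#' @param report A [cohort_report()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
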