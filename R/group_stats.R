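# Two-group inference: normality-gated pooled t / Mann-Whitney, a
# summary-statistics t-test, Fisher's exact test, and cohort-level reports.

new_comparison <- function(metric, test, statistic, df, p, summaries,
                           alpha = 0.05) {
  structure(list(metric = metric, test = test, statistic = statistic,
                 df = df, p = p, summaries = summaries,
                 significant = is.finite(p) && p < alpha),
            class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("%s: %s, statistic = %.4g%s, p = %.4g%s\n",
              x$metric, x$test, x$statistic,
              if (!is.na(x$df)) sprintf(" (df = %g)", x$df) else "",
              x$p, if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Compare two samples with a normality-gated test
#'
#' Policy `"auto"` applies a Shapiro-Wilk test (alpha = 0.05) to each
#' group: if both are compatible with normality a pooled-variance
#' two-sided Student t-test is used, otherwise a two-sided Mann-Whitney
#' test (exact where feasible, midrank normal approximation under ties).
#' Groups of fewer than 3 observations cannot be normality-tested and are
#' routed to Mann-Whitney.
#'
#' @param x,y Numeric samples (n >= 2 each).
#' @param policy `"auto"`, `"force_t"` or `"force_mw"`.
#' @param metric Label carried into the result.
#' @return A `ComparisonResult` with group summaries (mean, SEM, n; and
#'   median, IQR for Mann-Whitney).
#' @export
compare_groups <- function(x, y, policy = c("auto", "force_t", "force_mw"),
                           metric = "metric") {
  policy <- match.arg(policy)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 finite observations")
  if (stats::sd(c(x, y)) == 0) {
    # all observations identical: no evidence of any difference
    summ <- data.frame(group = c("x", "y"), n = c(length(x), length(y)),
                       mean = c(mean(x), mean(y)), sem = c(0, 0),
                       median = c(x[1L], y[1L]), iqr = c(0, 0))
    return(new_comparison(metric,
                          if (policy == "force_mw") "mann_whitney" else "student_t",
                          0, length(x) + length(y) - 2, 1, summ))
  }
  use_t <- switch(policy,
    force_t = TRUE,
    force_mw = FALSE,
    auto = {
      normal <- function(v) {
        if (length(v) < 3L || stats::sd(v) == 0) return(FALSE)
        stats::shapiro.test(v)$p.value >= 0.05
      }
      normal(x) && normal(y)
    })
  summ <- data.frame(
    group = c("x", "y"),
    n = c(length(x), length(y)),
    mean = c(mean(x), mean(y)),
    sem = c(stats::sd(x) / sqrt(length(x)), stats::sd(y) / sqrt(length(y))),
    median = c(stats::median(x), stats::median(y)),
    iqr = c(stats::IQR(x), stats::IQR(y)))
  if (use_t) {
    if (stats::sd(c(x, y)) == 0) {
      res <- new_comparison(metric, "student_t", 0,
                            length(x) + length(y) - 2, 1, summ)
      return(res)
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    new_comparison(metric, "student_t", unname(tt$statistic),
                   unname(tt$parameter), tt$p.value, summ)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL, correct = TRUE))
    new_comparison(metric, "mann_whitney", unname(wt$statistic), NA_real_,
                   wt$p.value, summ)
  }
}

#' Two-sided unpaired t-test from printed summary statistics
#'
#' Recomputes a two-sample Student t-test from group means, standard
#' errors of the mean, and sample sizes:
#' `t = (mean1 - mean2) / sqrt(sem1^2 + sem2^2)` with `df = n1 + n2 - 2`
#' (for n1 = n2 this equals the pooled-variance test). Intended for
#' checking p-values reported alongside mean +/- SEM.
#'
#' @param mean1,sem1,n1,mean2,sem2,n2 Group summaries (SEM >= 0, n >= 2).
#' @return List with `t`, `df` and two-sided `p`. With both SEMs zero the
#'   test degenerates: equal means give p = 1; unequal means give p = 0
#'   with a warning.
#' @export
ttest_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2) {
  for (v in c(sem1, sem2)) stopifnot_scalar(v, "sem", nonneg = TRUE)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  df <- n1 + n2 - 2
  se <- sqrt(sem1^2 + sem2^2)
  if (se == 0) {
    if (mean1 == mean2) return(list(t = 0, df = df, p = 1))
    warning("zero SEMs with unequal means: p reported as 0 (degenerate limit)")
    return(list(t = sign(mean1 - mean2) * Inf, df = df, p = 0))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities, over all
#' tables with the observed margins, that do not exceed the probability of
#' the observed table.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `matrix(c(a, b, c, d), 2, byrow = TRUE)`.
#' @return The two-sided p-value (1 for an all-zero table).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) == 0) return(1)
  stats::fisher.test(matrix(cells, 2L, 2L, byrow = TRUE))$p.value
}

#' Two-group comparisons for every metric of a cohort table
#'
#' @param table Data.frame with one row per donor, a `group` column
#'   (values `"pregnant"`/`"control"`), optionally a logical `gdm` column,
#'   and metric columns.
#' @param metrics Character vector of metric column names to test.
#' @param grouping `"pregnant_vs_control"` (all donors) or
#'   `"gdm_vs_normal"` (within the pregnant group).
#' @param policy Test policy passed to [compare_groups()].
#' @return A data.frame with one row per metric: metric, test, statistic,
#'   df, p, significant, and group means/SEMs/ns. No multiplicity
#'   correction is applied across metrics.
#' @export
cohort_report <- function(table, metrics,
                          grouping = c("pregnant_vs_control", "gdm_vs_normal"),
                          policy = "auto") {
  grouping <- match.arg(grouping)
  missing_cols <- setdiff(c(metrics, "group"), names(table))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (grouping == "pregnant_vs_control") {
    g1 <- table$group == "pregnant"; g2 <- table$group == "control"
    labels <- c("pregnant", "control")
  } else {
    if (!"gdm" %in% names(table)) stop("missing column(s): gdm")
    preg <- table[table$group == "pregnant", , drop = FALSE]
    g1 <- preg$gdm; g2 <- !preg$gdm
    table <- preg
    labels <- c("gdm", "normal")
  }
  if (sum(g1) < 2L || sum(g2) < 2L)
    stop("each group needs at least 2 donors for '", grouping, "'")
  rows <- lapply(metrics, function(m) {
    r <- compare_groups(table[[m]][g1], table[[m]][g2], policy = policy,
                        metric = m)
    data.frame(metric = m, test = r$test, statistic = r$statistic,
               df = r$df, p = r$p, significant = r$significant,
               mean_1 = r$summaries$mean[1L], sem_1 = r$summaries$sem[1L],
               n_1 = r$summaries$n[1L], mean_2 = r$summaries$mean[2L],
               sem_2 = r$summaries$sem[2L], n_2 = r$summaries$n[2L])
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- labels
  out
}
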