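# Statistical test dispatch, effect sizes, and summary-table reporting for
# one-sample, paired and unpaired contrasts.

group_stats <- function(x, conf = 0.95, t_based = FALSE) {
  n <- length(x)
  s <- stats::sd(x)
  sem <- s / sqrt(n)
  half <- if (t_based) stats::qt(1 - (1 - conf) / 2, n - 1) * sem
          else stats::qnorm(1 - (1 - conf) / 2) * sem
  list(mean = mean(x), median = stats::median(x), sd = s, sem = sem,
       ci_half = half, n = n)
}

# |z| recovered from a two-sided normal-approximation p-value
z_from_p <- function(p) {
  p <- min(max(p, .Machine$double.xmin), 1)
  stats::qnorm(1 - p / 2)
}

#' Cohen's d
#'
#' Standardized mean difference: pooled-SD denominator for independent
#' samples, SD of the differences for paired samples, and the sample SD for
#' a one-sample contrast against zero (`y = NULL`). Sign follows
#' `mean(x) - mean(y)`.
#'
#' @param x,y Numeric samples; `y = NULL` for one-sample.
#' @param paired Paired samples?
#' @return Cohen's d (`NA` with a warning when the denominator is zero).
#' @export
effect_size_d <- function(x, y = NULL, paired = FALSE) {
  if (is.null(y)) {
    denom <- stats::sd(x)
    num <- mean(x)
  } else if (paired) {
    d <- x - y
    denom <- stats::sd(d)
    num <- mean(d)
  } else {
    nx <- length(x); ny <- length(y)
    denom <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
                    (nx + ny - 2))
    num <- mean(x) - mean(y)
  }
  if (!is.finite(denom) || denom == 0) {
    warning("zero variance: Cohen's d undefined")
    return(NA_real_)
  }
  num / denom
}

#' Effect size r for rank-based tests
#'
#' `r = |z| / sqrt(n)`, the z statistic of the normal approximation divided
#' by the square root of the total sample size; reported as a magnitude in
#' `[0, 1]`.
#'
#' @param z_statistic z statistic (sign ignored).
#' @param n_total Total number of observations.
#' @return Effect size r.
#' @export
effect_size_r <- function(z_statistic, n_total) {
  if (!is.finite(z_statistic)) stop("z must be finite")
  if (n_total <= 0) stop("n_total must be positive")
  abs(z_statistic) / sqrt(n_total)
}

#' Normality-dispatched two-sample / one-sample test
#'
#' Shapiro-Wilk normality at `alpha_normality` decides the route, as in the
#' source analyses: normal data go to t-tests (Welch for unpaired, matching
#' the reduced degrees of freedom reported in the original tables), paired
#' data are tested on their differences, non-normal data go to the Wilcoxon
#' rank-sum (unpaired) or signed-rank (paired / one-sample) test. Zero
#' variance falls back to the nonparametric route. Effect sizes: Cohen's d
#' for t-tests, r = |z|/sqrt(n) for Wilcoxon tests. The CI column is the
#' 95% half-width (t-based for t-tests, normal-approximation otherwise).
#'
#' @param x Numeric sample.
#' @param y Second sample or `NULL` for a one-sample test against zero.
#' @param paired Paired samples?
#' @param alpha_normality Shapiro-Wilk level (default 0.05).
#' @param comparison_name Label carried into the report.
#' @return List of class `stat_result`: `comparison_name`, `groups` (per
#'   group: mean, median, sd, sem, ci_half, n), `test_name`,
#'   `test_statistic`, `n`, `df`, `p_value`, `effect_size`,
#'   `effect_size_type`.
#' @export
dispatch_test <- function(x, y = NULL, paired = FALSE,
                          alpha_normality = 0.05,
                          comparison_name = "comparison") {
  if (length(x) < 3 || (!is.null(y) && length(y) < 3)) {
    stop("need at least 3 observations per sample")
  }
  shapiro_normal <- function(v) {
    if (stats::sd(v) == 0) return(FALSE)        # degenerate -> nonparametric
    stats::shapiro.test(v)$p.value >= alpha_normality
  }
  one_sample <- is.null(y)
  if (one_sample || paired) {
    d <- if (one_sample) x else x - y
    if (all(d == 0)) {
      res <- list(test_name = if (one_sample) "One-sample Wilcoxon test"
                  else "Wilcoxon signed-rank test",
                  statistic = 0, df = NA_real_, p = 1,
                  effect = 0, effect_type = "r")
    } else if (shapiro_normal(d)) {
      tt <- stats::t.test(d, mu = 0)
      res <- list(test_name = if (one_sample) "One-sample t-test"
                  else "Paired t-test",
                  statistic = unname(tt$statistic),
                  df = unname(tt$parameter), p = tt$p.value,
                  effect = effect_size_d(d), effect_type = "cohens_d")
    } else {
      wt <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = FALSE,
                                                correct = TRUE))
      z <- z_from_p(wt$p.value)
      res <- list(test_name = if (one_sample) "One-sample Wilcoxon test"
                  else "Wilcoxon signed-rank test",
                  statistic = unname(wt$statistic), df = NA_real_,
                  p = wt$p.value,
                  effect = effect_size_r(z, length(d)), effect_type = "r")
    }
    n_out <- length(x)
  } else {
    if (shapiro_normal(x) && shapiro_normal(y)) {
      tt <- stats::t.test(x, y, var.equal = FALSE)
      res <- list(test_name = "Student's t-test",
                  statistic = unname(tt$statistic),
                  df = unname(tt$parameter), p = tt$p.value,
                  effect = effect_size_d(x, y), effect_type = "cohens_d")
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = TRUE))
      z <- z_from_p(wt$p.value)
      res <- list(test_name = "Wilcoxon rank-sum test",
                  statistic = unname(wt$statistic), df = NA_real_,
                  p = wt$p.value,
                  effect = effect_size_r(z, length(x) + length(y)),
                  effect_type = "r")
    }
    n_out <- c(length(x), length(y))
  }
  t_based <- grepl("t-test", res$test_name)
  groups <- list(x = group_stats(x, t_based = t_based))
  if (!is.null(y)) groups$y <- group_stats(y, t_based = t_based)
  structure(list(comparison_name = comparison_name, groups = groups,
                 test_name = res$test_name,
                 test_statistic = res$statistic, n = n_out, df = res$df,
                 p_value = res$p, effect_size = res$effect,
                 effect_size_type = res$effect_type),
            class = "stat_result")
}

#' Summary table of statistical results
#'
#' One row per comparison in the layout of the source report tables: group
#' means, medians, SDs, SEMs, CI half-widths, test name and statistic, N,
#' df (NA for rank tests), p, and effect size. Values are rounded to 2
#' significant figures in the written table; `digits = NA` keeps full
#' precision.
#'
#' @param stat_results List of `stat_result` objects.
#' @param path Optional file to write the table to (tab-separated text).
#' @param digits Significant digits (default 2; `NA` = no rounding).
#' @return The summary data.frame, invisibly when `path` is given.
#' @export
build_summary_table <- function(stat_results, path = NULL, digits = 2) {
  if (length(stat_results) == 0) stop("need at least one result")
  fmt2 <- function(g, field) {
    vapply(stat_results, function(r) {
      v <- vapply(r$groups, function(g) g[[field]], numeric(1))
      paste(if (is.na(digits)) v else signif(v, digits), collapse = " / ")
    }, character(1))
  }
  num <- function(v) if (is.na(digits)) v else signif(v, digits)
  df <- data.frame(
    comparison = vapply(stat_results, `[[`, character(1),
                        "comparison_name"),
    mean = fmt2(stat_results, "mean"),
    median = fmt2(stat_results, "median"),
    sd = fmt2(stat_results, "sd"),
    sem = fmt2(stat_results, "sem"),
    ci = fmt2(stat_results, "ci_half"),
    test = vapply(stat_results, `[[`, character(1), "test_name"),
    test_statistic = num(vapply(stat_results, `[[`, numeric(1),
                                "test_statistic")),
    n = vapply(stat_results, function(r) paste(r$n, collapse = " / "),
               character(1)),
    df = num(vapply(stat_results, `[[`, numeric(1), "df")),
    p = num(vapply(stat_results, `[[`, numeric(1), "p_value")),
    effect_size = num(vapply(stat_results, `[[`, numeric(1),
                             "effect_size")),
    effect_size_type = vapply(stat_results, `[[`, character(1),
                              "effect_size_type"),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    return(invisible(df))
  }
  df
}
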