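#' Cross-tabulate two binary depth diagnoses
#'
#' Builds the 2 x 2 agreement table between two raters (or a rater and
#' the algorithm) in a fixed orientation: `a` both floating, `b` rater 1
#' sunken / rater 2 floating, `c` rater 1 floating / rater 2 sunken,
#' `d` both sunken.
#'
#' @param labels_1,labels_2 equal-length character vectors of binary
#'   labels (`"floating"` / `"sunken"`).
#' @return an object of class `agreement_table`.
#' @seealso [agreement_counts()] to build the table from its four cells,
#'   [accuracy()], [mcc()].
#' @export
agreement_table <- function(labels_1, labels_2) {
  if (length(labels_1) != length(labels_2))
    stop("label vectors must have the same length")
  bad <- setdiff(unique(c(labels_1, labels_2)), c("floating", "sunken"))
  if (length(bad) > 0L)
    stop("labels must be binary (floating/sunken); found: ",
         paste(bad, collapse = ", "))
  agreement_counts(
    a = sum(labels_1 == "floating" & labels_2 == "floating"),
    b = sum(labels_1 == "sunken" & labels_2 == "floating"),
    c = sum(labels_1 == "floating" & labels_2 == "sunken"),
    d = sum(labels_1 == "sunken" & labels_2 == "sunken"))
}

#' Agreement table from its four cell counts
#'
#' @param a both raters floating.
#' @param b rater 1 sunken, rater 2 floating.
#' @param c rater 1 floating, rater 2 sunken.
#' @param d both raters sunken.
#' @return an object of class `agreement_table`.
#' @export
agreement_counts <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  structure(list(counts = counts), class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  m <- matrix(x$counts[c("a", "b", "c", "d")], 2, 2, byrow = TRUE,
              dimnames = list(`rater 2` = c("floating", "sunken"),
                              `rater 1` = c("floating", "sunken")))
  cat(sprintf("<agreement_table> n = %d\n", sum(x$counts)))
  print(m)
  invisible(x)
}

#' Agreement accuracy of a 2 x 2 table
#'
#' Fraction of concordant diagnoses, `(a + d) / (a + b + c + d)`.
#'
#' @param x an [agreement_table()].
#' @param ... unused.
#' @return scalar in \[0, 1\].
#' @export
accuracy <- function(x, ...) UseMethod("accuracy")

#' @export
accuracy.agreement_table <- function(x, ...) {
  n <- sum(x$counts)
  if (n == 0L) stop("empty agreement table")
  unname((x$counts[["a"]] + x$counts[["d"]]) / n)
}

#' Matthews correlation coefficient of a 2 x 2 table
#'
#' The chance-robust agreement statistic
#' \deqn{MCC = \frac{ad - bc}{\sqrt{(a+b)(a+c)(d+b)(d+c)}},}
#' in \[-1, 1\]; defined as 0 when any marginal is zero (the usual
#' convention for a degenerate table).
#'
#' @param x an [agreement_table()].
#' @param ... unused.
#' @return scalar in \[-1, 1\].
#' @export
mcc <- function(x, ...) UseMethod("mcc")

#' @export
mcc.agreement_table <- function(x, ...) {
  n <- sum(x$counts)
  if (n == 0L) stop("empty agreement table")
  .mcc_counts(x$counts[["a"]], x$counts[["b"]], x$counts[["c"]],
              x$counts[["d"]])
}

#' Sample Pearson correlation between two coefficient series
#'
#' Thin validated wrapper used to compare depth-coefficient variants
#' across a cohort.
#'
#' @param x,y equal-length numeric vectors, length >= 3, each with
#'   nonzero variance.
#' @return scalar in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: Pearson correlation undefined")
  stats::cor(x, y)
}

#' Two-sample t-test between pulse groups
#'
#' Compares a covariate (BMI, blood pressure, depth coefficient, ...)
#' between two groups of subjects.  Welch's unequal-variance form is the
#' default — group spreads of the floating and sunken cohorts differ
#' appreciably — with the pooled equal-variance form behind a flag.
#'
#' @param group_a,group_b numeric vectors (n >= 2 each).
#' @param var_equal use the pooled equal-variance statistic instead of
#'   Welch's; default `FALSE`.
#' @return an object of class `group_stats`: per-group n/mean/sd, the
#'   t statistic, degrees of freedom and the two-sided p-value.
#' @export
welch_ttest <- function(group_a, group_b, var_equal = FALSE) {
  group_a <- as.numeric(group_a)
  group_b <- as.numeric(group_b)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 observations")
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal,
                      alternative = "two.sided")
  structure(
    list(n = c(a = length(group_a), b = length(group_b)),
         mean = c(a = mean(group_a), b = mean(group_b)),
         sd = c(a = stats::sd(group_a), b = stats::sd(group_b)),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, var_equal = var_equal),
    class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("Two-sample t-test (%s)\n",
              if (x$var_equal) "pooled variance" else "Welch"))
  cat(sprintf("  group a: n = %d, mean = %.4g, sd = %.4g\n",
              x$n[["a"]], x$mean[["a"]], x$sd[["a"]]))
  cat(sprintf("  group b: n = %d, mean = %.4g, sd = %.4g\n",
              x$n[["b"]], x$mean[["b"]], x$sd[["b"]]))
  cat(sprintf("  t = %.3f, df = %.1f, p = %.3g\n", x$t, x$df, x$p_value))
  invisible(x)
}
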