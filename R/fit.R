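#' Fit depth-classification thresholds to a labelled cohort
#'
#' Estimates the decision threshold(s) of the depth classifier by an
#' exhaustive grid sweep against reference diagnoses.  With
#' `rule = "single"` the discriminant maximizing accuracy (optionally
#' MCC) is chosen; with `rule = "dual"` the pair `(c_f, c_s)` is chosen
#' on the selection-rate frontier: among threshold pairs deciding at
#' least `min_selection_rate` of the cohort, the one with maximal
#' accuracy over the decided subjects (ties go to the higher selection
#' rate, then to the smaller `c_f`).
#'
#' @param cfs numeric vector of depth coefficients in \[0, 1\].
#' @param reference character vector of reference labels (`"floating"` /
#'   `"sunken"`).
#' @param rule `"single"` (one discriminant) or `"dual"` (reject
#'   option).
#' @param grid_step threshold grid spacing; default 0.01.
#' @param criterion objective for the single rule: `"accuracy"`
#'   (default) or `"mcc"`; ties go to the smallest threshold.
#' @param min_selection_rate minimum fraction of subjects the dual rule
#'   must decide; default 0.7 (roughly the regime in which the reject
#'   option buys accuracy without discarding most of the cohort).
#' @return an object of class `cfs_classifier` with components
#'   `thresholds`, `sweep`, `rule`, and the training data; supports
#'   [print()], [summary()], [coef()], [predict()], [fitted()] and
#'   [plot()].
#' @examples
#' coh <- simulate_cohort(20, 30, seed = 1)
#' d <- cohort_cfs(coh, method = "new", variant = "v2")
#' fit <- cfs_classifier(d$cfs, d$reference, rule = "single")
#' coef(fit)
#' table(predict(fit, d$cfs), d$reference)
#' @export
cfs_classifier <- function(cfs, reference, rule = c("single", "dual"),
                           grid_step = 0.01,
                           criterion = c("accuracy", "mcc"),
                           min_selection_rate = 0.7) {
  rule <- match.arg(rule)
  criterion <- match.arg(criterion)
  .check_cohort(cfs, reference)
  if (rule == "single") {
    sw <- sweep_single(cfs, reference, grid_step)
    best <- if (criterion == "accuracy") attr(sw, "best_accuracy")
            else attr(sw, "best_mcc")
    thresholds <- c(c_star = best$c_star)
  } else {
    sw <- sweep_dual(cfs, reference, grid_step)
    cand <- sw$frontier[sw$frontier$selection_rate >= min_selection_rate &
                          sw$frontier$n_decided > 0, ]
    if (nrow(cand) == 0L)
      stop("no threshold pair reaches the requested selection rate")
    cand <- cand[order(-cand$accuracy, -cand$selection_rate, cand$c_f), ]
    thresholds <- c(c_f = cand$c_f[1L], c_s = cand$c_s[1L])
  }
  structure(
    list(call = match.call(), rule = rule, criterion = criterion,
         thresholds = thresholds, sweep = sw, grid_step = grid_step,
         min_selection_rate = if (rule == "dual") min_selection_rate else NA,
         cfs = cfs, reference = reference),
    class = "cfs_classifier")
}

#' @export
coef.cfs_classifier <- function(object, ...) object$thresholds

#' @rdname cfs_classifier
#' @param object,x a fitted `cfs_classifier`.
#' @param newdata numeric vector of depth coefficients to classify;
#'   defaults to the training coefficients.
#' @param ... unused.
#' @export
predict.cfs_classifier <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$cfs
  th <- object$thresholds
  if (object$rule == "single") classify_single(newdata, th[["c_star"]])
  else classify_dual(newdata, th[["c_f"]], th[["c_s"]])
}

#' @export
fitted.cfs_classifier <- function(object, ...) predict(object)

#' @export
print.cfs_classifier <- function(x, ...) {
  cat(sprintf("<cfs_classifier> %s-threshold rule, n = %d\n",
              x$rule, length(x$cfs)))
  cat("thresholds: ",
      paste(sprintf("%s = %.2f", names(x$thresholds), x$thresholds),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.cfs_classifier <- function(object, ...) {
  pred <- predict(object)
  ref <- object$reference
  decided <- pred != "middle_depth"
  n_con <- sum(pred[decided] == ref[decided])
  out <- list(
    rule = object$rule,
    thresholds = object$thresholds,
    n = length(ref),
    n_decided = sum(decided),
    selection_rate = selection_rate(pred),
    n_concordant = n_con,
    accuracy = n_con / sum(decided),
    mcc = if (object$rule == "single") {
      a <- sum(pred == "floating" & ref == "floating")
      b <- sum(pred == "sunken" & ref == "floating")
      cc <- sum(pred == "floating" & ref == "sunken")
      d <- sum(pred == "sunken" & ref == "sunken")
      .mcc_counts(a, b, cc, d)
    } else NA_real_,
    class_counts = table(factor(pred, levels = PULSE_LABELS)))
  class(out) <- "summary.cfs_classifier"
  out
}

#' @export
print.summary.cfs_classifier <- function(x, ...) {
  cat(sprintf("Depth classifier (%s-threshold rule)\n", x$rule))
  cat("thresholds: ",
      paste(sprintf("%s = %.2f", names(x$thresholds), x$thresholds),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("decided %d / %d subjects (selection rate %.1f%%)\n",
              x$n_decided, x$n, 100 * x$selection_rate))
  cat(sprintf("concordant with reference: %d / %d (accuracy %.1f%%)\n",
              x$n_concordant, x$n_decided, 100 * x$accuracy))
  if (!is.na(x$mcc)) cat(sprintf("MCC = %.2f\n", x$mcc))
  cat("label counts:\n")
  print(x$class_counts)
  invisible(x)
}

#' @rdname cfs_classifier
#' @export
plot.cfs_classifier <- function(x, ...) {
  if (x$rule == "single") {
    sw <- x$sweep
    op <- par(mar = c(4.5, 4.5, 2, 4.5))
    on.exit(par(op))
    plot(sw$c_star, sw$n_concordant_floating, type = "l", col = "steelblue",
         ylim = c(0, max(sw$n_concordant)), xlab = "discriminant C*",
         ylab = "concordant decisions",
         main = "single-threshold sweep", ...)
    lines(sw$c_star, sw$n_concordant_sunken, col = "firebrick")
    lines(sw$c_star, sw$n_concordant, col = "black", lwd = 2)
    abline(v = x$thresholds[["c_star"]], lty = 2)
    legend("topleft", bty = "n", lwd = c(1, 1, 2),
           col = c("steelblue", "firebrick", "black"),
           legend = c("floating", "sunken", "total"))
  } else {
    fr <- x$sweep$frontier
    plot(fr$selection_rate, fr$accuracy, type = "s", pch = 19,
         xlab = "selection rate", ylab = "accuracy over decided",
         main = "accuracy vs. selection-rate frontier", ...)
    s <- summary(x)
    points(s$selection_rate, s$accuracy, pch = 19, col = "firebrick")
  }
  invisible(x)
}
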