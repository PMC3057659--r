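#' Single-threshold depth classification
#'
#' The basic decision rule: a pulse with depth coefficient at or below
#' the discriminant is floating, above it sunken.  The boundary belongs
#' to the floating class.
#'
#' @param cfs numeric vector of depth coefficients in \[0, 1\].
#' @param c_star discriminant threshold in \[0, 1\].
#' @return character vector of labels, `"floating"` or `"sunken"`.
#' @export
classify_single <- function(cfs, c_star) {
  .check_unit_interval(cfs, "cfs")
  .check_unit_interval(c_star, "c_star", scalar = TRUE)
  ifelse(cfs <= c_star, "floating", "sunken")
}

#' Dual-threshold depth classification with a middle-depth regime
#'
#' Uses separate discriminants for the two classes: coefficients at or
#' below `c_f` are floating, above `c_s` sunken, and the band in between
#' is labelled `"middle_depth"` (a reject option that trades selection
#' rate for accuracy, or — read positively — the third depth class).
#' With `c_f == c_s` the rule reduces exactly to [classify_single()].
#'
#' @param cfs numeric vector of depth coefficients in \[0, 1\].
#' @param c_f floating discriminant; must satisfy `c_f <= c_s`.
#' @param c_s sunken discriminant.
#' @return character vector of labels in
#'   `c("floating", "sunken", "middle_depth")`.
#' @export
classify_dual <- function(cfs, c_f, c_s) {
  .check_unit_interval(cfs, "cfs")
  if (!is.numeric(c_f) || !is.numeric(c_s) || length(c_f) != 1L ||
      length(c_s) != 1L)
    stop("'c_f' and 'c_s' must be scalars")
  if (c_f > c_s)
    stop(sprintf("'c_f' (%g) must not exceed 'c_s' (%g)", c_f, c_s))
  out <- rep("middle_depth", length(cfs))
  out[cfs <= c_f] <- "floating"
  out[cfs > c_s] <- "sunken"
  out
}

#' Selection rate of a labelling
#'
#' Fraction of subjects actually assigned a floating or sunken label;
#' middle-depth (undetermined) subjects count toward the denominator
#' only.
#'
#' @param labels character vector of pulse-class labels.
#' @return scalar in \[0, 1\].
#' @export
selection_rate <- function(labels) {
  if (length(labels) == 0L) stop("'labels' must be non-empty")
  bad <- setdiff(unique(labels), PULSE_LABELS)
  if (length(bad) > 0L)
    stop("unknown labels: ", paste(bad, collapse = ", "))
  mean(labels %in% c("floating", "sunken"))
}

#' Sweep the single-threshold rule over a discriminant grid
#'
#' For every threshold on a regular grid over \[0, 1\], classifies the
#' cohort, cross-tabulates against the reference diagnoses and records
#' the concordant counts, accuracy and Matthews correlation coefficient.
#'
#' @param cfs numeric vector of depth coefficients.
#' @param reference character vector of reference labels (`"floating"`
#'   or `"sunken"`), same length as `cfs`.
#' @param grid_step grid spacing for the threshold sweep; default 0.01
#'   (discriminants are conventionally quoted to two decimals).
#' @return data.frame of class `cfs_sweep` with columns `c_star`,
#'   `n_concordant_floating`, `n_concordant_sunken`, `n_concordant`,
#'   `accuracy`, `mcc`, plus attributes `best_accuracy` and `best_mcc`
#'   (one row each; smallest threshold on ties).
#' @export
sweep_single <- function(cfs, reference, grid_step = 0.01) {
  .check_cohort(cfs, reference)
  grid <- seq(0, 1, by = grid_step)
  n <- length(cfs)
  rows <- lapply(grid, function(cs) {
    pred <- classify_single(cfs, cs)
    a <- sum(pred == "floating" & reference == "floating")
    b <- sum(pred == "sunken" & reference == "floating")
    cc <- sum(pred == "floating" & reference == "sunken")
    d <- sum(pred == "sunken" & reference == "sunken")
    data.frame(c_star = cs, n_concordant_floating = a,
               n_concordant_sunken = d, n_concordant = a + d,
               accuracy = (a + d) / n, mcc = .mcc_counts(a, b, cc, d))
  })
  res <- do.call(rbind, rows)
  class(res) <- c("cfs_sweep", "data.frame")
  attr(res, "best_accuracy") <- res[which.max(res$accuracy), , drop = FALSE]
  attr(res, "best_mcc") <- res[which.max(res$mcc), , drop = FALSE]
  res
}

#' Sweep the dual-threshold rule over all grid pairs
#'
#' Evaluates every pair `c_f <= c_s` on a regular grid: number of
#' decided subjects, concordant counts among the decided, accuracy over
#' the decided and selection rate.  Also extracts the selection-rate
#' frontier: for each achievable number of decisions, the maximum
#' concordant count and the threshold pair(s) achieving it.
#'
#' @inheritParams sweep_single
#' @return list of class `cfs_sweep_dual` with elements `table` (one row
#'   per grid pair: `c_f`, `c_s`, `n_decided`, `n_concordant`,
#'   `accuracy`, `selection_rate`) and `frontier` (one row per achievable
#'   `n_decided`, keeping the pair with maximal concordant count;
#'   among ties the widest band, i.e. smallest `c_f`, then largest
#'   `c_s`).  Accuracy is `NA` where no subject is decided.
#' @export
sweep_dual <- function(cfs, reference, grid_step = 0.01) {
  .check_cohort(cfs, reference)
  grid <- seq(0, 1, by = grid_step)
  n <- length(cfs)
  ref_f <- reference == "floating"
  pairs <- which(upper.tri(matrix(0, length(grid), length(grid)),
                           diag = TRUE), arr.ind = TRUE)
  c_f <- grid[pairs[, "row"]]
  c_s <- grid[pairs[, "col"]]
  m <- length(c_f)
  n_dec <- integer(m)
  n_con <- integer(m)
  for (i in seq_len(m)) {
    flo <- cfs <= c_f[i]
    snk <- cfs > c_s[i]
    n_dec[i] <- sum(flo) + sum(snk)
    n_con[i] <- sum(flo & ref_f) + sum(snk & !ref_f)
  }
  tab <- data.frame(c_f = c_f, c_s = c_s, n_decided = n_dec,
                    n_concordant = n_con,
                    accuracy = ifelse(n_dec > 0, n_con / n_dec, NA_real_),
                    selection_rate = n_dec / n)
  ord <- order(tab$n_decided, -tab$n_concordant, tab$c_f, -tab$c_s)
  sorted <- tab[ord, ]
  frontier <- sorted[!duplicated(sorted$n_decided), ]
  frontier <- frontier[order(frontier$n_decided), ]
  rownames(frontier) <- NULL
  structure(list(table = tab, frontier = frontier, grid_step = grid_step,
                 n = n),
            class = "cfs_sweep_dual")
}

#' @export
print.cfs_sweep_dual <- function(x, ...) {
  cat(sprintf("<cfs_sweep_dual> %d threshold pairs on a %.2g grid, n = %d\n",
              nrow(x$table), x$grid_step, x$n))
  cat("frontier (max concordant per number of decisions):\n")
  print(utils::head(x$frontier[order(-x$frontier$n_decided), ], 10),
        row.names = FALSE)
  invisible(x)
}

.mcc_counts <- function(a, b, cc, d) {
  m1 <- (a + b) * (a + cc) * (d + b) * (d + cc)
  if (m1 == 0) return(0)
  (a * d - b * cc) / sqrt(m1)
}

.check_unit_interval <- function(x, name, scalar = FALSE) {
  if (!is.numeric(x) || (scalar && length(x) != 1L))
    stop(sprintf("'%s' must be numeric%s", name, if (scalar) " scalar" else ""))
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name))
  invisible(x)
}

.check_cohort <- function(cfs, reference) {
  if (length(cfs) != length(reference))
    stop("'cfs' and 'reference' must have the same length")
  if (length(cfs) == 0L) stop("empty cohort")
  .check_unit_interval(cfs, "cfs")
  bad <- setdiff(unique(reference), c("floating", "sunken"))
  if (length(bad) > 0L)
    stop("reference labels must be binary (floating/sunken); found: ",
         paste(bad, collapse = ", "))
  invisible(NULL)
}
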