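#' Depth coefficient from the interpolated P-H curve
#'
#' The classic depth score: interpolate the discrete (P, H) points with a
#' shape-preserving piecewise cubic, locate the pressure P_opt at which
#' the interpolated pulse strength is maximal, and report its relative
#' position in the measured pressure range,
#' \deqn{C_{fs} = (P_{opt} - P_0) / (P_{max} - P_0),}
#' clipped to \[0, 1\].  Values near 0 indicate a floating pulse
#' (strength maximal at light pressure), values near 1 a sunken pulse.
#'
#' @param x a [step_profile()], or a numeric vector of pressures when
#'   `strengths` is supplied separately.
#' @param strengths pulse strengths matching `x` when `x` is a pressure
#'   vector.
#' @return a `cfs_coefficient` object (fields `value`, `method = "lee"`,
#'   `p_opt`, `p0`, `p_max`).
#' @details The monotone Fritsch–Carlson cubic
#'   (`splinefun(method = "monoH.FC")`) is used so the interpolant cannot
#'   overshoot between data points — unconstrained splines can place a
#'   spurious maximum outside the data's rise-and-fall pattern and flip
#'   the depth call.  The argmax is located on a dense grid (smallest
#'   maximizing pressure on ties, biasing toward floating) and polished
#'   by golden-section search in the bracketing cell.
#' @export
cfs_lee <- function(x, strengths = NULL) {
  if (inherits(x, "step_profile")) {
    P <- x$pressures
    H <- x$strengths
  } else {
    P <- as.numeric(x)
    H <- as.numeric(strengths)
  }
  if (length(P) < 3L || length(P) != length(H))
    stop("need at least 3 matched (pressure, strength) points")
  if (any(diff(P) <= 0))
    stop("'pressures' must be strictly increasing")
  f <- stats::splinefun(P, H, method = "monoH.FC")
  grid <- seq(P[1L], P[length(P)], length.out = 10001L)
  yg <- f(grid)
  i <- which.max(yg)                 # first index: smallest P on ties
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  p_opt <- grid[i]
  if (hi > lo) {
    opt <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE,
                           tol = .Machine$double.eps^0.5)
    if (opt$objective > yg[i]) p_opt <- opt$maximum
  }
  p0 <- P[1L]
  p_max <- P[length(P)]
  value <- min(1, max(0, (p_opt - p0) / (p_max - p0)))
  new_cfs(value, method = "lee", variant = "none",
          extra = list(p_opt = p_opt, p0 = p0, p_max = p_max))
}

#' Pick the shallow and deep strengths for the ratio coefficient
#'
#' Two selections from the five per-step strengths are supported:
#' variant `"v1"` uses the light/heavy pressure-step pairs,
#' `(H_shallow, H_deep) = ((H1 + H2)/2, (H4 + H5)/2)`; variant `"v2"`
#' compares single steps, `(H1, H4)` — i.e. pulse strengths at roughly
#' 37 and 143 mmHg with the standard five-step protocol.
#'
#' @param strengths numeric vector of five strengths (or a
#'   [step_profile()]).
#' @param variant `"v1"` or `"v2"`.
#' @return named numeric vector `c(shallow = , deep = )`.
#' @export
select_strengths <- function(strengths, variant = c("v1", "v2")) {
  variant <- match.arg(variant)
  h <- if (inherits(strengths, "step_profile")) strengths$strengths
       else as.numeric(strengths)
  if (length(h) != 5L) stop("expected five pulse strengths")
  if (variant == "v1")
    c(shallow = (h[1L] + h[2L]) / 2, deep = (h[4L] + h[5L]) / 2)
  else
    c(shallow = h[1L], deep = h[4L])
}

#' Depth coefficient from the shallow/deep strength ratio
#'
#' The normalized comparison of pulse strengths at a light and a heavy
#' hold-down pressure,
#' \deqn{C_{fs} = \frac{1}{2}\left(1 +
#'   \frac{H_{deep} - H_{shallow}}{H_{deep} + H_{shallow}}\right)
#'   = \frac{H_{deep}}{H_{shallow} + H_{deep}},}
#' which lies in \[0, 1\]: 0 for a purely floating pulse (no strength at
#' depth), 1 for a purely sunken one, and exactly 1/2 when the two
#' strengths are equal.  Unlike the interpolated-curve score it needs no
#' interpolation and is robust to non-unimodal P-H data.
#'
#' @param h_shallow pulse strength at the light pressure step(s), >= 0.
#' @param h_deep pulse strength at the heavy pressure step(s), >= 0.
#' @param variant optional tag recording which strength selection
#'   produced the pair (`"v1"`, `"v2"`, or `"none"`).
#' @return a `cfs_coefficient` object (fields `value`, `method = "new"`,
#'   `variant`, `h_shallow`, `h_deep`).
#' @export
cfs_new <- function(h_shallow, h_deep, variant = "none") {
  if (!is.finite(h_shallow) || !is.finite(h_deep) ||
      h_shallow < 0 || h_deep < 0)
    stop("strengths must be finite and non-negative")
  if (h_shallow == 0 && h_deep == 0)
    stop("undefined depth coefficient: both shallow and deep strengths ",
         "are zero (no pulse detected)")
  new_cfs(h_deep / (h_shallow + h_deep), method = "new", variant = variant,
          extra = list(h_shallow = h_shallow, h_deep = h_deep))
}

#' Depth coefficient for a three-location measurement
#'
#' Averages the strength profiles over Chon, Gwan and Cheok first (the
#' simultaneous-palpation extension), then computes the requested
#' coefficient on the averaged profile.
#'
#' @param measurement a [subject_measurement()] (or list of three
#'   [step_profile()]s).
#' @param method `"new"` (strength-ratio) or `"lee"`
#'   (interpolated-curve).
#' @param variant strength selection for `method = "new"`: `"v1"` or
#'   `"v2"`.
#' @return a `cfs_coefficient` object.
#' @export
cfs_subject <- function(measurement, method = c("new", "lee"),
                        variant = c("v1", "v2")) {
  method <- match.arg(method)
  profiles <- if (inherits(measurement, "subject_measurement"))
    measurement$profiles else measurement
  avg <- location_average(profiles)
  if (method == "lee") return(cfs_lee(avg))
  variant <- match.arg(variant)
  hs <- select_strengths(avg, variant)
  cfs_new(hs[["shallow"]], hs[["deep"]], variant = variant)
}

new_cfs <- function(value, method, variant, extra = list()) {
  stopifnot(value >= 0, value <= 1)
  structure(c(list(value = value, method = method, variant = variant),
              extra),
            class = "cfs_coefficient")
}

#' @export
print.cfs_coefficient <- function(x, ...) {
  tag <- if (x$variant == "none") x$method
         else sprintf("%s(%s)", x$method, x$variant)
  cat(sprintf("C_fs [%s] = %.4f\n", tag, x$value))
  invisible(x)
}

#' @export
as.double.cfs_coefficient <- function(x, ...) x$value
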