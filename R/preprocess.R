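#' Segment a recording into its five pressure steps
#'
#' Finds the five constant-pressure plateaus of a stepped hold-down
#' pressure protocol.  Explicit step boundaries stored on the record are
#' echoed unchanged; otherwise plateaus are detected on the pressure trace
#' by thresholding the local slope of a median-filtered copy.  Intervals
#' are returned ordered by increasing mean pressure.
#'
#' @param record a [pulse_record()].
#' @param min_plateau_s minimum plateau duration in seconds for a run of
#'   quasi-constant pressure to count as a step.
#' @param max_slope_mmhg_s absolute pressure slope (mmHg/s) below which
#'   the trace is considered to be holding a plateau.
#' @return a list with `boundaries` (5 x 2 matrix of inclusive sample
#'   indices) and `pressures` (per-step mean pressure, mmHg, increasing).
#' @details Slopes are measured over a 0.25 s central difference of the
#'   trace after median filtering over ~0.5 s, which suppresses both
#'   sensor noise and pulse ripple feeding into the pressure channel.
#' @export
segment_steps <- function(record, min_plateau_s = 2,
                          max_slope_mmhg_s = 20) {
  stopifnot(inherits(record, "pulse_record"))
  if (!is.null(record$step_boundaries)) {
    b <- record$step_boundaries
    p <- .step_pressures_for(record, b)
    ord <- order(p)
    return(list(boundaries = b[ord, , drop = FALSE], pressures = p[ord]))
  }
  tr <- record$pressure_trace
  fs <- record$sampling_rate
  n <- length(tr)
  k <- max(3L, round(0.5 * fs))
  if (k %% 2L == 0L) k <- k + 1L
  sm <- if (n > k) runmed(tr, k) else tr
  h <- max(1L, round(0.125 * fs))
  slope <- rep(0, n)
  idx <- (h + 1L):(n - h)
  if (length(idx) < 2L) stop("pressure trace too short to segment")
  slope[idx] <- (sm[idx + h] - sm[idx - h]) * fs / (2 * h)
  # edge samples inherit the nearest interior slope
  slope[seq_len(h)] <- slope[h + 1L]
  slope[(n - h + 1L):n] <- slope[n - h]
  holding <- abs(slope) <= max_slope_mmhg_s
  r <- rle(holding)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= round(min_plateau_s * fs)
  if (sum(keep) != 5L)
    stop(sprintf("expected 5 pressure plateaus, found %d", sum(keep)))
  b <- cbind(first = starts[keep], last = ends[keep])
  p <- vapply(seq_len(5L), function(i) mean(tr[b[i, 1L]:b[i, 2L]]),
              numeric(1))
  ord <- order(p)
  b <- b[ord, , drop = FALSE]
  rownames(b) <- paste0("step", 1:5)
  list(boundaries = b, pressures = p[ord])
}

.step_pressures_for <- function(record, boundaries) {
  if (!is.null(record$pressure_trace)) {
    vapply(seq_len(5L), function(i) {
      mean(record$pressure_trace[boundaries[i, 1L]:boundaries[i, 2L]])
    }, numeric(1))
  } else if (!is.null(record$step_pressures)) {
    record$step_pressures
  } else {
    stop("cannot determine step pressures: record has neither a pressure ",
         "trace nor explicit step pressures")
  }
}

#' Remove slow baseline drift by polynomial detrending
#'
#' Models the baseline of a pressure-step segment as a polynomial of the
#' given order and subtracts it, aligning the wander that respiration,
#' arm movement and the pressure-dependent sensor offset push around
#' while leaving the (much faster) pulse oscillation intact.
#'
#' By default (`robust = TRUE`) the polynomial is fitted by asymmetric
#' least squares: samples above the current baseline get a small weight
#' (0.01), samples below it full weight, and the fit is iterated to a
#' fixed point, after which the polynomial is refitted through the
#' deepest 30% of residuals only.  The pulse spends a substantial part
#' of each cycle on its diastolic foot, so the asymmetric fit settles on
#' the foot and the polynomial stays a pure baseline model.  Fitting the
#' raw samples symmetrically (`robust = FALSE`) lets the polynomial
#' absorb a few percent of the beat train itself — the low-order
#' projection of a 1–2 Hz pulse over a 5 s window is not negligible —
#' which biases every downstream strength estimate.
#'
#' @param samples numeric vector, one pressure-step segment.
#' @param order polynomial order of the baseline model (default 5).
#' @param robust fit the polynomial asymmetrically to the beat feet
#'   (default) rather than symmetrically to all samples.
#' @return the baseline-corrected samples.  With `robust = FALSE` the
#'   output has mean ~ 0; with the default baseline model the beat
#'   remains positive above its corrected foot (only the peak-to-trough
#'   amplitude matters downstream).
#' @export
detrend_baseline <- function(samples, order = 5L, robust = TRUE) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n <= order + 1L)
    stop(sprintf(
      "segment of %d samples is too short for an order-%d baseline fit",
      n, order))
  basis <- cbind(1, stats::poly(seq_len(n), degree = order))
  if (!robust) {
    fit <- stats::lm.fit(basis, samples)
    return(samples - as.numeric(basis %*% fit$coefficients))
  }
  w <- rep(1, n)
  base <- samples
  for (it in 1:15) {
    fit <- stats::lm.wfit(basis, samples, w)
    base <- as.numeric(basis %*% fit$coefficients)
    w_new <- ifelse(samples > base, 0.01, 1)
    if (it > 1L && all(w_new == w)) break
    w <- w_new
  }
  # hard refit through the deepest 30% of residuals, iterated to a fixed
  # point: on a flat or polynomial foot this is exact, and it drops the
  # residual pull the soft pass still feels from the beats
  ptp <- max(samples) - min(samples)
  for (it in 1:8) {
    r <- samples - base
    sel <- r <= quantile(r, 0.3, names = FALSE)
    if (sum(sel) <= order + 1L) break
    fit <- stats::lm.fit(basis[sel, , drop = FALSE], samples[sel])
    newbase <- as.numeric(basis %*% fit$coefficients)
    converged <- max(abs(newbase - base)) < 1e-12 * max(ptp, 1e-300)
    base <- newbase
    if (converged) break
  }
  samples - base
}

#' Ensemble-average the beats of a baseline-corrected segment
#'
#' Detects beat peaks within a physiologic heart-rate band, aligns the
#' beats on their peaks and averages them point-wise over a fixed window
#' of one median beat period.  Beats whose window would run past the
#' segment edges are discarded.
#'
#' @param samples baseline-corrected segment (numeric vector).
#' @param sampling_rate sampling rate in Hz.
#' @param hr_bounds heart-rate band in beats/min used to constrain peak
#'   picking; default `c(40, 180)`.
#' @return numeric vector: the averaged single-beat waveform, with
#'   attributes `n_beats` (beats averaged) and `period` (median beat
#'   period in samples).
#' @details Peak picking keeps local maxima whose local prominence
#'   (height above the surrounding minimum within one minimum beat
#'   period) exceeds 25% of the segment peak-to-trough range, then
#'   enforces the minimum peak distance `60 / hr_bounds[2]` s greedily by
#'   descending height.  The averaging window spans 0.35 periods before
#'   to 0.65 periods after each peak.
#' @export
average_beat <- function(samples, sampling_rate, hr_bounds = c(40, 180)) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 3L) stop("segment too short for beat detection")
  min_dist <- max(1L, round(sampling_rate * 60 / hr_bounds[2L]))
  peaks <- .find_beat_peaks(samples, min_dist)
  if (length(peaks) < 2L)
    stop(sprintf("fewer than 2 beats detected (found %d)", length(peaks)))
  period <- median(diff(peaks))
  pre <- floor(0.35 * period)
  post <- ceiling(0.65 * period)
  keep <- peaks - pre >= 1L & peaks + post <= n
  peaks <- peaks[keep]
  if (length(peaks) < 2L)
    stop("fewer than 2 complete beats inside the segment after discarding ",
         "edge beats")
  mat <- vapply(peaks, function(p) samples[(p - pre):(p + post)],
                numeric(pre + post + 1L))
  beat <- rowMeans(mat)
  attr(beat, "n_beats") <- length(peaks)
  attr(beat, "period") <- period
  beat
}

# local maxima filtered by local prominence, then greedy min-distance
.find_beat_peaks <- function(x, min_dist, prominence_frac = 0.25) {
  n <- length(x)
  ptp <- max(x) - min(x)
  if (ptp <= 0) return(integer(0))
  cand <- which(x > c(-Inf, x[-n]) & x >= c(x[-1L], -Inf))
  prom <- vapply(cand, function(i) {
    lo <- max(1L, i - min_dist)
    hi <- min(n, i + min_dist)
    x[i] - min(x[lo:hi])
  }, numeric(1))
  cand <- cand[prom >= prominence_frac * ptp]
  if (length(cand) == 0L) return(integer(0))
  # keep the highest candidates first, dropping any within min_dist
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Pulse strength of an averaged beat
#'
#' The peak-to-trough amplitude of the ensemble-averaged beat: the H of
#' the P-H curve for one pressure step.
#'
#' @param beat numeric vector, an averaged single-beat waveform.
#' @return non-negative scalar, in the device's amplitude units.
#' @export
pulse_strength <- function(beat) {
  beat <- as.numeric(beat)
  if (length(beat) == 0L) stop("'beat' must be non-empty")
  max(beat) - min(beat)
}

#' Reduce a raw record to its per-step strength profile
#'
#' Runs the full acquisition chain for one recording: segment the five
#' pressure steps, trim the settle time at each plateau edge, detrend the
#' baseline per step, ensemble-average the beats, and take the
#' peak-to-trough strength — yielding the discrete P-H curve
#' (P1..P5, H1..H5).
#'
#' @param record a [pulse_record()].
#' @param poly_order baseline polynomial order (default 5).
#' @param hr_bounds heart-rate band for beat detection (beats/min).
#' @param edge_trim_s seconds discarded at both plateau edges before beat
#'   analysis (actuator settle time); default 0.25.
#' @return a [step_profile()].
#' @export
build_profile <- function(record, poly_order = 5L, hr_bounds = c(40, 180),
                          edge_trim_s = 0.25) {
  stopifnot(inherits(record, "pulse_record"))
  seg <- segment_steps(record)
  fs <- record$sampling_rate
  trim <- round(edge_trim_s * fs)
  strengths <- vapply(seq_len(5L), function(i) {
    lo <- seg$boundaries[i, 1L] + trim
    hi <- seg$boundaries[i, 2L] - trim
    if (hi - lo + 1L < 3L)
      stop(sprintf("step %d: plateau too short after edge trimming", i))
    tryCatch({
      y <- detrend_baseline(record$samples[lo:hi], order = poly_order)
      beat <- average_beat(y, fs, hr_bounds)
      pulse_strength(beat)
    }, error = function(e) {
      stop(sprintf("step %d: %s", i, conditionMessage(e)), call. = FALSE)
    })
  }, numeric(1))
  step_profile(record$location, seg$pressures, strengths,
               subject_id = record$subject_id)
}

#' Average strength profiles over the three palpation locations
#'
#' Element-wise mean of pressures and strengths over Chon, Gwan and
#' Cheok: H_i = (H_Chon,i + H_Gwan,i + H_Cheok,i) / 3.
#'
#' @param profiles list of three [step_profile()]s, one per location.
#' @return a [step_profile()] with `location = "averaged"`.
#' @export
location_average <- function(profiles) {
  if (!is.list(profiles) ||
      !all(vapply(profiles, inherits, logical(1), "step_profile")))
    stop("'profiles' must be a list of step_profile objects")
  locs <- vapply(profiles, `[[`, character(1), "location")
  if (!setequal(locs, PULSE_LOCATIONS) || length(locs) != 3L)
    stop("need exactly one profile per location (Chon, Gwan, Cheok); got: ",
         paste(locs, collapse = ", "))
  P <- rowMeans(vapply(profiles, `[[`, numeric(5), "pressures"))
  H <- rowMeans(vapply(profiles, `[[`, numeric(5), "strengths"))
  step_profile("averaged", P, H, subject_id = profiles[[1L]]$subject_id)
}

#' Maximum pulse strength over the pressure steps
#'
#' @param x a [step_profile()] or a numeric vector of five strengths.
#' @return scalar, `max(H1..H5)`.
#' @export
h_max <- function(x) {
  h <- if (inherits(x, "step_profile")) x$strengths else as.numeric(x)
  if (length(h) != 5L) stop("expected five pulse strengths")
  max(h)
}
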