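#' Raw pulse record
#'
#' Container for a single-channel pulse waveform recorded at one palpation
#' location while the hold-down pressure is stepped through five levels.
#' The pressure information is carried either as a per-sample pressure
#' trace (mmHg) or as five explicit step boundaries (sample-index
#' intervals); explicit boundaries always take precedence during
#' segmentation.
#'
#' @param samples numeric vector of sensor amplitudes (device-specific
#'   units).
#' @param sampling_rate sampling rate in Hz; must be positive.
#' @param pressure_trace optional numeric vector, same length as
#'   `samples`, hold-down pressure in mmHg per sample.
#' @param step_boundaries optional 5 x 2 integer matrix of inclusive
#'   sample-index intervals, one row per pressure step.
#' @param step_pressures optional numeric vector of five per-step mean
#'   pressures (mmHg); used when boundaries are supplied without a trace.
#' @param location palpation position, one of `"Chon"`, `"Gwan"`,
#'   `"Cheok"`.
#' @param subject_id opaque subject identifier.
#' @return an object of class `pulse_record`.
#' @seealso [segment_steps()], [build_profile()], [read_waveform_csv()]
#' @export
pulse_record <- function(samples, sampling_rate, pressure_trace = NULL,
                         step_boundaries = NULL, step_pressures = NULL,
                         location = "Gwan", subject_id = "subject") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("'samples' must be non-empty")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("'sampling_rate' must be a single positive number")
  if (is.null(pressure_trace) && is.null(step_boundaries))
    stop("a pulse_record needs either a 'pressure_trace' or 'step_boundaries'")
  if (!is.null(pressure_trace)) {
    pressure_trace <- as.numeric(pressure_trace)
    if (length(pressure_trace) != length(samples))
      stop("'pressure_trace' must have the same length as 'samples'")
  }
  if (!is.null(step_boundaries)) {
    step_boundaries <- .validate_boundaries(step_boundaries, length(samples))
  }
  if (!is.null(step_pressures)) {
    step_pressures <- as.numeric(step_pressures)
    if (length(step_pressures) != 5L)
      stop("'step_pressures' must contain five values")
  }
  location <- match.arg(location, PULSE_LOCATIONS)
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         pressure_trace = pressure_trace, step_boundaries = step_boundaries,
         step_pressures = step_pressures, location = location,
         subject_id = as.character(subject_id)),
    class = "pulse_record")
}

.validate_boundaries <- function(b, n_samples) {
  b <- as.matrix(b)
  storage.mode(b) <- "integer"
  if (nrow(b) != 5L || ncol(b) != 2L)
    stop("'step_boundaries' must be a 5 x 2 matrix of sample indices")
  if (any(b[, 1L] < 1L) || any(b[, 2L] > n_samples) || any(b[, 1L] > b[, 2L]))
    stop("'step_boundaries' intervals must lie within the recording")
  ord <- order(b[, 1L])
  b <- b[ord, , drop = FALSE]
  if (any(b[-1L, 1L] <= b[-5L, 2L]))
    stop("'step_boundaries' intervals must be non-overlapping")
  dimnames(b) <- list(paste0("step", 1:5), c("first", "last"))
  b
}

#' @export
print.pulse_record <- function(x, ...) {
  cat(sprintf("<pulse_record> subject %s, location %s\n",
              x$subject_id, x$location))
  cat(sprintf("  %d samples at %g Hz (%.1f s)\n", length(x$samples),
              x$sampling_rate, length(x$samples) / x$sampling_rate))
  cat(sprintf("  pressure: %s\n",
              if (!is.null(x$pressure_trace)) "per-sample trace"
              else "explicit step boundaries"))
  invisible(x)
}

#' Per-step strength profile (P-H curve data)
#'
#' Holds the five hold-down pressures and the matching pulse strengths for
#' one palpation location: the discrete P-H curve every depth coefficient
#' consumes.
#'
#' @param location palpation position (or `"averaged"` for a
#'   three-location average).
#' @param pressures five strictly increasing hold-down pressures (mmHg).
#' @param strengths five non-negative pulse strengths (device units).
#' @param subject_id opaque subject identifier.
#' @return an object of class `step_profile`.
#' @export
step_profile <- function(location, pressures, strengths,
                         subject_id = "subject") {
  location <- match.arg(location, c(PULSE_LOCATIONS, "averaged"))
  pressures <- as.numeric(pressures)
  strengths <- as.numeric(strengths)
  if (length(pressures) != 5L || length(strengths) != 5L)
    stop("a step_profile holds exactly five (pressure, strength) pairs")
  if (any(!is.finite(pressures)) || any(diff(pressures) <= 0))
    stop("'pressures' must be finite and strictly increasing")
  if (any(!is.finite(strengths)) || any(strengths < 0))
    stop("'strengths' must be finite and non-negative")
  structure(
    list(location = location, pressures = pressures, strengths = strengths,
         subject_id = as.character(subject_id)),
    class = "step_profile")
}

#' @export
print.step_profile <- function(x, ...) {
  cat(sprintf("<step_profile> subject %s, location %s\n",
              x$subject_id, x$location))
  m <- rbind(`P (mmHg)` = round(x$pressures, 1),
             `H (device units)` = signif(x$strengths, 4))
  colnames(m) <- paste0("step", 1:5)
  print(m)
  invisible(x)
}

#' Plot the P-H curve of a strength profile
#'
#' @param x a [step_profile()].
#' @param ... passed to [plot()].
#' @export
plot.step_profile <- function(x, ...) {
  plot(x$pressures, x$strengths, type = "b", pch = 19,
       xlab = "hold-down pressure (mmHg)",
       ylab = "pulse strength (device units)",
       main = sprintf("%s / %s", x$subject_id, x$location), ...)
  invisible(x)
}

#' Subject-level measurement: one profile per palpation location
#'
#' @param profiles list of three [step_profile()]s, exactly one per
#'   location (Chon, Gwan, Cheok).
#' @param covariates optional named list or one-row data.frame of subject
#'   covariates (BMI, blood pressures, heart rate, gender, ...).
#' @param reference_label optional reference diagnosis, `"floating"` or
#'   `"sunken"`.
#' @param subject_id opaque subject identifier.
#' @return an object of class `subject_measurement`.
#' @export
subject_measurement <- function(profiles, covariates = NULL,
                                reference_label = NULL,
                                subject_id = "subject") {
  if (!is.list(profiles) ||
      !all(vapply(profiles, inherits, logical(1), "step_profile")))
    stop("'profiles' must be a list of step_profile objects")
  locs <- vapply(profiles, `[[`, character(1), "location")
  if (!setequal(locs, PULSE_LOCATIONS) || length(locs) != 3L)
    stop("need exactly one profile per location (Chon, Gwan, Cheok); got: ",
         paste(locs, collapse = ", "))
  names(profiles) <- locs
  profiles <- profiles[PULSE_LOCATIONS]
  if (!is.null(reference_label))
    reference_label <- match.arg(reference_label, c("floating", "sunken"))
  structure(
    list(profiles = profiles, covariates = covariates,
         reference_label = reference_label,
         subject_id = as.character(subject_id)),
    class = "subject_measurement")
}

#' @export
print.subject_measurement <- function(x, ...) {
  cat(sprintf("<subject_measurement> subject %s%s\n", x$subject_id,
              if (!is.null(x$reference_label))
                sprintf(" (reference: %s)", x$reference_label) else ""))
  for (p in x$profiles)
    cat(sprintf("  %-5s H = %s\n", p$location,
                paste(signif(p$strengths, 4), collapse = ", ")))
  invisible(x)
}
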