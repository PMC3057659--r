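# shared constructions for waveform-level tests

# one beat sampled over an integer period, unit peak-to-trough
beat_tile <- function(period) {
  tau <- (seq_len(period) - 1) / period
  s <- exp(-(tau - 0.28)^2 / (2 * 0.045^2)) +
    0.22 * exp(-(tau - 0.52)^2 / (2 * 0.055^2))
  s <- s - min(s)
  s <- pmax(s - 0.02 * max(s), 0)   # flat diastolic foot
  s / max(s)
}

# five-plateau pressure staircase with linear ramps
staircase_trace <- function(levels, fs = 100, step_s = 5, ramp_s = 0.5) {
  ns <- round(step_s * fs)
  nr <- round(ramp_s * fs)
  out <- numeric(0)
  for (j in seq_along(levels)) {
    out <- c(out, rep(levels[j], ns))
    if (j < length(levels))
      out <- c(out, levels[j] + seq_len(nr) / (nr + 1) *
                 (levels[j + 1] - levels[j]))
  }
  out
}

# a record whose plateaus carry tiled beats of the given strengths
staircase_record <- function(strengths,
                             levels = c(37, 73, 108, 143, 181),
                             fs = 100, step_s = 5, ramp_s = 0.5,
                             period = 80, location = "Gwan",
                             subject_id = "fixture") {
  trace <- staircase_trace(levels, fs, step_s, ramp_s)
  ns <- round(step_s * fs)
  nr <- round(ramp_s * fs)
  tile <- beat_tile(period)
  amp <- numeric(length(trace))
  pos <- 0L
  for (j in seq_along(strengths)) {
    amp[pos + seq_len(ns)] <- strengths[j]
    pos <- pos + ns
    if (j < length(strengths)) {
      amp[pos + seq_len(nr)] <- strengths[j] + seq_len(nr) / (nr + 1) *
        (strengths[j + 1] - strengths[j])
      pos <- pos + nr
    }
  }
  samples <- amp * rep_len(tile, length(trace))
  pulse_record(samples, fs, pressure_trace = trace, location = location,
               subject_id = subject_id)
}

# profile with prescribed strengths at the standard step pressures
profile_with <- function(strengths, location = "Gwan",
                         pressures = c(37, 73, 108, 143, 181)) {
  step_profile(location, pressures, strengths)
}

# three-location measurement from a 3 x 5 strength matrix (rows = Chon,
# Gwan, Cheok)
measurement_with <- function(h, reference_label = NULL) {
  profs <- lapply(1:3, function(i)
    profile_with(h[i, ], location = c("Chon", "Gwan", "Cheok")[i]))
  subject_measurement(profs, reference_label = reference_label)
}
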