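#' Read a pulse waveform CSV
#'
#' The interchange dialect is a plain UTF-8 CSV with a header and columns
#' `time_s`, `amplitude` and (optionally) `pressure_mmHg`, one file per
#' subject-location.  The sampling rate is inferred from the median time
#' step; files whose time base is non-monotone or jitters by more than
#' 5% of the median step are rejected.  When the pressure column is
#' absent, step boundaries (and optionally per-step pressures) must come
#' from a JSON sidecar.
#'
#' @param path CSV file path.
#' @param sidecar optional path to a JSON sidecar with fields
#'   `step_boundaries` (5 x 2 array of sample indices) and optionally
#'   `step_pressures`; also read automatically from `<path>.json` when
#'   that file exists.
#' @param location,subject_id metadata for the record; defaults are
#'   taken from the sidecar when present.
#' @return a [pulse_record()].
#' @export
read_waveform_csv <- function(path, sidecar = NULL, location = "Gwan",
                              subject_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  for (col in c("time_s", "amplitude"))
    if (!col %in% names(df))
      stop(sprintf("waveform file '%s' lacks required column '%s'",
                   path, col))
  t <- df$time_s
  if (length(t) < 2L) stop("waveform file has fewer than 2 samples")
  dt <- diff(t)
  if (any(dt <= 0)) stop("'time_s' must be strictly increasing")
  med <- median(dt)
  if (max(abs(dt - med)) / med > 0.05)
    stop(sprintf(
      "irregular sampling in '%s': time step deviates by %.1f%% from the median",
      path, 100 * max(abs(dt - med)) / med))
  side <- NULL
  if (is.null(sidecar) && file.exists(paste0(path, ".json")))
    sidecar <- paste0(path, ".json")
  if (!is.null(sidecar))
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  boundaries <- side$step_boundaries
  if (!is.null(boundaries)) boundaries <- matrix(as.integer(boundaries),
                                                 ncol = 2L)
  if (is.null(subject_id))
    subject_id <- if (!is.null(side$subject_id)) side$subject_id
                  else sub("\\.csv$", "", basename(path))
  if (!is.null(side$location)) location <- side$location
  pulse_record(
    samples = df$amplitude, sampling_rate = 1 / med,
    pressure_trace = if ("pressure_mmHg" %in% names(df)) df$pressure_mmHg,
    step_boundaries = boundaries,
    step_pressures = side$step_pressures,
    location = location, subject_id = subject_id)
}

#' Write a pulse waveform CSV
#'
#' Inverse of [read_waveform_csv()]; records carrying explicit step
#' boundaries get a JSON sidecar at `<path>.json`.
#'
#' @param record a [pulse_record()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(record, path) {
  stopifnot(inherits(record, "pulse_record"))
  n <- length(record$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / record$sampling_rate,
                   amplitude = record$samples)
  if (!is.null(record$pressure_trace))
    df$pressure_mmHg <- record$pressure_trace
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(record$step_boundaries) || !is.null(record$step_pressures)) {
    side <- list(subject_id = record$subject_id,
                 location = record$location)
    if (!is.null(record$step_boundaries))
      side$step_boundaries <- unname(record$step_boundaries)
    if (!is.null(record$step_pressures))
      side$step_pressures <- record$step_pressures
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Write / read per-step strength profiles
#'
#' Long-format CSV with columns `subject_id`, `location`, `step`,
#' `pressure_mmHg`, `strength`.
#'
#' @param profiles a list of [step_profile()]s, a list of
#'   [subject_measurement()]s, or a [simulate_cohort()] result.
#' @param path CSV path.
#' @return `write_profiles_csv()` returns `path` invisibly;
#'   `read_profiles_csv()` returns a list of [subject_measurement()]s
#'   (subjects with all three locations) or bare [step_profile()]s.
#' @export
write_profiles_csv <- function(profiles, path) {
  if (inherits(profiles, "pulse_cohort")) profiles <- profiles$measurements
  flat <- list()
  for (p in profiles) {
    if (inherits(p, "subject_measurement"))
      flat <- c(flat, unname(p$profiles))
    else if (inherits(p, "step_profile"))
      flat <- c(flat, list(p))
    else stop("unsupported profile container")
  }
  rows <- lapply(flat, function(p)
    data.frame(subject_id = p$subject_id, location = p$location,
               step = 1:5, pressure_mmHg = p$pressures,
               strength = p$strengths))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject_id", "location", "step", "pressure_mmHg", "strength")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("profiles file lacks column(s): ", paste(missing, collapse = ", "))
  out <- list()
  for (sid in unique(df$subject_id)) {
    sub <- df[df$subject_id == sid, ]
    profs <- lapply(split(sub, sub$location), function(d) {
      d <- d[order(d$step), ]
      step_profile(d$location[1L], d$pressure_mmHg, d$strength,
                   subject_id = sid)
    })
    out[[as.character(sid)]] <-
      if (setequal(names(profs), PULSE_LOCATIONS))
        subject_measurement(unname(profs), subject_id = sid)
      else if (length(profs) == 1L) profs[[1L]]
      else profs
  }
  out
}

#' Run the full depth-classification pipeline
#'
#' Executes simulate (or load) -> preprocess -> depth coefficients ->
#' classification -> agreement statistics, writing `profiles.csv`,
#' `cfs.csv`, `labels.csv` and `stats.json` under `out_dir`.
#'
#' @param config a list with entries:
#'   \describe{
#'     \item{`n_floating`, `n_sunken`, `seed`, `waveforms`}{cohort
#'       simulation settings (used unless `input_dir` is given).}
#'     \item{`input_dir`}{directory of waveform CSVs (with optional JSON
#'       sidecars), three per subject, named
#'       `<subject>_<location>.csv`; overrides simulation.}
#'     \item{`method`, `variant`}{depth coefficient, as in
#'       [cfs_subject()]; defaults `"new"`, `"v2"`.}
#'     \item{`c_star` or (`c_f`, `c_s`)}{decision thresholds; a pair
#'       engages the dual rule with its middle-depth regime.  Must
#'       satisfy `c_f <= c_s`; validated before any computation.}
#'     \item{`out_dir`}{output directory (created if needed).}
#'   }
#' @return invisibly, a list with the cfs table, labels, selection rate
#'   and (when references exist) the agreement statistics.
#' @export
run_pipeline <- function(config) {
  method <- config$method %||% "new"
  variant <- config$variant %||% "v2"
  out_dir <- config$out_dir %||% stop("config needs an 'out_dir'")
  if (!is.null(config[["c_f"]]) || !is.null(config[["c_s"]])) {
    if (is.null(config[["c_f"]]) || is.null(config[["c_s"]]))
      stop("dual rule needs both 'c_f' and 'c_s'")
    if (config[["c_f"]] > config[["c_s"]])
      stop(sprintf("invalid thresholds: c_f (%g) > c_s (%g)",
                   config[["c_f"]], config[["c_s"]]))
    .check_unit_interval(c(config[["c_f"]], config[["c_s"]]), "thresholds")
  } else {
    .check_unit_interval(config[["c_star"]] %||% 0.5, "c_star", scalar = TRUE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$input_dir)) {
    files <- list.files(config$input_dir, pattern = "\\.csv$",
                        full.names = TRUE)
    if (length(files) == 0L)
      stop("no waveform CSVs found in ", config$input_dir)
    recs <- lapply(files, function(f) {
      loc <- regmatches(f, regexpr("Chon|Gwan|Cheok", f))
      rec <- tryCatch(
        read_waveform_csv(f, location = if (length(loc)) loc else "Gwan"),
        error = function(e) stop("stage read: file ", basename(f), ": ",
                                 conditionMessage(e), call. = FALSE))
      rec
    })
    sids <- vapply(recs, function(r)
      sub("_(Chon|Gwan|Cheok)$", "", r$subject_id), character(1))
    meas <- lapply(split(recs, sids), function(rs) {
      profs <- lapply(rs, function(r)
        tryCatch(build_profile(r),
                 error = function(e)
                   stop("stage preprocess: subject ", r$subject_id, ": ",
                        conditionMessage(e), call. = FALSE)))
      subject_measurement(profs, subject_id = sub("_(Chon|Gwan|Cheok)$",
                                                  "",
                                                  rs[[1L]]$subject_id))
    })
    meas <- unname(meas)
    reference <- rep(NA_character_, length(meas))
  } else {
    cohort <- simulate_cohort(config$n_floating %||% 49,
                              config$n_sunken %||% 72,
                              seed = config$seed %||% 1,
                              waveforms = isTRUE(config$waveforms))
    if (isTRUE(config$waveforms)) {
      meas <- lapply(seq_along(cohort$measurements), function(i) {
        profs <- lapply(cohort$records[[i]], build_profile)
        subject_measurement(
          unname(profs),
          reference_label = cohort$measurements[[i]]$reference_label,
          subject_id = cohort$measurements[[i]]$subject_id)
      })
    } else meas <- cohort$measurements
    reference <- vapply(meas, function(m)
      m$reference_label %||% NA_character_, character(1))
  }

  write_profiles_csv(meas, file.path(out_dir, "profiles.csv"))
  cfs_tab <- data.frame(
    subject_id = vapply(meas, `[[`, character(1), "subject_id"),
    method = method, variant = if (method == "new") variant else "none",
    cfs = vapply(meas, function(m)
      tryCatch(cfs_subject(m, method = method, variant = variant)$value,
               error = function(e)
                 stop("stage coefficients: subject ", m$subject_id, ": ",
                      conditionMessage(e), call. = FALSE)), numeric(1)))
  utils::write.csv(cfs_tab, file.path(out_dir, "cfs.csv"),
                   row.names = FALSE)

  labels <- if (!is.null(config[["c_f"]]))
    classify_dual(cfs_tab$cfs, config[["c_f"]], config[["c_s"]])
  else
    classify_single(cfs_tab$cfs, config[["c_star"]] %||% 0.5)
  lab_tab <- data.frame(subject_id = cfs_tab$subject_id, label = labels,
                        reference = reference)
  utils::write.csv(lab_tab, file.path(out_dir, "labels.csv"),
                   row.names = FALSE)

  stats <- list(n = length(labels),
                selection_rate = selection_rate(labels),
                label_counts = as.list(table(labels)))
  if (!anyNA(reference)) {
    decided <- labels != "middle_depth"
    if (any(decided)) {
      tab <- agreement_table(labels[decided], reference[decided])
      stats$accuracy <- accuracy(tab)
      stats$mcc <- mcc(tab)
      stats$n_decided <- sum(decided)
    }
  }
  jsonlite::write_json(stats, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cfs = cfs_tab, labels = lab_tab, stats = stats))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
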