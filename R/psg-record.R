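#' Signal trace
#'
#' A single labelled channel: samples, sampling rate and physical unit.
#'
#' @param label channel name (non-empty string).
#' @param samples numeric vector, all finite.
#' @param fs sampling rate in Hz (> 0).
#' @param unit physical unit string.
#' @return object of class `signal_trace`.
#' @export
signal_trace <- function(label, samples, fs, unit = "") {
  stopifnot(is.character(label), nzchar(label), fs > 0)
  if (!all(is.finite(samples))) {
    stop_somnoage("trace '", label, "' contains non-finite samples",
                  class = "somnoage_trace_error")
  }
  structure(list(label = label, samples = as.numeric(samples),
                 fs = fs, unit = unit),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace '%s': %d samples @ %g Hz [%s]>\n",
              x$label, length(x$samples), x$fs, x$unit))
  invisible(x)
}

#' Subject metadata
#'
#' Ages above 89 are stored as 90 with `age_truncated = TRUE`, matching
#' cohort de-identification practice.
#'
#' @param subject_id identifier string.
#' @param age chronological age in years (`NA` if unknown).
#' @param sex `"M"`, `"F"` or `NA`.
#' @param bmi body-mass index in kg/m^2.
#' @param cohort cohort label.
#' @param cpap_user,neuro_disorder logical flags forcing test-set
#'   allocation downstream.
#' @return object of class `subject_meta`.
#' @export
subject_meta <- function(subject_id, age = NA_real_, sex = NA_character_,
                         bmi = NA_real_, cohort = "default",
                         cpap_user = FALSE, neuro_disorder = FALSE) {
  truncated <- isTRUE(!is.na(age) && age > 89)
  if (truncated) age <- 90
  if (!is.na(age) && age < 0) {
    stop_somnoage("age must be nonnegative", class = "somnoage_meta_error")
  }
  structure(list(subject_id = as.character(subject_id), age = age, sex = sex,
                 bmi = bmi, cohort = cohort, cpap_user = isTRUE(cpap_user),
                 neuro_disorder = isTRUE(neuro_disorder),
                 age_truncated = truncated),
            class = "subject_meta")
}

#' Polysomnography record
#'
#' @param meta a [subject_meta()].
#' @param traces named list of [signal_trace()] keyed by label.
#' @param start_time recording start (POSIXct or string), informational.
#' @param duration_s recording duration in seconds; defaults to the
#'   longest trace duration.
#' @return object of class `psg_record`.
#' @export
psg_record <- function(meta, traces, start_time = NA, duration_s = NULL) {
  stopifnot(inherits(meta, "subject_meta"), length(traces) >= 1)
  names(traces) <- vapply(traces, `[[`, "", "label")
  if (is.null(duration_s)) {
    duration_s <- max(vapply(traces, function(tr) length(tr$samples) / tr$fs, 0))
  }
  if (duration_s <= 0) {
    stop_somnoage("duration_s must be positive", class = "somnoage_record_error")
  }
  structure(list(meta = meta, traces = traces, start_time = start_time,
                 duration_s = duration_s, flags = character(0)),
            class = "psg_record")
}

#' @export
print.psg_record <- function(x, ...) {
  cat(sprintf("<psg_record %s: %d traces, %.1f h, age %s>\n",
              x$meta$subject_id, length(x$traces), x$duration_s / 3600,
              format(x$meta$age)))
  invisible(x)
}

#' Default channel-synonym table
#'
#' Maps common vendor labels to the canonical channel roles
#' `C3-M2, C4-M1, L-EOG, R-EOG, chinEMG, ECG, airflow, nasal_pressure,
#' thor_belt, abd_belt, SaO2`. Legacy mastoid labels A1/A2 are treated as
#' M1/M2. Matching is case-insensitive on a whitespace-squeezed label.
#'
#' @return named character vector: names are raw labels (lower case),
#'   values canonical roles.
#' @export
default_channel_synonyms <- function() {
  c("c3-m2" = "C3-M2", "c3-a2" = "C3-M2", "eeg c3-a2" = "C3-M2",
    "eeg c3-m2" = "C3-M2", "c3m2" = "C3-M2",
    "c4-m1" = "C4-M1", "c4-a1" = "C4-M1", "eeg c4-a1" = "C4-M1",
    "eeg c4-m1" = "C4-M1", "c4m1" = "C4-M1",
    "c3" = "C3", "eeg c3" = "C3", "c4" = "C4", "eeg c4" = "C4",
    "m1" = "M1", "a1" = "M1", "m2" = "M2", "a2" = "M2",
    "loc" = "L-EOG", "e1" = "L-EOG", "eog(l)" = "L-EOG", "eog l" = "L-EOG",
    "l-eog" = "L-EOG", "eogl" = "L-EOG",
    "roc" = "R-EOG", "e2" = "R-EOG", "eog(r)" = "R-EOG", "eog r" = "R-EOG",
    "r-eog" = "R-EOG", "eogr" = "R-EOG",
    "chin" = "chinEMG", "chin emg" = "chinEMG", "emg chin" = "chinEMG",
    "chin1-chin2" = "chinEMG", "chinemg" = "chinEMG",
    "ecg" = "ECG", "ekg" = "ECG", "ecg ii" = "ECG", "ecg1-ecg2" = "ECG",
    "airflow" = "airflow", "flow" = "airflow", "oral airflow" = "airflow",
    "thermistor" = "airflow",
    "nasal pressure" = "nasal_pressure", "nasal_pressure" = "nasal_pressure",
    "cannula" = "nasal_pressure", "pres" = "nasal_pressure",
    "thor" = "thor_belt", "chest" = "thor_belt", "thorax" = "thor_belt",
    "thor_belt" = "thor_belt",
    "abdo" = "abd_belt", "abd" = "abd_belt", "abdomen" = "abd_belt",
    "abd_belt" = "abd_belt",
    "sao2" = "SaO2", "spo2" = "SaO2", "osat" = "SaO2", "sat" = "SaO2")
}

.canon_label <- function(label, synonyms) {
  key <- tolower(gsub("\\s+", " ", trimws(label)))
  out <- unname(synonyms[key])
  ifelse(is.na(out), NA_character_, out)
}

#' Derive a referential channel
#'
#' Computes `"A-B"` as the samplewise difference of traces `A` and `B`,
#' or passes through a single trace `"A"`. When both a pre-derived
#' referential trace (for example `C3-M2`) and the raw operands exist, the
#' pre-derived trace is preferred to avoid double-referencing. Missing
#' operands yield a declared-missing marker (`NULL` with attribute), which
#' downstream assembly turns into a zero-substituted channel.
#'
#' @param record a [psg_record()].
#' @param spec derivation string, `"A-B"` or `"A"`.
#' @return a [signal_trace()], or a [missing_trace()] marker.
#' @export
derive_channel <- function(record, spec) {
  if (!is.null(record$traces[[spec]])) return(record$traces[[spec]])
  parts <- strsplit(spec, "-", fixed = TRUE)[[1]]
  if (length(parts) == 2) {
    a <- record$traces[[parts[1]]]
    b <- record$traces[[parts[2]]]
    if (is.null(a) || is.null(b)) return(missing_trace(spec))
    if (a$fs != b$fs) {
      stop_somnoage("operands of '", spec, "' have mismatched sampling rates (",
                    a$fs, " vs ", b$fs, "); resample first",
                    class = "somnoage_derive_error")
    }
    n <- min(length(a$samples), length(b$samples))
    return(signal_trace(spec, a$samples[seq_len(n)] - b$samples[seq_len(n)],
                        a$fs, a$unit))
  }
  tr <- record$traces[[spec]]
  if (is.null(tr)) return(missing_trace(spec))
  tr
}

#' Declared-missing channel marker
#'
#' Consumed by [assemble()], which substitutes a flat zero channel and
#' sets the corresponding mask bit.
#'
#' @param label role the marker stands in for.
#' @return object of class `missing_trace`.
#' @export
missing_trace <- function(label = "") {
  structure(list(label = label), class = "missing_trace")
}

#' @rdname missing_trace
#' @param x object to test.
#' @export
is_missing_trace <- function(x) inherits(x, "missing_trace")

#' Read a hypnogram from a tab-separated file
#'
#' One stage token per 30-s epoch, one per line. Tokens outside
#' `W, N1, N2, N3, REM` become `UNSCORED` with a warning that counts them.
#'
#' @param path file path.
#' @return object of class `hypnogram`: list with `stages` (character)
#'   and `epoch_len_s = 30`.
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) {
    stop_somnoage("hypnogram file not found: ", path,
                  class = "somnoage_ingest_error")
  }
  toks <- trimws(readLines(path, warn = FALSE))
  toks <- toks[nzchar(toks)]
  hypnogram(toks)
}

#' Construct a hypnogram from stage tokens
#'
#' @param stages character vector of per-30-s stage tokens.
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(stages) {
  valid <- c("W", "N1", "N2", "N3", "REM", "UNSCORED")
  bad <- !(stages %in% valid)
  if (any(bad)) {
    warning(sprintf("%d out-of-vocabulary stage tokens set to UNSCORED",
                    sum(bad)), call. = FALSE)
    stages[bad] <- "UNSCORED"
  }
  structure(list(stages = stages, epoch_len_s = 30), class = "hypnogram")
}

#' Read scored events from a tab-separated file
#'
#' Expected dialect: `type<TAB>onset_s<TAB>duration_s`, with types in
#' `arousal, apnea, hypopnea`. Intervals are half-open
#' `[onset, onset + duration)`.
#'
#' @param path file path.
#' @return a tibble of class `event_list` with columns `type`, `onset_s`,
#'   `duration_s`, sorted by onset.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) {
    stop_somnoage("event file not found: ", path,
                  class = "somnoage_ingest_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty event file: ", path, call. = FALSE)
    return(event_list(tibble::tibble(type = character(0),
                                     onset_s = numeric(0),
                                     duration_s = numeric(0))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) < 3) {
      stop_somnoage("malformed event line ", i, ": ", lines[i],
                    class = "somnoage_parse_error")
    }
  }
  ev <- tibble::tibble(
    type = vapply(parts, `[[`, "", 1),
    onset_s = as.numeric(vapply(parts, `[[`, "", 2)),
    duration_s = as.numeric(vapply(parts, `[[`, "", 3))
  )
  bad <- which(is.na(ev$onset_s) | is.na(ev$duration_s) |
                 ev$onset_s < 0 | ev$duration_s <= 0)
  if (length(bad)) {
    stop_somnoage("invalid onset/duration at line ", bad[1],
                  class = "somnoage_parse_error")
  }
  event_list(ev)
}

#' Construct an event list
#'
#' @param events data frame with columns `type`, `onset_s`, `duration_s`.
#' @return tibble of class `event_list`, sorted by onset.
#' @export
event_list <- function(events) {
  ev <- tibble::as_tibble(events)
  stopifnot(all(c("type", "onset_s", "duration_s") %in% names(ev)))
  if (nrow(ev) && (any(ev$onset_s < 0) || any(ev$duration_s <= 0))) {
    stop_somnoage("events must have onset_s >= 0 and duration_s > 0",
                  class = "somnoage_parse_error")
  }
  ev <- dplyr::arrange(ev, .data$onset_s)
  class(ev) <- c("event_list", class(ev))
  ev
}

#' Read subject metadata from a sidecar CSV
#'
#' Columns: `subject_id, age, sex, bmi, cohort, cpap_user, neuro_disorder`
#' (missing columns are filled with defaults).
#'
#' @param path CSV path.
#' @return tibble, one row per subject.
#' @export
read_subject_meta <- function(path) {
  if (!file.exists(path)) {
    stop_somnoage("metadata file not found: ", path,
                  class = "somnoage_ingest_error")
  }
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  stopifnot("subject_id" %in% names(df))
  defaults <- list(age = NA_real_, sex = NA_character_, bmi = NA_real_,
                   cohort = "default", cpap_user = FALSE,
                   neuro_disorder = FALSE)
  for (nm in names(defaults)) if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  df$subject_id <- as.character(df$subject_id)
  df
}
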