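#' Channel-set specification for the age-estimation models
#'
#' The four signal sets feeding the per-modality models:
#' * `"a"` central EEG: `C3-M2, C4-M1` (C = 2)
#' * `"b"` EEG+EOG+EMG: set (a) plus `L-EOG, R-EOG, chinEMG` (C = 5)
#' * `"c"` ECG only (C = 1)
#' * `"d"` respiratory: `airflow, nasal_pressure, thor_belt, abd_belt,
#'   SaO2` (C = 5)
#'
#' @param model_id one of `"a"`, `"b"`, `"c"`, `"d"`.
#' @return object of class `channel_set_spec` with fields `model_id`,
#'   `channels`, `C`.
#' @export
channel_set_spec <- function(model_id = c("a", "b", "c", "d")) {
  model_id <- match.arg(model_id)
  channels <- switch(model_id,
    a = c("C3-M2", "C4-M1"),
    b = c("C3-M2", "C4-M1", "L-EOG", "R-EOG", "chinEMG"),
    c = "ECG",
    d = c("airflow", "nasal_pressure", "thor_belt", "abd_belt", "SaO2"))
  structure(list(model_id = model_id, channels = channels,
                 C = length(channels)),
            class = "channel_set_spec")
}

#' All canonical channel roles (the full montage)
#' @return character vector of the 11 canonical roles.
#' @export
full_montage <- function() {
  c("C3-M2", "C4-M1", "L-EOG", "R-EOG", "chinEMG", "ECG",
    "airflow", "nasal_pressure", "thor_belt", "abd_belt", "SaO2")
}

#' Assemble preprocessed channels into the model input stack
#'
#' Stacks per-channel preprocessed traces into the C x T array in the
#' channel-set order. Missing channels are substituted by flat zero rows
#' with the corresponding mask bit set. T is trimmed to the shortest
#' present channel; channels differing by more than 1 s are treated as a
#' recording fault and the record is excluded. A record missing more
#' than one signal of the full montage is excluded rather than
#' zero-filled.
#'
#' @param traces named list of preprocessed [signal_trace()] /
#'   [missing_trace()] objects covering (at least) `spec$channels`. The
#'   missing-signal count is taken over all entries present in `traces`
#'   whose names belong to the full montage.
#' @param spec a [channel_set_spec()].
#' @param meta a [subject_meta()].
#' @param fs sampling rate of the stack (Hz).
#' @return object of class `preprocessed_record` with fields `x`
#'   (C x T), `mask`, `fs`, `channels`, `meta`, `excluded`,
#'   `exclude_reason`.
#' @export
assemble <- function(traces, spec, meta, fs = 128) {
  stopifnot(inherits(spec, "channel_set_spec"))
  montage <- intersect(names(traces), full_montage())
  n_missing <- sum(vapply(traces[montage], is_missing_trace, TRUE))
  if (n_missing > 1) {
    return(structure(list(x = NULL, mask = NULL, fs = fs,
                          channels = spec$channels, meta = meta,
                          excluded = TRUE,
                          exclude_reason = "gt1_signal_missing"),
                     class = "preprocessed_record"))
  }
  present <- spec$channels[!vapply(traces[spec$channels], is_missing_trace, TRUE)]
  if (length(present) == 0) {
    return(structure(list(x = NULL, mask = NULL, fs = fs,
                          channels = spec$channels, meta = meta,
                          excluded = TRUE, exclude_reason = "all_missing"),
                     class = "preprocessed_record"))
  }
  lens <- vapply(traces[present], function(tr) length(tr$samples), 0)
  if (max(lens) - min(lens) > fs) {
    return(structure(list(x = NULL, mask = NULL, fs = fs,
                          channels = spec$channels, meta = meta,
                          excluded = TRUE,
                          exclude_reason = "channel_length_mismatch"),
                     class = "preprocessed_record"))
  }
  Tn <- min(lens)
  x <- matrix(0, nrow = spec$C, ncol = Tn,
              dimnames = list(spec$channels, NULL))
  mask <- setNames(integer(spec$C), spec$channels)
  for (ch in spec$channels) {
    if (is_missing_trace(traces[[ch]])) {
      mask[ch] <- 1L
    } else {
      x[ch, ] <- traces[[ch]]$samples[seq_len(Tn)]
    }
  }
  structure(list(x = x, mask = unname(mask), fs = fs,
                 channels = spec$channels, meta = meta,
                 excluded = FALSE, exclude_reason = NA_character_),
            class = "preprocessed_record")
}

#' Cohort inclusion rules
#'
#' A recording is excluded when the participant's age is unknown, the
#' night was a CPAP split-night, or total sleep time is under 3 h
#' (strictly; exactly 3 h is kept). Total sleep time is 30 s times the
#' number of scored non-wake epochs. Without a hypnogram the sleep-time
#' rule is skipped with a warning.
#'
#' @param record a [psg_record()].
#' @param hypnogram a [hypnogram()] or `NULL`.
#' @param split_night logical: was this a CPAP split-night?
#' @return a tibble row: `keep` (logical), `reason` (code or `"ok"`),
#'   `tst_h` (hours, `NA` without hypnogram).
#' @export
inclusion_filter <- function(record, hypnogram = NULL, split_night = FALSE) {
  tst_h <- NA_real_
  if (is.na(record$meta$age)) {
    return(tibble::tibble(keep = FALSE, reason = "age_unknown", tst_h = tst_h))
  }
  if (isTRUE(split_night)) {
    return(tibble::tibble(keep = FALSE, reason = "cpap_split_night",
                          tst_h = tst_h))
  }
  if (is.null(hypnogram)) {
    warning("no hypnogram: sleep-time rule skipped", call. = FALSE)
  } else {
    tst_h <- sum(hypnogram$stages %in% c("N1", "N2", "N3", "REM")) * 30 / 3600
    if (tst_h < 3) {
      return(tibble::tibble(keep = FALSE, reason = "tst_lt_3h", tst_h = tst_h))
    }
  }
  tibble::tibble(keep = TRUE, reason = "ok", tst_h = tst_h)
}

#' Full preprocessing of one recording
#'
#' Runs the standardization chain per channel in the order resample ->
#' filter -> normalize, then assembles the C x T stack for the given
#' channel set: rational resampling to 128 Hz (linear interpolation for
#' SaO2), zero-phase order-16 elliptic prefiltering, percentile
#' amplitude normalization (fixed 60/100% anchors for SaO2), and zero
#' substitution of missing channels.
#'
#' @param record a [psg_record()] with canonical (or derivable) labels.
#' @param spec a [channel_set_spec()] (or its `model_id`).
#' @param target_fs pipeline rate, 128 Hz.
#' @param montage roles the recording is expected to carry; the
#'   missing-signal exclusion rule counts absences over this set.
#'   Defaults to the full 11-role montage; restrict it (for example to
#'   `spec$channels`) for reduced recordings acquired without the full
#'   sensor complement.
#' @return a `preprocessed_record` (possibly with `excluded = TRUE`).
#' @export
preprocess_record <- function(record, spec = channel_set_spec("a"),
                              target_fs = 128, montage = full_montage()) {
  if (is.character(spec)) spec <- channel_set_spec(spec)
  traces <- list()
  for (ch in union(spec$channels, montage)) {
    tr <- derive_channel(record, ch)
    if (is_missing_trace(tr) || !(ch %in% spec$channels)) {
      # channels outside the requested set only feed the missing count
      traces[[ch]] <- if (is_missing_trace(tr)) tr else signal_trace(ch, 0, 1)
      next
    }
    tr <- resample_trace(tr, target_fs, is_sao2 = identical(ch, "SaO2"))
    fspec <- design_filter(ch, fs = target_fs)
    tr <- apply_filter(tr, fspec)
    tr <- if (identical(ch, "SaO2")) normalize_sao2(tr) else normalize_amplitude(tr)
    traces[[ch]] <- tr
  }
  assemble(traces, spec, record$meta, fs = target_fs)
}
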