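#' Per-role prefilter specification
#'
#' The standardized prefilters, one per channel role, all from a single
#' elliptic family: order 16, at most 1 dB passband ripple, at least
#' 40 dB stopband attenuation, applied forwards and backwards (zero
#' phase). Band edges in Hz at a 128 Hz sampling rate:
#'
#' * EEG (`C3-M2`, `C4-M1`) and EOG: band-pass 0.3-45
#' * chin EMG: high-pass 10
#' * ECG: high-pass 0.3
#' * nasal pressure: high-pass 0.1
#' * airflow and respiratory belts: band-pass 0.1-15
#' * SaO2: no filtering
#'
#' @param role canonical channel role.
#' @param fs sampling rate the filter is designed for (Hz).
#' @return object of class `filter_spec`: list with `role`, `type`
#'   (`"bandpass"`, `"highpass"` or `"none"`), `cutoffs_hz`, `order`,
#'   `rp_db`, `rs_db` and (unless `type == "none"`) the designed `sos`.
#' @export
design_filter <- function(role, fs = 128) {
  spec <- switch(role,
    "C3-M2" = , "C4-M1" = , "L-EOG" = , "R-EOG" =
      list(type = "bandpass", cutoffs = c(0.3, 45)),
    "chinEMG" = list(type = "highpass", cutoffs = 10),
    "ECG" = list(type = "highpass", cutoffs = 0.3),
    "nasal_pressure" = list(type = "highpass", cutoffs = 0.1),
    "airflow" = , "thor_belt" = , "abd_belt" =
      list(type = "bandpass", cutoffs = c(0.1, 15)),
    "SaO2" = list(type = "none", cutoffs = numeric(0)),
    stop_somnoage("unknown channel role: ", role,
                  class = "somnoage_filter_error")
  )
  out <- list(role = role, type = spec$type, cutoffs_hz = spec$cutoffs,
              order = 16, rp_db = 1, rs_db = 40, fs = fs)
  if (spec$type != "none") {
    if (any(spec$cutoffs <= 0) || any(spec$cutoffs >= fs / 2)) {
      stop_somnoage("cutoffs must lie strictly inside (0, fs/2)",
                    class = "somnoage_filter_error")
    }
    type <- if (spec$type == "bandpass") "pass" else "high"
    out$sos <- ellip_sos(out$order, out$rp_db, out$rs_db,
                         spec$cutoffs / (fs / 2), type)
  }
  structure(out, class = "filter_spec")
}

#' Apply a prefilter to a trace, zero phase
#'
#' SaO2 (`type == "none"`) passes through untouched; everything else is
#' filtered forwards and backwards through the cascaded second-order
#' sections with odd-reflection edge padding.
#'
#' @param trace a [signal_trace()] at the design sampling rate.
#' @param spec a [design_filter()] result.
#' @return filtered [signal_trace()].
#' @export
apply_filter <- function(trace, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$type == "none") return(trace)
  if (abs(trace$fs - spec$fs) > 1e-9) {
    stop_somnoage("trace fs (", trace$fs, ") != filter design fs (", spec$fs, ")",
                  class = "somnoage_filter_error")
  }
  y <- sos_filtfilt(spec$sos, trace$samples)
  if (!all(is.finite(y))) {
    stop_somnoage("non-finite output from filter for role ", spec$role,
                  class = "somnoage_filter_error")
  }
  signal_trace(trace$label, y, trace$fs, trace$unit)
}
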