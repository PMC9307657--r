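#' Percentile amplitude normalization
#'
#' Affine map sending the trace's 5th percentile to -1 and its 95th
#' percentile to +1, computed over the whole recording. Values outside
#' the percentile range may exceed +/-1. A constant trace (5th == 95th
#' percentile) is mapped to all zeros and flagged degenerate.
#'
#' @param trace a non-SaO2 [signal_trace()].
#' @return normalized [signal_trace()]; attribute `degenerate` is set
#'   when the trace was constant.
#' @export
normalize_amplitude <- function(trace) {
  p <- quantile(trace$samples, c(0.05, 0.95), names = FALSE, type = 7)
  if (p[2] <= p[1]) {
    out <- signal_trace(trace$label, rep(0, length(trace$samples)),
                        trace$fs, trace$unit)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  y <- 2 * (trace$samples - p[1]) / (p[2] - p[1]) - 1
  signal_trace(trace$label, y, trace$fs, trace$unit)
}

#' Oxygen-saturation normalization
#'
#' Affine map with fixed physiological anchors: 60% saturation maps to
#' -1 and 100% to +1, i.e. `v -> (v - 80) / 20`. Input is expected in
#' percent (0-100 scale); negative values are clipped to 0 before the
#' map and flagged.
#'
#' @param trace the SaO2 [signal_trace()] in percent.
#' @return normalized [signal_trace()]; attribute `clipped` counts
#'   clipped samples.
#' @export
normalize_sao2 <- function(trace) {
  x <- trace$samples
  nclip <- sum(x < 0)
  if (nclip > 0) x <- pmax(x, 0)
  out <- signal_trace(trace$label, (x - 80) / 20, trace$fs, trace$unit)
  if (nclip > 0) attr(out, "clipped") <- nclip
  out
}
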