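#' Resample a trace to the pipeline rate
#'
#' Non-SaO2 channels are resampled by rational-factor polyphase
#' filtering: the signal is upsampled by `p`, low-pass filtered with a
#' Kaiser-window FIR anti-aliasing filter, and decimated by `q`, where
#' `p/q = target_fs/fs` in lowest terms. SaO2 is resampled by linear
#' interpolation, as oximeter output is a slowly varying percentage for
#' which ringing from a sharp filter would be an artifact.
#'
#' @param trace a [signal_trace()].
#' @param target_fs target sampling rate in Hz.
#' @param kaiser_beta Kaiser window shape parameter. The default 7.86
#'   corresponds to roughly 80 dB of stopband attenuation.
#' @param half_len filter half-length in output-rate samples per side
#'   (the FIR spans `2 * half_len * max(p, q) + 1` taps at the
#'   upsampled rate).
#' @param is_sao2 route to the linear-interpolation branch.
#' @return resampled [signal_trace()] with `fs = target_fs` and duration
#'   preserved within one output sample.
#' @export
resample_trace <- function(trace, target_fs = 128, kaiser_beta = 7.86,
                           half_len = 10, is_sao2 = identical(trace$label, "SaO2")) {
  fs <- trace$fs
  x <- trace$samples
  n_out <- floor(length(x) * target_fs / fs)
  if (is_sao2) {
    t_out <- (seq_len(n_out) - 1) / target_fs
    t_in <- (seq_along(x) - 1) / fs
    y <- approx(t_in, x, xout = pmin(t_out, max(t_in)), rule = 2)$y
    return(signal_trace(trace$label, y, target_fs, trace$unit))
  }
  if (fs < 1) {
    stop_somnoage("cannot meaningfully anti-alias a non-SaO2 channel at fs < 1 Hz",
                  class = "somnoage_resample_error")
  }
  if (abs(fs - target_fs) < 1e-9) return(trace)
  # rational ratio p/q in lowest terms (rates rounded to mHz)
  a <- round(target_fs * 1000); b <- round(fs * 1000)
  g <- .gcd(a, b)
  p <- a / g; q <- b / g
  m <- max(p, q)
  nh <- half_len * m                      # taps per side at the high rate
  fc <- 1 / m                             # cutoff as fraction of high-rate Nyquist
  h <- fc * .sinc(fc * (-nh:nh)) * .kaiser_win(2 * nh + 1, kaiser_beta)
  h <- h / sum(h)                         # exact unit DC gain
  # upsample by p (zero insertion)
  nx <- length(x)
  up <- numeric(nx * p)
  up[seq(1, by = p, length.out = nx)] <- x * p
  y_full <- .fft_conv(up, h)
  # compensate the filter delay of nh high-rate samples, decimate by q
  idx <- nh + 1 + (seq_len(n_out) - 1) * q
  idx[idx > length(y_full)] <- length(y_full)
  y <- y_full[idx]
  signal_trace(trace$label, y, target_fs, trace$unit)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

.sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

.kaiser_win <- function(n, beta) {
  k <- seq(0, n - 1)
  besselI(beta * sqrt(pmax(0, 1 - (2 * k / (n - 1) - 1)^2)), 0) / besselI(beta, 0)
}

# linear convolution via FFT, full length
.fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1
  nfft <- nextn(n, 2)
  y <- Re(fft(fft(c(x, numeric(nfft - length(x)))) *
                fft(c(h, numeric(nfft - length(h)))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}
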