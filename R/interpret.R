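#' Sample-level relevance attribution by expected gradients
#'
#' Gradient-SHAP-style attribution against the all-zero baseline: for
#' each draw an interpolation coefficient `alpha ~ Uniform(0, 1)` is
#' sampled (optionally with small Gaussian input noise), the gradient of
#' the model output with respect to the input is evaluated at
#' `alpha * (x + noise)`, the gradients are averaged over draws and
#' multiplied elementwise by `x - baseline = x`.
#'
#' For a linear model the result equals `w * x` exactly for any number
#' of draws; in general the attributions sum approximately to
#' `f(x) - f(0)` (completeness).
#'
#' @param model either trained phase-1 weights (class `agenet_phase1`)
#'   or a function `f(x)` returning `list(y = scalar, dx = gradient)`.
#' @param x input epoch: `C x q` matrix (or any array the model
#'   accepts).
#' @param n_draws number of interpolation draws (>= 1).
#' @param noise_sd standard deviation of the input noise added before
#'   interpolation (0 disables smoothing of the expectation).
#' @param seed RNG seed.
#' @param netcfg the [agenet_config()] when `model` is a weight set.
#' @return object of class `relevance_track`: list with `scores` (same
#'   shape as `x`), `yhat`, `baseline_output` and `fs`.
#' @export
gradient_shap <- function(model, x, n_draws = 64, noise_sd = 0.09,
                          seed = 1L, netcfg = attr(model, "config")) {
  if (n_draws < 1) {
    stop_somnoage("n_draws must be >= 1", class = "somnoage_interpret_error")
  }
  if (inherits(model, "agenet_phase1")) {
    f <- function(xx) {
      fw <- phase1_forward(model, xx, netcfg, keep_cache = TRUE)
      bw <- phase1_backward(model, fw$cache, 1, netcfg, need_dx = TRUE)
      dx <- bw$dx
      dim(dx) <- dim(xx)
      list(y = fw$yhat, dx = dx)
    }
  } else if (is.function(model)) {
    f <- model
  } else {
    stop_somnoage("model must be phase-1 weights or a value-and-gradient function",
                  class = "somnoage_interpret_error")
  }
  set.seed(seed)
  gsum <- array(0, dim(x) %||% length(x))
  for (d in seq_len(n_draws)) {
    # stratified draw: alpha uniform within the d-th subinterval, so the
    # estimator keeps its expectation with much lower variance
    alpha <- (d - runif(1)) / n_draws
    xn <- if (noise_sd > 0) x + rnorm(length(x), sd = noise_sd) else x
    gsum <- gsum + f(alpha * xn)$dx
  }
  scores <- (gsum / n_draws) * x
  y1 <- f(x)$y
  y0 <- f(array(0, dim(x) %||% length(x)))$y
  structure(list(scores = scores, yhat = y1, baseline_output = y0,
                 fs = if (!is.null(netcfg)) netcfg$fs else NA_real_),
            class = "relevance_track")
}

#' Gaussian smoothing of a relevance track
#'
#' Per-channel convolution with a unit-sum Gaussian window of 10 s
#' length and 0.234 s standard deviation (1280 samples, sigma = 29.952
#' samples at 128 Hz), with reflection padding so the output has the
#' input length and total score is conserved away from the edges.
#'
#' @param track a `relevance_track` (or plain matrix/vector of scores).
#' @param fs sampling rate (Hz).
#' @param win_s window length in seconds.
#' @param sigma_s kernel standard deviation in seconds.
#' @return smoothed object of the same type.
#' @export
smooth_relevance <- function(track, fs = 128, win_s = 10, sigma_s = 0.234) {
  scores <- if (inherits(track, "relevance_track")) track$scores else track
  if (inherits(track, "relevance_track") && is.finite(track$fs)) fs <- track$fs
  L <- round(win_s * fs)
  sigma <- sigma_s * fs
  tt <- seq_len(L) - (L + 1) / 2
  kern <- exp(-0.5 * (tt / sigma)^2)
  kern <- kern / sum(kern)
  sm_vec <- function(v) .conv_same_reflect(v, kern)
  out <- if (is.matrix(scores)) t(apply(scores, 1, sm_vec)) else sm_vec(scores)
  if (inherits(track, "relevance_track")) {
    track$scores <- out
    track
  } else out
}

# same-length convolution with reflection padding, FFT-based
.conv_same_reflect <- function(x, h) {
  n <- length(x)
  L <- length(h)
  pl <- L %/% 2
  pr <- L - pl - 1
  left <- if (pl > 0) x[pmin(n, seq(pl, 1))] else numeric(0)
  right <- if (pr > 0) x[pmax(1, seq(n - 1, n - pr))] else numeric(0)
  xp <- c(left, x, right)
  y <- .fft_conv(xp, h)
  y[(L - 1) + seq_len(n)]
}

#' Average relevance across channels
#'
#' @param track a `relevance_track` or score matrix.
#' @param mask optional 0/1 substitution mask; when given, a second
#'   masked average over non-substituted channels is attached as
#'   attribute `"masked"`.
#' @return numeric vector of length `q` (the channel mean).
#' @export
channel_average <- function(track, mask = NULL) {
  scores <- if (inherits(track, "relevance_track")) track$scores else track
  if (!is.matrix(scores)) return(as.numeric(scores))
  out <- colMeans(scores)
  if (!is.null(mask) && any(mask == 0)) {
    attr(out, "masked") <- colMeans(scores[mask == 0, , drop = FALSE])
  }
  out
}

#' Anchor times of hypnogram stage transitions
#'
#' A transition anchor is the start of the first epoch of the new
#' stage, keyed by its `from->to` pair.
#'
#' @param hypnogram a [hypnogram()].
#' @return tibble with columns `time_s`, `from`, `to`, `key`.
#' @export
transition_anchors <- function(hypnogram) {
  st <- hypnogram$stages
  if (length(st) < 2) {
    return(tibble::tibble(time_s = numeric(0), from = character(0),
                          to = character(0), key = character(0)))
  }
  idx <- which(st[-1] != st[-length(st)])
  tibble::tibble(time_s = 30 * idx, from = st[idx], to = st[idx + 1],
                 key = paste0(st[idx], "->", st[idx + 1]))
}

#' Event-locked average of relevance traces
#'
#' Aligns a channel-averaged relevance trace on a set of anchor times
#' and returns the pointwise mean and standard error across anchors in
#' a window of +/- `w_s` seconds. Anchors without full context are
#' dropped and counted. With a single anchor the SEM is 0 by
#' convention.
#'
#' @param traces list of numeric relevance vectors (one per record) or
#'   a single vector.
#' @param anchors list of anchor-time vectors in seconds (parallel to
#'   `traces`), e.g. event onsets or [transition_anchors()] times.
#' @param w_s half-window in seconds.
#' @param fs sampling rate (Hz).
#' @return object of class `event_locked_average`: list with `time_s`,
#'   `mean`, `sem`, `n`, `n_dropped`.
#' @export
event_locked_average <- function(traces, anchors, w_s = 30, fs = 128) {
  if (!is.list(traces)) traces <- list(traces)
  if (!is.list(anchors)) anchors <- list(anchors)
  stopifnot(length(traces) == length(anchors))
  wn <- round(w_s * fs)
  segs <- list()
  n_drop <- 0L
  for (i in seq_along(traces)) {
    v <- traces[[i]]
    for (a in anchors[[i]]) {
      c0 <- round(a * fs)               # sample index of the anchor (0-based)
      lo <- c0 - wn + 1L; hi <- c0 + wn
      if (lo < 1 || hi > length(v)) { n_drop <- n_drop + 1L; next }
      segs[[length(segs) + 1]] <- v[lo:hi]
    }
  }
  if (length(segs) == 0) {
    return(structure(list(time_s = numeric(0), mean = numeric(0),
                          sem = numeric(0), n = 0L, n_dropped = n_drop,
                          reason = "no usable anchors"),
                     class = "event_locked_average"))
  }
  m <- do.call(rbind, segs)
  mu <- colMeans(m)
  sem <- if (nrow(m) > 1) apply(m, 2, sd) / sqrt(nrow(m)) else rep(0, ncol(m))
  structure(list(time_s = (seq_len(2 * wn) - wn - 0.5) / fs,
                 mean = mu, sem = sem, n = nrow(m), n_dropped = n_drop,
                 reason = NA_character_),
            class = "event_locked_average")
}

#' Whole-night relevance for a preprocessed record
#'
#' Convenience wrapper: relevance per 5-min epoch (concatenated in
#' time), Gaussian-smoothed and channel-averaged, with epoch boundaries
#' recorded.
#'
#' @param p1 trained phase-1 weights.
#' @param pre a `preprocessed_record`.
#' @param netcfg the [agenet_config()].
#' @param n_draws,noise_sd,seed passed to [gradient_shap()].
#' @return list with `relevance` (vector over the night), `epoch_bounds_s`
#'   and `fs`.
#' @export
night_relevance <- function(p1, pre, netcfg, n_draws = 64, noise_sd = 0.09,
                            seed = 1L) {
  eps <- segment_epochs(pre, netcfg$q)
  parts <- lapply(seq_along(eps), function(i) {
    tr <- gradient_shap(p1, eps[[i]], n_draws = n_draws, noise_sd = noise_sd,
                        seed = seed + i, netcfg = netcfg)
    channel_average(smooth_relevance(tr, fs = netcfg$fs), mask = pre$mask)
  })
  list(relevance = unlist(parts),
       epoch_bounds_s = seq_along(eps) * netcfg$epoch_s,
       fs = netcfg$fs)
}
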