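#' Network configuration for the two-phase age-estimation model
#'
#' The phase-1 (epoch-level) network maps a `C x q` 5-minute window
#' (q = 128 Hz x 60 s x 5 = 38400 samples) through a channel-mixing 1x1
#' convolution, a stack of inverted residual bottleneck blocks (expand ->
#' depthwise temporal convolution with stride -> rectify -> project,
#' residual add when shapes match), a bidirectional LSTM, additive attention pooling
#' and two dense layers ending in a linear scalar. The epoch latent
#' `z_i` concatenates the last dense hidden activation with the time
#' average of the Bi-LSTM output, so `M = dense_dim + 2 * lstm_hidden`.
#' The phase-2 (night-level) network runs a Bi-LSTM, additive attention
#' and two dense layers over the latent sequence. Output layers have no
#' nonlinearity.
#'
#' @param C number of input channels.
#' @param mixer_filters width of the channel-mixing layer.
#' @param block_filters,block_expansion,block_kernel,block_stride
#'   per-block output widths, expansion factors, depthwise kernel sizes
#'   and strides (recycled to the number of blocks). The product of the
#'   strides sets the time reduction into the Bi-LSTM; the default
#'   4 blocks of stride 4 turn a 5-min epoch into 150 steps. By default
#'   the kernel equals the stride, so the depthwise stage tiles the
#'   time axis with non-overlapping windows.
#' @param lstm_hidden phase-1 Bi-LSTM hidden size per direction.
#' @param attn_dim additive-attention projection size.
#' @param dense_dim phase-1 hidden dense size (the latent's dense part).
#' @param p2_lstm_hidden,p2_attn_dim,p2_dense_dim phase-2 sizes.
#' @param out_scale fixed output scaling (years per unit of the final
#'   linear layer's activation); keeps the head's weights O(1) when the
#'   target spans decades.
#' @param epoch_s epoch length in seconds (5 min).
#' @param fs sampling rate (128 Hz).
#' @param seed weight-initialization seed.
#' @return object of class `agenet_config`.
#' @export
agenet_config <- function(C = 2,
                          mixer_filters = 32,
                          block_filters = c(32, 48, 64, 64),
                          block_expansion = 4,
                          block_kernel = NULL,
                          block_stride = 4,
                          lstm_hidden = 64,
                          attn_dim = 64,
                          dense_dim = 64,
                          p2_lstm_hidden = 64,
                          p2_attn_dim = 64,
                          p2_dense_dim = 64,
                          out_scale = 25,
                          epoch_s = 300, fs = 128, seed = 1L) {
  nb <- length(block_filters)
  cfg <- list(
    C = C, mixer_filters = mixer_filters,
    block_filters = block_filters,
    block_expansion = rep_len(block_expansion, nb),
    block_kernel = rep_len(block_kernel %||% block_stride, nb),
    block_stride = rep_len(block_stride, nb),
    lstm_hidden = lstm_hidden, attn_dim = attn_dim, dense_dim = dense_dim,
    p2_lstm_hidden = p2_lstm_hidden, p2_attn_dim = p2_attn_dim,
    p2_dense_dim = p2_dense_dim, out_scale = out_scale,
    epoch_s = epoch_s, fs = fs, seed = as.integer(seed))
  cfg$q <- as.integer(epoch_s * fs)
  cfg$M <- dense_dim + 2L * lstm_hidden
  stopifnot(all(unlist(cfg[c("mixer_filters", "block_filters", "lstm_hidden",
                             "attn_dim", "dense_dim")]) >= 1))
  structure(cfg, class = "agenet_config")
}

#' Latent dimension implied by a configuration
#' @param config an [agenet_config()].
#' @return integer M.
#' @export
latent_dim <- function(config) config$M

lstm_init <- function(H, Fin) {
  list(W = nn_rng_mat(4 * H, Fin, Fin), U = nn_rng_mat(4 * H, H, H),
       b = numeric(4 * H))
}

#' Initialize phase-1 weights
#'
#' Fan-in-scaled uniform initialization, deterministic in the config
#' seed.
#'
#' @param config an [agenet_config()].
#' @return nested parameter list of class `agenet_phase1`.
#' @export
init_phase1 <- function(config) {
  set.seed(config$seed)
  Fm <- config$mixer_filters
  p <- list(mixer = list(W = nn_rng_mat(Fm, config$C, config$C),
                         b = numeric(Fm)))
  fin <- Fm
  p$blocks <- vector("list", length(config$block_filters))
  for (i in seq_along(config$block_filters)) {
    fe <- fin * config$block_expansion[i]
    fo <- config$block_filters[i]
    # depthwise kernels start as a coarse cosine filter bank (frequencies
    # spread over the channels), so the stem is frequency-selective
    # already at initialization and band-power features are reachable
    # within a few gradient steps
    kk <- config$block_kernel[i]
    freqs <- (seq_len(fe) - 1) %% kk / kk          # cycles per sample
    dwW <- t(vapply(seq_len(fe), function(ci) {
      2 * cos(2 * pi * freqs[ci] * (seq_len(kk) - 1)) / kk
    }, numeric(kk)))
    dwW <- dwW + matrix(runif(fe * kk, -0.2 / kk, 0.2 / kk), fe, kk)
    p$blocks[[i]] <- list(
      expand = list(W = nn_rng_mat(fe, fin, fin), b = numeric(fe)),
      dw = list(W = dwW),
      proj = list(W = nn_rng_mat(fo, fe, fe), b = numeric(fo)))
    fin <- fo
  }
  H <- config$lstm_hidden
  p$lstm <- list(fw = lstm_init(H, fin), bw = lstm_init(H, fin))
  p$attn <- list(W = nn_rng_mat(config$attn_dim, 2 * H, 2 * H),
                 b = numeric(config$attn_dim),
                 v = as.numeric(nn_rng_mat(config$attn_dim, 1, config$attn_dim)))
  # small positive bias keeps the rectified hidden units alive at
  # initialization (attention-pooled inputs are concentrated, so a
  # zero-bias head can start with every unit dead and no gradient)
  p$fc1 <- list(W = nn_rng_mat(config$dense_dim, 2 * H, 2 * H),
                b = rep(0.1, config$dense_dim))
  p$out <- list(W = nn_rng_mat(1, config$dense_dim, config$dense_dim),
                b = numeric(1))
  structure(p, class = "agenet_phase1", config = config)
}

#' Initialize phase-2 weights
#' @param config an [agenet_config()].
#' @return nested parameter list of class `agenet_phase2`.
#' @export
init_phase2 <- function(config) {
  set.seed(config$seed + 1L)
  H <- config$p2_lstm_hidden
  p <- list(lstm = list(fw = lstm_init(H, config$M), bw = lstm_init(H, config$M)),
            attn = list(W = nn_rng_mat(config$p2_attn_dim, 2 * H, 2 * H),
                        b = numeric(config$p2_attn_dim),
                        v = as.numeric(nn_rng_mat(config$p2_attn_dim, 1,
                                                  config$p2_attn_dim))),
            fc1 = list(W = nn_rng_mat(config$p2_dense_dim, 2 * H, 2 * H),
                       b = rep(0.1, config$p2_dense_dim)),
            out = list(W = nn_rng_mat(1, config$p2_dense_dim,
                                      config$p2_dense_dim),
                       b = numeric(1)))
  structure(p, class = "agenet_phase2", config = config)
}

.as_batch <- function(x, C) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  stopifnot(dim(x)[1] == C)
  x
}

#' Phase-1 forward pass
#'
#' @param params weights from [init_phase1()] (or a trained set).
#' @param x epoch tensor: `C x q` matrix or `C x q x B` array.
#' @param config the [agenet_config()]; defaults to the one attached to
#'   `params`.
#' @param keep_cache retain intermediate activations for a backward pass.
#' @return list with `yhat` (length-B estimate in years, unclamped),
#'   `yhat_clamped` (reporting value, >= 0), `latent` (`M x B`), and
#'   `cache` when requested.
#' @export
phase1_forward <- function(params, x, config = attr(params, "config"),
                           keep_cache = FALSE) {
  x <- .as_batch(x, config$C)
  cc <- list()
  cc$mixer <- conv1x1_fwd(params$mixer$W, params$mixer$b, x)
  h <- cc$mixer$Y
  cc$blocks <- vector("list", length(params$blocks))
  for (i in seq_along(params$blocks)) {
    bl <- params$blocks[[i]]
    e <- conv1x1_fwd(bl$expand$W, bl$expand$b, h)
    dw <- dwconv_fwd(bl$dw$W, e$Y, config$block_stride[i])
    r2 <- relu_fwd(dw$Y)
    pr <- conv1x1_fwd(bl$proj$W, bl$proj$b, r2$Y)
    resid <- config$block_stride[i] == 1 && dim(pr$Y)[1] == dim(h)[1]
    out <- if (resid) pr$Y + h else pr$Y
    cc$blocks[[i]] <- list(e = e, dw = dw, r2 = r2, pr = pr, resid = resid)
    h <- out
  }
  .check_finite(h, "bottleneck stack")
  cc$lstm <- bilstm_fwd(params$lstm, h)
  lstm_mean <- colSums(aperm(cc$lstm$Y, c(2, 1, 3))) / dim(cc$lstm$Y)[2]
  cc$attn <- attention_fwd(params$attn, cc$lstm$Y)
  cc$fc1 <- dense_fwd(params$fc1$W, params$fc1$b, cc$attn$Y)
  cc$rfc1 <- relu_fwd(cc$fc1$Y)
  cc$out <- dense_fwd(params$out$W, 0, cc$rfc1$Y)
  yhat <- as.numeric(config$out_scale * cc$out$Y + params$out$b)
  .check_finite(yhat, "output layer")
  latent <- rbind(cc$rfc1$Y, lstm_mean)
  res <- list(yhat = yhat, yhat_clamped = pmax(yhat, 0), latent = latent)
  if (keep_cache) res$cache <- cc
  res
}

.check_finite <- function(x, where) {
  if (!all(is.finite(x))) {
    stop_somnoage("non-finite activations at ", where,
                  class = "somnoage_net_error")
  }
}

#' Phase-1 backward pass
#'
#' @param params phase-1 weights.
#' @param cache from `phase1_forward(..., keep_cache = TRUE)`.
#' @param dy gradient of the loss w.r.t. the unclamped output (length B).
#' @param config the [agenet_config()].
#' @param need_dx also return the gradient w.r.t. the input tensor.
#' @return list `grads` (same structure as `params`) and optionally `dx`.
#' @export
phase1_backward <- function(params, cache, dy,
                            config = attr(params, "config"),
                            need_dx = FALSE) {
  g <- list()
  dYout <- matrix(dy, nrow = 1)
  bo <- dense_bwd(params$out$W, cache$out, config$out_scale * dYout)
  g$out <- list(W = bo$dW, b = sum(dYout))
  dh <- relu_bwd(cache$rfc1, bo$dX)
  b1 <- dense_bwd(params$fc1$W, cache$fc1, dh)
  g$fc1 <- list(W = b1$dW, b = b1$db)
  ba <- attention_bwd(params$attn, cache$attn, b1$dX)
  g$attn <- list(W = ba$dW, b = ba$db, v = ba$dv)
  dlstm_y <- ba$dX
  bl <- bilstm_bwd(params$lstm, cache$lstm, dlstm_y)
  g$lstm <- list(fw = list(W = bl$fw$dW, U = bl$fw$dU, b = bl$fw$db),
                 bw = list(W = bl$bw$dW, U = bl$bw$dU, b = bl$bw$db))
  dX <- bl$dX
  g$blocks <- vector("list", length(params$blocks))
  for (i in rev(seq_along(params$blocks))) {
    cb <- cache$blocks[[i]]
    pb <- params$blocks[[i]]
    d_out <- dX
    bpr <- conv1x1_bwd(pb$proj$W, cb$pr, d_out)
    dr2 <- relu_bwd(cb$r2, bpr$dX)
    bdw <- dwconv_bwd(pb$dw$W, cb$dw, dr2)
    bex <- conv1x1_bwd(pb$expand$W, cb$e, bdw$dX)
    dX <- bex$dX
    if (cb$resid) dX <- dX + d_out
    g$blocks[[i]] <- list(expand = list(W = bex$dW, b = bex$db),
                          dw = list(W = bdw$dW),
                          proj = list(W = bpr$dW, b = bpr$db))
  }
  bm <- conv1x1_bwd(params$mixer$W, cache$mixer, dX)
  g$mixer <- list(W = bm$dW, b = bm$db)
  g <- g[names(params)]
  res <- list(grads = g)
  if (need_dx) res$dx <- bm$dX
  res
}

#' Phase-2 forward pass over a latent sequence
#'
#' @param params weights from [init_phase2()].
#' @param z latent sequence: `M x n_epochs` matrix or `M x n x B` array.
#' @param config the [agenet_config()].
#' @param keep_cache retain activations for the backward pass.
#' @return list with `yhat` (unclamped), `yhat_clamped` (final age
#'   estimate, >= 0), and `cache` when requested.
#' @export
phase2_forward <- function(params, z, config = attr(params, "config"),
                           keep_cache = FALSE) {
  z <- .as_batch(z, config$M)
  if (dim(z)[2] < 1) {
    stop_somnoage("latent sequence must contain at least one epoch",
                  class = "somnoage_net_error")
  }
  cc <- list()
  cc$lstm <- bilstm_fwd(params$lstm, z)
  cc$attn <- attention_fwd(params$attn, cc$lstm$Y)
  cc$fc1 <- dense_fwd(params$fc1$W, params$fc1$b, cc$attn$Y)
  cc$rfc1 <- relu_fwd(cc$fc1$Y)
  cc$out <- dense_fwd(params$out$W, 0, cc$rfc1$Y)
  yhat <- as.numeric(config$out_scale * cc$out$Y + params$out$b)
  .check_finite(yhat, "phase-2 output layer")
  res <- list(yhat = yhat, yhat_clamped = pmax(yhat, 0))
  if (keep_cache) res$cache <- cc
  res
}

#' Phase-2 backward pass
#' @inheritParams phase1_backward
#' @param cache from `phase2_forward(..., keep_cache = TRUE)`.
#' @return list `grads` (and `dz` when `need_dx`).
#' @export
phase2_backward <- function(params, cache, dy,
                            config = attr(params, "config"),
                            need_dx = FALSE) {
  g <- list()
  bo <- dense_bwd(params$out$W, cache$out, config$out_scale * matrix(dy, nrow = 1))
  g$out <- list(W = bo$dW, b = sum(dy))
  dh <- relu_bwd(cache$rfc1, bo$dX)
  b1 <- dense_bwd(params$fc1$W, cache$fc1, dh)
  g$fc1 <- list(W = b1$dW, b = b1$db)
  ba <- attention_bwd(params$attn, cache$attn, b1$dX)
  g$attn <- list(W = ba$dW, b = ba$db, v = ba$dv)
  bl <- bilstm_bwd(params$lstm, cache$lstm, ba$dX)
  g$lstm <- list(fw = list(W = bl$fw$dW, U = bl$fw$dU, b = bl$fw$db),
                 bw = list(W = bl$bw$dW, U = bl$bw$dU, b = bl$bw$db))
  g <- g[names(params)]
  res <- list(grads = g)
  if (need_dx) res$dz <- bl$dX
  res
}

#' Segment a preprocessed record into 5-minute epoch tensors
#'
#' Consecutive non-overlapping `C x q` windows from sample 0; the tail
#' remainder is dropped (floor rule).
#'
#' @param pre a `preprocessed_record` (or a plain `C x T` matrix).
#' @param q epoch length in samples (38400 at 128 Hz).
#' @return list of `C x q` matrices, length `floor(T / q)`.
#' @export
segment_epochs <- function(pre, q = 38400L) {
  x <- if (inherits(pre, "preprocessed_record")) pre$x else pre
  if (is.null(x)) {
    stop_somnoage("record has no tensor (excluded?)", class = "somnoage_net_error")
  }
  Tn <- ncol(x)
  n <- Tn %/% q
  if (n < 1) {
    stop_somnoage("recording shorter than one epoch (T = ", Tn, " < q = ", q, ")",
                  class = "somnoage_net_error")
  }
  lapply(seq_len(n), function(i) x[, ((i - 1) * q + 1):(i * q), drop = FALSE])
}

#' Scaled Huber training objective
#'
#' Quadratic for absolute errors under 5 years, linear beyond, divided
#' by 112.5 so that a 25-year error gives a loss of exactly 1:
#' `L = (e^2 / 2) / 112.5` for `|e| < 5`, `L = 5 (|e| - 2.5) / 112.5`
#' otherwise, with `e = y - yhat`.
#'
#' @param y chronological age(s), years.
#' @param yhat estimate(s), years (unclamped).
#' @param delta quadratic/linear crossover, years.
#' @param scale normalizing divisor.
#' @return per-element loss (same length as the inputs).
#' @export
huber_loss <- function(y, yhat, delta = 5, scale = 112.5) {
  e <- y - yhat
  ifelse(abs(e) < delta, 0.5 * e^2, delta * (abs(e) - 0.5 * delta)) / scale
}

#' Gradient of the scaled Huber loss with respect to the estimate
#' @inheritParams huber_loss
#' @return `dL/dyhat`, bounded in magnitude by `delta / scale`.
#' @export
huber_grad <- function(y, yhat, delta = 5, scale = 112.5) {
  e <- y - yhat
  ifelse(abs(e) < delta, -e, -delta * sign(e)) / scale
}

#' Additive attention pooling (standalone)
#'
#' Scores `s_t = v' tanh(W h_t + b)`, weights by softmax over time,
#' output the weighted sum. Exposed for inspection and testing; the
#' networks use the same primitive internally.
#'
#' @param H `d x T` matrix (one sequence) of time-step activations.
#' @param params list with `W`, `b`, `v`; defaults to a seeded random
#'   projection of dimension `attn_dim`.
#' @param attn_dim projection size used when `params` is `NULL`.
#' @param seed seed for the default random projection.
#' @return list with `pooled` (length d) and `weights` (length T,
#'   nonnegative, summing to 1).
#' @export
additive_attention <- function(H, params = NULL, attn_dim = 8, seed = 1) {
  stopifnot(is.matrix(H))
  if (is.null(params)) {
    set.seed(seed)
    params <- list(W = nn_rng_mat(attn_dim, nrow(H), nrow(H)),
                   b = numeric(attn_dim),
                   v = as.numeric(nn_rng_mat(attn_dim, 1, attn_dim)))
  }
  x <- H
  dim(x) <- c(nrow(H), ncol(H), 1L)
  fw <- attention_fwd(params, x)
  list(pooled = as.numeric(fw$Y), weights = as.numeric(fw$alpha))
}

#' Build the epoch latent from phase-1 internals
#'
#' `z_i` concatenates the last dense hidden activation with the time
#' mean of the Bi-LSTM output. [phase1_forward()] already returns this
#' as `$latent`; this helper recomputes it from a cache for clarity.
#'
#' @param cache a phase-1 forward cache.
#' @return `M x B` latent matrix.
#' @export
build_latent <- function(cache) {
  lstm_mean <- colSums(aperm(cache$lstm$Y, c(2, 1, 3))) / dim(cache$lstm$Y)[2]
  rbind(cache$rfc1$Y, lstm_mean)
}

#' Number of trainable parameters implied by a configuration
#' @param config an [agenet_config()].
#' @param phase 1 or 2.
#' @return integer count.
#' @export
n_parameters <- function(config, phase = 1) {
  p <- if (phase == 1) init_phase1(config) else init_phase2(config)
  sum(unlist(nn_map(length, p)))
}
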