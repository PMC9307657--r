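# Minimal batched neural-network primitives with hand-derived gradients.
# Tensors are arrays with dim (channels, time, batch); parameters are
# nested named lists of numeric arrays. No external autodiff is used:
# every layer returns a cache for its backward pass, and gradient
# correctness is pinned by finite-difference tests.

# He-uniform initialization: bound sqrt(6 / fan_in) keeps activation
# variance roughly constant through rectified layers.
nn_rng_mat <- function(nr, nc, fan_in) {
  s <- sqrt(6 / fan_in)
  matrix(runif(nr * nc, -s, s), nr, nc)
}

nn_map <- function(f, x, ...) {
  rest <- list(...)
  if (is.list(x)) {
    out <- x                      # keep names, class and attributes
    for (i in seq_along(x)) {
      out[[i]] <- do.call(nn_map, c(list(f, x[[i]]), lapply(rest, `[[`, i)))
    }
    out
  } else {
    do.call(f, c(list(x), rest))
  }
}

# walk leaves with their path names; f(leaf, path) -> leaf
nn_map_named <- function(f, x, path = character(0)) {
  if (is.list(x)) {
    out <- lapply(seq_along(x), function(i) {
      nm <- if (!is.null(names(x))) names(x)[i] else as.character(i)
      nn_map_named(f, x[[i]], c(path, nm))
    })
    names(out) <- names(x)
    out
  } else f(x, path)
}

nn_zeros_like <- function(p) nn_map(function(a) {
  if (is.null(dim(a))) numeric(length(a)) else array(0, dim(a))
}, p)

# ---- 1x1 convolution across channels (a matrix map per time step) ----

conv1x1_fwd <- function(W, b, X) {
  d <- dim(X)
  Xm <- matrix(X, d[1], d[2] * d[3])
  Y <- W %*% Xm + b
  dim(Y) <- c(nrow(W), d[2], d[3])
  list(Y = Y, Xm = Xm, d = d)
}

conv1x1_bwd <- function(W, cache, dY) {
  d <- cache$d
  dYm <- matrix(dY, dim(dY)[1], d[2] * d[3])
  dX <- crossprod(W, dYm)
  dim(dX) <- d
  list(dW = tcrossprod(dYm, cache$Xm), db = rowSums(dYm), dX = dX)
}

# ---- depthwise temporal convolution with stride ----

# When kernel == stride the windows tile the time axis without overlap
# and the convolution is a per-channel reshape + matrix product (the
# fast path used by the default block design); otherwise a general
# zero-padded strided convolution is applied.
dwconv_fwd <- function(W, X, stride) {
  k <- ncol(W)
  d <- dim(X)
  if (k == stride) {
    # Non-overlapping windows make the convolution a single dense
    # matrix product: out = A X, where A (C x C*k) holds W[c, j] at
    # column c + C (j - 1) and the input is viewed as (C*k, T/k * B).
    C <- d[1]
    T_out <- d[2] %/% k
    Tk <- T_out * k
    Xu <- if (Tk < d[2]) X[, seq_len(Tk), , drop = FALSE] else X
    Xm <- matrix(Xu, C * k, T_out * d[3])
    A <- matrix(0, C, C * k)
    A[cbind(rep(seq_len(C), k), seq_len(C * k))] <- as.vector(W)
    Y <- A %*% Xm
    dim(Y) <- c(C, T_out, d[3])
    return(list(Y = Y, Xm = Xm, A = A, stride = stride, k = k,
                tiled = TRUE, T_in = d[2], B = d[3]))
  }
  pad <- (k - 1L) %/% 2L
  Xp <- array(0, c(d[1], d[2] + 2L * pad, d[3]))
  Xp[, pad + seq_len(d[2]), ] <- X
  T_out <- (d[2] + 2L * pad - k) %/% stride + 1L
  base <- (seq_len(T_out) - 1L) * stride
  Y <- array(0, c(d[1], T_out, d[3]))
  for (j in seq_len(k)) {
    Y <- Y + W[, j] * Xp[, base + j, , drop = FALSE]
  }
  list(Y = Y, Xp = Xp, stride = stride, k = k, pad = pad, T_in = d[2],
       tiled = FALSE)
}

dwconv_bwd <- function(W, cache, dY) {
  k <- cache$k
  if (isTRUE(cache$tiled)) {
    C <- nrow(W); B <- cache$B
    T_out <- dim(dY)[2]
    dYm <- matrix(dY, C, T_out * B)
    dWfull <- tcrossprod(dYm, cache$Xm)      # (C, C*k); band holds dW
    dW <- matrix(dWfull[cbind(rep(seq_len(C), k), seq_len(C * k))], C, k)
    dXm <- crossprod(cache$A, dYm)           # (C*k, T_out*B)
    if (k * T_out == cache$T_in) {
      dim(dXm) <- c(C, cache$T_in, B)
      return(list(dW = dW, dX = dXm))
    }
    dX <- array(0, c(C, cache$T_in, B))
    dX[, seq_len(k * T_out), ] <- dXm
    return(list(dW = dW, dX = dX))
  }
  dXp <- array(0, dim(cache$Xp))
  dW <- matrix(0, nrow(W), k)
  T_out <- dim(dY)[2]
  base <- (seq_len(T_out) - 1L) * cache$stride
  for (j in seq_len(k)) {
    sl <- cache$Xp[, base + j, , drop = FALSE]
    dW[, j] <- rowSums(matrix(dY * sl, dim(dY)[1]))
    dXp[, base + j, ] <- dXp[, base + j, , drop = FALSE] + W[, j] * dY
  }
  dX <- dXp[, cache$pad + seq_len(cache$T_in), , drop = FALSE]
  list(dW = dW, dX = dX)
}

# Leaky rectifier (slope 0.01 on the negative side). The small leak
# matters at desk scale: with few gradient steps a hard rectifier can
# permanently silence head units for half the input space.
relu_fwd <- function(X) {
  Y <- X
  neg <- Y < 0
  Y[neg] <- 0.01 * Y[neg]
  list(Y = Y)
}
relu_bwd <- function(cache, dY) dY * ifelse(cache$Y > 0, 1, 0.01)

# ---- LSTM (single direction) ----

lstm_dir_fwd <- function(p, X) {
  d <- dim(X)                       # (F, T, B)
  H <- ncol(p$U)
  Tn <- d[2]; B <- d[3]
  hs <- array(0, c(H, Tn, B)); cs <- array(0, c(H, Tn, B))
  gi <- array(0, c(H, Tn, B)); gf <- array(0, c(H, Tn, B))
  gg <- array(0, c(H, Tn, B)); go <- array(0, c(H, Tn, B))
  h <- matrix(0, H, B); cc <- matrix(0, H, B)
  Wx <- p$W %*% matrix(X, d[1], Tn * B)    # precompute input projections
  dim(Wx) <- c(4 * H, Tn, B)
  for (t in seq_len(Tn)) {
    a <- matrix(Wx[, t, ], 4 * H, B) + p$U %*% h + p$b
    i <- 1 / (1 + exp(-a[1:H, , drop = FALSE]))
    f <- 1 / (1 + exp(-a[H + 1:H, , drop = FALSE]))
    g <- tanh(a[2 * H + 1:H, , drop = FALSE])
    o <- 1 / (1 + exp(-a[3 * H + 1:H, , drop = FALSE]))
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    hs[, t, ] <- h; cs[, t, ] <- cc
    gi[, t, ] <- i; gf[, t, ] <- f; gg[, t, ] <- g; go[, t, ] <- o
  }
  list(Y = hs, cs = cs, gi = gi, gf = gf, gg = gg, go = go, X = X)
}

lstm_dir_bwd <- function(p, cache, dY) {
  X <- cache$X
  d <- dim(X); Tn <- d[2]; B <- d[3]
  H <- ncol(p$U)
  dW <- matrix(0, 4 * H, d[1]); dU <- matrix(0, 4 * H, H); db <- numeric(4 * H)
  dX <- array(0, d)
  dh_next <- matrix(0, H, B); dc_next <- matrix(0, H, B)
  dA <- array(0, c(4 * H, Tn, B))
  for (t in seq(Tn, 1)) {
    i <- matrix(cache$gi[, t, ], H, B); f <- matrix(cache$gf[, t, ], H, B)
    g <- matrix(cache$gg[, t, ], H, B); o <- matrix(cache$go[, t, ], H, B)
    cc <- matrix(cache$cs[, t, ], H, B)
    c_prev <- if (t > 1) matrix(cache$cs[, t - 1, ], H, B) else matrix(0, H, B)
    tc <- tanh(cc)
    dh <- matrix(dY[, t, ], H, B) + dh_next
    dc <- dh * o * (1 - tc^2) + dc_next
    di <- dc * g * i * (1 - i)
    df <- dc * c_prev * f * (1 - f)
    dg <- dc * i * (1 - g^2)
    do_ <- dh * tc * o * (1 - o)
    a_grad <- rbind(di, df, dg, do_)
    dA[, t, ] <- a_grad
    h_prev <- if (t > 1) matrix(cache$Y[, t - 1, ], H, B) else matrix(0, H, B)
    dU <- dU + tcrossprod(a_grad, h_prev)
    dh_next <- crossprod(p$U, a_grad)
    dc_next <- dc * f
  }
  dAm <- matrix(dA, 4 * H, Tn * B)
  Xm <- matrix(X, d[1], Tn * B)
  dW <- tcrossprod(dAm, Xm)
  db <- rowSums(dAm)
  dXm <- crossprod(p$W, dAm)
  dim(dXm) <- d
  list(dW = dW, dU = dU, db = db, dX = dXm)
}

bilstm_fwd <- function(p, X) {
  fw <- lstm_dir_fwd(p$fw, X)
  Xr <- X[, rev(seq_len(dim(X)[2])), , drop = FALSE]
  bw <- lstm_dir_fwd(p$bw, Xr)
  Ybw <- bw$Y[, rev(seq_len(dim(X)[2])), , drop = FALSE]
  H <- dim(fw$Y)[1]
  Y <- array(0, c(2 * H, dim(X)[2], dim(X)[3]))
  Y[1:H, , ] <- fw$Y
  Y[H + 1:H, , ] <- Ybw
  list(Y = Y, fw = fw, bw = bw, H = H)
}

bilstm_bwd <- function(p, cache, dY) {
  H <- cache$H
  Tn <- dim(dY)[2]
  g_fw <- lstm_dir_bwd(p$fw, cache$fw, dY[1:H, , , drop = FALSE])
  dY_bw <- dY[H + 1:H, rev(seq_len(Tn)), , drop = FALSE]
  g_bw <- lstm_dir_bwd(p$bw, cache$bw, dY_bw)
  dX <- g_fw$dX + g_bw$dX[, rev(seq_len(Tn)), , drop = FALSE]
  list(fw = g_fw[c("dW", "dU", "db")], bw = g_bw[c("dW", "dU", "db")], dX = dX)
}

# ---- additive (Bahdanau-style) attention pooling over time ----

attention_fwd <- function(p, X) {
  d <- dim(X)                       # (D, T, B)
  Hm <- matrix(X, d[1], d[2] * d[3])
  u <- tanh(p$W %*% Hm + p$b)       # (A, T*B)
  s <- colSums(u * p$v)
  dim(s) <- c(d[2], d[3])
  s <- s - rep(apply(s, 2, max), each = d[2])
  e <- exp(s)
  alpha <- e / rep(colSums(e), each = d[2])     # (T, B), sums to 1 per b
  alpha_arr <- array(rep(alpha, each = d[1]), d)
  pooled <- colSums(aperm(X * alpha_arr, c(2, 1, 3)))   # (D, B)
  list(Y = pooled, alpha = alpha, u = u, X = X)
}

attention_bwd <- function(p, cache, dY) {
  X <- cache$X
  d <- dim(X)
  alpha <- cache$alpha
  # dP appears through pooled = sum_t alpha_t x_t
  dpool_arr <- aperm(array(rep(dY, times = d[2]), c(d[1], d[3], d[2])),
                     c(1, 3, 2))                          # (D, T, B)
  dsc <- colSums(X * dpool_arr)                           # (T, B)
  inner <- colSums(alpha * dsc)                           # per batch
  dscore <- alpha * (dsc - rep(inner, each = d[2]))       # softmax backward
  alpha_arr <- array(rep(alpha, each = d[1]), d)
  dX <- dpool_arr * alpha_arr
  dsv <- as.vector(dscore)
  du <- outer(p$v, dsv)                                   # (A, T*B)
  dv <- as.vector(cache$u %*% dsv)
  dpre <- du * (1 - cache$u^2)
  Hm <- matrix(X, d[1], d[2] * d[3])
  dW <- tcrossprod(dpre, Hm)
  db <- rowSums(dpre)
  dXm <- crossprod(p$W, dpre)
  dim(dXm) <- d
  list(dW = dW, db = db, dv = dv, dX = dX + dXm)
}

dense_fwd <- function(W, b, X) list(Y = W %*% X + b, X = X)
dense_bwd <- function(W, cache, dY) {
  list(dW = tcrossprod(dY, cache$X), db = rowSums(dY),
       dX = crossprod(W, dY))
}
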