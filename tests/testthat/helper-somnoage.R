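# Tiny network configuration used across tests: epochs of 64 samples so
# forward/backward passes are fast; strides multiply to 16.
tiny_cfg <- function(C = 2, seed = 7, q_samples = 64) {
  agenet_config(C = C, mixer_filters = 3, block_filters = c(4, 4),
                block_expansion = 2, block_stride = c(4, 4),
                lstm_hidden = 3, attn_dim = 4, dense_dim = 5,
                p2_lstm_hidden = 4, p2_attn_dim = 4, p2_dense_dim = 4,
                epoch_s = q_samples / 128, fs = 128, seed = seed)
}

# deterministic pseudo-EEG trace for filter/resampler tests
test_trace <- function(label = "C3-M2", n = 2560, fs = 128, seed = 1) {
  set.seed(seed)
  signal_trace(label, rnorm(n), fs, "uV")
}

# nested-list parameter access used by gradient checks
getp <- function(x, path) {
  for (k in path) x <- x[[k]]
  x
}
setp <- function(x, path, i, val) {
  if (length(path) == 1) {
    x[[path[[1]]]][i] <- val
    return(x)
  }
  x[[path[[1]]]] <- setp(x[[path[[1]]]], path[-1], i, val)
  x
}

# Brute-force Efron partial likelihood for a single covariate; the
# independent oracle for the Cox fitting route.
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sum_r <- sum(exp(beta * x[R]))
    sum_d <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_r - l / d * sum_d)
    }
  }
  ll
}
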