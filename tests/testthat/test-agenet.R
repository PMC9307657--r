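test_that("scaled Huber loss matches its printed anchors and properties", {
  expect_equal(huber_loss(25, 0), 1)          # 25-year error gives loss 1
  expect_equal(huber_loss(0, 25), 1)
  expect_equal(huber_loss(10, 10), 0)
  # boundary: both branch formulas agree at |e| = 5
  expect_equal(huber_loss(5, 0), 12.5 / 112.5)
  expect_equal(0.5 * 5^2 / 112.5, 5 * (5 - 2.5) / 112.5)
  # even in e, nondecreasing in |e|, C1 at the crossover
  e <- seq(-40, 40, by = 0.25)
  L <- huber_loss(e, 0)
  expect_equal(L, rev(L))
  expect_true(all(diff(L[e >= 0]) >= 0))
  g <- huber_grad(0, -e)                       # d/dyhat at yhat = -e... sign check below
  eps <- 1e-7
  for (e0 in c(4.999, 5, 5.001, -5)) {
    num <- (huber_loss(e0, eps) - huber_loss(e0, -eps)) / (2 * eps)
    expect_equal(huber_grad(e0, 0), num, tolerance = 1e-5)
  }
  # gradient magnitude bounded by 5/112.5
  expect_lte(max(abs(huber_grad(e, 0))), 5 / 112.5 + 1e-12)
})

test_that("additive attention yields a probability vector over time", {
  set.seed(11)
  H1 <- matrix(rnorm(6), 6, 1)
  r1 <- additive_attention(H1)
  expect_equal(r1$weights, 1)
  expect_equal(r1$pooled, as.numeric(H1))
  # identical time steps: uniform weights
  Hc <- matrix(rep(rnorm(4), 5), 4, 5)
  rc <- additive_attention(Hc)
  expect_equal(rc$weights, rep(0.2, 5), tolerance = 1e-12)
  for (i in 1:5) {
    Hr <- matrix(rnorm(4 * 7), 4, 7)
    rr <- additive_attention(Hr, seed = i)
    expect_true(all(rr$weights >= 0))
    expect_equal(sum(rr$weights), 1, tolerance = 1e-6)
  }
})

test_that("epoch segmentation follows the floor rule", {
  cfg <- tiny_cfg()
  q <- cfg$q
  x <- matrix(rnorm(2 * (3 * q + q %/% 2)), 2)
  eps <- segment_epochs(x, q)
  expect_length(eps, 3)
  expect_equal(dim(eps[[1]]), c(2, q))
  expect_length(segment_epochs(matrix(0, 2, q), q), 1)
  expect_error(segment_epochs(matrix(0, 2, q - 1), q), "shorter",
               class = "somnoage_net_error")
})

test_that("phase-1 forward is deterministic, stateless and bias-anchored", {
  cfg <- tiny_cfg()
  p <- init_phase1(cfg)
  set.seed(12)
  x <- array(rnorm(2 * cfg$q * 3), c(2, cfg$q, 3))
  f1 <- phase1_forward(p, x, cfg)
  f2 <- phase1_forward(p, x, cfg)
  expect_identical(f1$yhat, f2$yhat)
  # per-epoch outputs do not depend on batch composition or order
  single <- vapply(1:3, function(b) phase1_forward(p, x[, , b], cfg)$yhat, 0)
  expect_equal(f1$yhat, single, tolerance = 1e-12)
  perm <- phase1_forward(p, x[, , c(3, 1, 2)], cfg)$yhat
  expect_equal(perm, f1$yhat[c(3, 1, 2)], tolerance = 1e-12)
  # all-zero weights: the output equals the output-layer bias
  p0 <- somnoage:::nn_map(function(a) a * 0, p)
  p0$out$b <- 37.5
  f0 <- phase1_forward(p0, x, cfg)
  expect_equal(f0$yhat, rep(37.5, 3))
  # clamping applies to reporting, not the raw output
  p0$out$b <- -3
  fneg <- phase1_forward(p0, x, cfg)
  expect_equal(fneg$yhat, rep(-3, 3))
  expect_equal(fneg$yhat_clamped, rep(0, 3))
})

test_that("latent dimension follows M = dense + 2 x lstm and the mean rule", {
  cfg64 <- agenet_config(C = 2, dense_dim = 64, lstm_hidden = 64,
                         epoch_s = 0.5)
  expect_equal(latent_dim(cfg64), 192)
  cfg <- tiny_cfg()
  expect_equal(cfg$M, 5 + 2 * 3)
  p <- init_phase1(cfg)
  set.seed(13)
  x <- matrix(rnorm(2 * cfg$q), 2)
  fw <- phase1_forward(p, x, cfg, keep_cache = TRUE)
  expect_equal(dim(fw$latent), c(cfg$M, 1L))
  expect_true(all(is.finite(fw$latent)))
  expect_equal(build_latent(fw$cache), fw$latent)
  # time-mean rule: a constant Bi-LSTM output would average to itself
  Y <- fw$cache$lstm$Y
  manual <- rowMeans(matrix(Y, dim(Y)[1]))
  expect_equal(unname(fw$latent[6:11, 1]), manual, tolerance = 1e-12)
})

test_that("phase-2 forward handles minimal and repeated sequences", {
  cfg <- tiny_cfg()
  p2 <- init_phase2(cfg)
  set.seed(14)
  z1 <- matrix(rnorm(cfg$M), cfg$M, 1)
  f1 <- phase2_forward(p2, z1, cfg)
  expect_length(f1$yhat, 1)
  expect_true(is.finite(f1$yhat))
  zz <- cbind(z1, z1)
  f2 <- phase2_forward(p2, zz, cfg)
  expect_true(is.finite(f2$yhat))
  expect_identical(phase2_forward(p2, zz, cfg)$yhat, f2$yhat)
  expect_error(phase2_forward(p2, z1[, 0, drop = FALSE], cfg),
               class = "somnoage_net_error")
})

test_that("backpropagated gradients match finite differences", {
  cfg <- tiny_cfg(seed = 3)
  set.seed(15)
  p <- init_phase1(cfg)
  # jitter biases so no pre-activation sits exactly on a ReLU kink
  p <- somnoage:::nn_map(function(a) a + 0.01 * rnorm(length(a)), p)
  x <- array(rnorm(2 * cfg$q * 2), c(2, cfg$q, 2))
  y <- c(40, 60)
  fw <- phase1_forward(p, x, cfg, keep_cache = TRUE)
  bw <- phase1_backward(p, fw$cache, huber_grad(y, fw$yhat) / 2, cfg,
                        need_dx = TRUE)
  loss <- function(pp) mean(huber_loss(y, phase1_forward(pp, x, cfg)$yhat))
  eps <- 1e-6
  paths <- list(list("mixer", "W"), list("blocks", 1L, "expand", "W"),
                list("blocks", 1L, "dw", "W"), list("blocks", 2L, "proj", "b"),
                list("lstm", "fw", "W"), list("lstm", "bw", "U"),
                list("attn", "W"), list("attn", "v"),
                list("fc1", "W"), list("out", "W"), list("out", "b"))
  for (pt in paths) {
    leaf <- getp(p, pt)
    g <- getp(bw$grads, pt)
    for (i in seq_len(min(4, length(leaf)))) {
      num <- (loss(setp(p, pt, i, leaf[i] + eps)) -
                loss(setp(p, pt, i, leaf[i] - eps))) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4,
                   label = paste("grad", paste(unlist(pt), collapse = "$")))
    }
  }
  # gradient w.r.t. the input (used by the attribution module)
  for (i in sample(length(x), 5)) {
    x2 <- x; x2[i] <- x2[i] + eps
    x3 <- x; x3[i] <- x3[i] - eps
    num <- (mean(huber_loss(y, phase1_forward(p, x2, cfg)$yhat)) -
              mean(huber_loss(y, phase1_forward(p, x3, cfg)$yhat))) / (2 * eps)
    expect_equal(bw$dx[i], num, tolerance = 1e-4)
  }
  # phase 2
  p2 <- somnoage:::nn_map(function(a) a + 0.01 * rnorm(length(a)),
                          init_phase2(cfg))
  z <- array(rnorm(cfg$M * 4 * 2), c(cfg$M, 4, 2))
  fw2 <- phase2_forward(p2, z, cfg, keep_cache = TRUE)
  bw2 <- phase2_backward(p2, fw2$cache, huber_grad(y, fw2$yhat) / 2, cfg)
  loss2 <- function(pp) mean(huber_loss(y, phase2_forward(pp, z, cfg)$yhat))
  for (pt in list(list("lstm", "fw", "U"), list("attn", "b"),
                  list("fc1", "W"), list("out", "W"), list("out", "b"))) {
    leaf <- getp(p2, pt)
    g <- getp(bw2$grads, pt)
    for (i in seq_len(min(4, length(leaf)))) {
      num <- (loss2(setp(p2, pt, i, leaf[i] + eps)) -
                loss2(setp(p2, pt, i, leaf[i] - eps))) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
})

test_that("parameter count and latent dim are pure functions of the config", {
  cfg <- tiny_cfg(seed = 1)
  n1 <- n_parameters(cfg, 1)
  n2 <- n_parameters(cfg, 2)
  expect_identical(n_parameters(tiny_cfg(seed = 99), 1), n1)
  expect_identical(n_parameters(tiny_cfg(seed = 99), 2), n2)
  expect_gt(n1, 0)
  cfg_wider <- agenet_config(C = 2, mixer_filters = 6, block_filters = c(4, 4),
                             block_expansion = 2, block_stride = c(4, 4),
                             lstm_hidden = 3, attn_dim = 4, dense_dim = 5,
                             epoch_s = 0.5, seed = 1)
  expect_gt(n_parameters(cfg_wider, 1), n1)
})
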