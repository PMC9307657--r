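test_that("Adam applies weight decay to weights but never biases", {
  cfg <- tiny_cfg()
  p <- init_phase1(cfg)
  p$out$b <- 5
  p$fc1$b <- rep(2, length(p$fc1$b))
  g0 <- somnoage:::nn_zeros_like(p)
  tc <- train_config(lr = 0.1, weight_decay = 0.5)
  st <- somnoage:::adam_init(p)
  # zero gradients: weights shrink through decay, biases stay put
  r <- somnoage:::adam_step(p, g0, st, tc)
  expect_equal(r$params$out$b, 5)
  expect_equal(r$params$fc1$b, p$fc1$b)
  expect_lt(sum(abs(r$params$fc1$W)), sum(abs(p$fc1$W)))
  expect_lt(sum(abs(r$params$lstm$fw$U)), sum(abs(p$lstm$fw$U)))
})

test_that("uniform split whittles the most represented cells first", {
  df <- tibble::tibble(subject_id = c("a", "b", "c", "d"),
                       age = c(30, 30, 30, 40),
                       cohort = "x", sex = "M")
  sp <- uniform_split(df, n_train = 2, n_val = 0, seed = 1)
  train_ages <- sort(sp$age[sp$set == "train"])
  expect_equal(train_ages, c(30, 40))   # both removals hit the age-30 cell
  expect_equal(sum(sp$set == "test"), 2)
})

test_that("forced-test subjects never reach train or val", {
  set.seed(31)
  df <- tibble::tibble(subject_id = sprintf("s%02d", 1:40),
                       age = runif(40, 20, 80),
                       cohort = sample(c("c1", "c2"), 40, TRUE),
                       sex = sample(c("M", "F"), 40, TRUE),
                       cpap_user = c(rep(TRUE, 4), rep(FALSE, 36)),
                       neuro_disorder = c(rep(FALSE, 38), TRUE, TRUE))
  for (sd in 1:5) {
    sp <- uniform_split(df, n_train = 15, n_val = 5, seed = sd)
    forced <- sp$subject_id[sp$cpap_user | sp$neuro_disorder]
    expect_true(all(sp$set[sp$subject_id %in% forced] == "test"))
  }
})

test_that("split is deterministic under a fixed seed and flattens ages", {
  set.seed(32)
  ages <- round(c(rnorm(60, 45, 6), runif(30, 20, 85)))
  df <- tibble::tibble(subject_id = sprintf("p%03d", seq_along(ages)),
                       age = ages, cohort = "c", sex = "M")
  s1 <- uniform_split(df, n_train = 40, n_val = 10, seed = 7)
  s2 <- uniform_split(df, n_train = 40, n_val = 10, seed = 7)
  expect_identical(s1$set, s2$set)
  # per-age counts of the training set vary less than the pool's
  cnt <- function(a) {
    tb <- table(factor(floor(a), levels = sort(unique(floor(ages)))))
    var(as.numeric(tb))
  }
  expect_lt(cnt(s1$age[s1$set == "train"]), cnt(ages))
  # no leakage between sets
  expect_length(intersect(s1$subject_id[s1$set == "train"],
                          s1$subject_id[s1$set == "val"]), 0)
  expect_error(uniform_split(df, n_train = 85, n_val = 10, seed = 1),
               class = "somnoage_split_error")
})

test_that("repeat nights of one subject share a split set", {
  df <- tibble::tibble(subject_id = rep(c("a", "b", "c", "d", "e"), each = 2),
                       age = rep(c(30, 40, 50, 60, 70), each = 2),
                       cohort = "c", sex = "F")
  sp <- uniform_split(df, n_train = 3, n_val = 1, seed = 2)
  per_subj <- tapply(sp$set, sp$subject_id, function(s) length(unique(s)))
  expect_true(all(per_subj == 1))
})

test_that("phase-1 training learns a variance-coded age signal", {
  # channel 1 amplitude encodes age; channel 2 is reference noise
  cfg <- tiny_cfg(seed = 4, q_samples = 256)
  set.seed(33)
  n <- 24
  ages <- runif(n, 20, 90)
  xs <- lapply(seq_len(n), function(i) {
    rbind(rnorm(4 * cfg$q, sd = ages[i] / 50), rnorm(4 * cfg$q))
  })
  tr <- 1:16; va <- 17:24
  tc <- train_config(lr = 2e-2, weight_decay = 0, batch_size = 16,
                     max_epochs = 12, patience = 12, seed = 5)
  r <- train_phase1(xs[tr], ages[tr], xs[va], ages[va], cfg, tc)
  baseline <- mean(huber_loss(ages[va], mean(ages[tr])))
  expect_lt(min(r$history$val_loss), baseline)
  expect_equal(nrow(r$history), 12)
})

test_that("zero learning rate leaves weights and loss untouched", {
  cfg <- tiny_cfg(seed = 6)
  set.seed(34)
  xs <- lapply(1:4, function(i) matrix(rnorm(2 * 2 * cfg$q), 2))
  ages <- c(30, 40, 50, 60)
  tc <- train_config(lr = 0, weight_decay = 0, batch_size = 4,
                     max_epochs = 3, patience = 3, seed = 5)
  r <- train_phase1(xs[1:3], ages[1:3], xs[4], ages[4], cfg, tc)
  expect_equal(sd(r$history$val_loss), 0)
  p_ref <- init_phase1(cfg)
  p_ref$out$b <- mean(ages[1:3])
  expect_equal(r$params$mixer$W, p_ref$mixer$W)
})

test_that("training is reproducible under a fixed seed", {
  cfg <- tiny_cfg(seed = 8)
  set.seed(35)
  xs <- lapply(1:6, function(i) matrix(rnorm(2 * 2 * cfg$q), 2))
  ages <- seq(25, 75, by = 10)
  tc <- train_config(lr = 1e-2, batch_size = 4, max_epochs = 2,
                     patience = 2, seed = 9)
  r1 <- train_phase1(xs[1:4], ages[1:4], xs[5:6], ages[5:6], cfg, tc)
  r2 <- train_phase1(xs[1:4], ages[1:4], xs[5:6], ages[5:6], cfg, tc)
  expect_equal(r1$history$val_loss, r2$history$val_loss, tolerance = 1e-6)
})

test_that("latent extraction honors recording order and caching round trip", {
  cfg <- tiny_cfg(seed = 10)
  p <- init_phase1(cfg)
  set.seed(36)
  x <- matrix(rnorm(2 * 5 * cfg$q + 2 * 10), 2)   # 5 epochs + remainder
  z <- extract_latents(p, list(x), cfg)[[1]]
  expect_equal(dim(z), c(cfg$M, 5L))
  # columns equal per-epoch forward latents, in order
  for (j in c(1, 3, 5)) {
    ep <- x[, ((j - 1) * cfg$q + 1):(j * cfg$q)]
    expect_equal(z[, j], phase1_forward(p, ep, cfg)$latent[, 1],
                 tolerance = 1e-12)
  }
  expect_warning(zl <- extract_latents(p, list(matrix(0, 2, 10)), cfg),
                 "shorter")
  expect_null(zl[[1]])
})

test_that("phase-2 training fits latents whose mean encodes age", {
  cfg <- tiny_cfg(seed = 12)
  set.seed(37)
  n <- 30
  ages <- runif(n, 20, 90)
  zs <- lapply(seq_len(n), function(i) {
    matrix(rnorm(cfg$M * 6, mean = (ages[i] - 55) / 20), cfg$M, 6)
  })
  tr <- 1:20; va <- 21:30
  tc <- train_config(lr = 2e-2, weight_decay = 0, batch_size = 10,
                     max_epochs = 40, patience = 40, seed = 13)
  r <- train_phase2(zs[tr], ages[tr], zs[va], ages[va], cfg, tc)
  pred <- vapply(va, function(i) phase2_forward(r$params, zs[[i]], cfg)$yhat, 0)
  null_mae <- mean(abs(ages[va] - mean(ages[tr])))
  expect_lt(mean(abs(pred - ages[va])), null_mae)
  # single-record overfit: capacity sanity
  r1 <- train_phase2(zs[1], ages[1], zs[1], ages[1], cfg,
                     train_config(lr = 5e-2, weight_decay = 0, batch_size = 1,
                                  max_epochs = 60, patience = 60, seed = 14))
  expect_lt(min(r1$history$val_loss), 0.02)
})
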