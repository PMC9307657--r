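#' Training configuration
#'
#' Adam with `beta1 = 0.9`, `beta2 = 0.999`; L2 weight decay on weight
#' matrices only, never on bias terms.
#'
#' @param lr learning rate.
#' @param weight_decay L2 coefficient applied to weights (not biases).
#' @param batch_size minibatch size.
#' @param max_epochs maximum passes over the training data.
#' @param patience early-stop patience on validation loss (epochs).
#' @param seed shuffling/initialization seed.
#' @param epochs_per_subject phase-1 subsample: number of 5-min epochs
#'   drawn per subject per training pass (`Inf` = all).
#' @param verbose print per-epoch losses.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, weight_decay = 1e-5, batch_size = 16,
                         max_epochs = 10, patience = 5, seed = 1L,
                         epochs_per_subject = Inf, verbose = FALSE) {
  structure(list(lr = lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                 weight_decay = weight_decay, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience,
                 seed = as.integer(seed),
                 epochs_per_subject = epochs_per_subject,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = nn_zeros_like(params), v = nn_zeros_like(params), t = 0L)
}

# One Adam update. Decay is added to the gradient for every leaf whose
# name is not "b" (biases are exempt).
adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  t <- state$t
  lr_t <- cfg$lr * sqrt(1 - cfg$beta2^t) / (1 - cfg$beta1^t)
  upd <- function(p, g, m, v, path) {
    if (cfg$weight_decay > 0 && path[length(path)] != "b") {
      g <- g + cfg$weight_decay * p
    }
    m <- cfg$beta1 * m + (1 - cfg$beta1) * g
    v <- cfg$beta2 * v + (1 - cfg$beta2) * g^2
    list(p = p - lr_t * m / (sqrt(v) + cfg$eps), m = m, v = v)
  }
  walk <- function(p, g, m, v, path = character(0)) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        nm <- if (!is.null(names(p))) names(p)[i] else as.character(i)
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]], c(path, nm))
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else upd(p, g, m, v, path)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

#' Uniform-age train/validation split
#'
#' Greedy sampling toward a uniform joint distribution: while the pool
#' exceeds `n_train` subjects, the most represented integer age is
#' found, within it the most represented cohort, within that the most
#' represented sex, and one uniformly chosen member of that cell is
#' removed. The removed subjects are then subjected to the same loop
#' targeting `n_val`; everything removed twice, plus all CPAP users and
#' subjects with neurological disorders (always forced out first), forms
#' the test set. The split is by subject: repeat nights follow their
#' subject.
#'
#' @param records tibble with columns `subject_id`, `age`, `cohort`,
#'   `sex`, and logical `cpap_user`, `neuro_disorder` (missing flag
#'   columns are treated as all-`FALSE`).
#' @param n_train,n_val target training/validation sizes (subjects).
#' @param seed RNG seed; ties in the greedy loop are broken by seeded
#'   uniform choice.
#' @return input tibble with a `set` column (`"train"`, `"val"`,
#'   `"test"`) and logical `forced_test`.
#' @export
uniform_split <- function(records, n_train, n_val, seed = 1L) {
  df <- tibble::as_tibble(records)
  stopifnot(all(c("subject_id", "age") %in% names(df)))
  if (!"cohort" %in% names(df)) df$cohort <- "default"
  if (!"sex" %in% names(df)) df$sex <- "U"
  if (!"cpap_user" %in% names(df)) df$cpap_user <- FALSE
  if (!"neuro_disorder" %in% names(df)) df$neuro_disorder <- FALSE

  subj <- df |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(age = dplyr::first(.data$age),
                     cohort = dplyr::first(.data$cohort),
                     sex = dplyr::first(.data$sex),
                     forced = any(.data$cpap_user | .data$neuro_disorder),
                     .groups = "drop")
  eligible <- subj$subject_id[!subj$forced & !is.na(subj$age)]
  if (n_train + n_val > length(eligible)) {
    stop_somnoage("n_train + n_val (", n_train + n_val,
                  ") exceeds the eligible pool (", length(eligible), ")",
                  class = "somnoage_split_error")
  }
  set.seed(seed)
  lookup <- subj[match(eligible, subj$subject_id), ]
  ages <- floor(lookup$age); names(ages) <- eligible
  cohorts <- setNames(lookup$cohort, eligible)
  sexes <- setNames(lookup$sex, eligible)

  whittle <- function(pool, target) {
    removed <- character(0)
    while (length(pool) > target) {
      a <- ages[pool]
      top_age <- as.numeric(names(which.max(table(a))))
      in_age <- pool[a == top_age]
      top_coh <- names(which.max(table(cohorts[in_age])))
      in_coh <- in_age[cohorts[in_age] == top_coh]
      top_sex <- names(which.max(table(sexes[in_coh])))
      cell <- in_coh[sexes[in_coh] %in% top_sex]
      drop1 <- cell[sample.int(length(cell), 1)]
      pool <- setdiff(pool, drop1)
      removed <- c(removed, drop1)
    }
    list(kept = pool, removed = removed)
  }
  s1 <- whittle(eligible, n_train)
  s2 <- whittle(s1$removed, n_val)
  set_of <- setNames(rep("test", nrow(subj)), subj$subject_id)
  set_of[s1$kept] <- "train"
  set_of[s2$kept] <- "val"
  df$set <- unname(set_of[df$subject_id])
  df$forced_test <- unname(setNames(subj$forced, subj$subject_id)[df$subject_id])
  df
}

# assemble a (C, q, B) batch from a list of C x T matrices + epoch index
.epoch_batch <- function(xs, rec_idx, ep_idx, q) {
  B <- length(rec_idx)
  C <- nrow(xs[[rec_idx[1]]])
  out <- array(0, c(C, q, B))
  for (b in seq_len(B)) {
    j0 <- (ep_idx[b] - 1L) * q
    out[, , b] <- xs[[rec_idx[b]]][, (j0 + 1):(j0 + q)]
  }
  out
}

#' Train the phase-1 (epoch-level) network
#'
#' Minimizes the scaled Huber loss over (5-min epoch, subject age)
#' pairs with Adam. Every epoch of a night carries its subject's age as
#' the label. Returns the best-validation checkpoint and a per-epoch
#' loss history; training aborts with the history attached if the
#' validation loss turns non-finite.
#'
#' @param train_x,val_x lists of `C x T` preprocessed signal matrices.
#' @param train_y,val_y subject ages (one per record).
#' @param netcfg an [agenet_config()].
#' @param traincfg a [train_config()].
#' @param params optional warm-start weights.
#' @return list with `params` (best checkpoint), `history` (tibble:
#'   epoch, train_loss, val_loss), `best_epoch`.
#' @export
train_phase1 <- function(train_x, train_y, val_x, val_y, netcfg,
                         traincfg = train_config(), params = NULL) {
  q <- netcfg$q
  if (is.null(params)) {
    params <- init_phase1(netcfg)
    params$out$b <- mean(train_y)      # start at the label mean
  }
  state <- adam_init(params)
  n_ep <- vapply(train_x, function(m) ncol(m) %/% q, 0L)
  if (any(n_ep < 1)) {
    stop_somnoage("training record shorter than one epoch",
                  class = "somnoage_train_error")
  }
  val_pairs <- .all_pairs(val_x, q)
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- list()
  set.seed(traincfg$seed)
  wait <- 0L
  for (ep in seq_len(traincfg$max_epochs)) {
    take <- pmin(n_ep, traincfg$epochs_per_subject)
    pairs <- do.call(rbind, lapply(seq_along(train_x), function(i) {
      cbind(i, sample.int(n_ep[i])[seq_len(take[i])])
    }))
    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    tr_loss <- 0; nb <- 0L
    for (s in seq(1, nrow(pairs), by = traincfg$batch_size)) {
      sel <- s:min(s + traincfg$batch_size - 1, nrow(pairs))
      xb <- .epoch_batch(train_x, pairs[sel, 1], pairs[sel, 2], q)
      yb <- train_y[pairs[sel, 1]]
      fw <- phase1_forward(params, xb, netcfg, keep_cache = TRUE)
      loss <- mean(huber_loss(yb, fw$yhat))
      dy <- huber_grad(yb, fw$yhat) / length(yb)
      bw <- phase1_backward(params, fw$cache, dy, netcfg)
      st <- adam_step(params, bw$grads, state, traincfg)
      params <- st$params; state <- st$state
      tr_loss <- tr_loss + loss; nb <- nb + 1L
    }
    vl <- .eval_pairs(params, val_x, val_y, val_pairs, netcfg,
                      traincfg$batch_size, phase = 1)
    hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = tr_loss / nb,
                                 val_loss = vl)
    if (traincfg$verbose) {
      message(sprintf("phase1 epoch %d: train %.4f val %.4f", ep,
                      tr_loss / nb, vl))
    }
    if (!is.finite(vl)) {
      stop_somnoage("phase-1 training diverged (non-finite validation loss)",
                    class = "somnoage_train_error")
    }
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, params = params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= traincfg$patience) break
    }
  }
  list(params = best$params, history = dplyr::bind_rows(hist),
       best_epoch = best$epoch)
}

.all_pairs <- function(xs, q) {
  do.call(rbind, lapply(seq_along(xs), function(i) {
    cbind(i, seq_len(ncol(xs[[i]]) %/% q))
  }))
}

.eval_pairs <- function(params, xs, ys, pairs, netcfg, batch_size, phase) {
  tot <- 0; n <- 0L
  q <- netcfg$q
  for (s in seq(1, nrow(pairs), by = batch_size)) {
    sel <- s:min(s + batch_size - 1, nrow(pairs))
    xb <- .epoch_batch(xs, pairs[sel, 1], pairs[sel, 2], q)
    yb <- ys[pairs[sel, 1]]
    fw <- phase1_forward(params, xb, netcfg)
    tot <- tot + sum(huber_loss(yb, fw$yhat))
    n <- n + length(sel)
  }
  tot / n
}

#' Extract per-record latent sequences with frozen phase-1 weights
#'
#' @param params trained phase-1 weights.
#' @param xs list of `C x T` preprocessed matrices.
#' @param netcfg the [agenet_config()].
#' @param batch_size forward batch size.
#' @return list of `M x n_epochs` latent matrices (records shorter than
#'   one 5-min epoch are skipped with a warning and returned as `NULL`).
#' @export
extract_latents <- function(params, xs, netcfg, batch_size = 16) {
  q <- netcfg$q
  out <- vector("list", length(xs))
  for (i in seq_along(xs)) {
    n <- ncol(xs[[i]]) %/% q
    if (n < 1) {
      warning("record ", i, " shorter than one epoch; skipped", call. = FALSE)
      next
    }
    Z <- matrix(0, netcfg$M, n)
    for (s in seq(1, n, by = batch_size)) {
      sel <- s:min(s + batch_size - 1, n)
      xb <- .epoch_batch(xs[i], rep(1L, length(sel)), sel, q)
      fw <- phase1_forward(params, xb, netcfg)
      Z[, sel] <- fw$latent
    }
    out[[i]] <- Z
  }
  out
}

#' Train the phase-2 (night-level) network on latent sequences
#'
#' @param train_z,val_z lists of `M x n_epochs` latent matrices.
#' @param train_y,val_y ages.
#' @param netcfg,traincfg as in [train_phase1()].
#' @param params optional warm start.
#' @return list with `params`, `history`, `best_epoch`.
#' @export
train_phase2 <- function(train_z, train_y, val_z, val_y, netcfg,
                         traincfg = train_config(), params = NULL) {
  if (is.null(params)) {
    params <- init_phase2(netcfg)
    params$out$b <- mean(train_y)      # start at the label mean
  }
  state <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- list(); wait <- 0L
  set.seed(traincfg$seed + 1L)
  lens <- vapply(train_z, ncol, 0L)
  for (ep in seq_len(traincfg$max_epochs)) {
    ord <- sample.int(length(train_z))
    tr_loss <- 0; nb <- 0L
    for (s in seq(1, length(ord), by = traincfg$batch_size)) {
      sel <- ord[s:min(s + traincfg$batch_size - 1, length(ord))]
      for (grp in split(sel, lens[sel])) {   # equal-length records batch
        zb <- array(unlist(train_z[grp]),
                    c(netcfg$M, lens[grp[1]], length(grp)))
        yb <- train_y[grp]
        fw <- phase2_forward(params, zb, netcfg, keep_cache = TRUE)
        loss <- mean(huber_loss(yb, fw$yhat))
        dy <- huber_grad(yb, fw$yhat) / length(yb)
        bw <- phase2_backward(params, fw$cache, dy, netcfg)
        st <- adam_step(params, bw$grads, state, traincfg)
        params <- st$params; state <- st$state
        tr_loss <- tr_loss + loss; nb <- nb + 1L
      }
    }
    vls <- vapply(seq_along(val_z), function(i) {
      mean(huber_loss(val_y[i], phase2_forward(params, val_z[[i]], netcfg)$yhat))
    }, 0)
    vl <- mean(vls)
    hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = tr_loss / nb,
                                 val_loss = vl)
    if (traincfg$verbose) {
      message(sprintf("phase2 epoch %d: train %.4f val %.4f", ep,
                      tr_loss / nb, vl))
    }
    if (!is.finite(vl)) {
      stop_somnoage("phase-2 training diverged (non-finite validation loss)",
                    class = "somnoage_train_error")
    }
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, params = params, epoch = ep); wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= traincfg$patience) break
    }
  }
  list(params = best$params, history = dplyr::bind_rows(hist),
       best_epoch = best$epoch)
}

#' Whole-night age prediction with a trained two-phase model
#'
#' @param p1,p2 trained phase-1 / phase-2 weights.
#' @param xs list of `C x T` preprocessed matrices (or a single matrix).
#' @param netcfg the [agenet_config()].
#' @return numeric vector of final age estimates (clamped at 0).
#' @export
predict_age <- function(p1, p2, xs, netcfg) {
  if (is.matrix(xs)) xs <- list(xs)
  zs <- extract_latents(p1, xs, netcfg)
  vapply(zs, function(z) {
    if (is.null(z)) return(NA_real_)
    phase2_forward(p2, z, netcfg)$yhat_clamped
  }, 0)
}
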