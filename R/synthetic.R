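#' Simulation specification for synthetic polysomnography
#'
#' Defines a cohort of synthetic overnight recordings whose signal
#' statistics drift with a known "physiological age" `age + delta`,
#' where `delta` is a zero-mean per-subject excess-aging offset that
#' also drives the survival generator. The encoded aging signatures
#' follow what is robustly reported for human sleep: slow-wave (delta)
#' EEG amplitude and N3 time decline with age, spindle density
#' declines, sleep fragmentation (arousal rate, wake intrusions) and
#' apnea/desaturation burden increase, and heart-rate variability
#' decreases.
#'
#' @param n_subjects cohort size.
#' @param rec_hours recording length in hours (2 for desk-scale tests,
#'   8 for full nights).
#' @param channels channel roles to synthesize (subset of
#'   [full_montage()]).
#' @param age_range uniform age range in years.
#' @param delta_sd SD of the excess-aging offset, years.
#' @param fs sampling rate of the synthesized signals, Hz.
#' @param delta_a0,delta_a1 delta-band EEG amplitude `a0 - a1 * age_eff`
#'   (microvolts, floored at 5).
#' @param arousal_c0,arousal_c1 arousal rate `c0 + c1 * age_eff` per
#'   hour of sleep.
#' @param apnea_a0,apnea_a1 apnea/hypopnea rate
#'   `max(0, a0 + a1 * (age_eff - 20))` per hour of sleep.
#' @param desat_d0,desat_d1 SaO2 dip depth `d0 + d1 * age_eff` percent.
#' @param spindle_s0,spindle_s1 N2 spindle rate `s0 - s1 * age_eff` per
#'   minute (floored at 0.2).
#' @param hr_base,hr_slope mean heart rate `hr_base + hr_slope * age_eff`
#'   bpm.
#' @param hrv_base,hrv_slope RR-interval SD
#'   `max(0.01, hrv_base - hrv_slope * age_eff)` seconds.
#' @param noise_sd measurement noise, microvolts.
#' @param seed cohort seed (mandatory); per-subject seeds are derived
#'   by hashing (seed, subject index).
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(n_subjects = 150, rec_hours = 2,
                     channels = c("C3-M2", "C4-M1"),
                     age_range = c(20, 90), delta_sd = 7.5, fs = 128,
                     delta_a0 = 70, delta_a1 = 0.625,
                     arousal_c0 = 1, arousal_c1 = 0.25,
                     apnea_a0 = 2, apnea_a1 = 0.35,
                     desat_d0 = 3, desat_d1 = 0.08,
                     spindle_s0 = 3.5, spindle_s1 = 0.03,
                     hr_base = 58, hr_slope = 0.12,
                     hrv_base = 0.10, hrv_slope = 8e-4,
                     noise_sd = 2, seed = 1L) {
  stopifnot(!missing(seed) || !is.null(seed))
  stopifnot(all(channels %in% full_montage()))
  structure(as.list(environment()), class = "sim_spec")
}

.subject_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 1000003 + idx * 7919) %% 2147483647)
}

# band-limited Gaussian noise via a low-order Butterworth filter
.bl_noise <- function(n, fs, band, order = 2) {
  x <- rnorm(n)
  w <- band / (fs / 2)
  flt <- if (length(w) == 2) signal::butter(order, w, type = "pass")
         else signal::butter(order, w, type = "high")
  y <- as.numeric(signal::filter(flt, x))
  y / max(sd(y), 1e-12)
}

# semi-Markov hypnogram: stage dwell times and transitions drift with
# effective age (more fragmentation, less N3)
.gen_hypnogram <- function(n_epochs, age_eff) {
  dwell <- c(W = 3, N1 = 2, N2 = 8,
             N3 = max(2, 14 - 0.12 * age_eff), REM = 6)
  p_n3 <- min(0.9, max(0.05, 0.55 - 0.005 * age_eff))
  p_frag <- min(0.6, 0.05 + 0.004 * age_eff)
  next_stage <- function(s) {
    switch(s,
      W = "N1",
      N1 = sample(c("N2", "W"), 1, prob = c(0.85, 0.15)),
      N2 = sample(c("N3", "REM", "N1", "W"), 1,
                  prob = c(p_n3, max(0.05, 1 - p_n3 - p_frag),
                           p_frag / 2, p_frag / 2)),
      N3 = sample(c("N2", "W"), 1, prob = c(1 - p_frag, p_frag)),
      REM = sample(c("N2", "N1", "W"), 1, prob = c(0.4, 0.3, 0.3)))
  }
  stages <- character(n_epochs)
  s <- "W"
  i <- 1L
  while (i <= n_epochs) {
    d <- max(1, rpois(1, dwell[[s]]))
    stages[i:min(n_epochs, i + d - 1)] <- s
    i <- i + d
    s <- next_stage(s)
  }
  hypnogram(stages)
}

#' Generate one synthetic subject
#'
#' Deterministic given `(spec, age, delta, seed)`. The hypnogram comes
#' from a semi-Markov chain whose fragmentation increases with
#' `age + delta`; EEG is a sum of stage-gated band-limited noises with
#' an age-dependent delta amplitude plus N2 spindle bursts; arousals
#' are brief high-beta bursts at an age-dependent rate; apneas gate the
#' airflow/nasal amplitude to near zero and trigger lagged SaO2 dips;
#' the ECG beat train loses rate variability with effective age.
#'
#' @param spec a [sim_spec()].
#' @param age chronological age, years.
#' @param delta excess-aging offset, years.
#' @param seed subject seed.
#' @param subject_id identifier.
#' @return list with `record` ([psg_record()]), `hypnogram`, `events`
#'   (an [event_list()]).
#' @export
gen_subject <- function(spec, age, delta = 0, seed = 1L,
                        subject_id = "sim") {
  set.seed(seed)
  fs <- spec$fs
  n_epochs <- as.integer(spec$rec_hours * 120)
  n <- n_epochs * 30L * fs
  age_eff <- age + delta
  hyp <- .gen_hypnogram(n_epochs, age_eff)
  st <- hyp$stages
  per_ep <- 30L * fs
  gate <- function(g) rep(g[st], each = per_ep)

  sleep_ep <- st %in% c("N1", "N2", "N3", "REM")
  tst_h <- sum(sleep_ep) * 30 / 3600
  ev_type <- character(0); ev_on <- numeric(0); ev_dur <- numeric(0)

  # arousal anchors (uniform over sleep epochs)
  n_arous <- rpois(1, max(0, spec$arousal_c0 + spec$arousal_c1 * age_eff) * tst_h)
  arous_on <- numeric(0)
  if (n_arous > 0 && any(sleep_ep)) {
    ep_pick <- sample(which(sleep_ep), n_arous, replace = TRUE)
    arous_on <- sort((ep_pick - 1) * 30 + runif(n_arous, 0, 25))
    dur <- runif(n_arous, 3, 10)
    ev_type <- c(ev_type, rep("arousal", n_arous))
    ev_on <- c(ev_on, arous_on); ev_dur <- c(ev_dur, dur)
  }

  # apnea anchors
  rate_ah <- max(0, spec$apnea_a0 + spec$apnea_a1 * (age_eff - 20))
  n_ap <- rpois(1, rate_ah * tst_h)
  ap_on <- numeric(0); ap_dur <- numeric(0)
  if (n_ap > 0 && any(sleep_ep)) {
    ep_pick <- sample(which(sleep_ep), n_ap, replace = TRUE)
    ap_on <- sort((ep_pick - 1) * 30 + runif(n_ap, 0, 10))
    ap_dur <- runif(n_ap, 15, 30)
    depth <- pmin(35, pmax(2, spec$desat_d0 + spec$desat_d1 * age_eff +
                             rnorm(n_ap)))
    ev_type <- c(ev_type, ifelse(depth < 4, "hypopnea", "apnea"))
    ev_on <- c(ev_on, ap_on); ev_dur <- c(ev_dur, ap_dur)
  }
  events <- event_list(tibble::tibble(type = ev_type, onset_s = ev_on,
                                      duration_s = ev_dur))

  burst_env <- function(onsets, durs, amp) {
    env <- numeric(n)
    for (i in seq_along(onsets)) {
      a <- max(1, round(onsets[i] * fs)); b <- min(n, round((onsets[i] + durs[i]) * fs))
      env[a:b] <- amp
    }
    env
  }
  arous_env <- burst_env(arous_on, rep(5, length(arous_on)), 1)

  traces <- list()
  mk_eeg <- function() {
    amp_delta <- max(5, spec$delta_a0 - spec$delta_a1 * age_eff)
    delta_g <- gate(c(W = 0.08, N1 = 0.15, N2 = 0.45, N3 = 1, REM = 0.08,
                      UNSCORED = 0.08))
    bg_g <- gate(c(W = 13, N1 = 10, N2 = 10, N3 = 10, REM = 10,
                   UNSCORED = 10))
    x <- amp_delta * delta_g * .bl_noise(n, fs, c(0.5, 2)) +
      bg_g * .bl_noise(n, fs, c(4, 30)) +
      25 * arous_env * .bl_noise(n, fs, c(16, 30)) +
      spec$noise_sd * rnorm(n)
    # N2 spindle bursts: 12 Hz with 1-s Gaussian envelope
    sp_rate <- max(0.2, spec$spindle_s0 - spec$spindle_s1 * age_eff)
    n2_ep <- which(st == "N2")
    if (length(n2_ep)) {
      n_sp <- rpois(1, sp_rate * length(n2_ep) * 0.5)
      if (n_sp > 0) {
        on <- (sample(n2_ep, n_sp, replace = TRUE) - 1) * 30 +
          runif(n_sp, 1, 28)
        tt <- seq(-0.75, 0.75, by = 1 / fs)
        sp <- 12 * exp(-0.5 * (tt / 0.25)^2) * sin(2 * pi * 12 * tt)
        for (o in on) {
          a <- round(o * fs)
          if (a + length(sp) <= n) x[a:(a + length(sp) - 1)] <-
              x[a:(a + length(sp) - 1)] + sp
        }
      }
    }
    x
  }
  for (ch in intersect(c("C3-M2", "C4-M1"), spec$channels)) {
    traces[[ch]] <- signal_trace(ch, mk_eeg(), fs, "uV")
  }
  for (ch in intersect(c("L-EOG", "R-EOG"), spec$channels)) {
    amp_g <- gate(c(W = 20, N1 = 10, N2 = 4, N3 = 4, REM = 30, UNSCORED = 4))
    traces[[ch]] <- signal_trace(ch,
      amp_g * .bl_noise(n, fs, c(0.3, 1)) + spec$noise_sd * rnorm(n), fs, "uV")
  }
  if ("chinEMG" %in% spec$channels) {
    amp_g <- gate(c(W = 20, N1 = 8, N2 = 5, N3 = 3, REM = 1.5, UNSCORED = 8))
    traces[["chinEMG"]] <- signal_trace("chinEMG",
      (amp_g + 20 * arous_env) * .bl_noise(n, fs, 20) +
        spec$noise_sd * rnorm(n), fs, "uV")
  }
  if ("ECG" %in% spec$channels) {
    hr <- spec$hr_base + spec$hr_slope * age_eff
    sd_rr <- max(0.01, spec$hrv_base - spec$hrv_slope * age_eff)
    rr <- 60 / hr + rnorm(ceiling(n / fs / (60 / hr) * 1.3) + 10, sd = sd_rr)
    rr <- pmax(0.4, rr)
    beats <- cumsum(rr)
    beats <- beats[beats < n / fs - 0.5]
    x <- numeric(n)
    tt <- seq(-0.05, 0.05, by = 1 / fs)
    qrs <- 1000 * exp(-0.5 * (tt / 0.012)^2)
    for (b in beats) {
      a <- round(b * fs)
      if (a > 0 && a + length(qrs) <= n) {
        x[a:(a + length(qrs) - 1)] <- x[a:(a + length(qrs) - 1)] + qrs
      }
    }
    traces[["ECG"]] <- signal_trace("ECG", x + 10 * rnorm(n), fs, "uV")
  }
  resp_chans <- intersect(c("airflow", "nasal_pressure", "thor_belt",
                            "abd_belt"), spec$channels)
  if (length(resp_chans) || "SaO2" %in% spec$channels) {
    f_resp <- 0.23
    phase <- 2 * pi * f_resp * (seq_len(n) / fs) +
      cumsum(rnorm(n, sd = 0.002))
    ap_gate_air <- 1 - 0.9 * burst_env(ap_on, ap_dur, 1)
    ap_gate_belt <- 1 - 0.6 * burst_env(ap_on, ap_dur, 1)
    base <- sin(phase)
    for (ch in resp_chans) {
      g <- if (ch %in% c("airflow", "nasal_pressure")) ap_gate_air
           else ap_gate_belt
      traces[[ch]] <- signal_trace(ch,
        50 * g * base + 2 * rnorm(n), fs, "au")
    }
  }
  if ("SaO2" %in% spec$channels) {
    sec <- spec$rec_hours * 3600
    sa <- rep(97 - 0.02 * age_eff, sec)
    if (n_ap > 0) {
      depth <- pmin(35, pmax(2, spec$desat_d0 + spec$desat_d1 * age_eff +
                               rnorm(n_ap)))
      for (i in seq_along(ap_on)) {
        t0 <- round(ap_on[i] + 15)          # lagged nadir onset
        down <- t0 + 0:9; rec <- t0 + 10 + 0:14
        prof <- c(seq(0, depth[i], length.out = 10),
                  depth[i] * exp(-(1:15) / 5))
        idx <- c(down, rec)
        ok <- idx >= 1 & idx <= sec
        sa[idx[ok]] <- sa[idx[ok]] - prof[ok]
      }
    }
    sa <- pmin(100, pmax(60, sa + rnorm(sec, sd = 0.3)))
    traces[["SaO2"]] <- signal_trace("SaO2", sa, 1, "%")
  }
  meta <- subject_meta(subject_id, age = age, cohort = "sim")
  list(record = psg_record(meta, traces, duration_s = n / fs),
       hypnogram = hyp, events = events)
}

#' Cohort ground truth without signal synthesis
#'
#' Draws the per-subject ages, excess-aging offsets and derived seeds
#' for a cohort. [gen_cohort()] uses exactly this table, so large
#' cohorts can be generated subject-by-subject (generate, preprocess,
#' discard) without holding every raw recording in memory.
#'
#' @param spec a [sim_spec()].
#' @return tibble: `subject_id`, `age`, `delta`, `seed`.
#' @export
cohort_truth <- function(spec) {
  set.seed(spec$seed)
  ages <- runif(spec$n_subjects, spec$age_range[1], spec$age_range[2])
  deltas <- rnorm(spec$n_subjects, 0, spec$delta_sd)
  tibble::tibble(
    subject_id = sprintf("sim%04d", seq_len(spec$n_subjects)),
    age = ages, delta = deltas,
    seed = vapply(seq_len(spec$n_subjects),
                  function(i) .subject_seed(spec$seed, i), 0L))
}

#' Generate a synthetic cohort with recorded ground truth
#'
#' @param spec a [sim_spec()].
#' @return list with `subjects` (list of [gen_subject()] outputs) and
#'   `truth` (tibble: subject_id, age, delta, seed).
#' @export
gen_cohort <- function(spec) {
  truth <- cohort_truth(spec)
  subjects <- lapply(seq_len(spec$n_subjects), function(i) {
    gen_subject(spec, truth$age[i], truth$delta[i], truth$seed[i],
                truth$subject_id[i])
  })
  list(subjects = subjects, truth = truth)
}

#' Generate proportional-hazards survival outcomes from cohort truth
#'
#' Survival times follow
#' `S(t | subject) = exp(-(t/lambda)^k * exp(beta_age (age - age_ref) +
#' beta_delta * delta))` by inverse-transform sampling, with
#' administrative censoring at `horizon` years. The excess-aging offset
#' `delta` plays the role of the biological component of the
#' age-estimate error, so the generating log-hazard slope `beta_delta`
#' is the target the survival chain should recover.
#'
#' @param truth tibble with `subject_id`, `age`, `delta`.
#' @param shape,scale baseline Weibull shape k and scale lambda (years).
#' @param beta_age log-hazard per year of age.
#' @param beta_delta log-hazard per year of excess aging.
#' @param age_ref centering age.
#' @param horizon administrative censoring horizon, years.
#' @param cv_frac fraction of deaths labelled cardiovascular.
#' @param seed RNG seed.
#' @return tibble of class `survival_records`: `subject_id`, `age`,
#'   `delta`, `time_years`, `event`, `cv_event`.
#' @export
gen_survival <- function(truth, shape = 1.4, scale = 40,
                         beta_age = 0.09, beta_delta = 0.0255,
                         age_ref = 60, horizon = 15, cv_frac = 0.35,
                         seed = 1L) {
  set.seed(seed)
  n <- nrow(truth)
  eta <- beta_age * (truth$age - age_ref) + beta_delta * truth$delta
  u <- runif(n)
  t_raw <- scale * (-log(u) / exp(eta))^(1 / shape)
  event <- as.integer(t_raw <= horizon)
  time <- pmin(t_raw, horizon)
  time[time <= 0] <- 1e-6
  cv <- as.integer(event == 1 & runif(n) < cv_frac)
  out <- tibble::tibble(subject_id = truth$subject_id, age = truth$age,
                        delta = truth$delta, time_years = time,
                        event = event, cv_event = cv)
  class(out) <- c("survival_records", class(out))
  out
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' EDF per recording, hypnogram and event TSVs, and a metadata CSV --
#' exactly the formats [read_edf()], [read_hypnogram()], [read_events()]
#' and [read_subject_meta()] consume.
#'
#' @param cohort a [gen_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) {
    id <- s$record$meta$subject_id
    write_edf(s$record, file.path(dir, paste0(id, ".edf")))
    writeLines(s$hypnogram$stages, file.path(dir, paste0(id, "_hypno.tsv")))
    ev <- s$events
    writeLines(sprintf("%s\t%.3f\t%.3f", ev$type, ev$onset_s, ev$duration_s),
               file.path(dir, paste0(id, "_events.tsv")))
  }
  truth <- cohort$truth
  write.csv(data.frame(subject_id = truth$subject_id, age = truth$age,
                       sex = NA, bmi = NA, cohort = "sim",
                       cpap_user = FALSE, neuro_disorder = FALSE),
            file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}
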