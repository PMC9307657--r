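#' Basic sleep metrics from a scored hypnogram and event list
#'
#' Standard summary definitions: total sleep time (TST) is 30 s times
#' the number of non-wake scored epochs; WASO is wake time between the
#' first and last sleep epoch; stage percentages are of TST; arousal and
#' apnea-hypopnea indices are events per hour of TST; sleep efficiency
#' is TST over time in bed.
#'
#' @param hypnogram a [hypnogram()].
#' @param events an [event_list()] (or `NULL` for no events).
#' @return one-row tibble: `tst_min`, `waso_min`, `n1_pct`, `n2_pct`,
#'   `n3_pct`, `rem_pct`, `se_pct`, `ari`, `ahi`, `flagged`.
#' @export
sleep_metrics <- function(hypnogram, events = NULL) {
  st <- hypnogram$stages
  sleep <- st %in% c("N1", "N2", "N3", "REM")
  tst_min <- sum(sleep) * 0.5
  if (tst_min == 0) {
    return(tibble::tibble(tst_min = 0, waso_min = NA_real_, n1_pct = NA_real_,
                          n2_pct = NA_real_, n3_pct = NA_real_,
                          rem_pct = NA_real_, se_pct = 0, ari = NA_real_,
                          ahi = NA_real_, flagged = TRUE))
  }
  first_s <- which(sleep)[1]
  last_s <- tail(which(sleep), 1)
  waso_min <- sum(st[first_s:last_s] == "W") * 0.5
  pct <- function(stage) 100 * sum(st == stage) * 0.5 / tst_min
  tib_min <- length(st) * 0.5
  n_ev <- function(type) {
    if (is.null(events) || nrow(events) == 0) return(0L)
    sum(events$type == type)
  }
  tst_h <- tst_min / 60
  tibble::tibble(
    tst_min = tst_min, waso_min = waso_min,
    n1_pct = pct("N1"), n2_pct = pct("N2"), n3_pct = pct("N3"),
    rem_pct = pct("REM"),
    se_pct = 100 * tst_min / tib_min,
    ari = n_ev("arousal") / tst_h,
    ahi = (n_ev("apnea") + n_ev("hypopnea")) / tst_h,
    flagged = FALSE)
}

#' Per-model and ensemble age estimates
#'
#' Collects per-record estimates from the available per-modality models
#' and adds the ensemble as the arithmetic mean of models a-d. The
#' ensemble is reported only where all four members are present.
#'
#' @param estimates tibble with columns `subject_id`, `model_id`
#'   (`"a"`..`"d"` or `"baseline"`), `estimate`, and optionally `age`.
#' @return wide tibble: one row per subject, columns per model plus
#'   `e` (ensemble, `NA` when a member is missing).
#' @export
ensemble_estimates <- function(estimates) {
  wide <- estimates |>
    dplyr::distinct(.data$subject_id, .data$model_id, .keep_all = TRUE) |>
    tidyr::pivot_wider(names_from = "model_id", values_from = "estimate")
  members <- intersect(c("a", "b", "c", "d"), names(wide))
  if (length(members) == 4) {
    wide$e <- rowMeans(wide[, members])
  } else {
    wide$e <- NA_real_
  }
  wide
}

#' Basic-sleep-measures regression baseline
#'
#' Ordinary least squares of age on sex, BMI, arousal index,
#' apnea-hypopnea index, TST, WASO and stage percentages. Rank-deficient
#' designs drop the offending columns with a warning. Predictions are
#' clamped at 0.
#'
#' @param data tibble containing `age` and the predictor columns
#'   (`sex`, `bmi`, `ari`, `ahi`, `tst_min`, `waso_min`, `n1_pct`,
#'   `n2_pct`, `n3_pct`, `rem_pct`); extra columns are ignored.
#' @return object of class `sleep_baseline` wrapping the `lm` fit.
#' @export
baseline_regression <- function(data) {
  preds <- c("sex", "bmi", "ari", "ahi", "tst_min", "waso_min",
             "n1_pct", "n2_pct", "n3_pct", "rem_pct")
  use <- intersect(preds, names(data))
  df <- as.data.frame(data[, c("age", use)])
  # constant columns carry no information and break the fit summary
  keep <- vapply(use, function(v) length(unique(df[[v]])) > 1, TRUE)
  use <- use[keep]
  fml <- stats::reformulate(if (length(use)) use else "1", response = "age")
  fit <- lm(fml, data = df)
  if (anyNA(coef(fit))) {
    dropped <- names(coef(fit))[is.na(coef(fit))]
    warning("rank-deficient design; dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  structure(list(fit = fit, predictors = use), class = "sleep_baseline")
}

#' @export
predict.sleep_baseline <- function(object, newdata = NULL, ...) {
  p <- if (is.null(newdata)) predict(object$fit)
       else predict(object$fit, newdata = as.data.frame(newdata))
  pmax(unname(p), 0)
}

#' Age-stratified mean absolute error
#'
#' MAE within half-open 5-year bins \[20,25), \[25,30), ..., \[85,90),
#' summarized as the mean and standard deviation across non-empty bins,
#' plus Pearson's correlation over all included records. Ages outside
#' \[20, 90) are excluded (their count is reported).
#'
#' @param estimates numeric vector of age estimates.
#' @param ages chronological ages.
#' @return object of class `somnoage_eval`: list with `by_bin` (tibble:
#'   bin_lo, bin_hi, n, mae), `mae_mean`, `mae_sd` (sample form),
#'   `mae_sd_pop`, `pearson_r`, `n_included`, `n_excluded`,
#'   `n_empty_bins`.
#' @export
stratified_mae <- function(estimates, ages) {
  stopifnot(length(estimates) == length(ages))
  inc <- !is.na(estimates) & !is.na(ages) & ages >= 20 & ages < 90
  n_exc <- sum(!inc)
  est <- estimates[inc]; age <- ages[inc]
  lo <- seq(20, 85, by = 5)
  bin <- findInterval(age, c(lo, 90))
  by_bin <- tibble::tibble(bin_lo = lo, bin_hi = lo + 5,
                           n = vapply(seq_along(lo), function(k) sum(bin == k), 0L),
                           mae = vapply(seq_along(lo), function(k) {
                             if (any(bin == k)) mean(abs(est[bin == k] - age[bin == k]))
                             else NA_real_
                           }, 0))
  maes <- by_bin$mae[!is.na(by_bin$mae)]
  if (length(maes) == 0) {
    stop_somnoage("all age bins are empty", class = "somnoage_eval_error")
  }
  r <- if (length(est) > 1 && sd(est) > 0 && sd(age) > 0) cor(est, age)
       else NA_real_
  structure(list(by_bin = by_bin,
                 mae_mean = mean(maes),
                 mae_sd = if (length(maes) > 1) sd(maes) else 0,
                 mae_sd_pop = sqrt(mean((maes - mean(maes))^2)),
                 pearson_r = r,
                 n_included = length(est), n_excluded = n_exc,
                 n_empty_bins = sum(is.na(by_bin$mae))),
            class = "somnoage_eval")
}

#' @export
print.somnoage_eval <- function(x, ...) {
  cat(sprintf("Stratified MAE: %.2f +/- %.2f years (across %d bins), r = %.3f\n",
              x$mae_mean, x$mae_sd, sum(!is.na(x$by_bin$mae)), x$pearson_r))
  invisible(x)
}

#' Night-to-night repeatability statistics
#'
#' Paired comparison of two nights' estimates: mean and SD of the
#' signed and absolute differences (night 2 minus night 1) and a
#' two-sided one-sample t-test of the signed difference against zero.
#' With zero variance in the differences the p-value is 1 by convention
#' (no evidence of a systematic shift).
#'
#' @param night1,night2 paired estimate vectors (same subjects, same
#'   order).
#' @return one-row tibble: `n`, `mean_diff`, `sd_diff`, `mean_abs_diff`,
#'   `sd_abs_diff`, `p_value`.
#' @export
repeatability <- function(night1, night2) {
  stopifnot(length(night1) == length(night2))
  ok <- !is.na(night1) & !is.na(night2)
  d <- night2[ok] - night1[ok]
  if (length(d) < 2) {
    stop_somnoage("need at least 2 pairs", class = "somnoage_eval_error")
  }
  p <- if (sd(d) == 0) 1 else t.test(d)$p.value
  tibble::tibble(n = length(d), mean_diff = mean(d), sd_diff = sd(d),
                 mean_abs_diff = mean(abs(d)), sd_abs_diff = sd(abs(d)),
                 p_value = p)
}
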