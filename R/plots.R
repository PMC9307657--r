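#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an age-stratification report
#'
#' Per-bin MAE as a bar chart with the across-bin mean as a reference
#' line.
#'
#' @param object a `somnoage_eval` from [stratified_mae()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot somnoage_eval
#' @export
autoplot.somnoage_eval <- function(object, ...) {
  df <- object$by_bin[!is.na(object$by_bin$mae), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_lo + 2.5, y = .data$mae)) +
    ggplot2::geom_col(width = 4.5, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mae_mean, linetype = "dashed") +
    ggplot2::labs(x = "Age (years)", y = "MAE (years)",
                  title = sprintf("Stratified MAE %.2f +/- %.2f years, r = %.2f",
                                  object$mae_mean, object$mae_sd,
                                  object$pearson_r)) +
    ggplot2::theme_minimal()
}

#' Plot an event-locked relevance average
#'
#' Mean relevance around the anchor with a dotted standard-error band.
#'
#' @param object an `event_locked_average`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot event_locked_average
#' @export
autoplot.event_locked_average <- function(object, ...) {
  df <- tibble::tibble(time_s = object$time_s, mean = object$mean,
                       lo = object$mean - object$sem,
                       hi = object$mean + object$sem)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = .data$lo), linetype = "dotted") +
    ggplot2::geom_line(ggplot2::aes(y = .data$hi), linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Time from anchor (s)", y = "Relevance",
                  subtitle = sprintf("n = %d anchors", object$n)) +
    ggplot2::theme_minimal()
}

#' Plot a Cox baseline survival with its Weibull extension
#'
#' @param object a `somnoage_cox`.
#' @param ext optional `weibull_extension`; fitted on the fly when
#'   omitted.
#' @param horizon extrapolation horizon in years.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot somnoage_cox
#' @export
autoplot.somnoage_cox <- function(object, ext = NULL, horizon = NULL, ...) {
  if (is.null(ext)) ext <- fit_weibull_extension(object)
  if (is.null(horizon)) horizon <- 2 * max(object$baseline$time)
  tt <- seq(0, horizon, length.out = 400)
  dfw <- tibble::tibble(time = tt, surv = weibull_survival(ext, tt))
  ggplot2::ggplot() +
    ggplot2::geom_step(data = object$baseline,
                       ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_line(data = dfw,
                       ggplot2::aes(x = .data$time, y = .data$surv),
                       colour = "firebrick", linetype = "dashed") +
    ggplot2::labs(x = "Years", y = "Baseline survival",
                  subtitle = sprintf("Weibull extension: k = %.2f, lambda = %.1f",
                                     ext$shape, ext$scale)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a relevance track
#'
#' Channel-averaged relevance over the epoch.
#'
#' @param object a `relevance_track`.
#' @param fs sampling rate override.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot relevance_track
#' @export
autoplot.relevance_track <- function(object, fs = NULL, ...) {
  fs <- fs %||% (if (is.finite(object$fs)) object$fs else 128)
  v <- channel_average(object)
  df <- tibble::tibble(time_s = (seq_along(v) - 1) / fs, relevance = v)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$relevance)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Relevance (channel mean)") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' @param history tibble with `epoch`, `train_loss`, `val_loss` (as
#'   returned by [train_phase1()] / [train_phase2()]).
#' @return a ggplot.
#' @export
plot_training_history <- function(history) {
  df <- tidyr::pivot_longer(history, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Epoch", y = "Scaled Huber loss", colour = NULL) +
    ggplot2::theme_minimal()
}
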