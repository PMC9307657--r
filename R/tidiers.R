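#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Cox fit
#'
#' One row per coefficient, with hazard ratios and Wald confidence
#' intervals.
#'
#' @param x a `somnoage_cox`.
#' @param ... unused.
#' @return tibble: `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, `hr`, `conf_low`, `conf_high`.
#' @method tidy somnoage_cox
#' @export
tidy.somnoage_cox <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s),
                 estimate = s[, "coef"],
                 std_error = s[, "se(coef)"],
                 statistic = s[, "z"],
                 p_value = s[, "Pr(>|z|)"],
                 hr = exp(s[, "coef"]),
                 conf_low = exp(s[, "coef"] - 1.96 * s[, "se(coef)"]),
                 conf_high = exp(s[, "coef"] + 1.96 * s[, "se(coef)"]))
}

#' @rdname tidy.somnoage_cox
#' @method glance somnoage_cox
#' @export
glance.somnoage_cox <- function(x, ...) {
  f <- x$fit
  tibble::tibble(n = f$n, n_event = f$nevent,
                 model_id = x$model_id, exposure = x$exposure,
                 concordance = unname(f$concordance["concordance"]),
                 logLik = as.numeric(stats::logLik(f)))
}

#' Tidy an age-stratification report
#'
#' @param x a `somnoage_eval` from [stratified_mae()].
#' @param ... unused.
#' @return the per-bin tibble with `bin_lo`, `bin_hi`, `n`, `mae`.
#' @method tidy somnoage_eval
#' @export
tidy.somnoage_eval <- function(x, ...) x$by_bin

#' @rdname tidy.somnoage_eval
#' @method glance somnoage_eval
#' @export
glance.somnoage_eval <- function(x, ...) {
  tibble::tibble(mae_mean = x$mae_mean, mae_sd = x$mae_sd,
                 pearson_r = x$pearson_r, n_included = x$n_included,
                 n_excluded = x$n_excluded, n_empty_bins = x$n_empty_bins)
}

#' Tidy a Weibull extension
#' @param x a `weibull_extension`.
#' @param ... unused.
#' @return one-row tibble: `shape`, `scale`, `n_points`.
#' @method tidy weibull_extension
#' @export
tidy.weibull_extension <- function(x, ...) {
  tibble::tibble(shape = x$shape, scale = x$scale, n_points = x$n_points)
}
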