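#' Age-estimate error and its age-corrected form
#'
#' The age-estimate error is `aee = estimate - age`. Because estimates
#' regress toward the mean, AEE carries a linear age trend; the
#' corrected form `aeec` is the residual of the OLS regression of AEE on
#' an intercept and age, so it is exactly orthogonal to age and has
#' mean zero over the fitted sample.
#'
#' @param data tibble with columns `subject_id`, `estimate`, `age` (and
#'   anything else, carried through).
#' @return the input with `aee` and `aeec` columns added.
#' @export
compute_aee <- function(data) {
  df <- tibble::as_tibble(data)
  stopifnot(all(c("estimate", "age") %in% names(df)))
  df$aee <- df$estimate - df$age
  compute_aeec(df)
}

#' @rdname compute_aee
#' @export
compute_aeec <- function(data) {
  df <- tibble::as_tibble(data)
  stopifnot(all(c("aee", "age") %in% names(df)))
  if (nrow(df) < 3) {
    stop_somnoage("need at least 3 records for the age correction",
                  class = "somnoage_survival_error")
  }
  if (length(unique(df$age)) == 1) {
    df$aeec <- df$aee - mean(df$aee)
    attr(df, "aeec_degenerate") <- TRUE
    return(df)
  }
  fit <- lm(aee ~ age, data = df)
  df$aeec <- unname(residuals(fit))
  df
}

#' Covariate summary by AEEc quartile
#'
#' Splits records at the 25/50/75th percentiles of the age-corrected
#' error and summarizes each covariate per quartile: mean +/- SD for
#' continuous covariates, count (percent) for logical/categorical ones.
#'
#' @param data tibble with an `aeec` column and covariate columns.
#' @param covariates character vector of covariate names.
#' @return long tibble: `quartile`, `covariate`, `level` (categoricals),
#'   `mean`, `sd`, `n`, `pct`.
#' @export
quartile_table <- function(data, covariates) {
  df <- tibble::as_tibble(data)
  stopifnot("aeec" %in% names(df), nrow(df) >= 4)
  cuts <- quantile(df$aeec, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  df$quartile <- findInterval(df$aeec, cuts, left.open = TRUE) + 1L
  rows <- list()
  for (cv in covariates) {
    x <- df[[cv]]
    for (qk in 1:4) {
      xi <- x[df$quartile == qk]
      if (is.numeric(x)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          quartile = qk, covariate = cv, level = NA_character_,
          mean = mean(xi, na.rm = TRUE), sd = sd(xi),
          n = length(xi), pct = NA_real_)
      } else {
        for (lv in unique(as.character(x))) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            quartile = qk, covariate = cv, level = lv,
            mean = NA_real_, sd = NA_real_,
            n = sum(as.character(xi) == lv, na.rm = TRUE),
            pct = 100 * mean(as.character(xi) == lv, na.rm = TRUE))
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Covariate sets of the three Cox specifications
#'
#' Model 1 adjusts for age only; model 2 adds demographic, lifestyle
#' and medication covariates plus cohort; model 3 adds sleep metrics
#' and comorbidities.
#'
#' @param model_id 1, 2 or 3.
#' @param drop_copd omit the COPD term from model 3.
#' @return character vector of covariate names.
#' @export
cox_covariates <- function(model_id, drop_copd = FALSE) {
  m1 <- "age"
  m2 <- c(m1, "sex", "bmi", "race", "smoking", "education", "alcohol",
          "caffeine", "benzodiazepines", "sedatives", "antidepressants",
          "cohort")
  m3 <- c(m2, "waso_min", "n2_pct", "rem_pct", "ari", "ahi", "sao2_below80",
          "ess", "hypertension", "chf", "heart_attack", "stroke", "t2d",
          if (!drop_copd) "copd")
  switch(as.character(model_id), "1" = m1, "2" = m2, "3" = m3,
         stop_somnoage("model_id must be 1, 2 or 3",
                       class = "somnoage_survival_error"))
}

#' Fit a Cox proportional-hazards model of mortality on AEE
#'
#' Partial-likelihood fit with Efron tie handling via the survival
#' package, wrapped with the pieces needed downstream: the exposure
#' coefficient (per year of AEE), the baseline survival evaluated at a
#' reference covariate row (median policy by default, mean by flag),
#' and the data/terms needed for Schoenfeld diagnostics and life
#' expectancy. Only covariates present in `data` are used (missing
#' model-2/3 covariates are dropped with a warning); for
#' cause-specific (cardiovascular) mortality, other deaths are treated
#' as censored.
#'
#' @param data tibble with `time_years`, `event` (0/1), the exposure
#'   column and covariates. CPAP users (column `cpap_user`, if present)
#'   are excluded.
#' @param model_id Cox specification 1, 2 or 3 (see [cox_covariates()]).
#' @param exposure exposure column name, default `"aee"`.
#' @param event_col event indicator column, default `"event"`
#'   (use `"cv_event"` for cardiovascular mortality).
#' @param reference `"median"` or `"mean"`: covariate value at which
#'   the baseline survival is anchored.
#' @param drop_copd passed to [cox_covariates()].
#' @return object of class `somnoage_cox`.
#' @export
fit_cox <- function(data, model_id = 1, exposure = "aee",
                    event_col = "event", reference = c("median", "mean"),
                    drop_copd = FALSE) {
  reference <- match.arg(reference)
  df <- tibble::as_tibble(data)
  if ("cpap_user" %in% names(df) && any(df$cpap_user, na.rm = TRUE)) {
    df <- df[!df$cpap_user %in% TRUE, ]
  }
  stopifnot(all(c("time_years", event_col, exposure) %in% names(df)))
  if (any(df$time_years <= 0)) {
    stop_somnoage("follow-up times must be positive",
                  class = "somnoage_survival_error")
  }
  if (sum(df[[event_col]]) < 1) {
    stop_somnoage("need at least one event", class = "somnoage_survival_error")
  }
  covs <- cox_covariates(model_id, drop_copd)
  missing_covs <- setdiff(covs, names(df))
  if (length(missing_covs)) {
    warning("covariates not in data, dropped: ",
            paste(missing_covs, collapse = ", "), call. = FALSE)
    covs <- intersect(covs, names(df))
  }
  terms <- c(exposure, covs)
  fml <- stats::as.formula(paste0("survival::Surv(time_years, ", event_col,
                                  ") ~ ", paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron", x = TRUE,
                         model = TRUE)
  if (!is.null(fit$info) && isTRUE(fit$info$flag)) {
    warning("possible separation in the Cox fit", call. = FALSE)
  }
  beta <- coef(fit)[exposure]
  se <- sqrt(diag(fit$var))[match(exposure, names(coef(fit)))]
  # reference covariate row: policy value of every numeric term, mode of
  # factors; baseline survival is the curve for this subject
  ref_row <- df[1, terms, drop = FALSE]
  for (v in terms) {
    x <- df[[v]]
    if (is.numeric(x)) {
      ref_row[[v]] <- if (reference == "median") median(x, na.rm = TRUE)
                      else mean(x, na.rm = TRUE)
    } else {
      tb <- table(x)
      ref_row[[v]] <- names(tb)[which.max(tb)]
    }
  }
  sf <- survival::survfit(fit, newdata = as.data.frame(ref_row))
  structure(list(fit = fit, beta_exposure = unname(beta),
                 se_exposure = unname(se), exposure = exposure,
                 model_id = model_id, covariates = covs,
                 reference = reference, ref_row = ref_row,
                 baseline = tibble::tibble(time = sf$time, surv = sf$surv,
                                           n_event = sf$n.event),
                 n = fit$n, n_event = fit$nevent),
            class = "somnoage_cox")
}

#' @export
print.somnoage_cox <- function(x, ...) {
  hr <- hr_per_10(x)
  cat(sprintf(
    "<somnoage_cox model %s: n = %d, events = %d>\nHR per 10-year %s: %.3f (95%% CI %.3f-%.3f)\n",
    x$model_id, x$n, x$n_event, x$exposure, hr$hr, hr$ci_lo, hr$ci_hi))
  invisible(x)
}

#' Hazard ratio per 10-year increment of the exposure
#'
#' `HR = exp(10 beta)`, with the 95% CI from
#' `exp(10 (beta +/- 1.96 se))`.
#'
#' @param fit a `somnoage_cox` (or a list with `beta_exposure`,
#'   `se_exposure`).
#' @param per increment in exposure units (years).
#' @return one-row tibble: `hr`, `ci_lo`, `ci_hi`, `beta`, `se`.
#' @export
hr_per_10 <- function(fit, per = 10) {
  b <- fit$beta_exposure; s <- fit$se_exposure
  tibble::tibble(hr = exp(per * b),
                 ci_lo = exp(per * (b - 1.96 * s)),
                 ci_hi = exp(per * (b + 1.96 * s)),
                 beta = b, se = s)
}

#' Scaled Schoenfeld residuals and proportional-hazards check
#'
#' Per-event scaled Schoenfeld residuals for the exposure with the
#' correlation-with-time test (identity time transform), as used to
#' confirm the proportional-hazards assumption graphically.
#'
#' @param fit a `somnoage_cox`.
#' @return list with `residuals` (tibble: time, residual) and `test`
#'   (tibble: chisq, df, p) for the exposure term.
#' @export
schoenfeld_check <- function(fit) {
  zp <- survival::cox.zph(fit$fit, transform = "identity")
  i <- match(fit$exposure, rownames(zp$table))
  res <- zp$y[, grep(paste0("^", fit$exposure), colnames(zp$y))[1]]
  list(residuals = tibble::tibble(time = zp$time, residual = unname(res)),
       test = tibble::tibble(chisq = zp$table[i, "chisq"],
                             df = zp$table[i, "df"],
                             p = zp$table[i, "p"]))
}

#' Weibull extension of a baseline survival curve
#'
#' Least-squares fit of `log(-log S(t)) = k log t - k log lambda` over
#' the steps of a (Kaplan-Meier-type) baseline survival estimate,
#' yielding the shape `k` and scale `lambda` of the parametric
#' survival `S(t) = exp(-(t/lambda)^k)` used to extrapolate beyond the
#' observed range. Steps at S = 0 or S = 1 are excluded.
#'
#' @param s0 tibble/data frame with columns `time` and `surv`
#'   (nonincreasing step function values after each step), or a
#'   `somnoage_cox` whose baseline is used.
#' @return object of class `weibull_extension`: list with `shape`,
#'   `scale`, `n_points`.
#' @export
fit_weibull_extension <- function(s0) {
  if (inherits(s0, "somnoage_cox")) s0 <- s0$baseline
  s0 <- tibble::as_tibble(s0)
  use <- s0$surv > 0 & s0$surv < 1 & s0$time > 0
  if ("n_event" %in% names(s0)) use <- use & s0$n_event > 0
  pts <- s0[use, ]
  pts <- dplyr::distinct(pts, .data$surv, .keep_all = TRUE)
  if (nrow(pts) < 3) {
    stop_somnoage("need at least 3 usable steps strictly inside (0, 1)",
                  class = "somnoage_survival_error")
  }
  yy <- log(-log(pts$surv))
  xx <- log(pts$time)
  fit <- lm(yy ~ xx)
  k <- unname(coef(fit)[2])
  lam <- exp(-unname(coef(fit)[1]) / k)
  if (!(k > 0) || !(lam > 0)) {
    stop_somnoage("degenerate Weibull fit (k or lambda <= 0)",
                  class = "somnoage_survival_error")
  }
  structure(list(shape = k, scale = lam, n_points = nrow(pts)),
            class = "weibull_extension")
}

#' @export
print.weibull_extension <- function(x, ...) {
  cat(sprintf("<weibull_extension: shape k = %.4f, scale lambda = %.2f>\n",
              x$shape, x$scale))
  invisible(x)
}

#' Survival function of a Weibull extension
#' @param ext a `weibull_extension`.
#' @param t times in years.
#' @param z relative risk score (power on the baseline survival).
#' @return survival probabilities.
#' @export
weibull_survival <- function(ext, t, z = 1) {
  exp(-(t / ext$scale)^ext$shape * z)
}

#' Life expectancy under the extended baseline survival
#'
#' Integrates `S0W(t)^z` over t in (0, Inf) by adaptive quadrature
#' (relative tolerance 1e-6), where `z` is the risk score
#' `exp(beta_AEE * aee + sum beta_j (x_j - x_ref_j))` of a subject with
#' the given AEE and all other covariates at their policy value within
#' `age0 +/- 10` years. The life-expectancy difference contrasts
#' AEE = -10 with AEE = +10.
#'
#' @param fit a `somnoage_cox`.
#' @param ext a `weibull_extension` of its baseline.
#' @param age0 index age (40, 60 or 80).
#' @param aee exposure value, years.
#' @param data the survival data (used to recompute covariate policy
#'   values within the age window); when `NULL` the fit's global
#'   reference row is used.
#' @return life expectancy in years (scalar).
#' @export
life_expectancy <- function(fit, ext, age0 = 60, aee = 0, data = NULL) {
  z <- .risk_score(fit, age0, aee, data)
  if (ext$shape * z <= 0) {
    stop_somnoage("divergent life-expectancy integral",
                  class = "somnoage_survival_error")
  }
  integrate(function(t) weibull_survival(ext, t, z), 0, Inf,
            rel.tol = 1e-6)$value
}

# risk score of the (age0, aee) subject relative to the baseline
# reference row the survival curve was computed for
.risk_score <- function(fit, age0, aee, data = NULL) {
  ref <- fit$ref_row
  new <- ref
  new[[fit$exposure]] <- aee
  if ("age" %in% names(new)) new$age <- age0
  if (!is.null(data)) {
    window <- data[!is.na(data$age) & abs(data$age - age0) <= 10, ]
    for (v in setdiff(names(new), c(fit$exposure, "age"))) {
      if (!v %in% names(window) || nrow(window) == 0) next
      x <- window[[v]]
      if (is.numeric(x)) {
        new[[v]] <- if (fit$reference == "median") median(x, na.rm = TRUE)
                    else mean(x, na.rm = TRUE)
      } else {
        tb <- table(x)
        new[[v]] <- names(tb)[which.max(tb)]
      }
    }
  }
  mm <- rbind(as.data.frame(ref), as.data.frame(new))
  lp <- predict(fit$fit, newdata = mm, type = "lp", reference = "zero")
  exp(lp[2] - lp[1])
}

#' Life-expectancy difference between AEE = -10 and AEE = +10
#'
#' @inheritParams life_expectancy
#' @param aee_lo,aee_hi the contrasted exposure values.
#' @return one-row tibble: `age0`, `le_lo` (life expectancy at
#'   `aee_lo`), `le_hi`, `le_diff = le_lo - le_hi`.
#' @export
le_difference <- function(fit, ext, age0 = 60, data = NULL,
                          aee_lo = -10, aee_hi = 10) {
  lo <- life_expectancy(fit, ext, age0, aee_lo, data)
  hi <- life_expectancy(fit, ext, age0, aee_hi, data)
  tibble::tibble(age0 = age0, le_lo = lo, le_hi = hi, le_diff = lo - hi)
}

#' Simple declared imputation policy for survival covariates
#'
#' Per-cohort median for numeric covariates and mode for categorical
#' ones, with a per-covariate imputation count attached. CPAP users are
#' excluded from the survival sample entirely. Covariates that are
#' entirely missing raise an error.
#'
#' @param data survival tibble (column `cohort` optional).
#' @param covariates columns to impute; default all covariate columns.
#' @return imputed tibble; attribute `"imputed_counts"` maps covariate
#'   to the number of filled values.
#' @export
impute_covariates <- function(data, covariates = NULL) {
  df <- tibble::as_tibble(data)
  if ("cpap_user" %in% names(df)) df <- df[!df$cpap_user %in% TRUE, ]
  if (is.null(covariates)) {
    covariates <- setdiff(names(df), c("subject_id", "time_years", "event",
                                       "cv_event", "cpap_user"))
  }
  if (!"cohort" %in% names(df)) df$cohort <- "default"
  counts <- integer(0)
  for (v in covariates) {
    x <- df[[v]]
    miss <- is.na(x)
    if (all(miss)) {
      stop_somnoage("covariate '", v, "' is entirely missing",
                    class = "somnoage_survival_error")
    }
    if (!any(miss)) { counts[v] <- 0L; next }
    for (ch in unique(df$cohort)) {
      sel <- df$cohort == ch & miss
      pool <- x[df$cohort == ch & !miss]
      if (length(pool) == 0) pool <- x[!miss]
      fill <- if (is.numeric(x)) median(pool) else {
        tb <- table(pool); names(tb)[which.max(tb)]
      }
      x[sel] <- fill
    }
    df[[v]] <- x
    counts[v] <- sum(miss)
  }
  attr(df, "imputed_counts") <- counts
  df
}
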