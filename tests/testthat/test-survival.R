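test_that("AEE and its age correction satisfy the normal equations", {
  df <- tibble::tibble(subject_id = c("a", "b", "c"),
                       estimate = c(65, 50, 45), age = c(60, 55, 40))
  r <- compute_aee(df)
  expect_equal(r$aee, c(5, -5, 5))
  expect_lt(abs(sum(r$aeec)), 1e-9)
  expect_lt(abs(sum(r$aeec * r$age)), 1e-9)
  # AEE exactly linear in age: residuals all zero
  set.seed(61)
  df2 <- tibble::tibble(subject_id = letters[1:10], age = runif(10, 20, 80))
  df2$estimate <- df2$age + (3 - 0.1 * df2$age)
  r2 <- compute_aee(df2)
  expect_lt(max(abs(r2$aeec)), 1e-9)
  # constant age: fall back to mean-centering with a flag
  df3 <- tibble::tibble(subject_id = letters[1:4], estimate = c(1, 2, 3, 4),
                        age = 50)
  r3 <- compute_aee(df3)
  expect_equal(r3$aeec, c(-1.5, -0.5, 0.5, 1.5))
  expect_error(compute_aee(df[1:2, ]), class = "somnoage_survival_error")
})

test_that("quartile table splits at the 25/50/75 percentiles", {
  df <- tibble::tibble(aeec = 1:8, flag = TRUE, bmi = c(20, 22, 24, 26, 28, 30, 32, 34))
  qt <- quartile_table(df, c("bmi", "flag"))
  counts <- qt[qt$covariate == "bmi", ]
  expect_equal(counts$n, rep(2L, 4))
  expect_equal(counts$mean, c(21, 25, 29, 33))
  flag <- qt[qt$covariate == "flag" & qt$level == "TRUE", ]
  expect_true(all(flag$pct == 100))
  # quartile sizes differ by at most 1 on arbitrary data
  set.seed(62)
  dfr <- tibble::tibble(aeec = rnorm(101), z = 1)
  qtr <- quartile_table(dfr, "z")
  expect_lte(diff(range(qtr$n[qtr$covariate == "z"])), 1)
})

test_that("Cox fit matches brute-force Efron partial likelihood", {
  # hand-built 4-subject data, one binary covariate, no ties
  d <- tibble::tibble(time_years = c(2, 4, 6, 8), event = c(1, 1, 0, 1),
                      aee = c(1, 0, 1, 0))
  fit <- suppressWarnings(fit_cox(d, model_id = 1, exposure = "aee"))
  bf <- optimize(function(b) -efron_loglik(b, d$time_years, d$event, d$aee),
                 c(-10, 10), tol = 1e-12)
  expect_equal(fit$beta_exposure, bf$minimum, tolerance = 1e-6)

  # 6 subjects with tied event times exercise the Efron correction
  set.seed(63)
  d2 <- tibble::tibble(time_years = c(1, 1, 3, 3, 5, 7),
                       event = c(1, 1, 1, 0, 1, 0),
                       aee = c(2, -1, 0.5, 1, -2, 0))
  fit2 <- suppressWarnings(fit_cox(d2, model_id = 1, exposure = "aee"))
  bf2 <- optimize(function(b) -efron_loglik(b, d2$time_years, d2$event, d2$aee),
                  c(-10, 10), tol = 1e-12)
  expect_equal(fit2$beta_exposure, bf2$minimum, tolerance = 1e-6)
})

test_that("Cox fit recovers a known hazard slope within 2 SE", {
  set.seed(64)
  truth <- tibble::tibble(subject_id = as.character(1:2000),
                          age = runif(2000, 40, 85),
                          delta = rnorm(2000, 0, 7.5))
  sv <- gen_survival(truth, beta_delta = 0.0255, seed = 65)
  sv$aee <- sv$delta
  fit <- fit_cox(sv, model_id = 1, exposure = "aee")
  expect_lt(abs(fit$beta_exposure - 0.0255), 2 * fit$se_exposure)
  expect_equal(fit$n_event, sum(sv$event))
  # baseline survival is a nonincreasing step function from 1
  expect_true(all(diff(fit$baseline$surv) <= 1e-12))
  expect_lte(max(fit$baseline$surv), 1)
})

test_that("hazard ratio per 10 years follows the closed form", {
  f0 <- list(beta_exposure = 0, se_exposure = 0.01)
  expect_equal(hr_per_10(f0)$hr, 1)
  f <- list(beta_exposure = 0.0255, se_exposure = 0.004)
  h <- hr_per_10(f)
  expect_equal(h$hr, exp(0.255))
  expect_equal(h$ci_lo, exp(0.255 - 1.96 * 0.04))
  expect_equal(h$ci_hi, exp(0.255 + 1.96 * 0.04))
  fm <- list(beta_exposure = -0.0255, se_exposure = 0.004)
  expect_equal(hr_per_10(fm)$hr, 1 / h$hr)
})

test_that("scaled Schoenfeld residuals sum to about zero under PH", {
  set.seed(66)
  truth <- tibble::tibble(subject_id = as.character(1:800),
                          age = runif(800, 40, 85), delta = rnorm(800, 0, 7.5))
  sv <- gen_survival(truth, seed = 67)
  sv$aee <- sv$delta
  fit <- fit_cox(sv, model_id = 1, exposure = "aee")
  sc <- schoenfeld_check(fit)
  expect_equal(nrow(sc$residuals), fit$n_event)
  # unscaled residuals are estimating-equation residuals summing to ~0;
  # the scaled ones stay centered
  expect_lt(abs(mean(sc$residuals$residual)) /
              (sd(sc$residuals$residual) + 1e-12), 0.3)
  expect_gt(sc$test$p, 1e-6)
})

test_that("Weibull extension recovers exact parameters and special cases", {
  tt <- seq(2, 60, by = 2)
  s0 <- tibble::tibble(time = tt, surv = exp(-(tt / 80)^1.5))
  ext <- fit_weibull_extension(s0)
  expect_equal(ext$shape, 1.5, tolerance = 1e-6)
  expect_equal(ext$scale, 80, tolerance = 1e-6)
  # exponential special case k = 1
  s1 <- tibble::tibble(time = tt, surv = exp(-tt / 40))
  e1 <- fit_weibull_extension(s1)
  expect_equal(e1$shape, 1, tolerance = 1e-6)
  expect_equal(e1$scale, 40, tolerance = 1e-6)
  # steps at 0/1 excluded; too few points errors
  s_bad <- tibble::tibble(time = c(1, 2), surv = c(0.8, 0.5))
  expect_error(fit_weibull_extension(s_bad), class = "somnoage_survival_error")
})

test_that("Weibull extension tracks a Kaplan-Meier curve from Weibull data", {
  set.seed(68)
  n <- 5000
  t_raw <- 60 * (-log(runif(n)))^(1 / 1.3)
  obs <- pmin(t_raw, 50)
  ev <- as.integer(t_raw <= 50)
  km <- survival::survfit(survival::Surv(obs, ev) ~ 1)
  ext <- fit_weibull_extension(tibble::tibble(time = km$time, surv = km$surv,
                                              n_event = km$n.event))
  grid <- seq(1, 50, by = 1)
  km_fun <- stats::stepfun(km$time, c(1, km$surv))
  expect_lt(max(abs(weibull_survival(ext, grid) - km_fun(grid))), 0.02)
})

test_that("life expectancy reproduces the exponential closed form", {
  ext <- structure(list(shape = 1, scale = 1 / 0.02, n_points = 10),
                   class = "weibull_extension")
  # risk score 1: LE = 1/rate = 50 years
  fit_stub <- structure(list(beta_exposure = 0.03, se_exposure = 0.005,
                             exposure = "aee",
                             ref_row = tibble::tibble(aee = 0),
                             reference = "median"),
                        class = "somnoage_cox")
  fit_stub$fit <- local({
    d <- tibble::tibble(time_years = rexp(50) + 0.1,
                        event = rbinom(50, 1, 0.5), aee = rnorm(50))
    survival::coxph(survival::Surv(time_years, event) ~ aee, data = d,
                    ties = "efron")
  })
  # with aee equal to the reference, z = 1 exactly
  le0 <- life_expectancy(fit_stub, ext, age0 = 60, aee = 0)
  expect_equal(le0, 50, tolerance = 1e-4)
  # doubling the risk score halves the exponential LE
  b <- coef(fit_stub$fit)[["aee"]]
  aee2 <- log(2) / b
  expect_equal(life_expectancy(fit_stub, ext, 60, aee2), 25, tolerance = 1e-3)
})

test_that("LE decreases in AEE and the difference closes as beta vanishes", {
  set.seed(69)
  truth <- tibble::tibble(subject_id = as.character(1:1500),
                          age = runif(1500, 40, 85),
                          delta = rnorm(1500, 0, 7.5))
  sv <- gen_survival(truth, beta_delta = 0.04, seed = 70)
  sv$aee <- sv$delta
  fit <- fit_cox(sv, model_id = 1, exposure = "aee")
  ext <- fit_weibull_extension(fit)
  les <- vapply(c(-10, 0, 10), function(a)
    life_expectancy(fit, ext, 60, a, data = sv), 0)
  expect_true(all(diff(les) < 0))
  d <- le_difference(fit, ext, 60, data = sv)
  expect_equal(d$le_diff, les[1] - les[3], tolerance = 1e-8)
  expect_gt(d$le_diff, 0)
  # null exposure: difference shrinks toward zero
  sv0 <- gen_survival(truth, beta_delta = 0, seed = 71)
  sv0$aee <- sv0$delta
  fit0 <- fit_cox(sv0, model_id = 1, exposure = "aee")
  ext0 <- fit_weibull_extension(fit0)
  d0 <- le_difference(fit0, ext0, 60, data = sv0)
  expect_lt(abs(d0$le_diff), d$le_diff)
})

test_that("covariate sets of the three model specifications are nested", {
  m1 <- cox_covariates(1); m2 <- cox_covariates(2); m3 <- cox_covariates(3)
  expect_equal(m1, "age")
  expect_true(all(m1 %in% m2) && all(m2 %in% m3))
  expect_true("copd" %in% m3)
  expect_false("copd" %in% cox_covariates(3, drop_copd = TRUE))
  expect_error(cox_covariates(4), class = "somnoage_survival_error")
})

test_that("imputation fills per-cohort medians/modes and drops CPAP users", {
  df <- tibble::tibble(subject_id = as.character(1:6),
                       cohort = c("a", "a", "a", "b", "b", "b"),
                       time_years = 1, event = 0,
                       bmi = c(1, 2, NA, 10, NA, 30),
                       smoke = c("y", NA, "y", "n", "n", NA),
                       cpap_user = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  out <- impute_covariates(df, c("bmi", "smoke"))
  expect_equal(nrow(out), 5)                    # CPAP user removed
  expect_equal(out$bmi[3], 1.5)                 # cohort-a median of 1, 2
  expect_equal(out$smoke[2], "y")   # cohort-a mode
  expect_equal(attr(out, "imputed_counts")[["bmi"]], 2L)
  # no missing data: identity
  out2 <- impute_covariates(out, "bmi")
  expect_identical(out2$bmi, out$bmi)
  dfa <- df; dfa$bmi <- NA_real_
  expect_error(impute_covariates(dfa, "bmi"), class = "somnoage_survival_error")
})

test_that("tidiers expose coefficients and fit summaries", {
  set.seed(72)
  truth <- tibble::tibble(subject_id = as.character(1:500),
                          age = runif(500, 40, 85), delta = rnorm(500, 0, 7.5))
  sv <- gen_survival(truth, seed = 73)
  sv$aee <- sv$delta
  fit <- fit_cox(sv, model_id = 1, exposure = "aee")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "hr", "conf_low") %in% names(td)))
  expect_true("aee" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$n, fit$n)
  ext <- fit_weibull_extension(fit)
  expect_equal(tidy(ext)$shape, ext$shape)
})
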