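test_that("BIC Bayes factor algebra: zero, boundary and error cases", {
  d <- make_field_data(n_id = 10, n_per = 20, seed = 2)
  d$lmedi <- log10(d$melanopic_edi_lx)
  full <- fit_lmm(d, c("lmedi", "age_years"), c("participant_id", "sex"))
  same <- log10_bayes_factor(full, full)
  expect_identical(same$log10_bf, 0)
  expect_identical(same$category, "none")
  expect_identical(same$method, "bic")
  # shifted BIC by exactly 2 ln 10 gives log10 BF exactly 1 -> weaker category
  null <- full
  null$bic <- full$bic + 2 * log(10)
  ev <- log10_bayes_factor(full, null)
  expect_equal(ev$log10_bf, 1, tolerance = 1e-12)
  expect_identical(ev$category, "moderate")
  null$n_obs <- full$n_obs - 1
  expect_error(log10_bayes_factor(full, null), "different observation sets")
})

test_that("evidence categories are total, symmetric and monotone", {
  vals <- c(-5, -2.0001, -1.6, -1.2, -0.8, -0.3, 0, 0.3, 0.8, 1.2, 1.6, 2.5)
  cats <- vapply(vals, bf_category, "")
  expect_identical(cats, c(
    "null-decisive", "null-decisive", "null-very strong", "null-strong",
    "null-moderate", "null-anecdotal", "none", "anecdotal", "moderate",
    "strong", "very strong", "decisive"))
  rank <- c(anecdotal = 1, moderate = 2, strong = 3, "very strong" = 4,
            decisive = 5)
  pos <- vals[vals > 0]
  expect_true(all(diff(rank[cats[vals > 0]]) >= 0))
  # boundaries fall into the weaker category
  expect_identical(bf_category(log10(3)), "anecdotal")
  expect_identical(bf_category(log10(30)), "strong")
  expect_identical(bf_category(2), "very strong")
})

test_that("log10 Bayes factors are additive across model chains", {
  d <- make_field_data(n_id = 12, n_per = 25, seed = 4)
  d$lmedi <- log10(d$melanopic_edi_lx)
  re <- c("participant_id", "sex")
  a <- fit_lmm(d, c("lmedi", "age_years"), re)
  b <- fit_lmm(d, "lmedi", re)
  c_ <- fit_lmm(d, character(0), re)
  expect_equal(log10_bayes_factor(a, c_)$log10_bf,
               log10_bayes_factor(a, b)$log10_bf +
                 log10_bayes_factor(b, c_)$log10_bf,
               tolerance = 1e-10)
})

test_that("mixed-model fits recover generator truth", {
  d <- make_field_data(n_id = 25, n_per = 60, beta_light = -1,
                       beta_age = 0, sigma_u = 0.3, seed = 11)
  d$lmedi <- log10(d$melanopic_edi_lx)
  fit <- fit_lmm(d, c("lmedi", "age_years"), c("participant_id", "sex"))
  co <- fit$coefficients
  sl <- co[co$term == "lmedi", ]
  expect_lt(abs(sl$estimate - (-1)), 3 * sl$se)
  ag <- co[co$term == "age_years", ]
  expect_lt(abs(ag$estimate), 3 * ag$se)  # null predictor stays near zero
  expect_identical(fit$n_obs, nrow(d))
  expect_equal(fit$bic, fit$k_params * log(fit$n_obs) - 2 * fit$loglik)
})

test_that("intercept-only fit matches the closed-form Gaussian likelihood", {
  set.seed(8)
  y <- rnorm(200, 4, 0.7)
  d <- data.frame(pupil_mm = y)
  fit <- fit_lmm(d, character(0), random = NULL)
  s2 <- mean((y - mean(y))^2)  # ML variance
  ll <- -length(y) / 2 * (log(2 * pi * s2) + 1)
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
})

test_that("rank-deficient designs fail naming the collinear terms", {
  d <- make_field_data(n_id = 8, n_per = 10, seed = 3)
  d$lmedi <- log10(d$melanopic_edi_lx)
  d$lmedi_copy <- d$lmedi
  expect_error(
    fit_lmm(d, c("lmedi", "lmedi_copy"), c("participant_id", "sex")),
    "collinear.*lmedi_copy")
  # zero-variance predictors are dropped, not fatal
  d$zilch <- 0
  fit <- fit_lmm(d, c("lmedi", "zilch"), c("participant_id", "sex"))
  expect_identical(fit$dropped_terms, "zilch")
})

test_that("confirmatory tests point the right way on calibrated data", {
  d <- make_field_data(n_id = 25, n_per = 50, beta_light = -0.9,
                       beta_age = -0.02, seed = 21)
  res <- run_confirmatory(d)
  expect_gt(res$CH1$log10_bf, 2)
  expect_identical(res$CH1$category, "decisive")
  expect_gt(res$CH3$log10_bf, 0)
  # no age effect in the generator -> CH3 favours the null
  d0 <- make_field_data(n_id = 25, n_per = 50, beta_age = 0, seed = 22)
  expect_lt(run_confirmatory(d0)$CH3$log10_bf, 0)
  expect_error(run_confirmatory(d0[, setdiff(names(d0), "age_years")]),
               "missing metric columns")
})

test_that("CH2 is indifferent when lux carries the same information", {
  d <- make_field_data(n_id = 15, n_per = 40, seed = 23,
                       lux_from_medi = function(m) 1.8 * m)
  res <- run_confirmatory(d)
  expect_equal(res$CH2$log10_bf, 0, tolerance = 1e-6)
})

test_that("CH2 favours the melanopic metric on dissociated spectra", {
  # lab-style dissociation: lux unrelated to mEDI given the pupil model
  set.seed(24)
  d <- make_field_data(n_id = 20, n_per = 60, seed = 24,
                       lux_from_medi = function(m) {
                         10^runif(length(m), 0, 3)
                       })
  res <- run_confirmatory(d)
  expect_gt(res$CH2$log10_bf, 2)
})

test_that("the transform check detects log-linear light coding", {
  d <- make_field_data(n_id = 15, n_per = 60, medi_range = c(0.5, 5e3),
                       seed = 31)
  expect_gt(transform_check(d)$log10_bf, 0)
  # linear response over a narrow range favours the linear model
  dl <- make_field_data(n_id = 15, n_per = 60, medi_range = c(100, 300),
                        seed = 32)
  dl$pupil_mm <- 6 - 0.004 * dl$melanopic_edi_lx +
    rep(rnorm(15, 0, 0.2), each = 60) + rnorm(nrow(dl), 0, 0.2)
  expect_lt(transform_check(dl)$log10_bf, 0)
})

test_that("exploratory tests favour the null when no effect is simulated", {
  d <- make_field_data(n_id = 30, n_per = 40, sex_diff = 0, iris_diff = 0,
                       seed = 41)
  res <- run_exploratory(d)
  expect_lte(res$EH1$log10_bf, 0)
  expect_lte(res$EH3$log10_bf, 0)
  expect_lte(res$EH4$log10_bf, 0)
  # a zero acute-caffeine column carries no information
  d$acute_caffeine_mgkg <- 0
  expect_lte(run_exploratory(d)$EH4$log10_bf, 0)
  expect_error(run_exploratory(d[, setdiff(names(d), "iris_colour")]),
               "missing covariate")
})

test_that("an iris-colour offset is detected by EH2", {
  d <- make_field_data(n_id = 40, n_per = 40, iris_diff = 0.5, sigma_u = 0.1,
                       seed = 42)
  expect_gt(run_exploratory(d)$EH2$log10_bf, 0)
})

test_that("predictor matrices are antisymmetric with zero diagonal", {
  d <- make_field_data(n_id = 12, n_per = 30, seed = 51)
  d$scone_edi_lx <- d$melanopic_edi_lx * 0.8
  d$rhodopic_edi_lx <- d$melanopic_edi_lx * 1.1
  res <- predictor_comparison(
    d, metrics = c("melanopic_edi_lx", "illuminance_lx", "scone_edi_lx",
                   "rhodopic_edi_lx"))
  m <- res$matrix
  expect_true(all(diag(m) == 0))
  expect_equal(m, -t(m), tolerance = 1e-12)
  expect_error(predictor_comparison(d, metrics = rep("illuminance_lx", 2)),
               "duplicate")
})

test_that("pairwise predictor comparison finds the generating pair", {
  set.seed(52)
  n_id <- 20; n_per <- 50
  d <- make_field_data(n_id = n_id, n_per = n_per, beta_light = 0, seed = 52)
  # pupil driven by two channels; all other metrics fully dissociated
  d$rhodopic_edi_lx <- 10^runif(nrow(d), -0.5, 4)
  d$scone_edi_lx <- 10^runif(nrow(d), -0.5, 4)
  d$illuminance_lx <- 10^runif(nrow(d), -0.5, 4)
  d$pupil_mm <- 6 - 0.6 * log10(d$melanopic_edi_lx) -
    0.4 * log10(d$rhodopic_edi_lx) +
    rep(rnorm(n_id, 0, 0.2), each = n_per) + rnorm(nrow(d), 0, 0.2)
  res <- predictor_comparison(
    d, metrics = c("melanopic_edi_lx", "rhodopic_edi_lx", "scone_edi_lx",
                   "illuminance_lx"),
    pairwise = TRUE)
  expect_identical(res$best, "melanopic_edi_lx+rhodopic_edi_lx")
  expect_equal(nrow(res$models), 6L)  # choose(4, 2)
})

test_that("diagnostics flag misfit, heteroscedasticity and collinearity", {
  d <- make_field_data(n_id = 15, n_per = 60, seed = 61)
  d$lmedi <- log10(d$melanopic_edi_lx)
  re <- c("participant_id", "sex")
  good <- fit_lmm(d, c("lmedi", "age_years"), re)
  dg <- regression_diagnostics(good, d)
  expect_lt(abs(dg$heteroscedasticity), 0.05)
  # fitting the light term on the linear scale leaves structured residuals
  bad <- fit_lmm(d, c("melanopic_edi_lx", "age_years"), re)
  db <- regression_diagnostics(bad, d)
  expect_gt(abs(db$residual_trend), abs(dg$residual_trend))
  d$lmedi_dup <- d$lmedi
  dv <- regression_diagnostics(good, d, fixed = c("lmedi", "lmedi_dup"))
  expect_true(is.infinite(dv$vif[["lmedi_dup"]]) ||
                is.infinite(dv$vif[["lmedi"]]))
  expect_true(dv$collinear)
})

test_that("autocorrelation matches known processes and handles gaps", {
  set.seed(71)
  n <- 2000
  white <- data.frame(participant_id = "w",
                      timestamp_s = seq(0, by = 10, length.out = n),
                      pupil_mm = rnorm(n))
  aw <- autocorrelation(white, max_lag = 3)
  expect_true(all(abs(aw$acf$acf) < 0.08))
  x <- as.numeric(arima.sim(list(ar = 0.8), n))
  ar1 <- data.frame(participant_id = "a",
                    timestamp_s = seq(0, by = 10, length.out = n),
                    pupil_mm = x)
  aa <- autocorrelation(ar1, max_lag = 2)
  # gapless series match the standard sample ACF exactly
  ref <- as.numeric(stats::acf(x, lag.max = 2, plot = FALSE,
                               demean = TRUE)$acf)[2:3]
  expect_equal(aa$acf$acf, ref, tolerance = 1e-10)
  expect_lt(abs(aa$acf$acf[1] - 0.8), 0.1)  # AR(1) closed form
  # gaps: dropping frames must not break the lag alignment
  keep <- sort(sample(n, n - 200))
  ag <- autocorrelation(ar1[keep, ], max_lag = 2)
  expect_lt(abs(ag$acf$acf[1] - 0.8), 0.12)
  const <- data.frame(participant_id = "c",
                      timestamp_s = seq(0, by = 10, length.out = 50),
                      pupil_mm = 5)
  ac <- autocorrelation(const, max_lag = 2)
  expect_identical(ac$undefined, "c")
  expect_true(all(is.nan(ac$acf$acf)))
  expect_error(autocorrelation(const, max_lag = 50), "smaller than")
})
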