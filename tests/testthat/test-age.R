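test_that("cluster assignment uses half-open bins and condition rules", {
  expect_identical(as.character(assign_cluster("field", 10)), "10-100 lx")
  expect_identical(as.character(assign_cluster("field", 1)), "1-10 lx")
  expect_identical(as.character(assign_cluster("field", 999.999)),
                   "100-1000 lx")
  expect_identical(as.character(assign_cluster("field", 1000)), ">1000 lx")
  expect_identical(as.character(assign_cluster("dark", 0.001)), "dark")
  expect_identical(as.character(assign_cluster("dark", 50)), "dark")
  expect_true(is.na(assign_cluster("field", 0.5)))
  expect_true(is.na(assign_cluster("lab", 100)))
  expect_true(is.na(assign_cluster("transition", 100)))
  expect_error(assign_cluster("field", NA), "missing mEDI")
})

test_that("field bins partition the light axis deterministically", {
  set.seed(1)
  medi <- 10^runif(500, 0, 5)
  cl <- assign_cluster(rep("field", 500), medi)
  expect_false(anyNA(cl))
  counts <- table(cut(medi, c(1, 10, 100, 1000, Inf), right = FALSE))
  expect_identical(as.integer(table(cl)[-1]), as.integer(counts))
})

test_that("cluster summaries use type-7 quartiles", {
  obs <- data.frame(
    participant_id = c(rep("A", 5), rep("B", 3)),
    condition = c(rep("field", 5), rep("dark", 3)),
    pupil_mm = c(3, 4, 5, 6, 7, 6.5, 6.5, 6.5),
    melanopic_edi_lx = c(rep(20, 5), rep(0.01, 3))
  )
  cs <- summarize_clusters(obs)
  a <- cs[cs$participant_id == "A", ]
  expect_identical(as.character(a$cluster), "10-100 lx")
  expect_equal(a$median_pupil_mm, 5)
  expect_equal(a$iqr_mm, 2)  # type-7 quartiles of {3,4,5,6,7} are 4 and 6
  b <- cs[cs$participant_id == "B", ]
  expect_identical(as.character(b$cluster), "dark")
  expect_equal(b$median_pupil_mm, 6.5)
  expect_equal(b$iqr_mm, 0)
  expect_identical(nrow(cs), 2L)  # disjoint clusters, one row each
})

test_that("age regression matches the closed-form OLS oracle", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    ages <- data.frame(participant_id = seq_len(n),
                       age_years = runif(n, 18, 87))
    s <- data.frame(participant_id = seq_len(n), cluster = "dark",
                    median_pupil_mm = runif(n, 2, 8))
    fit <- age_regression(s, ages)
    o <- oracle_ols(ages$age_years, s$median_pupil_mm)
    expect_equal(fit$slope, o$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(fit$ci95_slope, o$ci_slope, tolerance = 1e-10)
    expect_equal(fit$ci95_intercept, o$ci_int, tolerance = 1e-10)
    expect_equal(fit$slope_per_decade, 10 * o$slope, tolerance = 1e-10)
  }
})

test_that("noiseless lines are recovered exactly and flagged degenerate", {
  ages <- data.frame(participant_id = 1:5, age_years = c(20, 30, 45, 60, 80))
  s <- data.frame(participant_id = 1:5, cluster = "dark",
                  median_pupil_mm = 8 - 0.04 * ages$age_years)
  fit <- age_regression(s, ages)
  expect_equal(fit$slope, -0.04, tolerance = 1e-12)
  expect_equal(fit$intercept, 8, tolerance = 1e-12)
  expect_true(fit$degenerate)
  expect_equal(diff(fit$ci95_slope), 0)
})

test_that("permuted ages give a null slope and few points error out", {
  set.seed(13)
  ages <- data.frame(participant_id = 1:40, age_years = runif(40, 18, 87))
  pupil <- 8 - 0.04 * ages$age_years + rnorm(40, 0, 0.2)
  s <- data.frame(participant_id = 1:40, cluster = "dark",
                  median_pupil_mm = pupil)
  perm <- ages
  perm$age_years <- sample(perm$age_years)
  fit <- age_regression(s, perm)
  expect_true(fit$ci95_slope[1] < 0 && fit$ci95_slope[2] > 0)
  expect_error(age_regression(s[1:2, ], ages), "at least 3")
})

test_that("per-individual log-linear fits recover the case anchors", {
  for (case in list(list(age = 18, b0 = 6.28, b1 = -0.998),
                    list(age = 87, b0 = 3.83, b1 = -0.463))) {
    obs <- simulate_loglinear_case(case$age, n = 200, sigma = 0,
                                   seed = 100 + case$age)
    fit <- individual_loglinear_fit(obs)
    expect_equal(fit$slope, case$b1, tolerance = 1e-9)
    expect_equal(fit$intercept, case$b0, tolerance = 1e-9)
  }
})

test_that("log-linear fits demand enough data and light span", {
  obs <- simulate_loglinear_case(30, n = 50, medi_range = c(99, 101),
                                 seed = 5)
  expect_error(individual_loglinear_fit(obs), "insufficient light span")
  obs2 <- simulate_loglinear_case(30, n = 5, seed = 6)
  expect_error(individual_loglinear_fit(obs2), ">= 10")
})

test_that("pupil range shrinks with age in the calibrated generator", {
  co <- sample_cohort(25, seed = 31,
                      config = generator_config(sigma_intercept = 0.1))
  cfg <- generator_config(p_low_confidence = 0, p_out_of_range = 0,
                          p_saturated = 0, sigma_intercept = 0.1)
  set.seed(32)
  dark <- simulate_dark(co, config = cfg)
  field <- simulate_field(co, n_per = 80, config = cfg)
  obs <- rbind(dark, field)
  ages <- co[, c("participant_id", "age_years")]
  fit <- pupil_range_regression(obs, ages)
  expect_lt(fit$slope, 0)
  expect_identical(fit$n, 25L)
  # degenerate: identical ranges give a zero slope
  flat <- obs
  flat$pupil_mm <- ifelse(flat$condition == "dark", 7, 3)
  f2 <- pupil_range_regression(flat, ages)
  expect_equal(f2$slope, 0, tolerance = 1e-12)
  expect_error(pupil_range_regression(obs[obs$participant_id == "P001", ],
                                      ages), "at least 3")
})

test_that("the unified pupil formula behaves as published", {
  # monotone in luminance
  d1 <- watson_yellott_pupil(1, 10, 30, 2)
  d2 <- watson_yellott_pupil(10, 10, 30, 2)
  d3 <- watson_yellott_pupil(100, 10, 30, 2)
  expect_true(d1 > d2 && d2 > d3)
  # senile miosis at low light: the 80-year-old pupil is smaller
  expect_lt(watson_yellott_pupil(1, 10, 80, 2),
            watson_yellott_pupil(1, 10, 20, 2))
  # independent hand transcription of the formula at reference points
  hand <- function(L, ddeg, y, eyes) {
    a <- pi * (ddeg / 2)^2
    Feff <- L * a * ifelse(eyes == 2, 1, 0.1)
    q <- (Feff / 846)^0.41
    Dsd <- 7.75 - 5.75 * q / (q + 2)
    Dsd + (y - 28.58) * (0.02132 - 0.009562 * Dsd)
  }
  for (L in c(0.1, 9, 100, 4000)) {
    expect_equal(watson_yellott_pupil(L, 10, 45, 2), hand(L, 10, 45, 2),
                 tolerance = 1e-12)
    expect_equal(watson_yellott_pupil(L, 25, 28.58, 1), hand(L, 25, 28.58, 1),
                 tolerance = 1e-12)
  }
  # at the reference age the correction vanishes
  expect_equal(watson_yellott_pupil(9, 10, 28.58, 2),
               7.75 - 5.75 * ((9 * pi * 25 / 846)^0.41 /
                                ((9 * pi * 25 / 846)^0.41 + 2)),
               tolerance = 1e-12)
  expect_true(all(watson_yellott_pupil(c(0.01, 1e5), 10, 50, 2) > 0 &
                    watson_yellott_pupil(c(0.01, 1e5), 10, 50, 2) < 9))
  expect_error(watson_yellott_pupil(10, 10, 30, 3), "n_eyes")
})

test_that("age-effect magnitude shrinks with light level", {
  # calibrated cluster-mode cohort, large enough to order adjacent slopes
  cfg <- generator_config(mode = "cluster", sigma_intercept = 0.25)
  set.seed(77)
  n <- 250
  ages <- runif(n, 18, 87)
  cohort <- data.frame(participant_id = sprintf("Q%03d", 1:n),
                       age_years = ages,
                       ri = rnorm(n, 0, cfg$sigma_intercept))
  rows <- list()
  for (cl in light_clusters()) {
    medi <- if (cl == "dark") rep(0.01, 40 * n) else {
      lohi <- list("1-10 lx" = c(1, 10), "10-100 lx" = c(10, 100),
                   "100-1000 lx" = c(100, 1000),
                   ">1000 lx" = c(1000, 2e4))[[cl]]
      10^runif(40 * n, log10(lohi[1]), log10(lohi[2]))
    }
    idx <- rep(1:n, each = 40)
    pupil <- true_pupil(ages[idx], medi, "cluster", cfg, cohort$ri[idx],
                        cluster = rep(cl, 40 * n)) +
      rnorm(40 * n, 0, 0.2)
    rows[[cl]] <- data.frame(
      participant_id = cohort$participant_id[idx],
      condition = ifelse(cl == "dark", "dark", "field"),
      pupil_mm = as.numeric(pupil), melanopic_edi_lx = medi)
  }
  obs <- do.call(rbind, rows)
  cs <- summarize_clusters(obs)
  slopes <- vapply(light_clusters(), function(cl) {
    age_regression(cs, cohort, cluster = cl)$slope_per_decade
  }, numeric(1))
  expect_true(all(diff(abs(slopes)) <= 0))
  expect_true(all(slopes < 0))
})
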