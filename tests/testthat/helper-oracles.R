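# Independent oracles and fixture builders shared across test files.
# These deliberately avoid the package's internal code paths.

# plain trapezoid integral of a piecewise-linear density (w, v) over [a, b],
# clamping negatives first and clipping to [a, b]; written segment-by-segment
oracle_trapz <- function(w, v, a, b) {
  v <- pmax(v, 0)
  total <- 0
  interp <- function(x) {
    i <- max(which(w <= x))
    i <- min(i, length(w) - 1)
    v[i] + (v[i + 1] - v[i]) * (x - w[i]) / (w[i + 1] - w[i])
  }
  for (i in seq_len(length(w) - 1)) {
    lo <- max(w[i], a); hi <- min(w[i + 1], b)
    if (hi <= lo) next
    total <- total + (interp(lo) + interp(hi)) / 2 * (hi - lo)
  }
  total
}

# random jagged raw spectrum for conservation tests
random_raw_spectrum <- function(n_pts = NULL, lo = NULL, hi = NULL) {
  if (is.null(n_pts)) n_pts <- sample(10:60, 1)
  if (is.null(lo)) lo <- runif(1, 350, 420)
  if (is.null(hi)) hi <- runif(1, 700, 800)
  w <- sort(runif(n_pts, lo, hi))
  w <- w[c(TRUE, diff(w) > 1e-6)]
  spectrum_raw(w, runif(length(w), 0, 0.05))
}

# brute-force re-implementation of the scree rule for cross-checking
oracle_scree <- function(loss, start = 0.5, step = 0.05, stop = 0.95) {
  cand <- seq(start, stop, by = step)
  counts <- sapply(cand, function(t) sum(loss > t))
  best_t <- NA
  best_drop <- Inf
  for (i in seq_len(length(cand) - 1)) {
    if (cand[i] <= start) next
    drop <- counts[i] - counts[i + 1]
    if (drop < best_drop) {
      best_drop <- drop
      best_t <- cand[i]
    }
  }
  best_t
}

# hand-built field-style observation table with controllable ground truth,
# independent of the package's generator (the LMM tests' oracle data)
make_field_data <- function(n_id = 20, n_per = 40, beta_light = -0.9,
                            beta_age = -0.02, sex_diff = 0, iris_diff = 0,
                            sigma_u = 0.3, sigma = 0.25,
                            medi_range = c(0.5, 2e4), lux_from_medi = NULL,
                            seed = 1) {
  set.seed(seed)
  age <- runif(n_id, 18, 87)
  sex <- rep(c("female", "male"), length.out = n_id)
  iris <- sample(c("blue", "hazel/green", "brown"), n_id, replace = TRUE)
  u <- rnorm(n_id, 0, sigma_u)
  idx <- rep(seq_len(n_id), each = n_per)
  medi <- 10^runif(n_id * n_per, log10(medi_range[1]), log10(medi_range[2]))
  lux <- if (is.null(lux_from_medi)) {
    medi * exp(rnorm(length(medi), 0, 0.03))
  } else {
    lux_from_medi(medi)
  }
  pupil <- 5.5 + beta_light * log10(medi) + beta_age * age[idx] + u[idx] +
    sex_diff * (sex[idx] == "male") + iris_diff * (iris[idx] == "blue") +
    rnorm(length(medi), 0, sigma)
  data.frame(
    participant_id = sprintf("S%02d", idx),
    timestamp_s = rep(seq(0, by = 10, length.out = n_per), n_id),
    condition = "field",
    pupil_mm = pupil,
    confidence = 1,
    saturated = FALSE,
    age_years = age[idx],
    sex = sex[idx],
    iris_colour = iris[idx],
    habitual_caffeine_mgkg = rep(rlnorm(n_id, 1, 0.5), each = n_per),
    acute_caffeine_mgkg = rep(rlnorm(n_id, 0.3, 0.5), each = n_per),
    melanopic_edi_lx = medi,
    illuminance_lx = lux,
    stringsAsFactors = FALSE
  )
}

# closed-form two-parameter OLS with t-based CIs (regression oracle)
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  se_slope <- sqrt(s2 / sxx)
  se_int <- sqrt(s2 * (1 / n + mean(x)^2 / sxx))
  tq <- qt(0.975, n - 2)
  list(intercept = intercept, slope = slope,
       ci_slope = slope + c(-1, 1) * tq * se_slope,
       ci_int = intercept + c(-1, 1) * tq * se_int)
}
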