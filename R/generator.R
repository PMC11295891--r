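#' Generator configuration
#'
#' Parameters of the synthetic-data generator. The pupil model is calibrated
#' to the study's printed regressions: the log-linear per-individual mode
#' interpolates between the young (age 18: 6.28 mm intercept, -0.998 mm per
#' log10-unit mEDI) and old (age 87: 3.83 mm, -0.463 mm) case anchors; the
#' cluster mode uses the per-cluster age regressions (dark 8.13 mm, -0.408 mm
#' per decade, down to 2.57 mm and -0.080 mm per decade above 1000 lx).
#' Noise is heteroscedastic, shrinking with light level; missingness and
#' saturation default to the study's observed rates.
#'
#' @param mode `"loglinear"` (per-individual dose--response) or `"cluster"`
#'   (per-cluster age model).
#' @param sigma_intercept SD of the participant random intercept, mm.
#' @param noise_sigma_lo,noise_sigma_hi Pupil noise SD (mm) at log10 mEDI = 0
#'   and 4; linear in log10 mEDI and clamped between the two.
#' @param p_low_confidence Fraction of frames drawn with detection confidence
#'   below 0.6 (default 0.4337).
#' @param p_out_of_range Fraction of frames with a mis-estimated pupil
#'   outside 1--9 mm (default 0.0016).
#' @param p_saturated Fraction of saturated spectra (default 0.0141).
#' @param floor_lx Light floor before log10 (default 0.01 lx).
#' @param field_lux_range Field illuminance range, lux (log-uniform draw).
#' @param daylight_cct_range CCT range of daylight spectra, K.
#' @param daylight_threshold_lx Above this illuminance all field spectra are
#'   daylight (default 1000 lx).
#' @param led_fwhm_nm FWHM of LED Gaussian primaries, nm (default 25).
#' @param age_range Cohort age range in years (default 18--87, uniform).
#' @param iris_probs Iris-colour probabilities (blue, hazel/green, brown),
#'   renormalized.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(mode = c("loglinear", "cluster"),
                             sigma_intercept = 0.3,
                             noise_sigma_lo = 0.5, noise_sigma_hi = 0.15,
                             p_low_confidence = 0.4337,
                             p_out_of_range = 0.0016,
                             p_saturated = 0.0141,
                             floor_lx = 0.01,
                             field_lux_range = c(0.5, 1e5),
                             daylight_cct_range = c(5000, 7500),
                             daylight_threshold_lx = 1000,
                             led_fwhm_nm = 25,
                             age_range = c(18, 87),
                             iris_probs = c(blue = 0.30, hazel_green = 0.20,
                                            brown = 0.49)) {
  structure(
    list(
      mode = match.arg(mode),
      case_anchors = list(
        young = list(age = 18, b0 = 6.28, b1 = -0.998),
        old = list(age = 87, b0 = 3.83, b1 = -0.463)
      ),
      cluster_params = data.frame(
        cluster = light_clusters(),
        b0 = c(8.13, 6.16, 4.32, 3.55, 2.57),
        b1_per_decade = c(-0.408, -0.374, -0.198, -0.141, -0.080)
      ),
      sigma_intercept = sigma_intercept,
      noise_sigma_lo = noise_sigma_lo, noise_sigma_hi = noise_sigma_hi,
      p_low_confidence = p_low_confidence,
      p_out_of_range = p_out_of_range,
      p_saturated = p_saturated,
      floor_lx = floor_lx,
      field_lux_range = field_lux_range,
      daylight_cct_range = daylight_cct_range,
      daylight_threshold_lx = daylight_threshold_lx,
      led_fwhm_nm = led_fwhm_nm,
      age_range = age_range,
      iris_probs = iris_probs / sum(iris_probs)
    ),
    class = "generator_config"
  )
}

#' Sample a synthetic cohort
#'
#' Ages uniform over the configured range, balanced sexes, iris colour
#' multinomial with the study's frequencies, log-normal habitual and acute
#' caffeine intake (mg per kg body weight, acute zero for half the cohort)
#' and Gaussian participant random intercepts.
#'
#' @param n Number of participants (>= 1).
#' @param seed Optional integer seed for reproducible replay.
#' @param config A [generator_config()].
#' @return Data.frame with `participant_id`, `age_years`, `sex`,
#'   `iris_colour`, `habitual_caffeine_mgkg`, `acute_caffeine_mgkg`,
#'   `random_intercept_mm`.
#' @export
sample_cohort <- function(n, seed = NULL, config = generator_config()) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  age <- runif(n, config$age_range[1], config$age_range[2])
  sex <- sample(rep(c("female", "male"), length.out = n))
  iris <- sample(c("blue", "hazel/green", "brown"), n, replace = TRUE,
                 prob = config$iris_probs)
  data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    age_years = age,
    sex = sex,
    iris_colour = iris,
    habitual_caffeine_mgkg = stats::rlnorm(n, log(2.5), 0.6),
    acute_caffeine_mgkg = ifelse(runif(n) < 0.5, 0,
                                 stats::rlnorm(n, log(1.5), 0.6)),
    random_intercept_mm = rnorm(n, 0, config$sigma_intercept),
    stringsAsFactors = FALSE
  )
}

# --- illuminant spectra ---------------------------------------------------

gaussian_line <- function(peak_nm, fwhm_nm) {
  s <- fwhm_nm / (2 * sqrt(2 * log(2)))
  exp(-(.pf_grid - peak_nm)^2 / (2 * s^2))
}

# daylight proxy: Planckian radiator at a mired-compressed effective
# temperature; the 0.7 compression reproduces published daylight-series
# melanopic DER values (~0.91 at 5000 K, ~1.04 at 7500 K) that a raw
# blackbody overstates
daylight_effective_cct <- function(cct_k, compression = 0.7) {
  1 / (1 / 6504 + compression * (1 / cct_k - 1 / 6504))
}

# unscaled spectral shapes for one illuminant family
illuminant_shape <- function(family, cct_k = 6500, colour = "white",
                             led_fwhm_nm = 25, daylight_correction = FALSE) {
  switch(
    family,
    blackbody = planck_spectrum(
      if (daylight_correction) daylight_effective_cct(cct_k) else cct_k),
    led_rgbw = 0.9 * gaussian_line(450, 20) + 1.5 * gaussian_line(560, 110) +
      0.25 * gaussian_line(467, led_fwhm_nm) +
      0.25 * gaussian_line(527, led_fwhm_nm) +
      0.25 * gaussian_line(630, led_fwhm_nm),
    fluorescent = 0.4 * gaussian_line(436, 12) + gaussian_line(546, 15) +
      0.9 * gaussian_line(611, 12) + 0.15 * gaussian_line(405, 10) +
      0.2 * gaussian_line(578, 12),
    lab_primary = switch(
      colour,
      red = gaussian_line(630, led_fwhm_nm),
      green = gaussian_line(527, led_fwhm_nm),
      blue = gaussian_line(467, led_fwhm_nm),
      white = gaussian_line(467, led_fwhm_nm) +
        1.1 * gaussian_line(527, led_fwhm_nm) +
        1.2 * gaussian_line(630, led_fwhm_nm),
      stop("unknown lab primary colour: ", colour, call. = FALSE)
    ),
    stop("unknown illuminant family: ", family, call. = FALSE)
  )
}

#' Generate an illuminant spectrum at a target illuminance
#'
#' Physically generated spectral power distributions: Planckian blackbody
#' (optionally with the daylight correction, see the methods vignette), an
#' RGBW LED (Gaussian primaries at 467/527/630 nm plus a two-Gaussian
#' phosphor white), a fluorescent line comb, or one of the laboratory panel
#' primaries (red/green/blue/white). The output is rescaled so its photopic
#' illuminance equals `target_illuminance_lx` exactly.
#'
#' @param family One of `"blackbody"`, `"led_rgbw"`, `"fluorescent"`,
#'   `"lab_primary"`.
#' @param target_illuminance_lx Target illuminance in lux (> 0).
#' @param cct_k Colour temperature for the blackbody family, K.
#' @param colour Lab-primary colour (`"red"`, `"green"`, `"blue"`,
#'   `"white"`).
#' @param daylight_correction Apply the daylight mired compression to the
#'   blackbody family.
#' @param config A [generator_config()] (LED width).
#' @return A [spectrum_regular] object with
#'   `illuminance(x) == target_illuminance_lx` to machine precision.
#' @export
illuminant_spectrum <- function(family, target_illuminance_lx, cct_k = 6500,
                                colour = "white", daylight_correction = FALSE,
                                config = generator_config()) {
  stopifnot(target_illuminance_lx >= 0)
  shape <- illuminant_shape(family, cct_k, colour, config$led_fwhm_nm,
                            daylight_correction)
  illum <- illuminance(new_spectrum_regular(shape))
  if (illum <= 0) {
    stop("unreachable target: illuminant has zero luminous content",
         call. = FALSE)
  }
  new_spectrum_regular(shape * (target_illuminance_lx / illum))
}

# metric table for a batch of illuminant draws, scaled to target lux.
# families/cct/colour are per-row vectors; daylight rows use the corrected
# blackbody. Returns photometrics_table() columns.
batch_metrics <- function(lux, family, cct_k, colour = NULL,
                          config = generator_config(),
                          daylight_correction = TRUE) {
  n <- length(lux)
  out <- NULL
  tab <- action_tables()
  # blackbody/daylight rows need per-row spectra; template families reuse one
  bb <- family == "blackbody"
  if (any(bb)) {
    te <- if (daylight_correction) daylight_effective_cct(cct_k[bb])
          else cct_k[bb]
    h <- 6.62607015e-34; cc <- 2.99792458e8; kb <- 1.380649e-23
    lm <- .pf_grid * 1e-9
    m <- exp(outer(1 / te, h * cc / (lm * kb))) - 1
    m <- sweep(1 / m, 2, lm^-5, "*")
    met <- photometrics_table(m)
    out <- scale_metrics(met, lux[bb])
    out$row <- which(bb)
  }
  for (fam in setdiff(unique(family), "blackbody")) {
    rows <- which(family == fam)
    cols <- if (fam == "lab_primary") unique(colour[rows]) else "white"
    for (col in cols) {
      r <- if (fam == "lab_primary") rows[colour[rows] == col] else rows
      shape <- illuminant_shape(fam, colour = col,
                                led_fwhm_nm = config$led_fwhm_nm)
      met1 <- photometrics_table(matrix(shape, nrow = 1))
      met <- met1[rep(1, length(r)), , drop = FALSE]
      met <- scale_metrics(met, lux[r])
      met$row <- r
      out <- if (is.null(out)) met else rbind(out, met)
    }
  }
  out <- out[order(out$row), , drop = FALSE]
  out$row <- NULL
  rownames(out) <- NULL
  out
}

# rescale all linear metric columns so illuminance equals target lux
scale_metrics <- function(met, lux) {
  fac <- lux / met$illuminance_lx
  lin <- setdiff(names(met), "mel_der")
  met[lin] <- met[lin] * fac
  met
}

#' Ground-truth pupil diameter of the generator model
#'
#' The noiseless pupil model: in log-linear mode, intercept and slope
#' linearly interpolate in age between the young and old case anchors and the
#' diameter is `b0(age) + b1(age) * log10(max(mEDI, floor)) + intercept`; in
#' cluster mode the diameter is the cluster's `b0 + b1 * age + intercept`.
#' Results are clipped to the physiological 1--9 mm range (clipping is
#' counted in the `n_clipped` attribute).
#'
#' @param age_years Participant age(s).
#' @param medi_lx Melanopic EDI in lux (>= 0).
#' @param mode `"loglinear"` or `"cluster"`.
#' @param config A [generator_config()].
#' @param random_intercept_mm Participant intercept offset(s), mm.
#' @param cluster Cluster labels (required in cluster mode; field samples
#'   below 1 lx use the 1--10 lx parameters).
#' @return Numeric pupil diameter(s), mm.
#' @export
true_pupil <- function(age_years, medi_lx, mode = c("loglinear", "cluster"),
                       config = generator_config(),
                       random_intercept_mm = 0, cluster = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(medi_lx >= 0))
  if (mode == "loglinear") {
    a <- config$case_anchors
    w <- (age_years - a$young$age) / (a$old$age - a$young$age)
    b0 <- a$young$b0 + w * (a$old$b0 - a$young$b0)
    b1 <- a$young$b1 + w * (a$old$b1 - a$young$b1)
    d <- b0 + b1 * log10(pmax(medi_lx, config$floor_lx)) + random_intercept_mm
  } else {
    if (is.null(cluster)) stop("cluster mode needs `cluster`", call. = FALSE)
    cp <- config$cluster_params
    idx <- match(as.character(cluster), cp$cluster)
    if (anyNA(idx)) stop("unknown cluster label", call. = FALSE)
    d <- cp$b0[idx] + cp$b1_per_decade[idx] / 10 * age_years +
      random_intercept_mm
  }
  clipped <- d < 1 | d > 9
  structure(pmin(pmax(d, 1), 9), n_clipped = sum(clipped))
}

# heteroscedastic pupil noise SD as a function of mEDI
noise_sigma <- function(medi_lx, config) {
  lg <- log10(pmax(medi_lx, config$floor_lx))
  s <- config$noise_sigma_lo +
    (config$noise_sigma_hi - config$noise_sigma_lo) * lg / 4
  pmin(pmax(s, min(config$noise_sigma_lo, config$noise_sigma_hi)),
       max(config$noise_sigma_lo, config$noise_sigma_hi))
}

# field cluster used by the cluster-mode pupil model: sub-1 lx field frames
# borrow the 1-10 lx parameters (they are excluded from cluster analyses)
field_model_cluster <- function(medi_lx) {
  brk <- c(-Inf, 10, 100, 1000, Inf)
  light_clusters()[-1][findInterval(medi_lx, brk, left.open = FALSE)]
}

# shared frame-level QC field simulation: confidence, missing pupils,
# out-of-range injections, saturation flags
apply_frame_artifacts <- function(df, config) {
  n <- nrow(df)
  low <- runif(n) < config$p_low_confidence
  df$confidence <- ifelse(low, runif(n, 0, 0.6), runif(n, 0.6, 1))
  df$pupil_mm[low & runif(n) < 0.1] <- NA  # undetected pupils
  oor <- runif(n) < config$p_out_of_range
  if (any(oor)) {
    hi <- runif(sum(oor)) < 0.5
    df$pupil_mm[oor] <- ifelse(hi, runif(sum(oor), 9.05, 12),
                               runif(sum(oor), 0.2, 0.95))
  }
  df$saturated <- runif(n) < config$p_saturated
  df
}

participant_frame <- function(cohort, n_each, timestamps, condition) {
  idx <- rep(seq_len(nrow(cohort)), each = n_each)
  data.frame(
    participant_id = cohort$participant_id[idx],
    timestamp_s = rep(timestamps, nrow(cohort)),
    condition = condition,
    age_years = cohort$age_years[idx],
    sex = cohort$sex[idx],
    iris_colour = cohort$iris_colour[idx],
    habitual_caffeine_mgkg = cohort$habitual_caffeine_mgkg[idx],
    acute_caffeine_mgkg = cohort$acute_caffeine_mgkg[idx],
    .ri = cohort$random_intercept_mm[idx],
    stringsAsFactors = FALSE
  )
}

finalize_obs <- function(df, met, config, mode) {
  df <- cbind(df, met)
  medi <- df$melanopic_edi_lx
  cl <- if (config$mode == "cluster" || mode == "cluster") {
    ifelse(df$condition == "dark", "dark", field_model_cluster(medi))
  } else NULL
  d0 <- true_pupil(df$age_years, medi, mode, config, df$.ri, cl)
  df$pupil_mm <- pmin(pmax(d0 + rnorm(nrow(df), 0, noise_sigma(medi, config)),
                           1), 9)
  df <- apply_frame_artifacts(df, config)
  df$.ri <- NULL
  df
}

#' Simulate field-condition observations
#'
#' Per sample: illuminance log-uniform over the configured range; daylight
#' (corrected blackbody, CCT uniform over the configured range) above the
#' daylight threshold, a mixture of LED, fluorescent and daylight sources
#' below; all light metrics computed from the generated spectrum; pupil from
#' the ground-truth model plus heteroscedastic Gaussian noise; confidence,
#' missingness, out-of-range and saturation artifacts at the configured
#' rates; 10 s timestamps.
#'
#' @param cohort A [sample_cohort()] table.
#' @param n_per Observations per participant.
#' @param config A [generator_config()].
#' @param seed Optional integer seed.
#' @return Observation data.frame (one row per 10 s frame) with participant
#'   covariates, QC fields and all light-metric columns; the cohort table is
#'   attached as attribute `truth`.
#' @export
simulate_field <- function(cohort, n_per = 100, config = generator_config(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_per >= 1)
  df <- participant_frame(cohort, n_per, seq(0, by = 10,
                                             length.out = n_per), "field")
  n <- nrow(df)
  lr <- log10(config$field_lux_range)
  lux <- 10^runif(n, lr[1], lr[2])
  cct <- runif(n, config$daylight_cct_range[1], config$daylight_cct_range[2])
  fam <- ifelse(lux >= config$daylight_threshold_lx, "blackbody",
                sample(c("blackbody", "led_rgbw", "fluorescent"), n,
                       replace = TRUE))
  met <- batch_metrics(lux, fam, cct, config = config,
                       daylight_correction = TRUE)
  out <- finalize_obs(df, met, config, config$mode)
  attr(out, "truth") <- cohort
  out
}

#' Simulate the laboratory light protocol
#'
#' Four spectrally distinct 3 min phases (red, blue, green, white panel
#' primaries) in seeded random order per participant, each phase preceded by
#' a 20 s dark interval (and one after the last), with three ascending 1 min
#' levels per phase: 10 lx, 100 lx and the colour maximum (red 480 lx, blue
#' 250 lx, green and white 1000 lx). The light programme spans 13 min 40 s
#' (82 frames at 10 s). Pupils follow the log-linear model on the resulting
#' mEDI.
#'
#' @inheritParams simulate_field
#' @return Observation data.frame, condition `"lab"`.
#' @export
simulate_lab <- function(cohort, config = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  maxima <- c(red = 480, blue = 250, green = 1000, white = 1000)
  per <- lapply(seq_len(nrow(cohort)), function(i) {
    phases <- sample(names(maxima))
    colour <- character(0); lux <- numeric(0)
    for (ph in phases) {
      colour <- c(colour, rep("dark", 2),
                  rep(ph, 18))
      lux <- c(lux, runif(2, 0.02, 0.19),
               rep(c(10, 100, maxima[[ph]]), each = 6))
    }
    colour <- c(colour, rep("dark", 2))
    lux <- c(lux, runif(2, 0.02, 0.19))
    data.frame(colour = colour, lux = lux)
  })
  sched <- do.call(rbind, per)
  n_each <- 82L
  df <- participant_frame(cohort, n_each,
                          seq(0, by = 10, length.out = n_each), "lab")
  fam <- ifelse(sched$colour == "dark", "blackbody", "lab_primary")
  met <- batch_metrics(sched$lux, fam, rep(2700, nrow(sched)),
                       colour = sched$colour, config = config,
                       daylight_correction = FALSE)
  out <- finalize_obs(df, met, config, "loglinear")
  attr(out, "truth") <- cohort
  out
}

#' Simulate the dark-adaptation condition
#'
#' Near-dark frames (illuminance below 0.2 lx, dim thermal spectra) at 10 s
#' cadence; pupils follow the dark-cluster age model plus noise.
#'
#' @inheritParams simulate_field
#' @param duration_s Duration in seconds (default 600 = 10 min).
#' @return Observation data.frame, condition `"dark"`.
#' @export
simulate_dark <- function(cohort, duration_s = 600,
                          config = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_each <- as.integer(duration_s / 10)
  df <- participant_frame(cohort, n_each,
                          seq(0, by = 10, length.out = n_each), "dark")
  n <- nrow(df)
  lux <- runif(n, 0.005, 0.19)
  met <- batch_metrics(lux, rep("blackbody", n), rep(2700, n),
                       config = config, daylight_correction = FALSE)
  out <- finalize_obs(df, met, config, "cluster")
  attr(out, "truth") <- cohort
  out
}

#' Simulate a single log-linear dose--response case
#'
#' Clean per-individual data in the style of the study's case regressions:
#' mEDI drawn log-uniform over `medi_range`, pupil from the log-linear
#' ground-truth model at the given age plus homoscedastic Gaussian noise.
#' No missingness or saturation (the case regressions describe QC-passed
#' data).
#'
#' @param age_years Participant age.
#' @param n Number of samples.
#' @param medi_range mEDI range in lux (log-uniform; default 0.1--10000).
#' @param sigma Noise SD in mm (default 0.3).
#' @param random_intercept_mm Participant intercept offset (default 0).
#' @param config A [generator_config()].
#' @param seed Optional integer seed.
#' @return Observation data.frame with `melanopic_edi_lx` and `pupil_mm`.
#' @export
simulate_loglinear_case <- function(age_years, n = 400,
                                    medi_range = c(0.1, 1e4), sigma = 0.3,
                                    random_intercept_mm = 0,
                                    config = generator_config(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  medi <- 10^runif(n, log10(medi_range[1]), log10(medi_range[2]))
  pupil <- true_pupil(age_years, medi, "loglinear", config,
                      random_intercept_mm) + rnorm(n, 0, sigma)
  data.frame(
    participant_id = "case",
    timestamp_s = seq(0, by = 10, length.out = n),
    condition = "field",
    age_years = age_years,
    pupil_mm = as.numeric(pmin(pmax(pupil, 1), 9)),
    confidence = 1,
    saturated = FALSE,
    melanopic_edi_lx = medi,
    stringsAsFactors = FALSE
  )
}

#' Simulate a full session (dark + lab + field) for a cohort
#'
#' Convenience wrapper concatenating [simulate_dark()], [simulate_lab()] and
#' [simulate_field()] with consecutive timestamps.
#'
#' @inheritParams simulate_field
#' @param n_field Field observations per participant.
#' @return Observation data.frame with attribute `truth`.
#' @export
simulate_session <- function(cohort, n_field = 100,
                             config = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dark <- simulate_dark(cohort, config = config)
  lab <- simulate_lab(cohort, config = config)
  field <- simulate_field(cohort, n_per = n_field, config = config)
  lab$timestamp_s <- lab$timestamp_s + max(dark$timestamp_s) + 10
  field$timestamp_s <- field$timestamp_s + max(lab$timestamp_s) + 10
  out <- rbind(dark, lab, field)
  out <- out[order(out$participant_id, out$timestamp_s), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truth") <- cohort
  out
}
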