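#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' Fits `response ~ fixed_1 + ... + (1|g_1) + ...` with [lme4::lmer()] under
#' ML (`REML = FALSE`), as required for information-criterion model
#' comparison. Variance components are allowed to hit the zero boundary; such
#' singular fits are flagged, not fatal. With no grouping factors an ordinary
#' Gaussian linear model is fitted (ML log-likelihood).
#'
#' @param data Observation data.frame.
#' @param fixed Character vector of fixed-effect column names (may be empty
#'   for an intercept-only model).
#' @param random Character vector of grouping-factor column names for random
#'   intercepts (e.g. `c("participant_id", "sex")`), or `NULL`.
#' @param response Response column (default `"pupil_mm"`).
#' @return An object of class `"pupil_fit"`: `formula`, `loglik` (ML),
#'   `n_obs`, `k_params` (fixed coefficients + variance components +
#'   residual), `bic` (`k log(n) - 2 loglik`), `coefficients` (estimate, SE,
#'   t), `singular`, and the underlying `model`.
#' @export
fit_lmm <- function(data, fixed, random = NULL, response = "pupil_mm") {
  stopifnot(is.data.frame(data))
  cols <- c(response, fixed, random)
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    stop("missing model columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data <- data[stats::complete.cases(data[, cols, drop = FALSE]), ,
               drop = FALSE]
  if (anyDuplicated(fixed)) stop("duplicate fixed terms", call. = FALSE)
  # a zero-variance predictor carries no information (it is confounded with
  # the intercept); drop it rather than fail, and record the drop
  dropped <- character(0)
  for (f in fixed) {
    if (is.numeric(data[[f]]) && stats::var(data[[f]]) == 0) {
      dropped <- c(dropped, f)
    }
  }
  fixed <- setdiff(fixed, dropped)
  # rank check of the fixed design, naming the collinear terms
  fixed_rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  mm <- stats::model.matrix(stats::as.formula(paste("~", fixed_rhs)), data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient fixed design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (g in random) {
    if (length(unique(data[[g]])) < 2L) {
      stop("grouping factor '", g, "' needs >= 2 levels", call. = FALSE)
    }
  }
  fml_txt <- paste(
    response, "~", fixed_rhs,
    if (length(random)) {
      paste("+", paste(sprintf("(1 | %s)", random), collapse = " + "))
    } else ""
  )
  fml <- stats::as.formula(fml_txt)
  if (length(random)) {
    model <- suppressWarnings(suppressMessages(
      lme4::lmer(fml, data = data, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))
    ))
    ll <- stats::logLik(model)
    co <- summary(model)$coefficients
    singular <- lme4::isSingular(model)
  } else {
    model <- stats::lm(fml, data = data)
    ll <- stats::logLik(model)  # ML Gaussian log-likelihood
    co <- summary(model)$coefficients[, 1:3, drop = FALSE]
    singular <- FALSE
  }
  k <- attr(ll, "df")
  n <- nrow(data)
  structure(
    list(
      formula = trimws(fml_txt),
      loglik = as.numeric(ll),
      n_obs = n,
      k_params = k,
      bic = k * log(n) - 2 * as.numeric(ll),
      coefficients = data.frame(
        term = rownames(co), estimate = co[, 1], se = co[, 2],
        statistic = co[, 3], row.names = NULL
      ),
      singular = singular,
      dropped_terms = dropped,
      model = model
    ),
    class = "pupil_fit"
  )
}

#' @export
print.pupil_fit <- function(x, ...) {
  cat("<pupil_fit> ", x$formula, "\n  n = ", x$n_obs, ", k = ", x$k_params,
      ", logLik = ", format(x$loglik, digits = 8),
      ", BIC = ", format(x$bic, digits = 8),
      if (x$singular) " [singular variance component]" else "", "\n", sep = "")
  invisible(x)
}

#' BIC-approximated log10 Bayes factor between two fitted models
#'
#' Approximates the Bayes factor of the full against the null model from the
#' BIC difference: `log10(BF10) ~ (BIC_null - BIC_full) / (2 ln 10)`.
#' Positive values favour the full model, negative the null. The comparison
#' is model-agnostic and applies to non-nested pairs as well. The verbal
#' evidence category follows standard Bayes-factor categorizations, assigned
#' symmetrically from `|log10 BF|` with boundary values falling into the
#' weaker category (e.g. BF exactly 10 is "moderate").
#'
#' @param full,null [fit_lmm()] results on the same observation set.
#' @param comparison Name recorded on the result.
#' @return An object of class `"evidence_result"`: `comparison`, `log10_bf`,
#'   `category`, `method` (`"bic"`), `n_obs`, `formula_full`, `formula_null`.
#' @export
log10_bayes_factor <- function(full, null, comparison = "full vs null") {
  stopifnot(inherits(full, "pupil_fit"), inherits(null, "pupil_fit"))
  if (full$n_obs != null$n_obs) {
    stop("models fitted on different observation sets (n = ", full$n_obs,
         " vs ", null$n_obs, ")", call. = FALSE)
  }
  lbf <- (null$bic - full$bic) / (2 * log(10))
  structure(
    list(
      comparison = comparison,
      log10_bf = lbf,
      category = bf_category(lbf),
      method = "bic",
      n_obs = full$n_obs,
      formula_full = full$formula,
      formula_null = null$formula
    ),
    class = "evidence_result"
  )
}

#' Verbal evidence category for a log10 Bayes factor
#'
#' Categories: anecdotal (0 < |log10 BF| <= log10(3)), moderate (<= 1),
#' strong (<= log10(30)), very strong (<= 2), decisive (> 2); `"none"` at
#' exactly 0. Negative values favour the null and get a `"null-"` prefix.
#' The function is total over the reals and monotone in `|log10_bf|`.
#'
#' @param log10_bf Numeric log10 Bayes factor.
#' @return Character category.
#' @export
bf_category <- function(log10_bf) {
  stopifnot(is.finite(log10_bf))
  m <- abs(log10_bf)
  base <- if (m > 2) "decisive"
    else if (m > log10(30)) "very strong"
    else if (m > 1) "strong"
    else if (m > log10(3)) "moderate"
    else if (m > 0) "anecdotal"
    else return("none")
  if (log10_bf < 0) paste0("null-", base) else base
}

#' @export
print.evidence_result <- function(x, ...) {
  cat("<evidence_result> ", x$comparison, ": log10(BF10) = ",
      format(x$log10_bf, digits = 4), " [", x$category, ", ", x$method,
      " approximation, n = ", x$n_obs, "]\n", sep = "")
  invisible(x)
}

# add floored log10 light columns in place
add_log_light <- function(data, metrics, floor_lx = 0.01) {
  for (m in metrics) {
    data[[paste0("log_", m)]] <- log10(pmax(data[[m]], floor_lx))
  }
  data
}

#' Confirmatory hypothesis tests (CH1--CH3)
#'
#' Runs the three registered model comparisons on field-condition
#' observations, each scored by [log10_bayes_factor()]:
#' \describe{
#'   \item{CH1 (light level)}{pupil ~ mel + age + (1|id) + (1|sex) against the
#'     model without the melanopic light term.}
#'   \item{CH2 (melanopic vs photopic)}{the same full model against one with
#'     photopic illuminance in place of the melanopic metric (non-nested).}
#'   \item{CH3 (age)}{the full model against the model without age.}
#' }
#' Light terms enter log10-transformed (floored at `floor_lx`) or linear,
#' per `light_transform`.
#'
#' @param data QC-passed observation table with `pupil_mm`, `age_years`,
#'   `participant_id`, `sex`, `melanopic_edi_lx`, `illuminance_lx` and
#'   `condition`.
#' @param light_transform `"log10"` (default) or `"linear"`.
#' @param floor_lx Floor applied before log10 (default 0.01 lx).
#' @param condition Condition subset to analyse (default `"field"`).
#' @return Named list of [log10_bayes_factor()] results (`CH1`, `CH2`,
#'   `CH3`).
#' @export
run_confirmatory <- function(data, light_transform = c("log10", "linear"),
                             floor_lx = 0.01, condition = "field") {
  light_transform <- match.arg(light_transform)
  need <- c("melanopic_edi_lx", "illuminance_lx", "age_years")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing metric columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- data[data$condition %in% condition, , drop = FALSE]
  d <- add_log_light(d, c("melanopic_edi_lx", "illuminance_lx"), floor_lx)
  mel <- if (light_transform == "log10") "log_melanopic_edi_lx"
         else "melanopic_edi_lx"
  phot <- if (light_transform == "log10") "log_illuminance_lx"
          else "illuminance_lx"
  re <- c("participant_id", "sex")
  full <- fit_lmm(d, c(mel, "age_years"), re)
  list(
    CH1 = log10_bayes_factor(full, fit_lmm(d, "age_years", re),
                             "CH1: light level"),
    CH2 = log10_bayes_factor(full, fit_lmm(d, c(phot, "age_years"), re),
                             "CH2: melanopic vs photopic"),
    CH3 = log10_bayes_factor(full, fit_lmm(d, mel, re), "CH3: age")
  )
}

#' Log10-transform model check for the light term
#'
#' Compares the CH1 full model with log10-transformed melanopic light against
#' the identical model with linear light (non-nested; BIC difference).
#' Positive log10 BF favours the log-transformed model.
#'
#' @inheritParams run_confirmatory
#' @return An [log10_bayes_factor()] result.
#' @export
transform_check <- function(data, floor_lx = 0.01, condition = "field") {
  d <- data[data$condition %in% condition, , drop = FALSE]
  d <- add_log_light(d, "melanopic_edi_lx", floor_lx)
  re <- c("participant_id", "sex")
  log_fit <- fit_lmm(d, c("log_melanopic_edi_lx", "age_years"), re)
  lin_fit <- fit_lmm(d, c("melanopic_edi_lx", "age_years"), re)
  log10_bayes_factor(log_fit, lin_fit, "transform check: log10 vs linear")
}

#' Exploratory hypothesis tests (EH1--EH4)
#'
#' Covariate checks on the field data, all against the base model
#' `pupil ~ log10 mEDI + age + (1|id) (+ (1|sex))`:
#' EH1 tests the sex random intercept (present vs absent), EH2 adds an iris
#' colour random intercept, EH3/EH4 add habitual/acute caffeine (mg per kg
#' body weight) as a fixed term.
#'
#' @inheritParams run_confirmatory
#' @return Named list of [log10_bayes_factor()] results (`EH1`--`EH4`).
#' @export
run_exploratory <- function(data, floor_lx = 0.01, condition = "field") {
  need <- c("sex", "iris_colour", "habitual_caffeine_mgkg",
            "acute_caffeine_mgkg")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing covariate columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- data[data$condition %in% condition, , drop = FALSE]
  d <- add_log_light(d, "melanopic_edi_lx", floor_lx)
  fx <- c("log_melanopic_edi_lx", "age_years")
  base_sex <- fit_lmm(d, fx, c("participant_id", "sex"))
  base_id <- fit_lmm(d, fx, "participant_id")
  list(
    EH1 = log10_bayes_factor(base_sex, base_id, "EH1: sex"),
    EH2 = log10_bayes_factor(
      fit_lmm(d, fx, c("participant_id", "sex", "iris_colour")), base_sex,
      "EH2: iris colour"),
    EH3 = log10_bayes_factor(
      fit_lmm(d, c(fx, "habitual_caffeine_mgkg"), c("participant_id", "sex")),
      base_sex, "EH3: habitual caffeine"),
    EH4 = log10_bayes_factor(
      fit_lmm(d, c(fx, "acute_caffeine_mgkg"), c("participant_id", "sex")),
      base_sex, "EH4: acute caffeine")
  )
}

#' Light-metric predictor comparison matrices
#'
#' Fits the standard model `pupil ~ log10(metric) + age + (1|id) + (1|sex)`
#' once per light metric (single mode) or once per unordered metric pair (all
#' 15 combinations of the six metrics, pairwise mode) and returns the matrix
#' of pairwise BIC-approximated log10 Bayes factors between the candidate
#' models. Entry (i, j) favours model i when positive; the matrix is exactly
#' antisymmetric with a zero diagonal.
#'
#' @param data QC-passed field observation table.
#' @param metrics Character vector of light-metric columns (default: the five
#'   alpha-opic EDIs plus photopic illuminance).
#' @param pairwise Compare metric pairs instead of single metrics.
#' @inheritParams run_confirmatory
#' @return List with `models` (data.frame: model label, BIC, n), `matrix`
#'   (log10 BF matrix) and `best` (label of the lowest-BIC model).
#' @export
predictor_comparison <- function(data,
                                 metrics = c("scone_edi_lx", "mcone_edi_lx",
                                             "lcone_edi_lx",
                                             "rhodopic_edi_lx",
                                             "melanopic_edi_lx",
                                             "illuminance_lx"),
                                 pairwise = FALSE, floor_lx = 0.01,
                                 condition = "field") {
  if (anyDuplicated(metrics)) {
    stop("duplicate metrics in `metrics`", call. = FALSE)
  }
  d <- data[data$condition %in% condition, , drop = FALSE]
  d <- add_log_light(d, metrics, floor_lx)
  sets <- if (pairwise) {
    utils::combn(metrics, 2, simplify = FALSE)
  } else {
    as.list(metrics)
  }
  labels <- vapply(sets, paste, "", collapse = "+")
  re <- c("participant_id", "sex")
  fits <- lapply(sets, function(s) {
    fit_lmm(d, c(paste0("log_", s), "age_years"), re)
  })
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  m <- outer(bics, bics, function(bi, bj) (bj - bi) / (2 * log(10)))
  dimnames(m) <- list(labels, labels)
  list(
    models = data.frame(model = labels, bic = bics,
                        n_obs = vapply(fits, `[[`, numeric(1), "n_obs")),
    matrix = m,
    best = labels[which.min(bics)]
  )
}

#' Regression-assumption diagnostics for a fitted model
#'
#' Checks the linear-model assumptions the light terms are prone to violate
#' on untransformed data: a residual-vs-fitted linear trend (curvature /
#' misfit indicator), a heteroscedasticity statistic (slope of |residual| on
#' fitted values) and collinearity of the fixed predictors (pairwise
#' correlations and variance inflation factors; a VIF of `Inf` flags an
#' exactly collinear pair).
#'
#' @param fit A [fit_lmm()] result.
#' @param data The data the model was fitted on.
#' @param fixed Fixed-effect columns to assess for collinearity (default:
#'   the numeric terms of the fit).
#' @return List with `residual_trend`, `heteroscedasticity`,
#'   `predictor_correlations`, `vif` and `collinear` (logical flag).
#' @export
regression_diagnostics <- function(fit, data, fixed = NULL) {
  stopifnot(inherits(fit, "pupil_fit"))
  r <- stats::residuals(fit$model)
  f <- stats::fitted(fit$model)
  trend <- unname(coef(stats::lm(r ~ f))[2])
  hetero <- unname(coef(stats::lm(abs(r) ~ f))[2])
  if (is.null(fixed)) {
    fixed <- setdiff(fit$coefficients$term, "(Intercept)")
    fixed <- intersect(fixed, names(data))
  }
  corr <- NULL
  vif <- NULL
  collinear <- FALSE
  if (length(fixed) >= 2L) {
    x <- as.matrix(data[stats::complete.cases(data[, fixed, drop = FALSE]),
                        fixed, drop = FALSE])
    corr <- stats::cor(x)
    vif <- vapply(seq_along(fixed), function(j) {
      r2 <- suppressWarnings(
        summary(stats::lm(x[, j] ~ x[, -j, drop = FALSE]))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    names(vif) <- fixed
    collinear <- any(!is.finite(vif))
  }
  list(residual_trend = trend, heteroscedasticity = hetero,
       predictor_correlations = corr, vif = vif, collinear = collinear)
}

#' Per-participant autocorrelation of a regularly sampled series
#'
#' Sample autocorrelation of a 10 s cadence series per participant, averaged
#' across participants. Gaps are allowed: lagged pairs spanning a missing
#' sample are dropped, and normalization uses the per-participant variance of
#' the observed values. Constant series have undefined ACF and are flagged.
#'
#' @param data Observation table with `participant_id`, `timestamp_s` and the
#'   value column.
#' @param value Value column name (e.g. `"pupil_mm"`).
#' @param max_lag Maximum lag in samples; must be smaller than every
#'   participant's series length.
#' @param cadence_s Sampling cadence in seconds (default 10).
#' @return List with `acf` (data.frame `lag`, `acf` averaged over
#'   participants), `by_participant` (matrix) and `undefined` (ids of
#'   constant series, excluded from the average).
#' @export
autocorrelation <- function(data, value = "pupil_mm", max_lag = 10,
                            cadence_s = 10) {
  stopifnot(max_lag >= 1)
  ids <- unique(data$participant_id)
  res <- matrix(NA_real_, nrow = length(ids), ncol = max_lag,
                dimnames = list(ids, NULL))
  undefined <- character(0)
  for (id in ids) {
    d <- data[data$participant_id == id, , drop = FALSE]
    idx <- round((d$timestamp_s - min(d$timestamp_s)) / cadence_s) + 1L
    n <- max(idx)
    if (max_lag >= n) {
      stop("max_lag (", max_lag, ") must be smaller than the series length (",
           n, ") for participant ", id, call. = FALSE)
    }
    x <- rep(NA_real_, n)
    x[idx] <- d[[value]]
    obs <- !is.na(x)
    m <- mean(x[obs])
    denom <- sum((x[obs] - m)^2)
    if (denom == 0) {
      undefined <- c(undefined, id)
      next
    }
    for (k in seq_len(max_lag)) {
      a <- x[seq_len(n - k)]
      b <- x[seq_len(n - k) + k]
      ok <- !is.na(a) & !is.na(b)
      res[id, k] <- sum((a[ok] - m) * (b[ok] - m)) / denom
    }
  }
  list(
    acf = data.frame(lag = seq_len(max_lag),
                     acf = colMeans(res, na.rm = TRUE)),
    by_participant = res,
    undefined = undefined
  )
}
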