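#' Light-level cluster labels
#'
#' The dark-adaptation condition plus the four half-open field mEDI bins used
#' for the age analyses: \[1, 10), \[10, 100), \[100, 1000), \[1000, Inf) lx.
#'
#' @return Character vector of cluster labels in light order.
#' @export
light_clusters <- function() {
  c("dark", "1-10 lx", "10-100 lx", "100-1000 lx", ">1000 lx")
}

#' Assign observations to light-level clusters
#'
#' Dark-adaptation observations map to `"dark"` regardless of their residual
#' mEDI; field observations map to the half-open mEDI bin containing them, or
#' to `NA` below 1 lx; lab and transition observations map to `NA` (they are
#' excluded from the cluster analyses).
#'
#' @param condition Character vector of protocol conditions (`"field"`,
#'   `"dark"`, `"lab"`, `"transition"`).
#' @param medi_lx Melanopic EDI in lux (required for field observations).
#' @return Factor with levels [light_clusters()]; `NA` where unassigned.
#' @export
assign_cluster <- function(condition, medi_lx) {
  stopifnot(length(condition) == length(medi_lx))
  bad <- condition == "field" & is.na(medi_lx)
  if (any(bad)) {
    stop("missing mEDI on ", sum(bad), " field observation(s)", call. = FALSE)
  }
  out <- rep(NA_character_, length(condition))
  out[condition == "dark"] <- "dark"
  fld <- condition == "field"
  brk <- c(1, 10, 100, 1000, Inf)
  bin <- findInterval(medi_lx[fld], brk)  # 0 below 1 lx
  lab <- c(NA, light_clusters()[-1])
  out[fld] <- lab[bin + 1L]
  factor(out, levels = light_clusters())
}

#' Per-participant pupil summaries by light cluster
#'
#' Median and interquartile range (linear-interpolation quartiles, type 7) of
#' pupil diameter per participant and light cluster. Participants with no
#' observations in a cluster are omitted from that cluster.
#'
#' @param obs QC-passed observation table with `participant_id`, `condition`,
#'   `pupil_mm` and `melanopic_edi_lx`.
#' @return Data.frame of class `"cluster_summary"`: `participant_id`,
#'   `cluster`, `median_pupil_mm`, `iqr_mm`, `n_obs`.
#' @export
summarize_clusters <- function(obs) {
  cl <- assign_cluster(obs$condition, obs$melanopic_edi_lx)
  keep <- !is.na(cl) & !is.na(obs$pupil_mm)
  d <- data.frame(participant_id = obs$participant_id[keep],
                  cluster = cl[keep], pupil = obs$pupil_mm[keep])
  agg <- do.call(rbind, lapply(
    split(d, list(d$participant_id, d$cluster), drop = TRUE),
    function(g) {
      data.frame(
        participant_id = g$participant_id[1],
        cluster = g$cluster[1],
        median_pupil_mm = stats::median(g$pupil),
        iqr_mm = unname(diff(stats::quantile(g$pupil, c(0.25, 0.75),
                                             type = 7))),
        n_obs = nrow(g)
      )
    }))
  agg <- agg[order(agg$cluster, agg$participant_id), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("cluster_summary", "data.frame")
  agg
}

# two-parameter OLS with t-based 95% CIs, shared by the regression helpers
ols_ci <- function(x, y, n_min = 3L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < n_min) {
    stop("need at least ", n_min, " points for regression (got ", length(x),
         ")", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  est <- coef(fit)
  # exact-line input has zero residual; that is a legitimate degenerate case
  degenerate <- suppressWarnings(summary(fit)$sigma) < 1e-12
  ci <- if (degenerate) {
    matrix(rep(est, 2), ncol = 2,
           dimnames = list(names(est), c("2.5 %", "97.5 %")))
  } else {
    stats::confint(fit, level = 0.95)
  }
  structure(
    list(
      intercept = unname(est[1]), slope = unname(est[2]),
      ci95_intercept = unname(ci[1, ]), ci95_slope = unname(ci[2, ]),
      n = length(x), degenerate = degenerate, model = fit
    ),
    class = "pupil_regression"
  )
}

#' @export
print.pupil_regression <- function(x, ...) {
  cat("<pupil_regression> n = ", x$n,
      "; intercept = ", format(x$intercept, digits = 4),
      " [", format(x$ci95_intercept[1], digits = 4), ", ",
      format(x$ci95_intercept[2], digits = 4), "]",
      "; slope = ", format(x$slope, digits = 4),
      " [", format(x$ci95_slope[1], digits = 4), ", ",
      format(x$ci95_slope[2], digits = 4), "]",
      if (x$degenerate) " [degenerate: zero residual]" else "", "\n",
      sep = "")
  invisible(x)
}

#' Age regression of median pupil size within one light cluster
#'
#' Ordinary least squares of per-participant median pupil diameter (mm) on
#' age (years), with 95% confidence intervals from the t distribution. The
#' slope is also reported per decade of age (point estimate and CI scaled by
#' ten).
#'
#' @param summary A [summarize_clusters()] table restricted to (or filtered
#'   by `cluster` for) a single cluster.
#' @param ages Data.frame with `participant_id` and `age_years`.
#' @param cluster Optional cluster label to filter `summary` by.
#' @return A `"pupil_regression"` object with additional fields
#'   `slope_per_decade` and `ci95_slope_per_decade`.
#' @export
age_regression <- function(summary, ages, cluster = NULL) {
  if (!is.null(cluster)) {
    summary <- summary[summary$cluster == cluster, , drop = FALSE]
  }
  if (length(unique(summary$cluster)) > 1L) {
    stop("`summary` spans several clusters; pass `cluster =`", call. = FALSE)
  }
  m <- merge(summary, ages[, c("participant_id", "age_years")],
             by = "participant_id")
  out <- ols_ci(m$age_years, m$median_pupil_mm)
  out$slope_per_decade <- 10 * out$slope
  out$ci95_slope_per_decade <- 10 * out$ci95_slope
  out
}

#' Per-individual log-linear pupil--light fit
#'
#' OLS of pupil diameter on log10 mEDI for one participant, pooling field and
#' dark-adaptation data; dark frames enter at the light floor. The intercept
#' is the predicted diameter at 1 lx mEDI; the slope is mm per log10-unit
#' mEDI.
#'
#' @param obs Observations of a single participant with `pupil_mm` and
#'   `melanopic_edi_lx`.
#' @param floor_lx Floor applied before log10 (default 0.01 lx).
#' @param min_obs Minimum number of valid observations (default 10).
#' @param min_span_decades Minimum required span of log10 mEDI (default 2).
#' @return A `"pupil_regression"` object.
#' @export
individual_loglinear_fit <- function(obs, floor_lx = 0.01, min_obs = 10L,
                                     min_span_decades = 2) {
  ok <- is.finite(obs$pupil_mm) & is.finite(obs$melanopic_edi_lx)
  x <- log10(pmax(obs$melanopic_edi_lx[ok], floor_lx))
  y <- obs$pupil_mm[ok]
  if (length(x) < min_obs) {
    stop("need >= ", min_obs, " valid observations (got ", length(x), ")",
         call. = FALSE)
  }
  span <- diff(range(x))
  if (span < min_span_decades) {
    stop("insufficient light span: ", format(span, digits = 3),
         " decades of mEDI (need >= ", min_span_decades, ")", call. = FALSE)
  }
  ols_ci(x, y)
}

#' Pupil-range regression on age
#'
#' Per-participant pupil range (maximum minus minimum observed diameter, mm,
#' requiring at least `min_obs` valid observations including the
#' dark-adaptation condition) regressed on age by OLS.
#'
#' @param obs QC-passed observation table (all conditions).
#' @param ages Data.frame with `participant_id` and `age_years`.
#' @param min_obs Minimum valid observations per participant (default 20).
#' @return A `"pupil_regression"` object with `slope_per_decade`, plus a
#'   `ranges` data.frame attribute.
#' @export
pupil_range_regression <- function(obs, ages, min_obs = 20L) {
  ok <- is.finite(obs$pupil_mm)
  d <- obs[ok, , drop = FALSE]
  ranges <- do.call(rbind, lapply(split(d, d$participant_id), function(g) {
    if (nrow(g) < min_obs || !any(g$condition == "dark")) return(NULL)
    data.frame(participant_id = g$participant_id[1],
               range_mm = max(g$pupil_mm) - min(g$pupil_mm))
  }))
  if (is.null(ranges)) stop("no participant meets the range criteria",
                            call. = FALSE)
  m <- merge(ranges, ages[, c("participant_id", "age_years")],
             by = "participant_id")
  out <- ols_ci(m$age_years, m$range_mm)
  out$slope_per_decade <- 10 * out$slope
  out$ci95_slope_per_decade <- 10 * out$ci95_slope
  attr(out, "ranges") <- m
  out
}

#' Watson--Yellott unified pupil-size formula
#'
#' Reference prediction of light-adapted pupil diameter from luminance, field
#' diameter, age and the number of stimulated eyes, per the unified formula
#' of Watson & Yellott (2012). The luminance--area product is scaled by the
#' monocular effect (factor 0.1 for one eye), passed through the
#' Stanley--Davies dose--response, and corrected linearly for age around the
#' 28.58-year reference observer.
#'
#' @param luminance_cdm2 Field luminance in cd m^-2 (> 0).
#' @param field_diameter_deg Circular field diameter in degrees (default 10).
#' @param age_years Observer age in years (formula validity roughly 20--83).
#' @param n_eyes 1 (monocular) or 2 (binocular).
#' @return Predicted pupil diameter in mm; nonincreasing in luminance,
#'   smaller for higher age at low luminance.
#' @examples
#' watson_yellott_pupil(100, 10, 30, 2)
#' @export
watson_yellott_pupil <- function(luminance_cdm2, field_diameter_deg = 10,
                                 age_years, n_eyes = 2) {
  if (!n_eyes %in% c(1, 2)) stop("n_eyes must be 1 or 2", call. = FALSE)
  stopifnot(all(luminance_cdm2 > 0), all(age_years >= 1))
  area_deg2 <- pi * (field_diameter_deg / 2)^2
  eye_factor <- if (n_eyes == 2) 1 else 0.1
  flux <- luminance_cdm2 * area_deg2 * eye_factor
  f <- (flux / 846)^0.41
  d_sd <- 7.75 - 5.75 * f / (f + 2)
  d_sd + (age_years - 28.58) * (0.02132 - 0.009562 * d_sd)
}
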