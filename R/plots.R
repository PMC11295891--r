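#' Plot the participant-exclusion scree curve
#'
#' Excluded participants as a function of the candidate data-loss threshold,
#' with the selected threshold marked.
#'
#' @param scree Result of [scree_threshold()].
#' @return The input, invisibly.
#' @export
plot_scree <- function(scree) {
  curve <- scree$curve
  graphics::plot(curve$threshold, curve$n_excluded, type = "b", pch = 16,
                 xlab = "data-loss threshold",
                 ylab = "participants excluded",
                 main = "Exclusion scree")
  graphics::abline(v = scree$threshold, lty = 2, col = "magenta")
  invisible(scree)
}

#' Plot a cluster age regression
#'
#' Per-participant median pupil size against age for one light cluster, with
#' the fitted OLS line.
#'
#' @param summary A [summarize_clusters()] table.
#' @param ages Data.frame with `participant_id` and `age_years`.
#' @param cluster Cluster label (see [light_clusters()]).
#' @return The [age_regression()] fit, invisibly.
#' @export
plot_age_effect <- function(summary, ages, cluster) {
  s <- summary[summary$cluster == cluster, , drop = FALSE]
  m <- merge(s, ages, by = "participant_id")
  fit <- age_regression(s, ages)
  graphics::plot(m$age_years, m$median_pupil_mm, pch = 15,
                 xlab = "age [years]", ylab = "median pupil [mm]",
                 main = cluster)
  graphics::abline(fit$intercept, fit$slope, col = "steelblue")
  invisible(fit)
}
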