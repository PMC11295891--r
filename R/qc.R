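#' Data-quality cascade for synchronized pupil/light observations
#'
#' Applies the study's quality filters to an observation table. An observation
#' is retained iff its pupil estimate is present, detection confidence is at
#' least `conf_min`, the pupil diameter lies within `[pupil_lo, pupil_hi]`
#' (inclusive) and its spectrum is not saturated. Exclusions are counted with
#' a fixed precedence so the per-rule counts do not overlap: missing pupil or
#' low confidence first, then out-of-range, then saturation.
#'
#' @param obs Observation data.frame with at least `participant_id`,
#'   `pupil_mm`, `confidence`, `saturated`.
#' @param conf_min Minimum detection confidence (default 0.6; frames below
#'   are excluded).
#' @param pupil_lo,pupil_hi Physiological pupil range in mm (default 1--9,
#'   inclusive).
#' @param drop_saturated Drop frames whose spectrum saturated (default TRUE).
#' @return A list of class `"qc_result"`: `retained` (filtered data.frame) and
#'   `report` (class `"qc_report"`: `n_total`, `n_low_confidence`,
#'   `n_out_of_range`, `n_saturated`, `n_retained` and per-rule proportions).
#' @export
apply_filters <- function(obs, conf_min = 0.6, pupil_lo = 1, pupil_hi = 9,
                          drop_saturated = TRUE) {
  if (!is.data.frame(obs) || nrow(obs) == 0L) {
    stop("`obs` must be a nonempty data.frame", call. = FALSE)
  }
  need <- c("participant_id", "pupil_mm", "confidence", "saturated")
  miss <- setdiff(need, names(obs))
  if (length(miss)) {
    stop("missing observation columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  conf <- obs$confidence
  conf[is.na(conf) | is.na(obs$pupil_mm)] <- 0  # missing pupil ~ confidence 0
  low <- conf < conf_min
  oor <- !low & (obs$pupil_mm < pupil_lo | obs$pupil_mm > pupil_hi)
  sat <- !low & !oor & drop_saturated & isTRUE_vec(obs$saturated)
  keep <- !low & !oor & !sat
  report <- structure(
    list(
      n_total = nrow(obs),
      n_low_confidence = sum(low),
      n_out_of_range = sum(oor),
      n_saturated = sum(sat),
      n_retained = sum(keep),
      proportions = c(
        low_confidence = mean(low),
        out_of_range = mean(oor),
        saturated = mean(sat),
        retained = mean(keep)
      )
    ),
    class = "qc_report"
  )
  structure(list(retained = obs[keep, , drop = FALSE], report = report),
            class = "qc_result")
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", x$n_total, " observations: ",
      x$n_low_confidence, " low-confidence/missing (",
      sprintf("%.2f%%", 100 * x$proportions[["low_confidence"]]), "), ",
      x$n_out_of_range, " out-of-range, ",
      x$n_saturated, " saturated, ",
      x$n_retained, " retained\n", sep = "")
  invisible(x)
}

#' Per-participant data-loss accounting
#'
#' @param raw Full observation table (before filtering).
#' @param retained Retained observation table (subset of `raw`).
#' @return A data.frame of class `"loss_table"`: `participant_id`, `n_total`,
#'   `n_retained`, `loss_fraction` (= 1 - n_retained / n_total).
#' @export
loss_table <- function(raw, retained) {
  tot <- table(raw$participant_id)
  kept <- table(factor(retained$participant_id, levels = names(tot)))
  extra <- setdiff(unique(retained$participant_id), names(tot))
  if (length(extra)) {
    stop("participants in `retained` but not `raw`: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    participant_id = names(tot),
    n_total = as.integer(tot),
    n_retained = as.integer(kept),
    stringsAsFactors = FALSE
  )
  out$loss_fraction <- 1 - out$n_retained / out$n_total
  class(out) <- c("loss_table", "data.frame")
  out
}

#' Scree-based participant-exclusion threshold
#'
#' Data-driven choice of the per-participant data-loss threshold: for every
#' candidate threshold t in `{start, start + step, ..., stop}` count the
#' participants whose loss fraction exceeds t, then pick the start of the
#' flattest step beyond `start` -- the smallest candidate t > start for which
#' the drop in excluded participants from t to t + step attains the minimum
#' over all consecutive candidate pairs. Ties resolve to the smallest
#' qualifying threshold.
#'
#' @param losses A [loss_table] (or data.frame with `loss_fraction`).
#' @param start,step,stop Candidate grid (fractions; defaults 0.50, 0.05,
#'   0.95).
#' @return List with `threshold`, and `curve`: data.frame of candidate
#'   `threshold` and `n_excluded` for plotting.
#' @export
scree_threshold <- function(losses, start = 0.50, step = 0.05, stop = 0.95) {
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  lf <- losses$loss_fraction
  if (is.null(lf) || !length(lf)) {
    stop("`losses` must contain a nonempty loss_fraction column",
         call. = FALSE)
  }
  cand <- seq(start, stop, by = step)
  counts <- vapply(cand, function(t) sum(lf > t), integer(1))
  if (length(cand) < 3L) {
    stop("candidate grid too short to locate a step beyond `start`",
         call. = FALSE)
  }
  # steps between consecutive candidates whose start is strictly beyond `start`
  drops <- counts[-length(counts)] - counts[-1]
  eligible <- which(cand[-length(cand)] > start)
  best <- eligible[which.min(drops[eligible])]
  list(
    threshold = cand[best],
    curve = data.frame(threshold = cand, n_excluded = counts)
  )
}

#' Exclude participants above a data-loss threshold
#'
#' @param losses A [loss_table].
#' @param threshold Loss-fraction threshold in (0, 1); participants with loss
#'   strictly greater are dropped.
#' @return Character vector of retained participant ids.
#' @export
exclude_participants <- function(losses, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  as.character(losses$participant_id[losses$loss_fraction <= threshold])
}
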