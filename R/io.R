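#' Read an observation table from CSV
#'
#' Canonical wide-form storage: one row per 10 s observation with the
#' mandatory columns `participant_id`, `timestamp_s`, `condition`,
#' `pupil_mm`, `confidence`, `saturated`, plus either spectral columns
#' `w380 ... w780` or precomputed metric columns. Unknown columns are
#' preserved.
#'
#' @param path CSV path.
#' @return Observation data.frame.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  mandatory <- c("participant_id", "timestamp_s", "condition", "pupil_mm",
                 "confidence", "saturated")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss)) {
    stop("missing mandatory columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("timestamp_s", "pupil_mm", "confidence")) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & trimws(v) != "")
      if (length(bad)) {
        stop("malformed numeric value in column '", col, "' at row ",
             bad[1], call. = FALSE)
      }
      raw[[col]] <- num
    }
  }
  raw$saturated <- as.logical(raw$saturated)
  ok_cond <- c("field", "dark", "lab", "transition")
  bad <- which(!raw$condition %in% ok_cond)
  if (length(bad)) {
    stop("invalid condition at row ", bad[1], ": '", raw$condition[bad[1]],
         "'", call. = FALSE)
  }
  raw
}

#' Write an observation table to CSV
#'
#' Round-trip stable with [read_observations()] (values preserved to at
#' least 1e-12 relative).
#'
#' @param obs Observation data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  out <- obs
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), NA, format(v, digits = 17, scientific = TRUE,
                                trim = TRUE))
  })
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Convert long-form spectra to the wide observation format
#'
#' @param long Data.frame with `sample_id`, `wavelength_nm`, `irradiance`.
#' @return Matrix with one regridded spectrum per row (rownames =
#'   sample ids), columns `w380 ... w780`.
#' @export
spectra_long_to_wide <- function(long) {
  need <- c("sample_id", "wavelength_nm", "irradiance")
  miss <- setdiff(need, names(long))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  ids <- unique(long$sample_id)
  mat <- t(vapply(ids, function(id) {
    d <- long[long$sample_id == id, , drop = FALSE]
    d <- d[order(d$wavelength_nm), ]
    as.numeric(regrid_spectrum(spectrum_raw(d$wavelength_nm, d$irradiance)))
  }, numeric(length(.pf_grid))))
  dimnames(mat) <- list(ids, paste0("w", .pf_grid))
  mat
}

#' Pipeline run configuration
#'
#' Bundles all tunables of [run_pipeline()]; defaults mirror the study's
#' constants. Can also be loaded from a YAML file with [read_run_config()].
#'
#' @param seed Integer seed for the synthetic session.
#' @param n_participants Cohort size (default 83).
#' @param n_field Field observations per participant (default 100).
#' @param mode Generator mode (`"loglinear"` or `"cluster"`).
#' @param conf_min,pupil_lo,pupil_hi,drop_saturated QC parameters (see
#'   [apply_filters()]).
#' @param threshold_mode `"fixed"` (use `loss_threshold`) or `"scree"`.
#' @param loss_threshold Fixed per-participant data-loss threshold (default
#'   0.75).
#' @param light_transform `"log10"` or `"linear"`.
#' @param floor_lx Light floor before log10.
#' @param pairwise_predictors Also fit the 15 pairwise predictor models
#'   (slower; default FALSE).
#' @param input_csv Optional path to an existing observation CSV; when given
#'   the generator is skipped.
#' @param out_dir Output directory.
#' @param generator A [generator_config()].
#' @return List of class `"run_config"`.
#' @export
run_config <- function(seed = 1, n_participants = 83, n_field = 100,
                       mode = c("loglinear", "cluster"),
                       conf_min = 0.6, pupil_lo = 1, pupil_hi = 9,
                       drop_saturated = TRUE,
                       threshold_mode = c("fixed", "scree"),
                       loss_threshold = 0.75,
                       light_transform = c("log10", "linear"),
                       floor_lx = 0.01, pairwise_predictors = FALSE,
                       input_csv = NULL, out_dir = tempfile("pupilfield_run_"),
                       generator = NULL) {
  mode <- match.arg(mode)
  cfg <- list(
    seed = seed, n_participants = n_participants, n_field = n_field,
    mode = mode, conf_min = conf_min, pupil_lo = pupil_lo,
    pupil_hi = pupil_hi, drop_saturated = drop_saturated,
    threshold_mode = match.arg(threshold_mode),
    loss_threshold = loss_threshold,
    light_transform = match.arg(light_transform),
    floor_lx = floor_lx, pairwise_predictors = pairwise_predictors,
    input_csv = input_csv, out_dir = out_dir,
    generator = if (is.null(generator)) generator_config(mode = mode)
                else generator
  )
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; generator parameters nest
#' under `generator:`.
#'
#' @param path YAML file path.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen_args <- y$generator
  y$generator <- NULL
  keep <- intersect(names(y), names(formals(run_config)))
  cfg <- do.call(run_config, y[keep])
  if (!is.null(gen_args)) {
    gen_args$mode <- cfg$mode
    keep_g <- intersect(names(gen_args), names(formals(generator_config)))
    cfg$generator <- do.call(generator_config, gen_args[keep_g])
  }
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  slim <- config[setdiff(names(config), "out_dir")]
  jsonlite::write_json(slim, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

evidence_to_list <- function(ev) {
  lapply(ev, function(e) {
    e[c("comparison", "formula_full", "formula_null", "log10_bf", "category",
        "method", "n_obs")]
  })
}

regression_to_list <- function(r) {
  out <- list(intercept = r$intercept, slope = r$slope,
              ci95_intercept = r$ci95_intercept, ci95_slope = r$ci95_slope,
              n = r$n)
  if (!is.null(r$slope_per_decade)) {
    out$slope_per_decade <- r$slope_per_decade
    out$ci95_slope_per_decade <- r$ci95_slope_per_decade
  }
  out
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the full workflow on a synthetic session (or an input CSV):
#' light metrics, the QC cascade, data-loss accounting, the participant
#' exclusion threshold (fixed or scree-based), confirmatory and exploratory
#' mixed-model tests, the transform check, predictor-comparison matrices and
#' the cluster/age analyses. All results are written under
#' `config$out_dir` (CSV + JSON + a plain-text log) with the configuration
#' hash for provenance, and returned invisibly as a list.
#'
#' @param config A [run_config()].
#' @return (Invisibly) list with `observations`, `qc_report`, `losses`,
#'   `threshold`, `retained_ids`, `evidence` (CH/EH/transform),
#'   `predictor_single` (and `_pairwise`), `cluster_summary`,
#'   `age_regressions`, `range_regression`, `config_hash`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  obs <- step("input", {
    if (!is.null(config$input_csv)) {
      read_observations(config$input_csv)
    } else {
      cohort <- sample_cohort(config$n_participants, seed = config$seed,
                              config = config$generator)
      simulate_session(cohort, n_field = config$n_field,
                       config = config$generator)
    }
  })
  qc <- step("qc", apply_filters(obs, config$conf_min, config$pupil_lo,
                                 config$pupil_hi, config$drop_saturated))
  losses <- step("loss accounting", loss_table(obs, qc$retained))
  scree <- step("scree", scree_threshold(losses))
  threshold <- if (config$threshold_mode == "scree") scree$threshold
               else config$loss_threshold
  ids <- step("exclusion", {
    ids <- exclude_participants(losses, threshold)
    if (!length(ids)) stop("no participants retained")
    ids
  })
  kept <- qc$retained[qc$retained$participant_id %in% ids, , drop = FALSE]
  field <- kept[kept$condition == "field", , drop = FALSE]
  evidence <- step("inference", c(
    run_confirmatory(field, config$light_transform, config$floor_lx),
    list(transform = transform_check(field, config$floor_lx)),
    run_exploratory(field, config$floor_lx)
  ))
  pred <- step("predictor comparison",
               predictor_comparison(field, floor_lx = config$floor_lx))
  pred_pair <- if (config$pairwise_predictors) {
    step("pairwise predictors",
         predictor_comparison(field, pairwise = TRUE,
                              floor_lx = config$floor_lx))
  } else NULL
  ages <- unique(kept[, c("participant_id", "age_years")])
  cs <- step("cluster summaries", summarize_clusters(kept))
  age_reg <- step("age regressions", {
    lapply(setNames(nm = intersect(light_clusters(), unique(cs$cluster))),
           function(cl) age_regression(cs, ages, cluster = cl))
  })
  range_reg <- step("range regression", pupil_range_regression(kept, ages))

  out <- config$out_dir
  write_observations(obs, file.path(out, "observations.csv"))
  jsonlite::write_json(
    c(unclass(qc$report)["proportions" != names(unclass(qc$report))],
      list(proportions = as.list(qc$report$proportions),
           config_hash = hash)),
    file.path(out, "qc_report.json"), auto_unbox = TRUE, digits = NA)
  write.csv(losses, file.path(out, "loss_table.csv"), row.names = FALSE)
  write.csv(scree$curve, file.path(out, "scree_curve.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = hash, evidence = evidence_to_list(evidence)),
    file.path(out, "evidence.json"), auto_unbox = TRUE, digits = NA)
  write.csv(cs, file.path(out, "cluster_summary.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = hash,
         age_regressions = lapply(age_reg, regression_to_list),
         range_regression = regression_to_list(range_reg)),
    file.path(out, "regressions.json"), auto_unbox = TRUE, digits = NA)
  writeLines(c(
    paste0("pupilfield run log"),
    paste0("config_hash: ", hash),
    paste0("seed: ", config$seed),
    paste0("R: ", R.version.string),
    paste0("threshold (", config$threshold_mode, "): ", threshold),
    paste0("participants retained: ", length(ids), "/",
           nrow(losses)),
    paste0("field observations analysed: ", nrow(field))
  ), file.path(out, "run_log.txt"))

  invisible(list(
    observations = obs, qc_report = qc$report, losses = losses,
    scree = scree, threshold = threshold, retained_ids = ids,
    evidence = evidence, predictor_single = pred,
    predictor_pairwise = pred_pair, cluster_summary = cs,
    age_regressions = age_reg, range_regression = range_reg,
    config_hash = hash
  ))
}
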