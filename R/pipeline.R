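# End-to-end orchestration: simulate -> segment -> extract -> classify
# -> report, plus the feature registry that is the single source of
# truth for the 210-column battery layout.

#' The gait feature registry
#'
#' One row per gait characteristic, in the canonical column order of
#' the feature matrix: 25 spatiotemporal, 56 frequency, 20 regularity,
#' 84 magnitude and 25 complexity characteristics (210 in total).
#'
#' @return Data frame with columns `name`, `domain`, `unit`,
#'   `description`.
#' @export
feature_registry <- function() {
  unit_of <- function(nm) {
    if (grepl("_cv$|asym$|^reg_|^frq_hr|^frq_ih|jerk_ratio|_asym_|gsi", nm)) ""
    else if (grepl("^st_cadence", nm)) "steps/min"
    else if (grepl("^st_.*time", nm)) "s"
    else if (grepl("velocity", nm)) "m/s"
    else if (grepl("length", nm)) "m"
    else if (grepl("^frq_peak_freq", nm)) "Hz"
    else if (grepl("^frq_peak_width", nm)) "Hz"
    else if (grepl("^frq_peak_slope", nm)) "power/Hz"
    else if (grepl("^frq_total_power|^frq_peak_amp|^frq_peak_range", nm)) "(m/s^2)^2/Hz"
    else if (grepl("jerk_rms", nm)) "m/s^3"
    else if (grepl("^mag_", nm)) "m/s^2"
    else if (grepl("^cpx_lyap", nm)) "1/s"
    else if (grepl("^cpx_", nm)) "normalized"
    else ""
  }
  desc_of <- function(nm, domain) {
    switch(domain,
      spatiotemporal = "event/pendulum-derived spatiotemporal measure",
      frequency = "power spectral density / harmonic-content measure",
      regularity = "autocorrelation-based regularity or symmetry measure",
      magnitude = "segment-averaged signal magnitude / smoothness measure",
      complexity = "phase-plot geometry or Lyapunov stability measure")
  }
  blocks <- list(
    spatiotemporal = spatiotemporal_feature_names(),
    frequency = frequency_feature_names(),
    regularity = regularity_feature_names(),
    magnitude = magnitude_feature_names(),
    complexity = complexity_feature_names())
  do.call(rbind, lapply(names(blocks), function(d) {
    nms <- blocks[[d]]
    data.frame(name = nms, domain = d,
               unit = vapply(nms, unit_of, ""),
               description = desc_of(nms[1], d),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Extract the 210-characteristic battery for one subject
#'
#' @param subject A `gait_subject` (recording + events + sensor
#'   height), raw; preprocessing is applied here.
#' @param lyap_n_ref Reference points for the Lyapunov estimator.
#' @return Named numeric vector of length 210 in registry order.
#' @export
subject_features <- function(subject, lyap_n_ref = 200) {
  rec <- preprocess(subject$recording)
  ev <- subject$events
  c(spatiotemporal_vector(rec, ev, subject$sensor_height),
    frequency_vector(rec, ev),
    regularity_vector(rec, ev),
    magnitude_vector(rec, ev),
    complexity_vector(rec, ev, n_ref = lyap_n_ref))
}

#' Extract the cohort feature matrix
#'
#' Runs the full preprocessing + segmentation + five-domain extraction
#' for every subject.  Subjects that fail to process are skipped with a
#' warning; the run aborts if more than `max_skip_frac` of them do.
#'
#' @param cohort A `gait_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]) or a cohort directory path.
#' @param lyap_n_ref Passed to [subject_features()].
#' @param max_skip_frac Maximum tolerated fraction of skipped subjects.
#' @return Data frame: `subject_id`, `group`, then the 210 gait
#'   feature columns in registry order.
#' @export
extract_features <- function(cohort, lyap_n_ref = 200,
                             max_skip_frac = 0.1) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "gait_cohort"))
  reg <- feature_registry()
  rows <- list(); skipped <- character()
  for (s in cohort$subjects) {
    id <- s$recording$subject_id
    fv <- tryCatch(subject_features(s, lyap_n_ref = lyap_n_ref),
                   error = function(e) {
                     warning("subject ", id, " skipped: ",
                             conditionMessage(e))
                     NULL
                   })
    if (is.null(fv)) { skipped <- c(skipped, id); next }
    stopifnot(identical(names(fv), reg$name))
    rows[[id]] <- data.frame(subject_id = id,
                             group = s$demographics$group,
                             t(fv), stringsAsFactors = FALSE)
  }
  if (length(skipped) > max_skip_frac * length(cohort$subjects))
    stop("more than ", round(100 * max_skip_frac),
         "% of subjects failed: ", paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the full design matrix (gait features + demographics)
#'
#' Appends the six demographic/clinical covariates (age, sex coded
#' 0/1 with male = 1, height, weight, BMI, MoCA) to the 210 gait
#' features, giving the 216-column design matrix.
#'
#' @param features Data frame from [extract_features()].
#' @param demographics Data frame with `subject_id`, `age`, `sex`,
#'   `height`, `weight`, `bmi`, `moca`; `NULL` returns the gait
#'   features only.
#' @return Numeric matrix with row order of `features`.
#' @export
design_matrix <- function(features, demographics = NULL) {
  X <- as.matrix(features[, !(names(features) %in% c("subject_id", "group")),
                          drop = FALSE])
  rownames(X) <- features$subject_id
  if (is.null(demographics)) return(X)
  d <- demographics[match(features$subject_id, demographics$subject_id), ]
  dem <- cbind(dem_age = d$age,
               dem_sex = as.numeric(d$sex == "M"),
               dem_height = d$height,
               dem_weight = d$weight,
               dem_bmi = d$bmi,
               dem_moca = d$moca)
  cbind(X, dem)
}

#' Run the complete analysis end to end
#'
#' simulate -> write cohort -> extract features -> six-model battery ->
#' group statistics -> reports, all under one output directory:
#' `cohort/`, `features.csv`, `feature_registry.csv`,
#' `reports/battery.csv`, `reports/group_stats.csv`,
#' `reports/vip.csv`, `reports/roc_<model>.csv`, `run_config.json`.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory.
#' @param seed Master seed for simulation and cross-validation.
#' @param subsets Battery subset names (default all six).
#' @param ncomp_max,folds PLS-DA settings.
#' @param write_raw Write the per-subject raw CSV files (default
#'   `TRUE`).
#' @return List with `features`, `battery`, `group_stats`, `vip`
#'   (invisibly).
#' @export
run_all <- function(config = cohort_config(), out_dir, seed = 1L,
                    subsets = names(battery_subsets()),
                    ncomp_max = 6, folds = 7, write_raw = TRUE) {
  dir.create(file.path(out_dir, "reports"), recursive = TRUE,
             showWarnings = FALSE)
  t0 <- Sys.time()
  cohort <- simulate_cohort(config, seed = seed)
  if (write_raw) write_cohort(cohort, file.path(out_dir, "cohort"))
  features <- extract_features(cohort)
  data.table::fwrite(features, file.path(out_dir, "features.csv"))
  data.table::fwrite(feature_registry(),
                     file.path(out_dir, "feature_registry.csv"))
  battery <- run_battery(features, cohort$demographics, subsets = subsets,
                         ncomp_max = ncomp_max, folds = folds, seed = seed)
  data.table::fwrite(battery, file.path(out_dir, "reports", "battery.csv"))
  for (nm in names(attr(battery, "roc")))
    data.table::fwrite(attr(battery, "roc")[[nm]],
                       file.path(out_dir, "reports",
                                 paste0("roc_", nm, ".csv")))
  # full-data model on the complete design matrix for VIP ranking
  X <- design_matrix(features, cohort$demographics)
  y <- factor(features$group, levels = c("PD", "CL"))
  astar <- battery$ncomp[battery$model == utils::tail(subsets, 1)]
  if (!length(astar)) astar <- 2
  full_fit <- plsda(X, y, ncomp = max(astar, 2))
  vtab <- vip(full_fit)
  reg <- feature_registry()
  vtab$domain <- reg$domain[match(vtab$feature, reg$name)]
  vtab$domain[is.na(vtab$domain)] <- "demographics"
  data.table::fwrite(vtab, file.path(out_dir, "reports", "vip.csv"))
  influential <- vtab$feature[vtab$vip_avg > 1 &
                                vtab$domain != "demographics"]
  gs <- group_compare(features, cor_features = influential)
  data.table::fwrite(gs, file.path(out_dir, "reports", "group_stats.csv"))
  cfg_echo <- c(unclass(config),
                list(seed = seed, subsets = subsets, ncomp_max = ncomp_max,
                     folds = folds,
                     elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs"))))
  jsonlite::write_json(cfg_echo, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(features = features, battery = battery,
                 group_stats = gs, vip = vtab))
}
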