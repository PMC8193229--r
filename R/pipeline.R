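## End-to-end pipelines: frames -> detections -> temporal features; key
## frames -> radiomics; feature-set selection; ISR + SVM evaluation.

#' Temporal and radiomic features of a single case
#'
#' Runs the detection-to-feature stage: structure events and phase
#' timeline at threshold `tau`, the five temporal features, the five
#' equal-proportion key frames, and the 1,750-dimensional radiomic vector.
#'
#' @param stack A [frame_stack()].
#' @param detections Detection table of the case; when `NULL` the
#'   [reference_detect()] phantom detector is run on the stack.
#' @param tau Confidence threshold for structure presence.
#' @return List with `temporal` (named T1..T5), `radiomics` (length
#'   1,750), `key_frames`, `timeline`, `events`, `detections`.
#' @export
extract_case_features <- function(stack, detections = NULL, tau = 0.5) {
  detections <- detections %||% reference_detect(stack)
  events <- structure_events(detections, tau = tau)
  timeline <- classify_phases(events, detections, tau = tau,
                              n_frames = length(stack$frames))
  temporal <- temporal_features(events, timeline)
  key <- select_key_frames(events, n_frames = length(stack$frames))
  radiomics <- case_radiomics_vector(stack, key)
  list(temporal = temporal, radiomics = radiomics, key_frames = key,
       timeline = timeline, events = events, detections = detections)
}

#' Extract the feature table of a generated cohort
#'
#' Reads the cohort written by [generate_cohort()] (or any directory with
#' the same layout), runs the reference detector on each case's frames and
#' assembles the per-case feature table: metadata, T1..T5, then the 1,750
#' radiomic features.
#'
#' @param cohort_dir Cohort directory (`frames/<case_id>/`, `manifest.csv`,
#'   `labels.csv`).
#' @param tau Confidence threshold.
#' @param use_truth_boxes If `TRUE`, use the stored ground-truth boxes
#'   instead of running the reference detector.
#' @param verbose Print progress.
#' @return Data frame: case_id, diagnosis, grade_class, T1..T5, radiomics.
#' @export
extract_cohort_features <- function(cohort_dir, tau = 0.5,
                                    use_truth_boxes = FALSE,
                                    verbose = FALSE) {
  manifest <- utils::read.csv(file.path(cohort_dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  truth <- if (use_truth_boxes) {
    read_detection_table(file.path(cohort_dir, "truth_boxes.csv"))
  } else NULL
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$case_id[i]
    stack <- read_frame_stack(file.path(cohort_dir, "frames", id),
                              frame_interval_ms = manifest$frame_interval_ms[i],
                              case_id = id)
    det <- if (is.null(truth)) NULL else truth[truth$case_id == id, , drop = FALSE]
    fx <- extract_case_features(stack, detections = det, tau = tau)
    rows[[i]] <- c(list(case_id = id, diagnosis = manifest$diagnosis[i],
                        grade_class = manifest$grade_class[i]),
                   as.list(c(fx$temporal, fx$radiomics)))
    if (verbose) message(sprintf("extracted %s (%d/%d)", id, i,
                                 nrow(manifest)))
  }
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
}

feature_columns <- function(features, feature_set) {
  nm <- names(features)
  temporal <- paste0("T", 1:5)
  radiomic <- setdiff(nm, c("case_id", "diagnosis", "grade_class", temporal))
  switch(feature_set,
         temporal = temporal,
         radiomics = radiomic,
         combined = c(temporal, radiomic),
         stop_("unknown feature_set: %s", feature_set))
}

#' AVM diagnosis pipeline
#'
#' End-to-end evaluation of one feature set (temporal, radiomics or
#' combined) for AVM vs non-AVM diagnosis under the split protocol:
#' stratified 7:3 split, leave-one-out cross-validation with in-fold ISR
#' selection on the cross-validation cohort, one final refit scored on the
#' independent test cohort.
#'
#' @param cohort_dir Cohort directory ([generate_cohort()] layout);
#'   ignored when `features` is supplied.
#' @param feature_set `"temporal"`, `"radiomics"` or `"combined"`.
#' @param config A [dsa_config()].
#' @param features Optional precomputed feature table from
#'   [extract_cohort_features()] (avoids re-extraction across feature
#'   sets).
#' @return Object of class `dsa_report`.
#' @export
run_diagnosis_pipeline <- function(cohort_dir = NULL,
                                   feature_set = c("combined", "temporal",
                                                   "radiomics"),
                                   config = dsa_config(),
                                   features = NULL) {
  feature_set <- match.arg(feature_set)
  features <- features %||% extract_cohort_features(cohort_dir,
                                                    tau = config$tau)
  cols <- feature_columns(features, feature_set)
  x <- as.matrix(features[, cols, drop = FALSE])
  labels <- features$diagnosis == "AVM"  # positive class: AVM
  ev <- split_evaluate(x, labels, config = config)
  structure(list(task = "diagnosis", feature_set = feature_set,
                 cv = ev$cv, test = ev$test,
                 selected_features = cols[ev$selected],
                 n_cases = nrow(x), n_features = ncol(x),
                 config = config), class = "dsa_report")
}

#' AVM grading pipeline
#'
#' High (IV-V) vs low (I-III) grade classification on the AVM cases,
#' evaluated with the leave-one-out cross-validation protocol only, for
#' the combined and radiomics-only feature sets side by side.
#'
#' @inheritParams run_diagnosis_pipeline
#' @return Object of class `dsa_grading_report`: list with `combined` and
#'   `radiomics` metric sets.
#' @export
run_grading_pipeline <- function(cohort_dir = NULL, config = dsa_config(),
                                 features = NULL) {
  features <- features %||% extract_cohort_features(cohort_dir,
                                                    tau = config$tau)
  avm <- features[features$diagnosis == "AVM", , drop = FALSE]
  if (nrow(avm) == 0L || any(!avm$grade_class %in% c("low", "high"))) {
    stop_("grading requires AVM cases with low/high grade_class")
  }
  if (!any(avm$grade_class == "high")) stop_("cohort has no high-grade case")
  if (!any(avm$grade_class == "low")) stop_("cohort has no low-grade case")
  labels <- avm$grade_class == "high"  # positive class: high grade
  out <- lapply(c(combined = "combined", radiomics = "radiomics"),
                function(fs) {
    cols <- feature_columns(avm, fs)
    loo_cv(as.matrix(avm[, cols, drop = FALSE]), labels, config)$metrics
  })
  structure(list(task = "grading", combined = out$combined,
                 radiomics = out$radiomics, n_cases = nrow(avm),
                 config = config), class = "dsa_grading_report")
}

#' @export
print.dsa_report <- function(x, ...) {
  cat(sprintf("AVM %s, %s features (%d cases, %d features; %d selected)\n",
              x$task, x$feature_set, x$n_cases, x$n_features,
              length(x$selected_features)))
  cat("  LOO cross-validation: "); print(x$cv)
  cat("  Independent test:     "); print(x$test)
  invisible(x)
}

#' @export
print.dsa_grading_report <- function(x, ...) {
  cat(sprintf("AVM grading, high vs low (%d AVM cases, LOO protocol)\n",
              x$n_cases))
  cat("  combined features:  "); print(x$combined)
  cat("  radiomics features: "); print(x$radiomics)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report A `dsa_report` or `dsa_grading_report`.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  to_list <- function(m) list(auc = m$auc, auc_ci = m$auc_ci, acc = m$acc,
                              sens = m$sens, spec = m$spec,
                              n_pos = m$n_pos, n_neg = m$n_neg)
  out <- if (inherits(report, "dsa_grading_report")) {
    list(task = report$task, n_cases = report$n_cases,
         combined = to_list(report$combined),
         radiomics = to_list(report$radiomics))
  } else {
    list(task = report$task, feature_set = report$feature_set,
         n_cases = report$n_cases,
         cv = to_list(report$cv), test = to_list(report$test),
         selected_features = report$selected_features)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
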