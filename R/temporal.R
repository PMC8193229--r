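## Phase timeline and temporal features: converts a per-case detection
## table into structure appearance events, per-frame phase labels, the five
## binary order-of-appearance features and the five equal-proportion key
## frames.

#' Structure appearance events of one case
#'
#' A class is "present" on a frame iff some detection row of that class has
#' confidence `score >= tau`; ground-truth rows with empty score always
#' count as present. Events are the first/last present frame per class.
#' `developed_first`/`developed_last` bound the developed span: the
#' first/last frame carrying any detection row at all.
#'
#' @param detections Detection table of a single case.
#' @param tau Confidence threshold (default 0.5, the conventional detector
#'   cutoff).
#' @return Object of class `structure_events`: list with `first`/`last`
#'   (named per-class vectors, `NA` when a class never appears),
#'   `developed_first`, `developed_last`, and `tau`.
#' @export
structure_events <- function(detections, tau = 0.5) {
  validate_detection_table(detections)
  if (length(unique(detections$case_id)) > 1L) {
    stop_("structure_events expects detections of a single case")
  }
  present <- is.na(detections$score) | detections$score >= tau
  first <- stats::setNames(rep(NA_integer_, length(DSA_CLASSES)), DSA_CLASSES)
  last <- first
  for (cls in DSA_CLASSES) {
    fr <- detections$frame[present & detections$label == cls]
    if (length(fr)) {
      first[cls] <- min(fr)
      last[cls] <- max(fr)
    }
  }
  structure(list(
    first = first, last = last,
    developed_first = if (nrow(detections)) min(detections$frame) else NA_integer_,
    developed_last = if (nrow(detections)) max(detections$frame) else NA_integer_,
    tau = tau
  ), class = "structure_events")
}

#' @export
print.structure_events <- function(x, ...) {
  cat(sprintf("Structure events (tau = %.2f):\n", x$tau))
  for (cls in names(x$first)) {
    cat(sprintf("  %-16s %s\n", cls,
                if (is.na(x$first[cls])) "absent"
                else sprintf("frames %d..%d", x$first[cls], x$last[cls])))
  }
  cat(sprintf("  developed span: %s..%s\n", x$developed_first,
              x$developed_last))
  invisible(x)
}

#' Classify each frame into a DSA phase
#'
#' Per-frame rules, applied with venous-over-arterial precedence (an
#' arteriovenous shunt makes venous structures appear while arteries are
#' still filled; such frames are venous):
#' * any venous class present: `late_venous` if the sinus is present,
#'   otherwise `early_venous`;
#' * artery/Willis present, no venous class: arterial; arterial frames
#'   strictly before the arterial frame of maximal summed detection-box
#'   area are `early_arterial` (vessel tree still filling), the rest
#'   `late_arterial`; ties take the earliest maximal frame as the start of
#'   the late phase;
#' * no class present: `pre_contrast` before the first present frame,
#'   `post_contrast` after the last, `capillary` between the last arterial
#'   and first venous frame; any other interior empty frame inherits the
#'   previous frame's label (robustness to single-frame detection
#'   dropouts).
#'
#' @param events [structure_events()] of the case (same `tau`).
#' @param detections The case's detection table.
#' @param tau Confidence threshold.
#' @param n_frames Total frames in the run; defaults to `max(frame) + 1`.
#' @return Character vector of per-frame phase labels (one of
#'   [dsa_phases()]), length `n_frames`.
#' @export
classify_phases <- function(events, detections, tau = 0.5, n_frames = NULL) {
  stopifnot(inherits(events, "structure_events"))
  validate_detection_table(detections)
  n_frames <- n_frames %||%
    (if (nrow(detections)) max(detections$frame) + 1L else 0L)
  if (n_frames == 0L) return(character(0))
  frames <- seq_len(n_frames) - 1L
  present <- is.na(detections$score) | detections$score >= tau
  det <- detections[present, , drop = FALSE]
  arterial_cls <- c("carotid_artery", "willis_circle")
  venous_cls <- c("vein", "venous_vessel", "venous_sinus")
  has <- function(f, classes) any(det$frame == f & det$label %in% classes)
  any_present <- vapply(frames, function(f) any(det$frame == f), logical(1))
  sinus_on <- vapply(frames, function(f) has(f, "venous_sinus"), logical(1))
  venous_on <- vapply(frames, function(f) has(f, venous_cls), logical(1))
  arterial_on <- vapply(frames, function(f) has(f, arterial_cls), logical(1)) &
    !venous_on
  ## early/late arterial split: maximal summed box area among arterial frames
  late_start <- NA_integer_
  if (any(arterial_on)) {
    area <- vapply(frames, function(f) {
      rows <- det[det$frame == f, , drop = FALSE]
      sum((rows$x_max - rows$x_min) * (rows$y_max - rows$y_min))
    }, numeric(1))
    a_frames <- frames[arterial_on]
    a_area <- area[arterial_on]
    late_start <- a_frames[which.max(a_area)]  # earliest maximal frame
  }
  first_present <- if (any(any_present)) min(frames[any_present]) else NA_integer_
  last_present <- if (any(any_present)) max(frames[any_present]) else NA_integer_
  last_arterial <- if (any(arterial_on)) max(frames[arterial_on]) else NA_integer_
  first_venous <- if (any(venous_on)) min(frames[venous_on]) else NA_integer_
  phase <- character(n_frames)
  for (i in seq_len(n_frames)) {
    f <- frames[i]
    if (venous_on[i]) {
      phase[i] <- if (sinus_on[i]) "late_venous" else "early_venous"
    } else if (arterial_on[i]) {
      phase[i] <- if (f < late_start) "early_arterial" else "late_arterial"
    } else if (is.na(first_present) || f < first_present) {
      phase[i] <- "pre_contrast"
    } else if (f > last_present) {
      phase[i] <- "post_contrast"
    } else if (!is.na(last_arterial) && !is.na(first_venous) &&
               f > last_arterial && f < first_venous) {
      phase[i] <- "capillary"
    } else {
      phase[i] <- if (i > 1L) phase[i - 1L] else "pre_contrast"
    }
  }
  phase
}

#' Five binary temporal features
#'
#' Order-of-appearance indicators of arteriovenous shunting:
#' * T1: sinus first appears at or before the last artery/Willis frame;
#' * T2: sinus first appears at or before the last Willis frame;
#' * T3: sinus first appears strictly before the venous vessels;
#' * T4: vein first appears at or before the last Willis frame;
#' * T5: the timeline contains no capillary frame.
#'
#' A comparison whose left-hand event is absent scores 0. In T3 an absent
#' right-hand event with a present sinus scores 1 (the sinus appeared,
#' venous vessels never did); absent right-hand events in T1/T2/T4 score 0.
#'
#' @param events [structure_events()] of the case.
#' @param timeline [classify_phases()] result of the same case and `tau`.
#' @return Named integer vector `c(T1..T5)` of 0/1 values.
#' @export
temporal_features <- function(events, timeline) {
  stopifnot(inherits(events, "structure_events"))
  fi <- events$first
  la <- events$last
  cmp <- function(lhs, rhs, strict = FALSE, absent_rhs = 0L) {
    if (is.na(lhs)) return(0L)
    if (is.na(rhs)) return(absent_rhs)
    as.integer(if (strict) lhs < rhs else lhs <= rhs)
  }
  art_end <- suppressWarnings(max(la["carotid_artery"], la["willis_circle"],
                                  na.rm = TRUE))
  if (!is.finite(art_end)) art_end <- NA_integer_
  c(T1 = cmp(fi[["venous_sinus"]], art_end),
    T2 = cmp(fi[["venous_sinus"]], la[["willis_circle"]]),
    T3 = cmp(fi[["venous_sinus"]], fi[["venous_vessel"]], strict = TRUE,
             absent_rhs = 1L),
    T4 = cmp(fi[["vein"]], la[["willis_circle"]]),
    T5 = as.integer(!any(timeline == "capillary")))
}

#' Select the five equal-proportion key frames
#'
#' Five frames sampled in equal proportion from the beginning to the end of
#' the developed span: `f_i = first + round(i * (last - first) / 4)` for
#' `i = 0..4`, rounding half up. Duplicate indices are permitted when the
#' developed span is short.
#'
#' With `method = "phase"` the five frames instead snap to the five named
#' phases (early arterial, late arterial, capillary, early venous, late
#' venous): the median frame of each phase, falling back to the
#' equal-proportion index for phases absent from the timeline. Whether the
#' key frames should coincide with the phases is an open modeling choice;
#' equal proportion is the default and no claim is made for either.
#'
#' @param events [structure_events()] with a developed span.
#' @param n_frames Total frames (indices are clamped to `n_frames - 1`).
#' @param method `"equal"` (default) or `"phase"`.
#' @param timeline [classify_phases()] result; required for
#'   `method = "phase"`.
#' @return Integer vector of 5 nondecreasing 0-based frame indices.
#' @export
select_key_frames <- function(events, n_frames = NULL,
                              method = c("equal", "phase"),
                              timeline = NULL) {
  stopifnot(inherits(events, "structure_events"))
  method <- match.arg(method)
  if (is.na(events$developed_first)) stop_("no contrast detected")
  a <- events$developed_first
  b <- events$developed_last
  idx <- a + round_half_up((0:4) * (b - a) / 4)
  if (method == "phase") {
    if (is.null(timeline)) stop_("method = \"phase\" requires a timeline")
    phases <- c("early_arterial", "late_arterial", "capillary",
                "early_venous", "late_venous")
    for (i in seq_along(phases)) {
      fr <- which(timeline == phases[i]) - 1L
      if (length(fr)) idx[i] <- fr[ceiling(length(fr) / 2)]
    }
    idx <- sort(idx)
  }
  if (!is.null(n_frames)) idx <- pmin(idx, n_frames - 1L)
  as.integer(idx)
}
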