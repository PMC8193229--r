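## Detection evaluation: IoU, greedy matching, all-point-interpolated
## average precision, mAP, and the reference phantom detector.

#' Intersection over union of two boxes
#'
#' Boxes are 0-based, half-open integer rectangles `c(x_min, y_min, x_max,
#' y_max)`, so areas are `(x_max - x_min) * (y_max - y_min)`.
#'
#' @param a,b Numeric vectors of length 4 (or 1-row data frames with the
#'   box columns).
#' @return IoU in `[0, 1]`; symmetric in its arguments.
#' @export
iou <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[3] - b[1]) * (b[4] - b[2])
  if (area_a <= 0 || area_b <= 0) stop_("boxes must have positive area")
  inter / (area_a + area_b - inter)
}

as_box <- function(x) {
  if (is.data.frame(x)) {
    as.numeric(x[1, c("x_min", "y_min", "x_max", "y_max")])
  } else {
    as.numeric(x[1:4])
  }
}

#' Greedy score-ordered matching of predictions to ground truth
#'
#' Predictions (one class) are processed in descending score, ties broken
#' by input order. A prediction is a true positive iff its best-IoU
#' unmatched ground-truth box on the same case and frame reaches the IoU
#' threshold; each truth box can be matched at most once.
#'
#' @param predictions Detection-table rows of one class, with scores.
#' @param truths Ground-truth rows of the same class.
#' @param iou_threshold Match threshold (default 0.5).
#' @return List with `matches` (data frame of predictions in rank order
#'   with logical `tp`) and `n_truth`.
#' @export
match_greedy <- function(predictions, truths, iou_threshold = 0.5) {
  if (nrow(predictions) && anyNA(predictions$score)) {
    stop_("predictions must carry scores")
  }
  ord <- order(-predictions$score)  # stable: ties keep input order
  pred <- predictions[ord, , drop = FALSE]
  matched <- rep(FALSE, nrow(truths))
  tp <- logical(nrow(pred))
  tkey <- if (nrow(truths)) paste(truths$case_id, truths$frame) else character(0)
  for (i in seq_len(nrow(pred))) {
    cand <- which(!matched & tkey == paste(pred$case_id[i], pred$frame[i]))
    if (length(cand) == 0L) next
    ious <- vapply(cand, function(j) iou(pred[i, ], truths[j, ]), numeric(1))
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      tp[i] <- TRUE
      matched[cand[best]] <- TRUE
    }
  }
  list(matches = cbind(pred, tp = tp), n_truth = nrow(truths))
}

#' Average precision of one structure class
#'
#' Area under the precision-recall curve with all-point interpolation: the
#' precision envelope `p(r) = max{precision at recall >= r}` is integrated
#' over the recall steps of the score-ranked prediction list.
#'
#' @param predictions,truths Detection-table rows of one class.
#' @param iou_threshold IoU match threshold (default 0.5).
#' @return AP in `[0, 1]`; `NA` (with a warning) when the class has no
#'   ground truth.
#' @export
average_precision <- function(predictions, truths, iou_threshold = 0.5) {
  if (nrow(truths) == 0L) {
    warning("class has no ground truth; AP undefined")
    return(NA_real_)
  }
  if (nrow(predictions) == 0L) return(0)
  m <- match_greedy(predictions, truths, iou_threshold)
  tp <- cumsum(m$matches$tp)
  fp <- cumsum(!m$matches$tp)
  recall <- tp / m$n_truth
  precision <- tp / (tp + fp)
  ## envelope: running max of precision from the right
  penv <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * penv)
}

#' Mean average precision over evaluated classes
#'
#' @param aps Named or unnamed numeric vector of per-class APs; `NA`
#'   entries (classes without ground truth) are excluded.
#' @return Arithmetic mean of the finite APs.
#' @export
mean_average_precision <- function(aps) {
  aps <- aps[!is.na(aps)]
  if (length(aps) == 0L) stop_("no evaluable class (all APs undefined)")
  mean(aps)
}

#' Evaluate a detection table against ground truth
#'
#' Computes per-class AP (all-point interpolation), precision-recall curve
#' points, and mAP over the classes that have ground truth.
#'
#' @param predictions Detection table with scores.
#' @param truths Ground-truth detection table (empty scores allowed).
#' @param iou_threshold IoU match threshold.
#' @return Object of class `detection_eval`: list with `ap` (named
#'   per-class vector, `NA` where no truth), `map`, `pr` (per-class data
#'   frames of recall/precision), `iou_threshold`.
#' @export
evaluate_detections <- function(predictions, truths, iou_threshold = 0.5) {
  validate_detection_table(truths)
  validate_detection_table(predictions)
  ap <- stats::setNames(rep(NA_real_, length(DSA_CLASSES)), DSA_CLASSES)
  pr <- list()
  for (cls in DSA_CLASSES) {
    p <- predictions[predictions$label == cls, , drop = FALSE]
    t <- truths[truths$label == cls, , drop = FALSE]
    if (nrow(t) == 0L) next
    ap[cls] <- average_precision(p, t, iou_threshold)
    if (nrow(p)) {
      m <- match_greedy(p, t, iou_threshold)
      tp <- cumsum(m$matches$tp); fp <- cumsum(!m$matches$tp)
      pr[[cls]] <- data.frame(recall = tp / m$n_truth,
                              precision = tp / (tp + fp))
    } else {
      pr[[cls]] <- data.frame(recall = numeric(0), precision = numeric(0))
    }
  }
  structure(list(ap = ap, map = mean_average_precision(ap), pr = pr,
                 iou_threshold = iou_threshold),
            class = "detection_eval")
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf("Detection evaluation (IoU >= %.2f)\n", x$iou_threshold))
  for (cls in names(x$ap)) {
    cat(sprintf("  %-16s AP = %s\n", cls,
                if (is.na(x$ap[cls])) "undefined (no truth)"
                else sprintf("%.4f", x$ap[cls])))
  }
  cat(sprintf("  mAP = %.4f\n", x$map))
  invisible(x)
}

#' @export
plot.detection_eval <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "Recall",
                 ylab = "Precision", main = "Precision-recall by structure")
  cols <- seq_along(x$pr)
  for (i in seq_along(x$pr)) {
    p <- x$pr[[i]]
    graphics::lines(c(0, p$recall), c(1, p$precision), col = cols[i],
                    type = "s")
  }
  graphics::legend("bottomleft", legend = names(x$pr), col = cols, lty = 1,
                   cex = 0.8)
  invisible(x)
}

#' Reference detector for phantom frame stacks
#'
#' A deterministic stand-in detector for synthetic phantoms: each frame is
#' background-subtracted (background = frame median), pixels darker than
#' the background by more than `pixel_threshold` gray levels are grouped
#' into 8-connected components, components of at least `min_area` pixels
#' become boxes, the class is assigned by the nearest canonical layout
#' anchor, and the confidence score is the component's mean contrast depth
#' normalized by the nominal rendering depth. Components nearest the nidus
#' anchor are discarded (the nidus is not one of the five structure
#' classes).
#'
#' @param stack A [frame_stack()] rendered with the phantom layout.
#' @param confidence_threshold Minimum score to report (default 0, report
#'   everything).
#' @param pixel_threshold Gray-level darkness cutoff below background.
#' @param min_area Minimum component area in pixels (suppresses noise
#'   speckle).
#' @return A detection table.
#' @export
reference_detect <- function(stack, confidence_threshold = 0,
                             pixel_threshold = 30, min_area = 12L) {
  stopifnot(inherits(stack, "frame_stack"))
  height <- nrow(stack$frames[[1]])
  width <- ncol(stack$frames[[1]])
  lay <- phantom_layout(width, height, nidus_diameter_px = 8L)
  anchors <- lay$anchors
  rows <- list()
  for (f in seq_along(stack$frames)) {
    img <- stack$frames[[f]]
    bg <- stats::median(img)
    mask <- img < (bg - pixel_threshold)
    comp <- label_components(mask)
    if (comp$n == 0L) next
    for (k in seq_len(comp$n)) {
      pix <- comp$idx[comp$label == k]
      if (length(pix) < min_area) next
      y <- ((pix - 1L) %% height)       # 0-based row
      x <- ((pix - 1L) %/% height)      # 0-based col
      cx <- mean(x); cy <- mean(y)
      d <- (anchors[, "x"] - cx)^2 + (anchors[, "y"] - cy)^2
      cls <- rownames(anchors)[which.min(d)]
      if (cls == "nidus") next
      score <- min(1, max(0, mean(bg - img[pix]) / PHANTOM_DEPTH))
      if (score < confidence_threshold) next
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = stack$case_id, frame = f - 1L, label = cls,
        x_min = min(x), y_min = min(y), x_max = max(x) + 1L,
        y_max = max(y) + 1L, score = score, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_detection_table())
  det <- do.call(rbind, rows)
  rownames(det) <- NULL
  det
}
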