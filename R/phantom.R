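## Synthetic DSA phantom generator: seeded hemodynamic schedules, rendered
## frame stacks with ground-truth boxes, and cohort generation.

PHANTOM_BACKGROUND <- 230
PHANTOM_DEPTH <- 120

#' Build a hemodynamic schedule for a synthetic DSA run
#'
#' Draws per-class onset/offset frames for the five vascular structures so
#' that the order of appearance matches the requested diagnosis. Normal
#' (non-AVM) hemodynamics fill artery, then circle of Willis, pass through a
#' vessel-free capillary gap, then veins, venous vessels and finally the
#' venous sinus. AVM hemodynamics shunt directly from artery to sinus: the
#' sinus opacifies while the artery and Willis circle are still filled,
#' before the venous vessels, and no capillary gap exists. High-grade AVM
#' schedules have an earlier sinus onset and a larger nidus than low-grade
#' ones drawn with the same seed.
#'
#' @param diagnosis `"AVM"` or `"non-AVM"`.
#' @param grade_class `"low"` (grades I-III), `"high"` (IV-V), or `"none"`.
#'   Must be `"none"` iff `diagnosis` is `"non-AVM"`.
#' @param n_frames Number of frames, between 20 and 50 (typical DSA run
#'   lengths).
#' @param rng_seed Integer seed; the schedule is deterministic given the
#'   arguments.
#' @param frame_interval_ms Frame interval in milliseconds (acquisition
#'   rates of 166-333 ms/frame are typical).
#' @return An object of class `hemodynamic_schedule`: a list with `classes`
#'   (data.frame of class, onset, offset; 0-based frame indices),
#'   `n_frames`, `frame_interval_ms`, `capillary_gap`, `nidus_diameter_px`,
#'   `diagnosis`, `grade_class` and `seed`.
#' @seealso [schedule_temporal_truth()], [render_case()]
#' @export
build_schedule <- function(diagnosis = c("AVM", "non-AVM"),
                           grade_class = c("low", "high", "none"),
                           n_frames = 30L, rng_seed = 1L,
                           frame_interval_ms = 250) {
  diagnosis <- match.arg(diagnosis)
  grade_class <- match.arg(grade_class)
  if (!is_count(n_frames) || n_frames < 20 || n_frames > 50) {
    stop_("n_frames must be an integer between 20 and 50, got %s",
          format(n_frames))
  }
  if (diagnosis == "non-AVM" && grade_class != "none") {
    stop_("grade_class must be \"none\" for non-AVM schedules")
  }
  if (diagnosis == "AVM" && grade_class == "none") {
    stop_("AVM schedules require grade_class \"low\" or \"high\"")
  }
  n <- as.integer(n_frames)
  j <- with_seed(rng_seed, list(
    a_on = sample(0:2, 1), a_off = sample(0:2, 1),
    w_on = sample(0:1, 1), w_off = sample(0:2, 1),
    gap = sample(0:1, 1),
    v_on = sample(0:1, 1), v_off = sample(0:1, 1),
    vv_on = sample(0:1, 1), vv_off = sample(0:1, 1),
    s_on = sample(0:1, 1), s_off = sample(0:1, 1),
    nidus = sample(0:6, 1)
  ))
  if (diagnosis == "non-AVM") {
    a_on <- 1L + j$a_on
    a_off <- round_half_up(0.32 * n) + j$a_off
    w_on <- a_on + j$w_on
    w_off <- a_off + j$w_off
    arterial_end <- max(a_off, w_off)
    v_on <- arterial_end + 2L + j$gap        # >= 1 empty capillary frame
    vv_on <- v_on + j$vv_on
    s_on <- vv_on + 2L + j$s_on              # sinus strictly after venous vessels
    v_off <- max(v_on, round_half_up(0.70 * n) + j$v_off)
    vv_off <- max(vv_on, round_half_up(0.78 * n) + j$vv_off)
    s_off <- max(s_on, n - 1L - j$s_off)
    capillary_gap <- TRUE
    nidus <- 0L
  } else {
    a_on <- 1L + j$a_on
    a_off <- min(round_half_up(0.50 * n) + j$a_off, n - 5L)
    w_on <- a_on + j$w_on
    w_off <- a_off + j$w_off
    span <- a_off - a_on
    frac <- if (grade_class == "high") 0.15 else 0.45
    s_on <- a_on + max(1L, round_half_up(frac * span)) + j$s_on
    v_on <- s_on + j$v_on                    # veins with (or just after) sinus
    vv_on <- s_on + 2L + j$vv_on             # sinus strictly before venous vessels
    v_off <- max(v_on, round_half_up(0.75 * n) + j$v_off)
    vv_off <- max(vv_on, round_half_up(0.85 * n) + j$vv_off)
    s_off <- n - 1L - j$s_off
    capillary_gap <- FALSE
    nidus <- if (grade_class == "high") 20L + j$nidus else 10L + (j$nidus %% 5L)
  }
  cl <- function(x) as.integer(max(0L, min(x, n - 1L)))
  classes <- data.frame(
    class = DSA_CLASSES,
    onset = c(cl(a_on), cl(w_on), cl(v_on), cl(vv_on), cl(s_on)),
    offset = c(cl(a_off), cl(w_off), cl(v_off), cl(vv_off), cl(s_off)),
    stringsAsFactors = FALSE
  )
  stopifnot(all(classes$onset <= classes$offset))
  out <- structure(list(
    classes = classes, n_frames = n,
    frame_interval_ms = frame_interval_ms,
    capillary_gap = capillary_gap, nidus_diameter_px = nidus,
    diagnosis = diagnosis, grade_class = grade_class, seed = rng_seed
  ), class = "hemodynamic_schedule")
  check_schedule_order(out)
  out
}

## Internal consistency check of the diagnosis-specific orderings.
check_schedule_order <- function(s) {
  on <- function(k) s$classes$onset[s$classes$class == k]
  off <- function(k) s$classes$offset[s$classes$class == k]
  if (s$diagnosis == "non-AVM") {
    ok <- on("venous_sinus") > off("carotid_artery") &&
      on("venous_sinus") > off("willis_circle") &&
      on("venous_sinus") > on("venous_vessel") &&
      on("vein") > off("willis_circle") && s$capillary_gap
  } else {
    ok <- on("venous_sinus") <= off("carotid_artery") &&
      on("venous_sinus") <= off("willis_circle") &&
      on("venous_sinus") < on("venous_vessel") &&
      on("vein") <= off("willis_circle") && !s$capillary_gap
  }
  if (!ok) stop_("internal error: schedule violates its ordering invariant")
  invisible(s)
}

#' Ground-truth temporal features of a schedule
#'
#' Applies the five order-of-appearance comparisons directly to the
#' scheduled onsets/offsets, with no rendering or detection involved:
#' T1 sinus onset at or before artery end, T2 at or before Willis
#' disappearance, T3 strictly before venous-vessel onset, T4 vein onset at
#' or before Willis disappearance, T5 no capillary gap.
#'
#' @param schedule A [build_schedule()] result.
#' @return Named integer vector `c(T1, T2, T3, T4, T5)` of 0/1 values.
#' @export
schedule_temporal_truth <- function(schedule) {
  stopifnot(inherits(schedule, "hemodynamic_schedule"))
  on <- function(k) schedule$classes$onset[schedule$classes$class == k]
  off <- function(k) schedule$classes$offset[schedule$classes$class == k]
  c(T1 = as.integer(on("venous_sinus") <= max(off("carotid_artery"),
                                              off("willis_circle"))),
    T2 = as.integer(on("venous_sinus") <= off("willis_circle")),
    T3 = as.integer(on("venous_sinus") < on("venous_vessel")),
    T4 = as.integer(on("vein") <= off("willis_circle")),
    T5 = as.integer(!schedule$capillary_gap))
}

## Canonical anteroposterior layout: template pixel masks and tight boxes.
## Coordinates are 0-based, boxes half-open. The nidus is an extra template
## (not one of the five structure classes).
phantom_layout <- function(width, height, nidus_diameter_px = 0L) {
  rect_mask <- function(x0, x1, y0, y1) {
    xs <- seq.int(floor(x0 * width), ceiling(x1 * width) - 1L)
    ys <- seq.int(floor(y0 * height), ceiling(y1 * height) - 1L)
    xs <- xs[xs >= 0 & xs < width]; ys <- ys[ys >= 0 & ys < height]
    list(x = rep(xs, each = length(ys)), y = rep(ys, times = length(xs)))
  }
  disc_mask <- function(cx, cy, r_out, r_in = -1) {
    xs <- 0:(width - 1L); ys <- 0:(height - 1L)
    gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
    d2 <- (gx - cx)^2 + (gy - cy)^2
    keep <- d2 <= r_out^2 & d2 > r_in^2
    list(x = gx[keep], y = gy[keep])
  }
  m <- min(width, height)
  templates <- list(
    carotid_artery = rect_mask(0.45, 0.55, 0.70, 0.95),
    willis_circle = disc_mask(0.5 * width, 0.5 * height, 0.12 * m, 0.06 * m),
    vein = rect_mask(0.33, 0.67, 0.05, 0.12),
    venous_vessel = rect_mask(0.10, 0.17, 0.10, 0.42),
    venous_sinus = rect_mask(0.80, 0.90, 0.08, 0.36)
  )
  if (nidus_diameter_px > 0) {
    templates$nidus <- disc_mask(0.75 * width, 0.68 * height,
                                 nidus_diameter_px / 2)
  }
  boxes <- lapply(templates, function(t) {
    c(x_min = min(t$x), y_min = min(t$y), x_max = max(t$x) + 1L,
      y_max = max(t$y) + 1L)
  })
  ## anchors for nearest-anchor class assignment in the reference detector
  anchors <- t(vapply(templates, function(t) c(mean(t$x), mean(t$y)),
                      numeric(2)))
  colnames(anchors) <- c("x", "y")
  ## host check: every template non-trivial and templates pairwise disjoint
  sizes <- vapply(templates, function(t) length(t$x), integer(1))
  if (any(sizes < 12L)) {
    stop_("image too small to host all structure templates")
  }
  all_idx <- unlist(lapply(templates, function(t) t$y + 1L + t$x * height))
  if (anyDuplicated(all_idx)) {
    stop_("image too small to host all structure templates without overlap")
  }
  list(templates = templates, boxes = boxes, anchors = anchors)
}

## Ramp weight: intensity ramps in over the first two active frames and out
## over the last two (0.6 at the edge frames, 1.0 inside).
ramp_weight <- function(frame, onset, offset) {
  ifelse(frame < onset | frame > offset, 0,
         ifelse(frame == onset | frame == offset, 0.6, 1))
}

#' Render a phantom DSA case from a schedule
#'
#' Draws one grayscale frame per scheduled frame on a fixed anteroposterior
#' layout (artery inferior-center, circle of Willis center, vein superior,
#' venous vessel superior-left, venous sinus superior-right, nidus blob when
#' `nidus_diameter_px > 0`). Active structures are rendered as dark
#' contrast-filled templates whose intensity ramps in over the first two
#' active frames and out over the last two; additive Gaussian noise is
#' applied per pixel and frames are quantized to 8 bits.
#'
#' @param schedule A [build_schedule()] result.
#' @param image_size Integer pair (width, height), each at least 64.
#' @param noise_sd Gaussian noise standard deviation in gray levels (>= 0).
#' @param rng_seed Integer seed; rendering is deterministic given all
#'   arguments.
#' @param case_id Case identifier stored in the frame stack and truth table.
#' @return An object of class `phantom_case`: list with `frames` (a
#'   [frame_stack()]), `truth_boxes` (ground-truth detection table, empty
#'   `score`), `truth_temporal`, `diagnosis`, `grade_class`, `schedule`,
#'   `seed`.
#' @export
render_case <- function(schedule, image_size = c(96L, 96L), noise_sd = 5,
                        rng_seed = 1L, case_id = "case") {
  stopifnot(inherits(schedule, "hemodynamic_schedule"))
  if (length(image_size) != 2L || any(image_size < 64)) {
    stop_("image_size must be two integers, each >= 64")
  }
  if (noise_sd < 0) stop_("noise_sd must be >= 0")
  width <- as.integer(image_size[1L]); height <- as.integer(image_size[2L])
  lay <- phantom_layout(width, height, schedule$nidus_diameter_px)
  n <- schedule$n_frames
  cls <- schedule$classes
  ## nidus opacifies with the shunt: from Willis onset to sinus offset
  nidus_on <- cls$onset[cls$class == "willis_circle"]
  nidus_off <- cls$offset[cls$class == "venous_sinus"]
  frames <- vector("list", n)
  rows <- list()
  with_seed(rng_seed, {
    for (f in seq_len(n) - 1L) {
      img <- matrix(PHANTOM_BACKGROUND, nrow = height, ncol = width)
      for (k in seq_len(nrow(cls))) {
        w <- ramp_weight(f, cls$onset[k], cls$offset[k])
        if (w > 0) {
          t <- lay$templates[[cls$class[k]]]
          img[cbind(t$y + 1L, t$x + 1L)] <-
            img[cbind(t$y + 1L, t$x + 1L)] - PHANTOM_DEPTH * w
          b <- lay$boxes[[cls$class[k]]]
          rows[[length(rows) + 1L]] <- data.frame(
            case_id = case_id, frame = f, label = cls$class[k],
            x_min = b[["x_min"]], y_min = b[["y_min"]],
            x_max = b[["x_max"]], y_max = b[["y_max"]],
            score = NA_real_, stringsAsFactors = FALSE)
        }
      }
      if (!is.null(lay$templates$nidus)) {
        w <- ramp_weight(f, nidus_on, nidus_off)
        if (w > 0) {
          t <- lay$templates$nidus
          img[cbind(t$y + 1L, t$x + 1L)] <-
            img[cbind(t$y + 1L, t$x + 1L)] - PHANTOM_DEPTH * w
        }
      }
      if (noise_sd > 0) {
        img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                            nrow = height)
      }
      frames[[f + 1L]] <- matrix(as.integer(pmax(0, pmin(255,
                                                         round(img)))),
                                 nrow = height)
    }
  })
  truth <- if (length(rows)) do.call(rbind, rows) else empty_detection_table()
  structure(list(
    frames = frame_stack(frames, case_id = case_id,
                         frame_interval_ms = schedule$frame_interval_ms),
    truth_boxes = truth,
    truth_temporal = schedule_temporal_truth(schedule),
    diagnosis = schedule$diagnosis, grade_class = schedule$grade_class,
    schedule = schedule, seed = rng_seed
  ), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("DSA phantom case '%s': %s (%s grade), %d frames %dx%d, %d truth boxes\n",
              x$frames$case_id, x$diagnosis, x$grade_class,
              x$schedule$n_frames, ncol(x$frames$frames[[1]]),
              nrow(x$frames$frames[[1]]), nrow(x$truth_boxes)))
  invisible(x)
}

#' @export
print.hemodynamic_schedule <- function(x, ...) {
  cat(sprintf("Hemodynamic schedule: %s (%s), %d frames @ %.0f ms, capillary gap: %s\n",
              x$diagnosis, x$grade_class, x$n_frames, x$frame_interval_ms,
              x$capillary_gap))
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' Generate a synthetic DSA cohort on disk
#'
#' Builds `n_cases` seeded phantom cases (AVM and non-AVM in the requested
#' proportions; `round(n * fraction)`, rounding half up) with frame counts
#' drawn uniformly in `n_frames_range` and frame intervals uniform in
#' 166-333 ms, and writes per-case frame directories of 8-bit grayscale
#' PNGs, a combined ground-truth detection table, a case label table and a
#' manifest.
#'
#' @param n_cases Number of cases (>= 2).
#' @param avm_fraction Fraction of AVM cases in `[0, 1]`.
#' @param high_grade_fraction Fraction of AVM cases that are high grade.
#' @param rng_seed Integer seed controlling all per-case seeds.
#' @param out_dir Output directory (created if missing).
#' @param image_size,noise_sd Passed to [render_case()].
#' @param n_frames_range Integer range for per-case frame counts.
#' @return The manifest data.frame (invisibly): case_id, seed, diagnosis,
#'   grade_class, n_frames, frame_interval_ms, noise_sd and truth T1-T5.
#'   Files written: `frames/<case_id>/frame_%04d.png`, `truth_boxes.csv`,
#'   `labels.csv`, `manifest.csv`.
#' @export
generate_cohort <- function(n_cases, avm_fraction, high_grade_fraction = 0.5,
                            rng_seed = 1L, out_dir,
                            image_size = c(96L, 96L), noise_sd = 5,
                            n_frames_range = c(20L, 50L)) {
  if (!is_count(n_cases) || n_cases < 2) stop_("n_cases must be >= 2")
  stopifnot(avm_fraction >= 0, avm_fraction <= 1,
            high_grade_fraction >= 0, high_grade_fraction <= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_("cannot create output directory %s", out_dir)
  n_avm <- round_half_up(n_cases * avm_fraction)
  n_high <- round_half_up(n_avm * high_grade_fraction)
  diagnosis <- c(rep("AVM", n_avm), rep("non-AVM", n_cases - n_avm))
  grade <- c(rep("high", n_high), rep("low", n_avm - n_high),
             rep("none", n_cases - n_avm))
  draws <- with_seed(rng_seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n_cases),
    n_frames = sample(seq.int(n_frames_range[1], n_frames_range[2]),
                      n_cases, replace = TRUE),
    interval = round(stats::runif(n_cases, 166, 333), 1),
    order = sample.int(n_cases)
  ))
  diagnosis <- diagnosis[draws$order]
  grade <- grade[draws$order]
  ids <- sprintf("case_%04d", seq_len(n_cases))
  frames_dir <- file.path(out_dir, "frames")
  dir.create(frames_dir, showWarnings = FALSE)
  truth_all <- vector("list", n_cases)
  tmat <- matrix(NA_integer_, n_cases, 5,
                 dimnames = list(NULL, paste0("T", 1:5)))
  for (i in seq_len(n_cases)) {
    sched <- build_schedule(diagnosis[i], grade[i],
                            n_frames = draws$n_frames[i],
                            rng_seed = draws$seeds[i],
                            frame_interval_ms = draws$interval[i])
    case <- render_case(sched, image_size = image_size, noise_sd = noise_sd,
                        rng_seed = draws$seeds[i], case_id = ids[i])
    case_dir <- file.path(frames_dir, ids[i])
    dir.create(case_dir, showWarnings = FALSE)
    for (f in seq_along(case$frames$frames)) {
      png::writePNG(case$frames$frames[[f]] / 255,
                    file.path(case_dir, sprintf("frame_%04d.png", f - 1L)))
    }
    truth_all[[i]] <- case$truth_boxes
    tmat[i, ] <- case$truth_temporal
  }
  manifest <- data.frame(
    case_id = ids, seed = draws$seeds, diagnosis = diagnosis,
    grade_class = grade, n_frames = draws$n_frames,
    frame_interval_ms = draws$interval, noise_sd = noise_sd,
    stringsAsFactors = FALSE)
  manifest <- cbind(manifest, as.data.frame(tmat))
  write_detection_table(do.call(rbind, truth_all),
                        file.path(out_dir, "truth_boxes.csv"))
  utils::write.csv(manifest[, c("case_id", "diagnosis", "grade_class")],
                   file.path(out_dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
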