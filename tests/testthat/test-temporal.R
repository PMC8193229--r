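test_that("structure events apply the confidence threshold", {
  det <- det_rows(
    det_row(3, "vein", c(0, 0, 5, 5), 0.9),
    det_row(4, "vein", c(0, 0, 5, 5), 0.8),
    det_row(7, "vein", c(0, 0, 5, 5), 0.95),
    det_row(2, "venous_sinus", c(0, 0, 5, 5), 0.4),
    det_row(5, "venous_sinus", c(0, 0, 5, 5), 0.6),
    det_row(1, "carotid_artery", c(0, 0, 5, 5), 0.3)
  )
  ev <- structure_events(det, tau = 0.5)
  expect_equal(unname(ev$first["vein"]), 3)
  expect_equal(unname(ev$last["vein"]), 7)
  # sub-threshold frames are excluded: sinus present only at frame 5
  expect_equal(unname(ev$first["venous_sinus"]), 5)
  expect_equal(unname(ev$last["venous_sinus"]), 5)
  # class never above threshold -> absent
  expect_true(is.na(ev$first["carotid_artery"]))
  # developed span counts any detection row
  expect_equal(ev$developed_first, 1)
  expect_equal(ev$developed_last, 7)
  # ground-truth rows (empty score) always count as present
  ev2 <- structure_events(det_row(2, "vein", c(0, 0, 5, 5)), tau = 0.5)
  expect_equal(unname(ev2$first["vein"]), 2)
})

test_that("phase rules label the canonical toy sequence", {
  # frames 0-2 partial arterial, 3-4 full, 5 empty, 6-7 vein, 8-9 vein+sinus
  rows <- list()
  for (f in 0:4) {
    grow <- if (f < 3) 4 + f else 10  # box area grows until complete at 3
    rows <- c(rows, list(
      det_row(f, "carotid_artery", c(0, 0, grow, 10), 0.9),
      det_row(f, "willis_circle", c(20, 20, 20 + grow, 30), 0.9)))
  }
  for (f in 6:9) rows <- c(rows, list(det_row(f, "vein", c(0, 0, 8, 8), 0.9)))
  for (f in 8:9) rows <- c(rows, list(det_row(f, "venous_sinus", c(12, 0, 20, 8), 0.9)))
  det <- do.call(rbind, rows)
  ev <- structure_events(det)
  tl <- classify_phases(ev, det, n_frames = 10)
  expect_equal(tl, c("early_arterial", "early_arterial", "early_arterial",
                     "late_arterial", "late_arterial", "capillary",
                     "early_venous", "early_venous", "late_venous",
                     "late_venous"))
  expect_equal(unname(temporal_features(ev, tl)), c(0, 0, 1, 0, 0))
})

test_that("no detections gives an all pre-contrast timeline", {
  det <- empty_det <- det_row(0, "vein", c(0, 0, 1, 1), 0.9)[0, ]
  ev <- structure_events(det)
  expect_equal(classify_phases(ev, det, n_frames = 5), rep("pre_contrast", 5))
})

test_that("venous precedence removes the capillary phase in shunting cases", {
  case <- phantom_fixture("AVM", seed = 13)
  det <- reference_detect(case$frames)
  ev <- structure_events(det)
  tl <- classify_phases(ev, det, n_frames = case$schedule$n_frames)
  s_on <- case$schedule$classes$onset[
    case$schedule$classes$class == "venous_sinus"]
  a_off <- case$schedule$classes$offset[
    case$schedule$classes$class == "carotid_artery"]
  # sinus frames during arterial filling are labeled venous
  expect_true(all(tl[(s_on + 1):(a_off + 1)] == "late_venous"))
  expect_false(any(tl == "capillary"))
  expect_equal(unname(temporal_features(ev, tl)), c(1, 1, 1, 1, 1))
})

test_that("temporal feature comparisons handle worked and absent-event cases", {
  mk_events <- function(first, last) {
    structure(list(first = first, last = last,
                   developed_first = min(first, na.rm = TRUE),
                   developed_last = max(last, na.rm = TRUE), tau = 0.5),
              class = "structure_events")
  }
  nm <- dsa_classes()
  # artery.last 14, willis.last 15, vein.first 20, venous_vessel.first 22,
  # sinus.first 10; a capillary frame exists
  ev <- mk_events(
    stats::setNames(c(2, 3, 20, 22, 10), nm),
    stats::setNames(c(14, 15, 25, 26, 27), nm))
  tl <- c(rep("late_arterial", 16), "capillary", rep("late_venous", 11))
  expect_equal(unname(temporal_features(ev, tl)), c(1, 1, 1, 0, 0))
  # sinus never present: T1-T3 are 0 regardless of the right-hand side
  ev2 <- mk_events(
    stats::setNames(c(2, 3, 8, 9, NA), nm),
    stats::setNames(c(14, 15, 25, 26, NA), nm))
  expect_equal(unname(temporal_features(ev2, tl)), c(0, 0, 0, 1, 0))
  # sinus present but venous vessels never appear: T3 = 1
  ev3 <- mk_events(
    stats::setNames(c(2, 3, 20, NA, 10), nm),
    stats::setNames(c(14, 15, 25, NA, 27), nm))
  expect_equal(unname(temporal_features(ev3, tl))[3], 1)
})

test_that("key frames are sampled in equal proportion with half-up rounding", {
  mk <- function(a, b) {
    structure(list(first = c(vein = a), last = c(vein = b),
                   developed_first = a, developed_last = b, tau = 0.5),
              class = "structure_events")
  }
  expect_equal(select_key_frames(mk(3, 43)), c(3, 13, 23, 33, 43))
  expect_equal(select_key_frames(mk(0, 2)), c(0, 1, 1, 2, 2))
  expect_equal(select_key_frames(mk(7, 7)), rep(7, 5))
  empty <- structure(list(first = c(vein = NA), last = c(vein = NA),
                          developed_first = NA_integer_,
                          developed_last = NA_integer_, tau = 0.5),
                     class = "structure_events")
  expect_error(select_key_frames(empty), "no contrast")
})

test_that("key frames ignore detections outside the developed span", {
  base <- det_rows(det_row(10, "vein", c(0, 0, 5, 5), 0.9),
                   det_row(30, "vein", c(0, 0, 5, 5), 0.9))
  k1 <- select_key_frames(structure_events(base))
  expect_equal(k1, c(10, 15, 20, 25, 30))
})

test_that("phase-snapped key frames land inside their phases when present", {
  case <- phantom_fixture("non-AVM", seed = 25)
  det <- reference_detect(case$frames)
  ev <- structure_events(det)
  n <- case$schedule$n_frames
  tl <- classify_phases(ev, det, n_frames = n)
  kf <- select_key_frames(ev, n, method = "phase", timeline = tl)
  expect_length(kf, 5)
  expect_true(all(diff(kf) >= 0))
  # the capillary slot falls on a capillary frame (the phase exists here)
  expect_true(any(tl[kf + 1] == "capillary"))
  expect_error(select_key_frames(ev, n, method = "phase"), "timeline")
})

test_that("a single-frame detection dropout only perturbs that frame's label", {
  case <- phantom_fixture("non-AVM", seed = 23)
  det <- reference_detect(case$frames)
  ev <- structure_events(det)
  n <- case$schedule$n_frames
  tl <- classify_phases(ev, det, n_frames = n)
  # drop all detections on a mid-arterial frame that is not the area maximum
  sched <- case$schedule$classes
  f_drop <- sched$onset[sched$class == "carotid_artery"] + 3
  det2 <- det[det$frame != f_drop, ]
  ev2 <- structure_events(det2)
  tl2 <- classify_phases(ev2, det2, n_frames = n)
  expect_equal(tl2[-(f_drop + 1)], tl[-(f_drop + 1)])
  # and the temporal features still match the generator's truth
  expect_equal(unname(temporal_features(ev2, tl2)),
               unname(case$truth_temporal))
})
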