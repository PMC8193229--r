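test_that("IoU follows half-open box arithmetic", {
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1.0)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 50 / 150)
  expect_equal(iou(c(0, 0, 10, 10), c(10, 0, 20, 10)), 0)  # touching = disjoint
  # symmetry and range over random boxes
  set.seed(42)
  for (i in 1:100) {
    a <- random_box(); b <- random_box()
    v <- iou(a, b)
    expect_identical(v, iou(b, a))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("greedy matching honors score order and single-match rule", {
  truth <- det_row(0, "vein", c(0, 0, 10, 10))
  preds <- det_rows(
    det_row(0, "vein", c(0, 0, 10, 9), 0.8),
    det_row(0, "vein", c(0, 0, 10, 10), 0.9)
  )
  m <- match_greedy(preds, truth, 0.5)
  expect_equal(m$matches$score, c(0.9, 0.8))  # descending score
  expect_equal(m$matches$tp, c(TRUE, FALSE))  # second overlap is FP

  # prediction on a frame with no truth is FP
  m2 <- match_greedy(det_row(5, "vein", c(0, 0, 10, 10), 0.7), truth, 0.5)
  expect_false(any(m2$matches$tp))

  # strict threshold: IoU just under the cutoff fails
  near <- det_row(0, "vein", c(0, 0, 10, 5), 0.9)  # IoU = 0.5 exactly
  below <- det_row(0, "vein", c(0, 0, 10, 4), 0.9) # IoU = 0.4
  expect_true(match_greedy(near, truth, 0.5)$matches$tp)
  expect_false(match_greedy(below, truth, 0.5)$matches$tp)
})

test_that("average precision matches the worked envelope example", {
  # 2 truths; ranked predictions TP, FP, TP -> AP = 0.5*1 + 0.5*(2/3)
  truths <- det_rows(det_row(0, "vein", c(0, 0, 10, 10)),
                     det_row(1, "vein", c(0, 0, 10, 10)))
  preds <- det_rows(
    det_row(0, "vein", c(0, 0, 10, 10), 0.9),   # TP
    det_row(2, "vein", c(0, 0, 10, 10), 0.8),   # FP (no truth on frame 2)
    det_row(1, "vein", c(0, 0, 10, 10), 0.7)    # TP
  )
  expect_equal(average_precision(preds, truths, 0.5), 0.5 + 0.5 * 2 / 3)
  # predictions identical to truths -> AP 1; all FP -> AP 0
  ident <- truths; ident$score <- 1.0
  expect_equal(average_precision(ident, truths, 0.5), 1.0)
  miss <- det_row(7, "vein", c(0, 0, 5, 5), 0.9)
  expect_equal(average_precision(miss, truths, 0.5), 0)
})

test_that("AP equals brute-force envelope enumeration on random instances", {
  set.seed(7)
  for (i in 1:200) {
    n_truth <- sample(1:4, 1)
    n_pred <- sample(1:6, 1)
    truths <- do.call(rbind, lapply(seq_len(n_truth), function(k)
      det_row(k - 1, "vein", c(0, 0, 10, 10))))
    preds <- do.call(rbind, lapply(seq_len(n_pred), function(k)
      det_row(sample(0:(n_truth + 1), 1), "vein", random_box(20, 20),
              round(stats::runif(1), 3))))
    ap <- average_precision(preds, truths, 0.5)
    m <- match_greedy(preds, truths, 0.5)
    expect_equal(ap, ap_oracle(m$matches$tp, n_truth), tolerance = 1e-9)
  }
})

test_that("AP is invariant to uniform score rescaling", {
  set.seed(8)
  truths <- do.call(rbind, lapply(0:2, function(f)
    det_row(f, "vein", c(0, 0, 10, 10))))
  preds <- do.call(rbind, lapply(0:4, function(k)
    det_row(sample(0:3, 1), "vein", random_box(15, 15), stats::runif(1))))
  a1 <- average_precision(preds, truths, 0.5)
  preds$score <- preds$score * 0.37
  expect_equal(average_precision(preds, truths, 0.5), a1)
})

test_that("mAP is the mean over classes with ground truth", {
  expect_equal(mean_average_precision(c(1.0, 0.5)), 0.75)
  expect_equal(mean_average_precision(c(a = 0.7)), 0.7)
  expect_equal(mean_average_precision(c(1, 1, 1, 1, 1)), 1.0)
  expect_equal(mean_average_precision(c(0.2, NA, 0.8)), 0.5)
  expect_error(mean_average_precision(c(NA_real_, NA_real_)), "no evaluable")
})

test_that("reference detector recovers phantom truth exactly without noise", {
  case <- phantom_fixture("non-AVM", seed = 21)
  det <- reference_detect(case$frames)
  # capillary-gap frame yields no detections
  active <- unique(case$truth_boxes$frame)
  gap <- setdiff(seq(min(active), max(active)), active)
  expect_true(all(!det$frame %in% gap))
  # arterial frame: exactly the artery + Willis boxes, IoU >= 0.9 vs truth
  sched <- case$schedule$classes
  f_art <- sched$onset[sched$class == "willis_circle"] + 2
  d_art <- det[det$frame == f_art, ]
  expect_setequal(d_art$label, c("carotid_artery", "willis_circle"))
  for (k in seq_len(nrow(d_art))) {
    tr <- case$truth_boxes[case$truth_boxes$frame == f_art &
                           case$truth_boxes$label == d_art$label[k], ]
    expect_gte(iou(d_art[k, ], tr), 0.9)
  }
  # full-case evaluation against own truth: per-class AP 1.0
  ev <- evaluate_detections(det, case$truth_boxes)
  expect_equal(unname(ev$ap), rep(1, 5))
  expect_equal(ev$map, 1.0)
  expect_gte(min(ev$ap), ev$map - 1e-12)  # mAP within [min AP, max AP]
  expect_lte(ev$map, max(ev$ap) + 1e-12)
})
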