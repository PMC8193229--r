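test_that("schedules satisfy the diagnosis-specific appearance orderings", {
  s_avm <- build_schedule("AVM", "low", 30, rng_seed = 1)
  s_nor <- build_schedule("non-AVM", "none", 30, rng_seed = 1)
  expect_equal(unname(schedule_temporal_truth(s_avm)), c(1, 1, 1, 1, 1))
  expect_equal(unname(schedule_temporal_truth(s_nor)), c(0, 0, 0, 0, 0))
  # deterministic for fixed arguments
  expect_identical(s_avm, build_schedule("AVM", "low", 30, rng_seed = 1))
  # high grade: earlier sinus onset and larger nidus than low, same seed
  for (seed in 1:20) {
    lo <- build_schedule("AVM", "low", 40, rng_seed = seed)
    hi <- build_schedule("AVM", "high", 40, rng_seed = seed)
    on <- function(s) s$classes$onset[s$classes$class == "venous_sinus"]
    expect_lt(on(hi), on(lo))
    expect_gt(hi$nidus_diameter_px, lo$nidus_diameter_px)
  }
})

test_that("schedule preconditions are enforced", {
  expect_error(build_schedule("AVM", "low", 10, rng_seed = 1), "20 and 50")
  expect_error(build_schedule("AVM", "low", 51, rng_seed = 1), "20 and 50")
  expect_error(build_schedule("non-AVM", "low", 30, rng_seed = 1), "none")
  expect_error(build_schedule("AVM", "none", 30, rng_seed = 1), "grade")
})

test_that("orderings hold across many seeds and frame counts", {
  for (seed in 1:1000) {
    n <- 20L + (seed %% 31L)
    # build_schedule self-checks its ordering invariant and errors on violation
    expect_silent(build_schedule("AVM", c("low", "high")[1 + seed %% 2], n,
                                 rng_seed = seed))
    expect_silent(build_schedule("non-AVM", "none", n, rng_seed = seed))
  }
})

test_that("rendering is deterministic and honors the schedule", {
  sched <- build_schedule("non-AVM", "none", 25, rng_seed = 3)
  a <- render_case(sched, noise_sd = 4, rng_seed = 5)
  b <- render_case(sched, noise_sd = 4, rng_seed = 5)
  expect_identical(a$frames$frames, b$frames$frames)
  expect_equal(length(a$frames$frames), 25)

  clean <- render_case(sched, noise_sd = 0, rng_seed = 5)
  # capillary-gap frames contain only background
  active <- unique(clean$truth_boxes$frame)
  gap <- setdiff(0:24, active)
  gap <- gap[gap > min(active) & gap < max(active)]
  expect_gt(length(gap), 0)
  for (f in gap) {
    expect_equal(length(unique(as.vector(clean$frames$frames[[f + 1]]))), 1)
  }
  # truth boxes exactly on frames within each class's [onset, offset]
  for (k in seq_len(nrow(sched$classes))) {
    cls <- sched$classes$class[k]
    fr <- sort(clean$truth_boxes$frame[clean$truth_boxes$label == cls])
    expect_equal(fr, seq(sched$classes$onset[k], sched$classes$offset[k]))
  }
  # every truth box lies within frame bounds
  tb <- clean$truth_boxes
  expect_true(all(tb$x_min >= 0 & tb$y_min >= 0 &
                  tb$x_max <= 96 & tb$y_max <= 96))
})

test_that("rendering rejects images too small to host the layout", {
  sched <- build_schedule("AVM", "high", 25, rng_seed = 1)
  expect_error(render_case(sched, image_size = c(32, 32)), "64")
})

test_that("cohort generation produces the requested class counts", {
  dir_a <- file.path(tempdir(), "coh-a")
  m <- generate_cohort(10, 1.0, 0.5, rng_seed = 1, out_dir = dir_a,
                       n_frames_range = c(20, 22))
  expect_equal(sum(m$diagnosis == "AVM"), 10)
  expect_equal(sum(m$grade_class == "high"), 5)
  expect_equal(sum(m$grade_class == "low"), 5)

  dir_b <- file.path(tempdir(), "coh-b")
  m2 <- generate_cohort(10, 0.0, 0.5, rng_seed = 1, out_dir = dir_b,
                        n_frames_range = c(20, 22))
  expect_equal(sum(m2$diagnosis == "AVM"), 0)
  expect_true(all(m2$grade_class == "none"))

  # files exist and round-trip: frames, truth boxes, manifest
  expect_true(file.exists(file.path(dir_a, "truth_boxes.csv")))
  expect_true(file.exists(file.path(dir_a, "labels.csv")))
  stack <- read_frame_stack(file.path(dir_a, "frames", m$case_id[1]))
  expect_equal(length(stack$frames), m$n_frames[1])
  unlink(c(dir_a, dir_b), recursive = TRUE)
})
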