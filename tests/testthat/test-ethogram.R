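test_that("corrected velocity follows the calibration identity", {
  # a displacement equal to the correction factor maps to velocity 1
  expect_equal(corrected_velocity(0.0042, dt = 1, fps = 1), 1.0)
  expect_equal(corrected_velocity(0), 0)
  expect_equal(corrected_velocity(0.25), 0.25 / 0.0042, tolerance = 1e-12)
  expect_equal(corrected_velocity(c(0, 0.0042)), c(0, 1))
  expect_error(corrected_velocity(-1), ">= 0")
  expect_error(corrected_velocity(1, dt = 0), "dt")
})

test_that("interval annotation applies the 0.25 mm rule per 10-s window", {
  # all displacements below threshold: immobile everywhere
  tr <- track_from_displacements(rep(0.1, 29))
  ann <- annotate_intervals(tr, fps = 1)
  expect_true(all(!ann$moving))
  expect_equal(nrow(ann), 3)

  # a single 0.30 mm step makes exactly its window moving
  disp <- rep(0.1, 29)
  disp[15] <- 0.30
  ann2 <- annotate_intervals(track_from_displacements(disp), fps = 1)
  expect_identical(ann2$moving, c(FALSE, TRUE, FALSE))
  expect_equal(ann2$max_displacement[2], 0.30)

  # the rule is "less than 0.25 mm" for immobility: 0.25 itself moves
  disp3 <- rep(0.1, 30)
  disp3[5] <- 0.25
  ann3 <- annotate_intervals(track_from_displacements(disp3), fps = 1)
  expect_true(ann3$moving[1])
})

test_that("gaps longer than one interval are marked missing", {
  tr <- track_from_displacements(rep(0.1, 50))
  tr <- tr[t < 10 | t >= 40] # remove three windows of frames
  ann <- annotate_intervals(tr, fps = 1)
  expect_true(any(ann$missing_interval))
  expect_true(all(ann[missing_interval == TRUE]$n_frames == 0))
  expect_false(any(ann[missing_interval == TRUE]$moving))
})

test_that("regular and irregular recordings annotate identically", {
  set.seed(13)
  disp <- runif(199, 0, 0.5)
  tr <- track_from_displacements(disp) # regular: vectorized path
  ann_fast <- annotate_intervals(tr, fps = 1)
  # appending one frame breaks the uniform window size: generic path
  extra <- data.table(
    fly_id = "f1", genotype = "g", t = 200, x = tr$x[200], y = 0
  )
  ann_slow <- annotate_intervals(rbind(tr, extra), fps = 1)[1:20]
  expect_equal(ann_fast$moving, ann_slow$moving)
  expect_equal(ann_fast$max_displacement, ann_slow$max_displacement)
  expect_equal(ann_fast$sum_displacement, ann_slow$sum_displacement)
  expect_equal(ann_fast$n_frames, ann_slow$n_frames)
})

test_that("annotation is invariant to rigid translation and reflection", {
  set.seed(42)
  disp <- runif(120, 0, 0.6)
  tr <- track_from_displacements(disp)
  ann <- annotate_intervals(tr, fps = 1)
  shifted <- copy(tr)[, `:=`(x = x + 17.3, y = y - 2)]
  reflected <- copy(tr)[, x := -x]
  expect_equal(
    annotate_intervals(shifted, fps = 1)$moving, ann$moving
  )
  expect_equal(
    annotate_intervals(reflected, fps = 1)$max_displacement,
    ann$max_displacement
  )
})

test_that("the 5-min rule counts bouts including their first five minutes", {
  # 330 s immobile: one bout of 330 s with all 33 windows asleep
  immob <- c(rep(FALSE, 3), rep(TRUE, 33), rep(FALSE, 3))
  sc <- score_sleep(annotations_from_immobility(immob))
  expect_equal(nrow(sc$bouts), 1)
  expect_equal(sc$bouts$duration, 330)
  expect_equal(sum(sc$annotations$asleep), 33)

  # 290 s: below the rule, no sleep at all
  immob2 <- c(rep(FALSE, 3), rep(TRUE, 29), rep(FALSE, 3))
  sc2 <- score_sleep(annotations_from_immobility(immob2))
  expect_equal(nrow(sc2$bouts), 0)
  expect_false(any(sc2$annotations$asleep))

  # exactly 300 s is not "longer than 5 min"
  immob3 <- c(rep(FALSE, 2), rep(TRUE, 30), rep(FALSE, 2))
  expect_equal(nrow(score_sleep(annotations_from_immobility(immob3))$bouts), 0)

  # two 400-s runs separated by one moving window: two bouts
  immob4 <- c(rep(TRUE, 40), FALSE, rep(TRUE, 40))
  sc4 <- score_sleep(annotations_from_immobility(immob4))
  expect_equal(sc4$bouts$duration, c(400, 400))
})

test_that("sleep intervals are a subset of immobile intervals", {
  set.seed(9)
  immob <- runif(500) < 0.7
  sc <- score_sleep(annotations_from_immobility(immob))
  ann <- sc$annotations
  expect_true(all(!ann$moving[ann$asleep]))
  expect_equal(sum(ann$asleep) * 10, sum(sc$bouts$duration))
})

test_that("death is a terminal immobility run of at least 24 h", {
  n_day <- 8640 # 10-s windows per day
  # immobile for the final 30 h of a 3-day record
  immob <- c(rep(FALSE, 3 * n_day - 10800), rep(TRUE, 10800))
  qc <- detect_death(annotations_from_immobility(immob))
  expect_true(qc$dead)
  expect_equal(qc$death_onset, (3 * n_day - 10800) * 10)
  expect_true(all(c(1L, 2L, 3L) %in% qc$excluded_days[[1]]))

  # moving during the final hour: alive
  immob2 <- c(rep(TRUE, 2 * n_day), rep(FALSE, 360))
  qc2 <- detect_death(annotations_from_immobility(immob2))
  expect_false(qc2$dead)
  expect_identical(qc2$excluded_days[[1]], 1L)

  # only 10 h terminal immobility: alive under the 24-h window
  immob3 <- c(rep(FALSE, 2 * n_day - 3600), rep(TRUE, 3600))
  expect_false(detect_death(annotations_from_immobility(immob3))$dead)
})

test_that("latency is measured from lights-off to the longest bout", {
  # two days; day 1 is excluded. Night 2: single bout starting ZT13.
  n_day <- 8640
  immob <- rep(FALSE, 2 * n_day)
  zt13_idx <- n_day + 13 * 360 # ZT13 of day 2 in 10-s windows
  immob[(zt13_idx + 1):(zt13_idx + 60)] <- TRUE # 600-s bout
  sc <- score_sleep(annotations_from_immobility(immob))
  f <- extract_features(sc$annotations, sc$bouts)
  expect_equal(f$latency_longest_bout, 60)
  expect_equal(f$n_bouts_night, 1)
  expect_equal(f$mean_bout_length_night, 10)
})

test_that("an always-immobile fly has full sleep and zero latency", {
  n_day <- 8640
  immob <- rep(TRUE, 2 * n_day)
  sc <- score_sleep(annotations_from_immobility(immob))
  qc <- detect_death(sc$annotations)
  # the terminal run triggers the death rule by construction; features on
  # day 2 require keeping it, so pass an alive QC result explicitly
  qc$dead <- FALSE
  qc$excluded_days <- list(1L)
  f <- extract_features(sc$annotations, sc$bouts, qc)
  expect_equal(f$sleep_fraction_day, 1)
  expect_equal(f$sleep_fraction_night, 1)
  expect_equal(f$n_bouts_night, 1)
  expect_equal(f$latency_longest_bout, 0)
})

test_that("morning anticipation indexes the pre-dawn activity ramp", {
  n_day <- 8640
  base <- rep(TRUE, 2 * n_day) # immobile everywhere by default
  mk <- function(active_idx) {
    immob <- base
    immob[active_idx] <- FALSE
    ann <- annotations_from_immobility(immob)
    morning_anticipation(ann)$morning_anticipation
  }
  night2 <- n_day + (12 * 360 + 1):(24 * 360) # ZT12-ZT24 of day 2
  # uniform activity through the night: ratio 0.5
  expect_equal(mk(night2), 0.5)
  # all late-night activity inside the final 3 h: ratio 1
  last3 <- n_day + (21 * 360 + 1):(24 * 360)
  expect_equal(mk(last3), 1.0)
  # linear ramp from 0 at ZT18 to max at ZT24: 0.75
  last6 <- n_day + (18 * 360 + 1):(24 * 360)
  ramp <- rep(seq_along(last6) / length(last6), 1)
  set.seed(2)
  act <- last6[runif(length(last6)) < ramp]
  expect_equal(mk(act), 0.75, tolerance = 0.03)
})

test_that("flies with zero retained days are dropped with a message", {
  n_day <- 8640
  immob <- rep(FALSE, n_day) # single day only, always excluded
  sc <- score_sleep(annotations_from_immobility(immob))
  expect_message(
    f <- extract_features(sc$annotations, sc$bouts),
    "zero retained days"
  )
  expect_equal(nrow(f), 0)
})
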