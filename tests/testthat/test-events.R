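# Helpers to build synthetic sample tables in degrees along the x axis.
deg_samples <- function(theta_x_deg, participant = "p1", trial = 1L,
                        valid = TRUE) {
  scr <- screen_geometry()
  # Invert the gaze-angle convention (angle from screen centre).
  x <- scr$width_px / 2 +
    tan(theta_x_deg * pi / 180) * scr$distance_mm * scr$width_px / scr$width_mm
  tibble::tibble(participant = participant, trial = trial,
                 t_ms = seq_along(theta_x_deg) - 1,
                 x_px = x, y_px = scr$height_px / 2,
                 valid = rep(valid, length.out = length(theta_x_deg)))
}

test_that("kinematics recover a linear sweep and are zero for stationary gaze", {
  s <- deg_samples(rep(1, 300))
  kin <- compute_kinematics(s)
  expect_true(all(abs(kin$vel) < 1e-9))
  # 1 degree per 10 ms = 100 deg/s.
  s2 <- deg_samples(0.1 * (0:249))
  kin2 <- compute_kinematics(s2)
  mid <- 50:200
  expect_equal(mean(kin2$vel[mid]), 100, tolerance = 0.01)
  # Invalid samples yield invalid kinematics.
  s3 <- deg_samples(rep(0, 100), valid = c(rep(TRUE, 50), rep(FALSE, 10),
                                           rep(TRUE, 40)))
  kin3 <- compute_kinematics(s3)
  expect_true(all(is.na(kin3$vel[51:60])))
})

test_that("threshold logic classifies sweeps, fixations and sub-motion jitter", {
  # Constant 50 deg/s sweep covering 1 degree: one saccade.
  sweep1 <- c(rep(0, 200), seq(0, 1, length.out = 21)[-1], rep(1, 200))
  ev <- detect_events(deg_samples(sweep1))
  expect_equal(sum(ev$kind == "saccade"), 1)
  expect_equal(ev$amplitude_deg[ev$kind == "saccade"], 1, tolerance = 0.05)
  # Everything sub-threshold: a single fixation.
  ev2 <- detect_events(deg_samples(rep(0.3, 400)))
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$kind, "fixation")
  expect_equal(ev2$duration_ms, 400)
  # Supra-threshold jitter with 0.05 degree displacement: motion threshold
  # suppresses the saccade.
  jitter <- c(rep(0, 100), rep(c(0, 0.05), 30), rep(0.05, 100))
  ev3 <- detect_events(deg_samples(jitter))
  expect_equal(sum(ev3$kind == "saccade"), 0)
})

test_that("events partition each trial's timeline exactly", {
  co <- small_cohort("exp1", 1, seed = 301, n_trials = 30)
  s <- inject_artifacts(co$samples, loss_rate = 0.05, blink_rate = 0.3,
                        seed = 4)
  ev <- detect_events(s, screen = roi_screen(co$rois))
  by_trial <- split(ev, ev$trial)
  for (tr in by_trial) {
    tr <- tr[order(tr$onset_ms), ]
    expect_equal(sum(tr$duration_ms), 3350)
    expect_equal(tr$onset_ms[1], 0)
    if (nrow(tr) > 1) {
      expect_equal(tr$onset_ms[-1], tr$offset_ms[-nrow(tr)])
    }
  }
})

test_that("raising the velocity threshold never increases the saccade count", {
  co <- small_cohort("exp1", 1, seed = 301, n_trials = 20)
  thresholds <- c(20, 30, 60, 120)
  counts <- vapply(thresholds, function(v) {
    ev <- detect_events(co$samples,
                        detection_params(velocity_threshold = v),
                        roi_screen(co$rois))
    sum(ev$kind == "saccade")
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("noise-free traces reproduce ground-truth event boundaries", {
  rois <- default_rois()
  d <- generate_design("exp1", "p01", seed = 8)[1:25, ]
  b <- simulate_behavior(d, seed = 9)
  sim <- simulate_gaze_cohort(b, gaze_sim_params(noise_sd = 0), rois,
                              seed = 10)
  ev <- detect_events(sim$samples, screen = roi_screen(rois))
  gt <- sim$events[sim$events$kind == "saccade", ]
  det <- ev[ev$kind == "saccade", ]
  expect_equal(nrow(det), nrow(gt))
  for (i in seq_len(nrow(gt))) {
    cand <- det[det$trial == gt$trial[i], ]
    err <- abs(cand$onset_ms - gt$t_on[i])
    expect_lte(min(err), 2)
    expect_lte(min(abs(cand$offset_ms - gt$t_off[i])), 3)
  }
})

test_that("anticipatory saccade selection applies the 100 ms latency criterion", {
  ev <- dplyr::bind_rows(
    make_event(kind = "saccade", onset = 830, offset = 860),   # 80 ms: out
    make_event(kind = "saccade", onset = 870, offset = 900),   # 120 ms: in
    make_event(kind = "saccade", onset = 1050, offset = 1080), # 300 ms: in
    make_event(kind = "saccade", onset = 1200, offset = 1230)  # third: out
  )
  got <- predictive_saccades(ev, outline_onset_ms = 750, face_onset_ms = 1750)
  expect_equal(got$onset_ms, c(870, 1050))
  expect_equal(got$sacc_rank, c(1, 2))
  # After face onset: excluded.
  got2 <- predictive_saccades(ev, outline_onset_ms = 750, face_onset_ms = 1000)
  expect_equal(nrow(got2), 1)
  # No qualifying saccade.
  got3 <- predictive_saccades(ev[1, ], 750, 1750)
  expect_equal(nrow(got3), 0)
})

test_that("blink runs become padded blink events", {
  theta <- rep(0, 400)
  s <- deg_samples(theta, valid = c(rep(TRUE, 200), rep(FALSE, 50),
                                    rep(TRUE, 150)))
  s$x_px[!s$valid] <- NA
  ev <- detect_events(s)
  bl <- ev[ev$kind == "blink", ]
  expect_equal(nrow(bl), 1)
  # 50 ms of invalidity padded by ~10 ms on each side.
  expect_equal(bl$duration_ms, 70, tolerance = 0.05)
  expect_equal(sum(ev$duration_ms), 400)
})
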