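test_that("detection window runs from target onset to the response", {
  tr <- social_trial(t_target = 1.0, t_resp = 1.6, t_end = 1.7)
  w <- detection_window(tr)
  expect_equal(c(w$start, w$end), c(1.0, 1.6))
  expect_true(w$has_response)

  # no response: window extends to trial end, RT undefined downstream
  tr$t_response <- NA
  w <- detection_window(tr)
  expect_equal(w$end, 1.7)
  expect_false(w$has_response)

  # anticipatory key press: empty window, flagged
  tr <- social_trial(t_target = 1.0, t_resp = 0.8)
  w <- detection_window(tr)
  expect_true(w$anticipatory)
  expect_equal(w$start, w$end)
})

test_that("RJA is coded from the first AOI exit", {
  aoi <- aoi_layout()
  tl <- quadrant_center("TL") # (0.3, 0.3)
  br <- quadrant_center("BR")
  tr <- social_trial(cue_q = "TL", t_target = 1, t_resp = 2.5)

  # cue AOI -> cued quadrant: RJA
  ev <- dplyr::bind_rows(
    make_event("fixation", 0.0, 1.2, 0.5, 0.5),
    make_event("saccade", 1.2, 1.25, 0.4, 0.4, tl[1], tl[2]),
    make_event("fixation", 1.25, 2.5, tl[1], tl[2])
  )
  expect_true(detect_rja(ev, tr, aoi))

  # first exit to the opposite quadrant, cued quadrant only second: no RJA
  ev2 <- dplyr::bind_rows(
    make_event("fixation", 0.0, 1.2, 0.5, 0.5),
    make_event("fixation", 1.25, 1.6, br[1], br[2]),
    make_event("fixation", 1.65, 2.5, tl[1], tl[2])
  )
  expect_false(detect_rja(ev2, tr, aoi))

  # gaze never leaves the AOI: no shift occurred
  ev3 <- make_event("fixation", 0.0, 2.5, 0.5, 0.5)
  expect_false(detect_rja(ev3, tr, aoi))

  # undefined outside social blocks
  tr_ns <- social_trial()
  tr_ns$cue_type <- "nonsocial"
  expect_true(is.na(detect_rja(ev, tr_ns, aoi)))

  # start condition fails when gaze is already away from the cue
  ev4 <- dplyr::bind_rows(
    make_event("fixation", 0.0, 2.0, br[1], br[2]),
    make_event("fixation", 2.0, 2.5, tl[1], tl[2])
  )
  expect_false(detect_rja(ev4, tr, aoi))
})

test_that("peripheral vision means no fixation or saccade endpoint leaves the AOI", {
  aoi <- aoi_layout()
  tr <- social_trial(t_target = 1, t_resp = 2.5)
  inside <- dplyr::bind_rows(
    make_event("fixation", 0.0, 1.5, 0.5, 0.5),
    make_event("saccade", 1.5, 1.53, 0.5, 0.5, 0.54, 0.52),
    make_event("fixation", 1.53, 2.5, 0.54, 0.52)
  )
  expect_true(detect_peripheral(inside, tr, aoi))

  one_out <- dplyr::bind_rows(
    inside,
    make_event("fixation", 2.2, 2.5, 0.3, 0.3)
  )
  expect_false(detect_peripheral(one_out, tr, aoi))

  # no events in the window: undefined (excluded from rate denominators)
  empty_win <- make_event("fixation", 0.0, 0.9, 0.5, 0.5)
  expect_true(is.na(detect_peripheral(empty_win, tr, aoi)))

  tr_ns <- social_trial()
  tr_ns$cue_type <- "nonsocial"
  expect_true(is.na(detect_peripheral(inside, tr_ns, aoi)))

  # an RJA trial can never be peripheral (an AOI exit occurred)
  tl <- quadrant_center("TL")
  rja_ev <- dplyr::bind_rows(
    make_event("fixation", 0.0, 1.2, 0.5, 0.5),
    make_event("fixation", 1.25, 2.5, tl[1], tl[2])
  )
  expect_true(detect_rja(rja_ev, social_trial(cue_q = "TL"), aoi))
  expect_false(detect_peripheral(rja_ev, social_trial(cue_q = "TL"), aoi))
})

test_that("trial features follow their definitions on constructed input", {
  aoi <- aoi_layout()
  tr <- social_trial(t_target = 1, t_resp = 2.5, t_end = 2.6)
  # window [1, 2.5]: 3 fixations of 0.1/0.2/0.3 s plus saccades
  tl <- quadrant_center("TL")
  ev <- dplyr::bind_rows(
    make_event("fixation", 0.5, 1.0, 0.5, 0.5),          # outside window
    make_event("fixation", 1.10, 1.20, 0.5, 0.5),
    make_event("saccade", 1.20, 1.24, 0.5, 0.5, tl[1], tl[2]),
    make_event("fixation", 1.30, 1.50, tl[1], tl[2]),
    make_event("saccade", 1.50, 1.54, tl[1], tl[2], 0.7, 0.7),
    make_event("fixation", 1.60, 1.90, 0.7, 0.7)
  )
  ev$amplitude_deg <- c(0, 0, 8, 0, 12, 0)
  ev$peak_vel_deg_s <- c(20, 20, 150, 20, 250, 20)
  gaze <- make_fixation_stream(300)
  gaze$valid[1:15] <- FALSE

  f <- extract_trial_features(gaze, ev, tr, aoi, geom300)
  expect_equal(f$rt, 1.5)
  expect_identical(f$n_saccades, 2L)
  expect_equal(f$per_fixation_duration, (0.1 + 0.2 + 0.3) / 3)
  expect_equal(f$null_rate, 15 / 300)
  expect_equal(f$saccade_length_deg, 10)       # mean of 8 and 12
  expect_equal(f$saccade_velocity_deg_s, 200)  # mean of peak velocities
  # sum variant
  f2 <- extract_trial_features(gaze, ev, tr, aoi, geom300,
                               saccade_length_stat = "sum")
  expect_equal(f2$saccade_length_deg, 20)

  # per_fixation_duration x fixation count == total fixation time (identity)
  expect_equal(f$per_fixation_duration * 3, 0.6)
})

test_that("features are invariant to uniform time translation", {
  sched <- generate_session_schedule(task_config(n_blocks = 1,
                                                 trials_per_block = 6),
                                     seed = 4)
  trials <- simulate_responses(sched, td_params(), task_config(), seed = 4)
  tr <- trials[1, ]
  g <- simulate_trial_gaze(tr, td_params(), geom300, seed = 77,
                           null_rate = 0)
  f1 <- extract_trial_features(g, segment_gaze(g, geom300), tr)

  shift <- 120
  g2 <- dplyr::mutate(g, t = t + shift)
  tr2 <- dplyr::mutate(tr, dplyr::across(dplyr::starts_with("t_"), ~ .x + shift))
  f2 <- extract_trial_features(g2, segment_gaze(g2, geom300), tr2)
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("round-trip: constructed saccade count is recovered", {
  # path with 4 clear saccades inside the detection window
  anchors_x <- c(0.5, 0.3, 0.7, 0.3, 0.7)
  anchors_y <- c(0.5, 0.3, 0.3, 0.7, 0.7)
  g <- make_path_stream(anchors_x, anchors_y,
                        n_fix = rep(90, 5), n_move = rep(15, 4))
  tr <- social_trial(t_target = 0.15, t_resp = max(g$t),
                     t_end = max(g$t) + 0.01)
  ev <- segment_gaze(g, geom300)
  f <- extract_trial_features(g, ev, tr)
  expect_identical(f$n_saccades, 4L)
})

test_that("rja implies not-peripheral across simulated social trials", {
  sched <- generate_session_schedule(task_config(n_blocks = 1,
                                                 trials_per_block = 12),
                                     seed = 6)
  trials <- simulate_responses(sched, td_params(), task_config(), seed = 6)
  aoi <- aoi_layout()
  for (i in seq_len(nrow(trials))) {
    g <- simulate_trial_gaze(trials[i, ], td_params(), geom300, aoi,
                             seed = 500 + i)
    ev <- suppressWarnings(segment_gaze(g, geom300))
    rja <- detect_rja(ev, trials[i, ], aoi)
    per <- detect_peripheral(ev, trials[i, ], aoi)
    if (isTRUE(rja)) expect_false(isTRUE(per))
  }
})
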