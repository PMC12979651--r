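# compact trial-feature rows for aggregation tests
tf_row <- function(id, cue, soa, congr, ...) {
  defaults <- list(
    id = id, block = 1L, trial = 1L, cue_type = cue, congruency = congr,
    soa_ms = soa, rt = NA_real_, correct = NA, n_saccades = 0L,
    saccade_length_deg = NA_real_, saccade_velocity_deg_s = NA_real_,
    fix_dur_cue_soa = 0, sd_fix_locations_deg = NA_real_, null_rate = 0,
    rja = NA, peripheral = NA, per_fixation_duration = NA_real_,
    anticipatory = FALSE
  )
  tibble::as_tibble(utils::modifyList(defaults, list(...)))
}

test_that("condition cells use medians for continuous and means for binary", {
  tf <- dplyr::bind_rows(
    tf_row("p1", "social", 500, "congruent", rt = 0.4, rja = TRUE),
    tf_row("p1", "social", 500, "congruent", rt = 0.5, rja = FALSE),
    tf_row("p1", "social", 500, "congruent", rt = 0.9, rja = TRUE),
    tf_row("p1", "social", 500, "congruent", rt = NA, rja = TRUE)
  )
  long <- aggregate_conditions(tf)
  cell <- function(feat) long$value[long$feature == feat &
                                      long$congruency == "congruent" &
                                      long$soa == "0.5"]
  expect_equal(cell("rt"), 0.5)    # median of {0.4, 0.5, 0.9}
  expect_equal(cell("rja"), 0.75)  # mean of {1, 0, 1, 1}

  # a cell with no defined trials stays missing, not zero
  expect_true(is.na(cell("per_fix_dur")))
})

test_that("rt is aggregated regardless of accuracy, rt_correct from correct trials", {
  tf <- dplyr::bind_rows(
    tf_row("p1", "social", 500, "congruent", rt = 1.0, correct = TRUE),
    tf_row("p1", "social", 500, "congruent", rt = 2.0, correct = FALSE),
    tf_row("p1", "social", 500, "congruent", rt = 3.0, correct = TRUE)
  )
  long <- aggregate_conditions(tf)
  expect_equal(long$value[long$feature == "rt"], 2.0)
  expect_equal(long$value[long$feature == "rt_correct"], 2.0) # median(1, 3)
})

test_that("aggregation is idempotent and permutation-invariant over trials", {
  sched <- generate_session_schedule(task_config(), seed = 9)
  trials <- simulate_responses(sched, adhd_params(), task_config(), seed = 9)
  tf <- dplyr::bind_rows(purrr::map(seq_len(24), function(i) {
    tf_row("p1", trials$cue_type[i], trials$soa_ms[i], trials$congruency[i],
           trial = i, rt = trials$rt[i], correct = trials$correct[i],
           n_saccades = i %% 7L, null_rate = (i %% 5) / 20,
           rja = if (trials$cue_type[i] == "social") i %% 2 == 0 else NA)
  }))
  a1 <- aggregate_participants(tf)
  a2 <- aggregate_participants(tf[sample.int(nrow(tf)), ])
  expect_equal(a1, a2)
})

test_that("GCE is incongruent minus congruent and recovers an injected cost", {
  df <- tibble::tibble(id = "p1",
                       rt.social.0.5.cong = 0.40,
                       rt.social.0.5.incong = 0.52)
  expect_equal(compute_gce(df, "rt", 0.5), 0.12)
  df2 <- tibble::tibble(id = "p1", rt.social.0.5.cong = 0.4,
                        rt.social.0.5.incong = 0.4)
  expect_equal(compute_gce(df2, "rt", 0.5), 0)
  expect_error(compute_gce(df, "nsacc", 0.5), "not found")

  # cohort-level recovery: +0.1 s incongruency cost on social trials
  p <- td_params(gce_rt_s = 0.1, rt_sdlog = 0.08, rt_subject_sdlog = 0,
                 rt_sdlog_subject_sd = 0, miss_prob = 0)
  cfg <- task_config()
  gces <- purrr::map_dbl(1:12, function(i) {
    sched <- generate_session_schedule(cfg, seed = i)
    tr <- simulate_responses(sched, p, cfg, seed = 1000 + i)
    tf <- dplyr::bind_rows(purrr::map(seq_len(nrow(tr)), function(j) {
      tf_row("p", tr$cue_type[j], tr$soa_ms[j], tr$congruency[j],
             trial = j, rt = tr$rt[j], correct = tr$correct[j])
    }))
    pm <- aggregate_participants(tf)
    mean(c(compute_gce(pm, "rt", 0.25), compute_gce(pm, "rt", 0.5),
           compute_gce(pm, "rt", 0.75)))
  })
  expect_lt(abs(mean(gces) - 0.1), 3 * sd(gces) / sqrt(length(gces)))

  # a feature identically distributed across congruency has mean GCE ~ 0
  p0 <- td_params(gce_rt_s = 0, rt_sdlog = 0.08, rt_subject_sdlog = 0,
                  rt_sdlog_subject_sd = 0, miss_prob = 0)
  gce0 <- purrr::map_dbl(1:12, function(i) {
    sched <- generate_session_schedule(cfg, seed = 100 + i)
    tr <- simulate_responses(sched, p0, cfg, seed = 2000 + i)
    tf <- dplyr::bind_rows(purrr::map(seq_len(nrow(tr)), function(j) {
      tf_row("p", tr$cue_type[j], tr$soa_ms[j], tr$congruency[j],
             trial = j, rt = tr$rt[j], correct = tr$correct[j])
    }))
    compute_gce(aggregate_participants(tf), "rt", 0.5)
  })
  expect_lt(abs(mean(gce0)), 3 * sd(gce0) / sqrt(length(gce0)))
})

test_that("eligibility filters implement the screening cutoffs", {
  p <- make_participants(
    list(id = "a1", group = "ADHD", kars_inattention = 5, kars_total = 20,
         cars = 20, calib_pass = TRUE),                      # excluded (<= 5)
    list(id = "a2", group = "ADHD", kars_inattention = 6, kars_total = 20,
         cars = 20, calib_pass = TRUE),                      # retained
    list(id = "t1", group = "TD", kars_inattention = 9, kars_total = 17,
         cars = 16, calib_pass = TRUE),                      # retained
    list(id = "t2", group = "TD", kars_inattention = 10, kars_total = 12,
         cars = 16, calib_pass = TRUE),                      # excluded (>= 10)
    list(id = "t3", group = "TD", kars_inattention = 4, kars_total = 18,
         cars = 16, calib_pass = TRUE),                      # excluded (>= 18)
    list(id = "t4", group = "TD", kars_inattention = 4, kars_total = 10,
         cars = 37, calib_pass = TRUE),                      # excluded (CARS)
    list(id = "t5", group = "TD", kars_inattention = 4, kars_total = 10,
         cars = 16, calib_pass = FALSE),                     # excluded (calib)
    list(id = "t6", group = "TD", kars_inattention = NA, kars_total = 10,
         cars = 16, calib_pass = TRUE)                       # flagged, kept
  )
  out <- apply_eligibility_filters(p)
  expect_setequal(out$id, c("a2", "t1", "t6"))
  log <- exclusion_log(out)
  expect_identical(nrow(log), 5L)
  expect_identical(log$reason[log$id == "a1"], "ADHD inattention <= 5")
  expect_identical(log$reason[log$id == "t3"], "TD KARS total >= 18")
  expect_identical(log$reason[log$id == "t5"], "failed calibration validation")
  expect_true(out$screen_flag[out$id == "t6"])
  expect_false(any(out$screen_flag[out$id != "t6"]))
})

test_that("imputation fills missing cells with the group median and flags them", {
  df <- tibble::tibble(
    id = paste0("p", 1:6),
    group = rep(c("ADHD", "TD"), each = 3),
    f1 = c(1, 2, NA, 10, 20, 30)
  )
  out <- impute_features(df, "f1")
  expect_equal(out$f1[3], 1.5) # ADHD median
  expect_identical(attr(out, "imputed")$f1, c(FALSE, FALSE, TRUE,
                                              FALSE, FALSE, FALSE))
})
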