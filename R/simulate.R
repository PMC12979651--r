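# Synthetic gaze, behaviour and cohort generator.
#
# The generator mirrors the task structure: a centre fixation through the
# cue phase and SOA, then -- unless the trial is resolved by peripheral
# vision -- a sequence of fixations and main-sequence-like saccades filling
# the target-detection period, ending on the target. Track loss is injected
# as blink-like bursts of invalid samples.

# draw participant-level realisations of the group parameters
resolve_subject_params <- function(params) {
  sp <- unclass(params)
  sp$fix_dur_mean_s <- max(0.12, rnorm(1, sp$fix_dur_mean_s, sp$fix_dur_between_sd_s))
  sp$rja_prob <- jitter_prob(sp$rja_prob, sp$rja_logit_sd)
  sp$peripheral_prob <- jitter_prob(sp$peripheral_prob, sp$peripheral_logit_sd)
  sp$null_rate_mean <- min(0.5, max(0, rnorm(1, sp$null_rate_mean, sp$null_rate_between_sd)))
  sp$rt_meanlog <- rnorm(1, sp$rt_meanlog, sp$rt_subject_sdlog)
  sp$rt_sdlog <- sp$rt_sdlog * exp(rnorm(1, 0, sp$rt_sdlog_subject_sd))
  sp$null_rate_trial_sd <- sp$null_rate_trial_sd *
    exp(rnorm(1, 0, sp$null_trial_sd_subject_sd))
  sp$accuracy <- jitter_prob(sp$accuracy, sp$accuracy_logit_sd)
  sp
}

# saccade duration (s) from amplitude (deg), main-sequence-like
saccade_duration <- function(amplitude_deg) {
  (2.2 * amplitude_deg + 21) / 1000
}

#' Simulate the gaze stream of one trial
#'
#' Generates eye-tracker samples for a single trial at the geometry's
#' sampling rate. Gaze rests at the screen centre through the cue phase and
#' SOA. After target onset plus a short latency, either (peripheral trial)
#' gaze keeps re-fixating small anchors inside the central cue area for the
#' whole detection period, or an overt shift occurs whose first landing
#' quadrant is the cued quadrant with probability `rja_prob`, followed by
#' search fixations that end on the target. Saccades follow a sigmoid
#' position profile whose peak velocity comfortably exceeds the
#' segmentation threshold. A blink-like fraction of samples is flagged
#' invalid.
#'
#' @param trial A one-row data frame or list with the trial design and
#'   phase timestamps (`cue_type`, `congruency`, `cue_quadrant`,
#'   `target_quadrant`, `t_cue_on`, `t_target_on`, `t_response`,
#'   `t_trial_end`).
#' @param params Group or participant parameters ([group_params()] or the
#'   result of the internal per-participant draw).
#' @param geometry A [screen_geometry()].
#' @param aoi An [aoi_layout()]; bounds the anchors of peripheral trials.
#' @param seed Optional integer seed (deterministic stream given the seed).
#' @param peripheral,rja Optional logicals overriding the random draws of
#'   the trial's behaviour mode (used for round-trip testing).
#' @param null_rate Optional override of the trial's target invalid-sample
#'   fraction.
#' @return A tibble with `t`, `x`, `y`, `valid`; invalid samples carry
#'   `NA` coordinates.
#' @examples
#' sched <- generate_session_schedule(task_config(), seed = 1)
#' trials <- simulate_responses(sched, td_params(), task_config(), seed = 1)
#' gaze <- simulate_trial_gaze(trials[1, ], td_params(), seed = 1)
#' @export
simulate_trial_gaze <- function(trial, params, geometry = screen_geometry(),
                                aoi = aoi_layout(), seed = NULL,
                                peripheral = NULL, rja = NULL,
                                null_rate = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  trial <- as.list(trial)
  fs <- geometry$sampling_rate_hz
  dt <- 1 / fs
  t0 <- trial$t_cue_on
  t_end <- trial$t_trial_end
  n <- max(2L, floor((t_end - t0) * fs))
  t <- t0 + (seq_len(n) - 1L) * dt

  is_peripheral <- peripheral %||% (runif(1) < params$peripheral_prob)
  is_rja <- rja %||% (runif(1) < params$rja_prob)

  latency <- max(0.08, rnorm(1, params$latency_mean_s, params$latency_sd_s))
  shift_t <- min(trial$t_target_on + latency, t_end - 0.15)

  anchors <- plan_anchors(trial, params, aoi, is_peripheral, is_rja,
                          avail = t_end - shift_t)
  segs <- plan_segments(anchors, shift_t, t_end, t0, geometry)

  idx <- findInterval(t, segs$t_on)
  x <- segs$x0[idx]
  y <- segs$y0[idx]
  sac <- segs$kind[idx] == "saccade"
  if (any(sac)) {
    k <- 2 * log(99) / segs$dur[idx[sac]]
    mid <- segs$t_on[idx[sac]] + segs$dur[idx[sac]] / 2
    frac <- plogis(k * (t[sac] - mid))
    x[sac] <- segs$x0[idx[sac]] + frac * (segs$x1[idx[sac]] - segs$x0[idx[sac]])
    y[sac] <- segs$y0[idx[sac]] + frac * (segs$y1[idx[sac]] - segs$y0[idx[sac]])
  }
  x <- pmin(pmax(x + rnorm(n, 0, params$noise_sd), 0), 1)
  y <- pmin(pmax(y + rnorm(n, 0, params$noise_sd), 0), 1)

  f <- null_rate %||%
    min(0.6, max(0, rnorm(1, params$null_rate_mean, params$null_rate_trial_sd)))
  valid <- rep(TRUE, n)
  n_invalid <- round(f * n)
  if (n_invalid > 0) {
    # one contiguous look-away/blink episode per trial: repeated short
    # dropouts would fragment fixations and bias the per-fixation
    # duration downward in the high-track-loss group
    start <- sample.int(n - n_invalid + 1L, 1)
    bad <- seq(start, start + n_invalid - 1L)
    valid[bad] <- FALSE
    x[bad] <- NA_real_
    y[bad] <- NA_real_
  }

  tibble::tibble(t = t, x = x, y = y, valid = valid)
}

# Decide the sequence of fixation anchors and their (unscaled) durations.
plan_anchors <- function(trial, params, aoi, is_peripheral, is_rja, avail) {
  fm <- params$fix_dur_mean_s
  fsd <- params$fix_dur_sd_s
  draw_dur <- function(k = 1) pmax(0.08, rnorm(k, fm, fsd))

  # incongruent social trials: the distractor sits at the cued location,
  # provoking extra short re-fixations (the gaze-cueing effect in the
  # saccade count) whether or not the trial is resolved peripherally
  extras <- if (identical(trial$congruency, "incongruent") &&
                identical(trial$cue_type, "social")) {
    rpois(1, params$gce_extra_saccades)
  } else 0L
  extra_durs <- if (extras > 0) runif(extras, 0.08, 0.15) else numeric(0)

  if (is_peripheral) {
    # small re-fixations confined well inside the cue AOI
    durs <- numeric(0)
    budget <- max(0.15, avail - sum(extra_durs) - 0.05 * extras)
    while (sum(durs) + 0.05 * length(durs) < budget && length(durs) < 60) {
      durs <- c(durs, draw_dur())
    }
    durs <- c(durs, extra_durs)
    if (!length(durs)) durs <- avail
    if (length(durs) > 1) durs <- durs[sample.int(length(durs))]
    k <- length(durs)
    ang <- runif(k, 0, 2 * pi)
    rad <- runif(k, 0, 0.5 * aoi$cue_radius)
    ax <- aoi$cue_center[1] + rad * cos(ang)
    ay <- aoi$cue_center[2] + rad * sin(ang)
    return(list(x = ax, y = ay, dur = durs))
  }

  first_q <- if (is_rja) trial$cue_quadrant else
    sample(setdiff(QUADRANTS, trial$cue_quadrant), 1)

  durs <- draw_dur()
  budget <- max(0.15, avail - sum(extra_durs) - 0.06 * extras)
  while (sum(durs) + 0.06 * length(durs) < budget && length(durs) < 60) {
    durs <- c(durs, draw_dur())
  }
  durs <- c(durs, extra_durs)
  if (length(durs) > 2) {
    mid <- seq(2L, length(durs) - 1L)
    durs <- durs[c(1L, mid[sample.int(length(mid))], length(durs))]
  }
  k <- length(durs)

  qc <- quadrant_center(first_q)
  ax <- qc[, "x"] + rnorm(1, 0, 0.03)
  ay <- qc[, "y"] + rnorm(1, 0, 0.03)
  if (k > 2) {
    mid_q <- sample(QUADRANTS, k - 2L, replace = TRUE)
    mc <- quadrant_center(mid_q)
    ax <- c(ax, mc[, "x"] + rnorm(k - 2L, 0, params$explore_spread))
    ay <- c(ay, mc[, "y"] + rnorm(k - 2L, 0, params$explore_spread))
  }
  if (k > 1) {
    tc <- quadrant_center(trial$target_quadrant)
    ax <- c(ax, tc[, "x"] + rnorm(1, 0, 0.02))
    ay <- c(ay, tc[, "y"] + rnorm(1, 0, 0.02))
  }
  list(x = pmin(pmax(ax, 0.02), 0.98), y = pmin(pmax(ay, 0.02), 0.98),
       dur = durs)
}

# Turn the anchor plan into an alternating fixation/saccade segment table
# covering [t0, t_end]; fixation durations are rescaled so the plan fits
# exactly.
plan_segments <- function(anchors, shift_t, t_end, t0, geometry) {
  cx <- c(0.5, anchors$x)
  cy <- c(0.5, anchors$y)
  k <- length(anchors$x)
  amp <- visual_angle(cx[-(k + 1)], cy[-(k + 1)], cx[-1], cy[-1], geometry)
  sac_dur <- saccade_duration(amp)
  total_sac <- sum(sac_dur)
  span <- t_end - shift_t
  fix_dur <- anchors$dur
  scale <- max(span - total_sac, 0.3 * span) / sum(fix_dur)
  fix_dur <- fix_dur * scale
  if (total_sac > 0.7 * span) sac_dur <- sac_dur * (0.7 * span / total_sac)

  kinds <- c("fixation",
             rbind(rep("saccade", k), rep("fixation", k)))
  durs <- c(shift_t - t0, rbind(sac_dur, fix_dur))
  x0 <- c(0.5, rbind(cx[-(k + 1)], cx[-1]))
  y0 <- c(0.5, rbind(cy[-(k + 1)], cy[-1]))
  x1 <- c(0.5, rbind(cx[-1], cx[-1]))
  y1 <- c(0.5, rbind(cy[-1], cy[-1]))

  t_on <- t0 + c(0, cumsum(durs))[seq_along(durs)]
  tibble::tibble(kind = kinds, t_on = t_on, dur = durs,
                 x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

#' Simulate behavioural responses and trial timestamps
#'
#' Adds phase timestamps and a key-press model to a session schedule.
#' Reaction times follow a shifted lognormal; incongruent social trials
#' incur the group's additive gaze-cueing cost. Key accuracy is Bernoulli
#' with an incongruency penalty, and a small fraction of trials time out
#' with no response.
#'
#' @param schedule Output of [generate_session_schedule()].
#' @param params [group_params()] (or per-participant resolved parameters).
#' @param config The [task_config()] used for the schedule.
#' @param seed Optional integer seed.
#' @return The schedule with added columns `t_cue_on`, `t_cue_point_end`,
#'   `t_target_on`, `t_response`, `t_trial_end`, `rt`, `key_pressed`,
#'   `correct`.
#' @export
simulate_responses <- function(schedule, params, config = task_config(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(schedule)
  social_incong <- schedule$cue_type == "social" &
    schedule$congruency == "incongruent"
  rt <- params$rt_shift_s +
    rlnorm(n, params$rt_meanlog, params$rt_sdlog) +
    params$gce_rt_s * social_incong
  rt <- pmin(pmax(rt, 0.5), config$max_response_s - 0.05)
  miss <- runif(n) < params$miss_prob
  acc_p <- pmin(pmax(
    params$accuracy -
      params$accuracy_incong_penalty * (schedule$congruency == "incongruent"),
    0), 1)
  correct <- runif(n) < acc_p
  key <- ifelse(correct, schedule$target_quadrant,
                vapply(schedule$target_quadrant,
                       function(q) sample(setdiff(QUADRANTS, q), 1), ""))
  key[miss] <- NA_character_
  correct[miss] <- NA
  rt[miss] <- NA_real_

  cue_phase_s <- config$cue_phase_ms / 1000
  soa_s <- schedule$soa_ms / 1000
  detect_span <- ifelse(miss, config$max_response_s, rt + 0.1)
  trial_span <- cue_phase_s + soa_s + detect_span
  t_cue_on <- c(0, cumsum(trial_span + config$iti_s))[seq_len(n)]

  dplyr::mutate(
    schedule,
    t_cue_on = t_cue_on,
    t_cue_point_end = t_cue_on + cue_phase_s,
    t_target_on = .data$t_cue_point_end + soa_s,
    t_response = ifelse(miss, NA_real_, .data$t_target_on + rt),
    t_trial_end = .data$t_target_on + detect_span,
    rt = rt,
    key_pressed = key,
    correct = correct
  )
}

#' Simulate one participant
#'
#' Draws participant-level parameters from the group distributions, builds
#' a balanced session schedule, simulates responses, and generates the gaze
#' stream for every trial. A three-point calibration-validation record is
#' also drawn.
#'
#' @param id Participant identifier.
#' @param group `"ADHD"` or `"TD"`.
#' @param params The group's [group_params()].
#' @param config A [task_config()].
#' @param geometry A [screen_geometry()].
#' @param aoi An [aoi_layout()].
#' @param seed Integer seed for this participant.
#' @param first_cue_type Cue type of the participant's first block.
#' @return A list with `participant` (one-row tibble), `trials`, `gaze`.
#' @export
simulate_participant <- function(id, group, params, config = task_config(),
                                 geometry = screen_geometry(),
                                 aoi = aoi_layout(), seed = 1,
                                 first_cue_type = "social") {
  set.seed(as.integer(seed))
  # The cohort spec describes the analysed sample (its questionnaire
  # moments are post-screening), so screening profiles are drawn
  # conditionally on passing the eligibility rules.
  for (try in 1:25) {
    quest <- simulate_questionnaires(1, params)
    calib <- pmax(rnorm(3, params$calib_error_mean_deg,
                        params$calib_error_sd_deg), 0.1)
    probe <- dplyr::bind_cols(
      tibble::tibble(id = id, group = group,
                     calib_pass = validate_calibration(calib)),
      quest
    )
    if (nrow(exclusion_log(apply_eligibility_filters(probe))) == 0) break
  }
  sp <- resolve_subject_params(params)
  schedule <- generate_session_schedule(config, seed = NULL,
                                        first_cue_type = first_cue_type)
  trials <- simulate_responses(schedule, sp, config)
  gaze <- purrr::map(seq_len(nrow(trials)), function(i) {
    g <- simulate_trial_gaze(trials[i, ], sp, geometry, aoi)
    g$trial <- trials$trial[i]
    g
  }) |>
    dplyr::bind_rows() |>
    dplyr::relocate("trial")

  participant <- dplyr::bind_cols(
    tibble::tibble(
      id = id,
      group = factor(group, levels = c("ADHD", "TD")),
      first_cue_type = first_cue_type,
      calib_error_mean = mean(calib),
      calib_pass = validate_calibration(calib)
    ),
    quest
  )
  trials$id <- id
  gaze$id <- id
  list(
    participant = participant,
    trials = dplyr::relocate(trials, "id"),
    gaze = dplyr::relocate(gaze, "id")
  )
}

#' Simulate a full cohort
#'
#' Generates participants for both groups (ADHD first, then TD, mirroring
#' an arrival order), alternating which cue type opens the session across
#' consecutive participants. A single master seed fans out into independent
#' per-participant seeds.
#'
#' @param spec A [cohort_spec()].
#' @param config A [task_config()].
#' @param geometry A [screen_geometry()].
#' @param aoi An [aoi_layout()].
#' @param seed Master integer seed.
#' @param keep_gaze If `FALSE`, gaze streams are dropped (saves memory when
#'   only schedules/responses are needed).
#' @return A `gc_cohort` list with tibbles `participants`, `trials`,
#'   `gaze`, plus the generating configuration.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(cohort_spec(n_adhd = 2, n_td = 2), seed = 1)
#' coh$participants
#' }
#' @export
simulate_cohort <- function(spec = cohort_spec(), config = task_config(),
                            geometry = screen_geometry(), aoi = aoi_layout(),
                            seed = 1, keep_gaze = TRUE) {
  stopifnot(inherits(spec, "gc_cohort_spec"))
  n_total <- spec$n_adhd + spec$n_td
  seeds <- derive_seeds(seed, n_total)
  groups <- c(rep("ADHD", spec$n_adhd), rep("TD", spec$n_td))
  ids <- c(sprintf("adhd%02d", seq_len(spec$n_adhd)),
           sprintf("td%02d", seq_len(spec$n_td)))
  out <- purrr::map(seq_len(n_total), function(i) {
    p <- if (groups[i] == "ADHD") spec$adhd else spec$td
    res <- simulate_participant(
      ids[i], groups[i], p, config, geometry, aoi, seed = seeds[i],
      first_cue_type = if (i %% 2L == 1L) "social" else "nonsocial"
    )
    if (!keep_gaze) res$gaze <- NULL
    res
  })
  structure(
    list(
      participants = dplyr::bind_rows(purrr::map(out, "participant")),
      trials = dplyr::bind_rows(purrr::map(out, "trials")),
      gaze = if (keep_gaze) dplyr::bind_rows(purrr::map(out, "gaze")) else NULL,
      spec = spec, config = config, geometry = geometry, aoi = aoi,
      seed = seed
    ),
    class = "gc_cohort"
  )
}

#' @export
print.gc_cohort <- function(x, ...) {
  cat("<gc_cohort> ", nrow(x$participants), " participants (",
      sum(x$participants$group == "ADHD"), " ADHD / ",
      sum(x$participants$group == "TD"), " TD), ",
      nrow(x$trials), " trials", sep = "")
  if (!is.null(x$gaze)) cat(", ", nrow(x$gaze), " gaze samples", sep = "")
  cat("\n")
  invisible(x)
}
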