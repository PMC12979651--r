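#' Area-of-interest layout
#'
#' A circular area of interest (AOI) centred on the cue stimulus, with the
#' remaining screen divided into quadrants by the screen midlines. The
#' default radius (0.08 normalized units) covers the 77-px cue stimulus
#' with margin; the AOI size is configurable because segment-level
#' behaviour codes (joint attention, peripheral vision) depend on it.
#'
#' @param cue_center Normalized coordinates of the cue centre.
#' @param cue_radius AOI radius in normalized units.
#' @return A `gc_aoi` list.
#' @export
aoi_layout <- function(cue_center = c(0.5, 0.5), cue_radius = 0.08) {
  stopifnot(length(cue_center) == 2, cue_radius > 0,
            cue_center[1] - cue_radius > 0, cue_center[1] + cue_radius < 1,
            cue_center[2] - cue_radius > 0, cue_center[2] + cue_radius < 1)
  structure(list(cue_center = as.numeric(cue_center),
                 cue_radius = cue_radius),
            class = "gc_aoi")
}

in_cue_aoi <- function(x, y, aoi) {
  sqrt((x - aoi$cue_center[1])^2 + (y - aoi$cue_center[2])^2) <= aoi$cue_radius
}

#' Target-detection window of a trial
#'
#' The interval over which all oculomotor outcome measures are computed:
#' from target onset to the key response, or to the end of the trial when
#' no key was pressed (in which case RT is undefined). A response logged
#' before target onset is flagged as anticipatory and yields an empty
#' window.
#'
#' @param trial A one-row data frame or list with `t_target_on`,
#'   `t_response` and `t_trial_end`.
#' @return A list with `start`, `end`, `has_response`, `anticipatory`.
#' @export
detection_window <- function(trial) {
  trial <- as.list(trial)
  stopifnot(!is.null(trial$t_target_on), !is.na(trial$t_target_on))
  has_resp <- !is.null(trial$t_response) && !is.na(trial$t_response)
  if (has_resp && trial$t_response < trial$t_target_on) {
    return(list(start = trial$t_target_on, end = trial$t_target_on,
                has_response = TRUE, anticipatory = TRUE))
  }
  end <- if (has_resp) trial$t_response else trial$t_trial_end
  list(start = trial$t_target_on, end = end,
       has_response = has_resp, anticipatory = FALSE)
}

# events overlapping [start, end); fixation durations clipped to the window
window_events <- function(events, win) {
  ov <- events$t_off > win$start & events$t_on < win$end
  ev <- events[ov, , drop = FALSE]
  ev$clipped_duration <- pmin(ev$t_off, win$end) - pmax(ev$t_on, win$start)
  ev
}

#' Detect a response to joint attention (RJA)
#'
#' A trial counts as RJA when gaze, starting inside the central cue AOI at
#' the opening of the target-detection window, first leaves the AOI into
#' the quadrant indicated by the cue, without first entering another
#' quadrant. The code is defined for social-cue trials only (`NA`
#' otherwise). If the window's first sample is track-lost, occupancy of
#' the AOI within the 100 ms preceding the window is accepted as the start
#' condition.
#'
#' @param events Event table of the trial ([segment_gaze()]).
#' @param trial One-row trial record.
#' @param aoi An [aoi_layout()].
#' @return `TRUE`, `FALSE`, or `NA` (nonsocial trial or no usable events).
#' @export
detect_rja <- function(events, trial, aoi = aoi_layout()) {
  trial <- as.list(trial)
  if (!identical(trial$cue_type, "social")) return(NA)
  win <- detection_window(trial)
  if (win$end <= win$start) return(NA)
  fix <- events[events$kind == "fixation", , drop = FALSE]
  if (!nrow(fix)) return(NA)

  # start condition: a fixation covering the window start (or the 100 ms
  # before it) whose centroid lies in the cue AOI
  pre <- fix[fix$t_on < win$start + 1e-9 & fix$t_off > win$start - 0.1, ,
             drop = FALSE]
  if (!nrow(pre) || !any(in_cue_aoi(pre$x, pre$y, aoi))) return(FALSE)

  inwin <- fix[fix$t_off > win$start & fix$t_on < win$end, , drop = FALSE]
  outside <- inwin[!in_cue_aoi(inwin$x, inwin$y, aoi), , drop = FALSE]
  if (!nrow(outside)) return(FALSE)
  first_exit <- outside[which.min(outside$t_on), ]
  quadrant_of(first_exit$x, first_exit$y) == trial$cue_quadrant
}

#' Detect target detection via peripheral vision
#'
#' A trial is coded as peripheral when gaze stays on the central cue
#' stimulus through the whole target-detection window: every fixation
#' centroid in the window lies inside the cue AOI and no saccade in the
#' window ends outside it. Assessed in all social-cue trials regardless of
#' key-press accuracy; `NA` for nonsocial trials or when the window
#' contains no usable events.
#'
#' @inheritParams detect_rja
#' @return `TRUE`, `FALSE`, or `NA`.
#' @export
detect_peripheral <- function(events, trial, aoi = aoi_layout()) {
  trial <- as.list(trial)
  if (!identical(trial$cue_type, "social")) return(NA)
  win <- detection_window(trial)
  if (win$end <= win$start) return(NA)
  ev <- window_events(events, win)
  if (!nrow(ev)) return(NA)
  fix <- ev[ev$kind == "fixation", , drop = FALSE]
  sac <- ev[ev$kind == "saccade", , drop = FALSE]
  if (!nrow(fix)) return(NA)
  all(in_cue_aoi(fix$x, fix$y, aoi)) &&
    (!nrow(sac) || all(in_cue_aoi(sac$end_x, sac$end_y, aoi)))
}

#' Extract per-trial behavioural and oculomotor features
#'
#' Computes the trial-level feature set within the target-detection window:
#' reaction time and accuracy; number of saccades (saccades whose onset
#' falls in the window); mean saccade amplitude and mean of per-saccade
#' peak velocities; summed fixation time inside the cue AOI between the
#' end of the cue phase and target onset; dispersion of fixation centroids
#' (`sqrt(var_x + var_y)` on the visual-angle scale); the trial's
#' invalid-sample fraction; RJA and peripheral-vision codes (social trials
#' only); and the per-fixation duration (total fixation time in the window
#' divided by the number of fixations).
#'
#' @param gaze The trial's raw gaze samples (`t`, `x`, `y`, `valid`).
#' @param events The trial's event table ([segment_gaze()]).
#' @param trial One-row trial record.
#' @param aoi An [aoi_layout()].
#' @param geometry A [screen_geometry()].
#' @param saccade_length_stat,saccade_velocity_stat Per-trial summary used
#'   for saccade amplitude (`"mean"` or `"sum"`) and saccade velocity
#'   (`"peak"` or `"mean"`): the trial-level summaries are not pinned down
#'   by the protocol, so both variants are exposed.
#' @return A one-row tibble of features.
#' @export
extract_trial_features <- function(gaze, events, trial, aoi = aoi_layout(),
                                   geometry = screen_geometry(),
                                   saccade_length_stat = c("mean", "sum"),
                                   saccade_velocity_stat = c("peak", "mean")) {
  saccade_length_stat <- match.arg(saccade_length_stat)
  saccade_velocity_stat <- match.arg(saccade_velocity_stat)
  trial <- as.list(trial)
  win <- detection_window(trial)

  rt <- if (win$has_response && !win$anticipatory) {
    trial$t_response - trial$t_target_on
  } else NA_real_

  ev <- window_events(events, win)
  sac <- ev[ev$kind == "saccade" & ev$t_on >= win$start, , drop = FALSE]
  fix <- ev[ev$kind == "fixation", , drop = FALSE]

  n_sac <- nrow(sac)
  sac_len <- if (n_sac) {
    if (saccade_length_stat == "mean") mean(sac$amplitude_deg)
    else sum(sac$amplitude_deg)
  } else NA_real_
  sac_vel <- if (n_sac) {
    if (saccade_velocity_stat == "peak") mean(sac$peak_vel_deg_s, na.rm = TRUE)
    else mean(sac$mean_vel_deg_s, na.rm = TRUE)
  } else NA_real_

  sd_fix <- if (nrow(fix) >= 2) {
    d <- deg_from_center(fix$x, fix$y, geometry)
    sqrt(var(d$x) + var(d$y))
  } else NA_real_

  per_fix <- if (nrow(fix)) sum(fix$clipped_duration) / nrow(fix) else NA_real_

  # fixation time on the cue AOI between cue-phase end and target onset
  soa_win <- list(start = trial$t_cue_point_end, end = trial$t_target_on)
  soa_fix <- window_events(events[events$kind == "fixation", , drop = FALSE],
                           soa_win)
  soa_fix <- soa_fix[in_cue_aoi(soa_fix$x, soa_fix$y, aoi), , drop = FALSE]
  fix_dur_cue_soa <- sum(soa_fix$clipped_duration)

  tibble::tibble(
    rt = rt,
    correct = if (is.null(trial$correct)) NA else trial$correct,
    n_saccades = n_sac,
    saccade_length_deg = sac_len,
    saccade_velocity_deg_s = sac_vel,
    fix_dur_cue_soa = fix_dur_cue_soa,
    sd_fix_locations_deg = sd_fix,
    null_rate = mean(!gaze$valid),
    rja = detect_rja(events, trial, aoi),
    peripheral = detect_peripheral(events, trial, aoi),
    per_fixation_duration = per_fix,
    anticipatory = win$anticipatory
  )
}

#' Extract features for every trial of one or more participants
#'
#' Runs the preprocessing chain (smooth, differentiate, segment) and
#' [extract_trial_features()] for each trial in a gaze table.
#'
#' @param gaze Gaze tibble with `trial` (and optionally `id`) columns.
#' @param trials Trial table (one row per trial, matching keys).
#' @inheritParams extract_trial_features
#' @param threshold_deg_s,min_duration_s,window,order Preprocessing
#'   parameters, see [segment_gaze()].
#' @return A tibble with one row per trial: the trial's design columns
#'   plus all features.
#' @export
extract_features <- function(gaze, trials, aoi = aoi_layout(),
                             geometry = screen_geometry(),
                             threshold_deg_s = 30, min_duration_s = 0.010,
                             window = 21, order = 9, ...) {
  keys <- intersect(c("id", "trial"), names(trials))
  gaze_split <- split(gaze, interaction(gaze[keys], drop = TRUE, lex.order = TRUE))
  key_of <- function(row) {
    paste(vapply(keys, function(k) as.character(row[[k]]), ""), collapse = ".")
  }
  design_cols <- intersect(
    c("id", "block", "trial", "cue_type", "congruency", "soa_ms",
      "cue_quadrant", "target_quadrant", "distractor_quadrant"),
    names(trials)
  )
  purrr::map(seq_len(nrow(trials)), function(i) {
    trial <- as.list(trials[i, ])
    g <- gaze_split[[key_of(trial)]]
    if (is.null(g)) {
      stop("no gaze samples found for trial ",
           paste(unlist(trial[keys]), collapse = "/"), call. = FALSE)
    }
    ev <- segment_gaze(suppressWarnings(
      gaze_velocity(smooth_gaze(g, window, order), geometry)),
      geometry, threshold_deg_s, min_duration_s)
    dplyr::bind_cols(
      tibble::as_tibble(trial[design_cols]),
      extract_trial_features(g, ev, trial, aoi, geometry, ...)
    )
  }) |> dplyr::bind_rows()
}
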