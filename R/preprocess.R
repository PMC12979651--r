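#' Savitzky-Golay smoothing of a gaze stream
#'
#' Applies least-squares local-polynomial (Savitzky-Golay) smoothing
#' independently to the `x` and `y` coordinates of a gaze stream. Smoothing
#' runs over contiguous runs of valid samples only; invalid samples are
#' left untouched and never enter a window. Runs shorter than the window
#' are passed through unchanged with a warning.
#'
#' @param gaze A data frame with `t`, `x`, `y`, `valid`.
#' @param window Odd window length in samples (default 21).
#' @param order Polynomial order (default 9); must be less than `window`.
#' @return The input tibble with smoothed `x`, `y`.
#' @examples
#' g <- tibble::tibble(t = (0:99) / 300,
#'                     x = 0.5 + rnorm(100, 0, 0.002), y = 0.5, valid = TRUE)
#' sm <- smooth_gaze(g)
#' var(sm$x) <= var(g$x)
#' @export
smooth_gaze <- function(gaze, window = 21, order = 9) {
  stopifnot(window %% 2 == 1, window > order, order >= 0)
  gaze <- tibble::as_tibble(gaze)
  runs <- valid_runs(gaze$valid)
  filt <- sgolay_cached(order, window)
  x <- gaze$x
  y <- gaze$y
  short <- 0L
  for (r in runs) {
    if (length(r) < window) {
      short <- short + 1L
      next
    }
    x[r] <- signal::sgolayfilt(x[r], filt)
    y[r] <- signal::sgolayfilt(y[r], filt)
  }
  gaze$x <- x
  gaze$y <- y
  if (short > 0) {
    warning(short, " valid run(s) shorter than the smoothing window were ",
            "passed through unsmoothed", call. = FALSE)
  }
  gaze
}

# Savitzky-Golay projection matrices are input-independent; cache them
.sgolay_cache <- new.env(parent = emptyenv())
sgolay_cached <- function(order, window) {
  key <- paste(order, window)
  if (is.null(.sgolay_cache[[key]])) {
    .sgolay_cache[[key]] <- signal::sgolay(p = order, n = window)
  }
  .sgolay_cache[[key]]
}

# indices of maximal contiguous runs of valid samples
valid_runs <- function(valid) {
  if (!length(valid)) return(list())
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  purrr::map2(starts[r$values], ends[r$values], seq)
}

#' Per-sample angular gaze velocity
#'
#' Computes the angular speed at each sample by central differences: the
#' visual angle between the neighbouring samples divided by their time
#' separation. Velocity is undefined (`NA`) at invalid samples and at the
#' boundaries of each contiguous valid run.
#'
#' @param gaze A (smoothed) gaze tibble with `t`, `x`, `y`, `valid`.
#' @param geometry A [screen_geometry()].
#' @return The input tibble with a `vel_deg_s` column.
#' @export
gaze_velocity <- function(gaze, geometry = screen_geometry()) {
  gaze <- tibble::as_tibble(gaze)
  n <- nrow(gaze)
  vel <- rep(NA_real_, n)
  if (n >= 3) {
    i <- 2:(n - 1)
    ok <- gaze$valid[i - 1] & gaze$valid[i] & gaze$valid[i + 1]
    ang <- visual_angle(gaze$x[i - 1], gaze$y[i - 1],
                        gaze$x[i + 1], gaze$y[i + 1], geometry)
    v <- ang / (gaze$t[i + 1] - gaze$t[i - 1])
    vel[i][ok] <- v[ok]
  }
  gaze$vel_deg_s <- vel
  gaze
}

#' I-VT segmentation of a gaze stream into fixations and saccades
#'
#' Velocity-threshold classification: samples with angular speed at or
#' above `threshold_deg_s` are saccade samples, those below are fixation
#' samples. Contiguous same-label runs become events; runs shorter than
#' `min_duration_s` are merged into the preceding event (the following one
#' at stream start) to suppress single-sample noise events. Boundary
#' samples of a valid run, whose central-difference velocity is undefined,
#' inherit the label of their nearest classified neighbour. Invalid gaps
#' split events, so the event list tiles exactly the valid portion of the
#' stream.
#'
#' @param gaze A gaze tibble; if `vel_deg_s` is absent the stream is
#'   smoothed ([smooth_gaze()]) and differentiated ([gaze_velocity()])
#'   first.
#' @param geometry A [screen_geometry()].
#' @param threshold_deg_s Velocity threshold in degrees/s (default 30; the
#'   boundary value itself counts as saccade).
#' @param min_duration_s Minimum event duration in seconds (default 0.010,
#'   i.e. 3 samples at 300 Hz).
#' @param window,order Savitzky-Golay parameters used when smoothing is
#'   still needed.
#' @return A tibble of events: `kind` (`"fixation"`/`"saccade"`), `t_on`,
#'   `t_off` (half-open interval), `duration`, centroid `x`, `y`, endpoint
#'   `end_x`, `end_y`, `amplitude_deg`, `peak_vel_deg_s`,
#'   `mean_vel_deg_s`, `n_samples`.
#' @export
segment_gaze <- function(gaze, geometry = screen_geometry(),
                         threshold_deg_s = 30, min_duration_s = 0.010,
                         window = 21, order = 9) {
  gaze <- tibble::as_tibble(gaze)
  if (!nrow(gaze)) return(empty_events())
  if (!"vel_deg_s" %in% names(gaze)) {
    gaze <- gaze_velocity(smooth_gaze(gaze, window, order), geometry)
  }
  fs <- geometry$sampling_rate_hz
  min_samples <- max(1L, round(min_duration_s * fs))
  dt <- 1 / fs

  groups <- list()
  kinds <- character(0)
  for (r in valid_runs(gaze$valid)) {
    if (length(r) < 2) next
    lab <- fill_boundary_labels(gaze$vel_deg_s[r] >= threshold_deg_s)
    for (g in merge_short_runs(lab, min_samples)) {
      groups[[length(groups) + 1L]] <- r[g]
      kinds <- c(kinds, if (isTRUE(lab[g[1]])) "saccade" else "fixation")
    }
  }
  if (!length(groups)) return(empty_events())

  first <- vapply(groups, function(i) i[1], 1L)
  last <- vapply(groups, function(i) i[length(i)], 1L)
  events <- tibble::tibble(
    kind = kinds,
    t_on = gaze$t[first],
    t_off = gaze$t[last] + dt,
    duration = (last - first + 1L) * dt,
    x = vapply(groups, function(i) mean(gaze$x[i]), 1),
    y = vapply(groups, function(i) mean(gaze$y[i]), 1),
    end_x = gaze$x[last], end_y = gaze$y[last],
    amplitude_deg = visual_angle(gaze$x[first], gaze$y[first],
                                 gaze$x[last], gaze$y[last], geometry),
    peak_vel_deg_s = vapply(groups, function(i)
      suppressWarnings(max(gaze$vel_deg_s[i], na.rm = TRUE)), 1),
    mean_vel_deg_s = vapply(groups, function(i)
      mean(gaze$vel_deg_s[i], na.rm = TRUE), 1),
    n_samples = last - first + 1L
  )
  events$peak_vel_deg_s[!is.finite(events$peak_vel_deg_s)] <- NA_real_
  events
}

empty_events <- function() {
  tibble::tibble(
    kind = character(), t_on = numeric(), t_off = numeric(),
    duration = numeric(), x = numeric(), y = numeric(),
    end_x = numeric(), end_y = numeric(), amplitude_deg = numeric(),
    peak_vel_deg_s = numeric(), mean_vel_deg_s = numeric(),
    n_samples = integer()
  )
}

# run-boundary samples have undefined velocity; give them the label of the
# nearest classified sample (fixation if the whole run is unclassified)
fill_boundary_labels <- function(lab) {
  if (all(is.na(lab))) return(rep(FALSE, length(lab)))
  idx <- which(!is.na(lab))
  first <- idx[1]; last <- idx[length(idx)]
  if (first > 1) lab[seq_len(first - 1)] <- lab[first]
  if (last < length(lab)) lab[(last + 1):length(lab)] <- lab[last]
  # interior NAs (shouldn't occur): forward fill
  for (i in which(is.na(lab))) lab[i] <- lab[i - 1]
  lab
}

# group indices 1..n into runs of equal label, merging runs shorter than
# min_samples into the preceding run (the following run at the start)
merge_short_runs <- function(lab, min_samples) {
  r <- rle(lab)
  while (length(r$lengths) > 1 && any(r$lengths < min_samples)) {
    j <- which(r$lengths < min_samples)[1]
    tgt <- if (j == 1) 2L else j - 1L
    r$lengths[tgt] <- r$lengths[tgt] + r$lengths[j]
    r$lengths <- r$lengths[-j]
    r$values <- r$values[-j]
    # re-merge neighbours that became equal
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  purrr::map2(starts, ends, seq)
}

#' Calibration-validation gate
#'
#' A validation point passes if its measured accuracy error is within
#' `limit_deg` of visual angle (boundary inclusive); the recording is
#' excluded if more than `max_failures` of the points fail.
#'
#' @param errors_deg Numeric vector of per-point accuracy errors (degrees);
#'   exactly three points in the protocol this package models.
#' @param limit_deg Per-point error limit (default 2).
#' @param max_failures Number of failing points tolerated (default 1).
#' @param n_points Required number of validation points (default 3).
#' @return `TRUE` (pass) or `FALSE` (exclude).
#' @examples
#' validate_calibration(c(2.5, 1.0, 1.5)) # one failure tolerated
#' validate_calibration(c(2.5, 2.5, 1.0)) # two failures: exclude
#' @export
validate_calibration <- function(errors_deg, limit_deg = 2, max_failures = 1,
                                 n_points = 3) {
  if (length(errors_deg) != n_points) {
    stop("expected ", n_points, " validation points, got ",
         length(errors_deg), call. = FALSE)
  }
  sum(errors_deg > limit_deg) <= max_failures
}

#' Preprocess all trials of a gaze table
#'
#' Convenience wrapper: splits a multi-trial gaze table by (participant,)
#' trial, smooths, differentiates and segments each stream, and returns the
#' combined event table.
#'
#' @param gaze A gaze tibble with `trial` (and optionally `id`) columns.
#' @inheritParams segment_gaze
#' @return An event tibble with `id`/`trial` columns prepended.
#' @export
preprocess_gaze <- function(gaze, geometry = screen_geometry(),
                            threshold_deg_s = 30, min_duration_s = 0.010,
                            window = 21, order = 9) {
  keys <- intersect(c("id", "trial"), names(gaze))
  gaze |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(g, key) {
      segment_gaze(g, geometry, threshold_deg_s, min_duration_s,
                   window, order)
    }) |>
    dplyr::ungroup()
}
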