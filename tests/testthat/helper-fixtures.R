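# shared fixtures and independent oracles, built in code

geom300 <- screen_geometry()

# a constant-position gaze stream with optional gaussian jitter
make_fixation_stream <- function(n = 200, x = 0.5, y = 0.5, jitter = 0,
                                 fs = 300, t0 = 0) {
  tibble::tibble(
    t = t0 + (seq_len(n) - 1) / fs,
    x = x + rnorm(n, 0, jitter),
    y = y + rnorm(n, 0, jitter),
    valid = TRUE
  )
}

# one smooth step displacement (sigmoid) between two anchors; produces a
# fixation - saccade - fixation pattern with a known peak velocity
make_step_stream <- function(x0 = 0.3, x1 = 0.7, y = 0.5,
                             n_pre = 120, n_move = 15, n_post = 120,
                             fs = 300) {
  n <- n_pre + n_move + n_post
  t <- (seq_len(n) - 1) / fs
  frac <- c(rep(0, n_pre),
            plogis(2 * log(99) * (seq_len(n_move) - (n_move + 1) / 2) /
                     n_move),
            rep(1, n_post))
  tibble::tibble(t = t, x = x0 + frac * (x1 - x0), y = y, valid = TRUE)
}

# Per-sample x-increment so that the central-difference chord velocity is
# exactly `v` deg/s (chord angle depends only on displacement, so a linear
# ramp has constant velocity everywhere)
norm_slope_for <- function(v, geometry = geom300, dt = 1 / 300) {
  (geometry$viewing_distance_cm / geometry$width_cm) *
    tan(v * dt * pi / 180) / dt
}

# continuous multi-step path: sigmoid moves between successive anchors with
# fixation plateaus, no positional jumps
make_path_stream <- function(xs, ys, n_fix, n_move, fs = 300) {
  stopifnot(length(xs) == length(ys), length(n_fix) == length(xs),
            length(n_move) == length(xs) - 1)
  x <- rep(xs[1], n_fix[1])
  y <- rep(ys[1], n_fix[1])
  for (i in seq_along(n_move)) {
    frac <- plogis(2 * log(99) *
                     (seq_len(n_move[i]) - (n_move[i] + 1) / 2) / n_move[i])
    x <- c(x, xs[i] + frac * (xs[i + 1] - xs[i]), rep(xs[i + 1], n_fix[i + 1]))
    y <- c(y, ys[i] + frac * (ys[i + 1] - ys[i]), rep(ys[i + 1], n_fix[i + 1]))
  }
  tibble::tibble(t = (seq_along(x) - 1) / fs, x = x, y = y, valid = TRUE)
}

# Independent brute-force I-VT oracle: per-sample threshold labels,
# boundary samples inherit the nearest label, run-length grouping. No
# minimum-duration merging (use only on streams without sub-minimum runs).
oracle_segment <- function(gaze, geometry, threshold = 30) {
  v <- gaze_velocity(gaze, geometry)$vel_deg_s
  lab <- v >= threshold
  # fill NAs from nearest classified neighbour (simple two-pass)
  for (i in seq_along(lab)) {
    if (is.na(lab[i]) && i > 1) lab[i] <- lab[i - 1]
  }
  for (i in rev(seq_along(lab))) {
    if (is.na(lab[i]) && i < length(lab)) lab[i] <- lab[i + 1]
  }
  r <- rle(lab)
  tibble::tibble(
    kind = ifelse(r$values, "saccade", "fixation"),
    n_samples = r$lengths
  )
}

# exhaustive-permutation two-sided Mann-Whitney p for tie-free samples
oracle_mwu_exact <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(n, n1), 2, u_of)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# naive Benjamini-Hochberg step-up rule, written independently
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, m / i * p[o[i]])
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# small handcrafted event tables for the AOI behaviour codes
make_event <- function(kind, t_on, t_off, x, y, end_x = x, end_y = y) {
  tibble::tibble(
    kind = kind, t_on = t_on, t_off = t_off, duration = t_off - t_on,
    x = x, y = y, end_x = end_x, end_y = end_y,
    amplitude_deg = 0, peak_vel_deg_s = 100, mean_vel_deg_s = 50,
    n_samples = as.integer(round((t_off - t_on) * 300))
  )
}

social_trial <- function(cue_q = "TL", target_q = "TL",
                         congruency = "congruent",
                         t_target = 1, t_resp = 2.5, t_end = 2.6) {
  list(
    cue_type = "social", congruency = congruency,
    cue_quadrant = cue_q, target_quadrant = target_q,
    distractor_quadrant = setdiff(c("TL", "TR", "BL", "BR"),
                                  c(cue_q, target_q))[1],
    soa_ms = 500, t_cue_on = 0, t_cue_point_end = 0.5,
    t_target_on = t_target, t_response = t_resp, t_trial_end = t_end,
    correct = TRUE
  )
}

# minimal participant table for filter tests
make_participants <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(purrr::map(rows, tibble::as_tibble))
}

# long-format simulator for LMM tests: participants x 4 conditions
make_lmm_data <- function(n_per_group, group_effect = 0, subj_sd = 1,
                          noise_sd = 1) {
  n <- 2 * n_per_group
  grid <- tidyr::expand_grid(
    id = paste0("s", seq_len(n)),
    congruency = c("congruent", "incongruent"),
    soa = c("0.25", "0.5")
  )
  subj <- tibble::tibble(
    id = paste0("s", seq_len(n)),
    group = rep(c("ADHD", "TD"), each = n_per_group),
    b0 = rnorm(n, 0, subj_sd),
    age = rnorm(n, 8, 1), sex = sample(c("male", "female"), n, TRUE),
    cars = rnorm(n, 16, 2), cdi = rnorm(n, 10, 4),
    staic_state = rnorm(n, 31, 5), staic_trait = rnorm(n, 29, 5)
  )
  dplyr::left_join(grid, subj, by = "id") |>
    dplyr::mutate(value = b0 + group_effect * (group == "ADHD") +
                    rnorm(dplyr::n(), 0, noise_sd))
}
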