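#' Group-level simulation parameters
#'
#' Bundles the oculomotor, behavioural and questionnaire parameters that
#' condition the synthetic-data generator for one diagnostic group. Use
#' [adhd_params()] and [td_params()] for defaults calibrated to the cohort
#' this package models; `group_params()` lets you override any subset.
#'
#' Oculomotor parameters (seconds / degrees / normalized units):
#' * `fix_dur_mean_s`, `fix_dur_sd_s`: within-trial distribution of single
#'   fixation durations during target search; `fix_dur_between_sd_s` is the
#'   between-participant SD of the mean.
#' * `rja_prob`: probability that, given an overt gaze shift occurs, the
#'   first shift out of the central cue area lands in the cued quadrant
#'   (response to joint attention). `rja_logit_sd` is the
#'   between-participant spread on the logit scale.
#' * `peripheral_prob`: probability that a trial is resolved by peripheral
#'   vision, i.e. gaze never leaves the central cue area during target
#'   detection; `peripheral_logit_sd` as above.
#' * `null_rate_mean`, `null_rate_between_sd`, `null_rate_trial_sd`:
#'   mean track-loss fraction, its between-participant SD, and the SD of
#'   the per-trial target fraction around the participant mean.
#' * `rt_shift_s`, `rt_meanlog`, `rt_sdlog`: shifted-lognormal reaction
#'   time model, `rt = shift + exp(N(meanlog, sdlog))`;
#'   `rt_subject_sdlog` shifts `meanlog` per participant and
#'   `rt_sdlog_subject_sd` spreads the within-participant RT variability
#'   (lognormal multiplier), so that participant-level RT-SD itself varies
#'   across children; `null_trial_sd_subject_sd` does the same for the
#'   per-trial track-loss spread.
#' * `gce_rt_s`: additive reaction-time cost on incongruent social trials
#'   (drives the gaze-cueing effect in RT).
#' * `gce_extra_saccades`: expected number of extra short re-fixations
#'   inserted in incongruent social trials (drives the gaze-cueing effect
#'   in saccade count).
#' * `accuracy`: probability of a correct key press;
#'   `accuracy_incong_penalty` is subtracted on incongruent trials;
#'   `accuracy_logit_sd` spreads accuracy across participants.
#' * `explore_spread`: SD (normalized units) of search-fixation scatter
#'   around quadrant centres; larger values produce longer, faster
#'   saccades and more dispersed fixations.
#' * `latency_mean_s`, `latency_sd_s`: delay from target onset to the
#'   first gaze shift.
#' * `noise_sd`: per-sample fixational noise (normalized units).
#' * `miss_prob`: probability a trial ends without any key press.
#' * `calib_error_mean_deg`, `calib_error_sd_deg`: distribution of
#'   per-point calibration-validation error.
#'
#' Questionnaire parameters are `c(mean, sd)` pairs on each instrument's
#' reported scale: `kars_inattention`, `kars_hyperactivity` (0-27 each),
#' `cars` (15-60), `cdi` (0-54), `staic_state`, `staic_trait` (20-60),
#' plus `age` (years, 6-10) and `male_ratio`.
#'
#' @param ... Named overrides of the defaults listed above.
#' @return A `gc_group_params` list.
#' @examples
#' td_params(rja_prob = 0.9)
#' @export
group_params <- function(...) {
  defaults <- list(
    fix_dur_mean_s = 0.26, fix_dur_sd_s = 0.07, fix_dur_between_sd_s = 0.08,
    rja_prob = 0.77, rja_logit_sd = 0.40,
    peripheral_prob = 0.56, peripheral_logit_sd = 0.35,
    null_rate_mean = 0.05, null_rate_between_sd = 0.03, null_rate_trial_sd = 0.10,
    null_trial_sd_subject_sd = 0.5,
    rt_shift_s = 0.30, rt_meanlog = log(2.0), rt_sdlog = 0.12,
    rt_subject_sdlog = 0.08, rt_sdlog_subject_sd = 0.6,
    gce_rt_s = 0.03, gce_extra_saccades = 0,
    accuracy = 0.98, accuracy_logit_sd = 0.8, accuracy_incong_penalty = 0.02,
    explore_spread = 0.12,
    latency_mean_s = 0.18, latency_sd_s = 0.03,
    noise_sd = 0.001, miss_prob = 0.02,
    calib_error_mean_deg = 1.84, calib_error_sd_deg = 0.30,
    age = c(7.9, 0.9), male_ratio = 12 / 27,
    kars_inattention = c(3.5, 2.8), kars_hyperactivity = c(2.1, 2.1),
    cars = c(15.1, 0.4), cdi = c(7.7, 3.7),
    staic_state = c(30.6, 4.9), staic_trait = c(28.3, 5.2)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown group parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- utils::modifyList(defaults, overrides)
  probs <- c("rja_prob", "peripheral_prob", "accuracy", "miss_prob",
             "male_ratio", "null_rate_mean")
  for (p in probs) {
    if (out[[p]] < 0 || out[[p]] > 1) {
      stop("`", p, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(out, class = "gc_group_params")
}

#' @rdname group_params
#' @export
td_params <- function(...) group_params(...)

#' @rdname group_params
#' @export
adhd_params <- function(...) {
  base <- list(
    fix_dur_mean_s = 0.45, fix_dur_sd_s = 0.10, fix_dur_between_sd_s = 0.12,
    rja_prob = 0.67, rja_logit_sd = 0.50,
    peripheral_prob = 0.64, peripheral_logit_sd = 0.40,
    null_rate_mean = 0.11, null_rate_between_sd = 0.08, null_rate_trial_sd = 0.15,
    rt_shift_s = 0.30, rt_meanlog = log(2.2), rt_sdlog = 0.25,
    rt_subject_sdlog = 0.12, rt_sdlog_subject_sd = 0.7,
    gce_rt_s = 0.12, gce_extra_saccades = 6,
    accuracy = 0.93, accuracy_logit_sd = 1.2, accuracy_incong_penalty = 0.12,
    explore_spread = 0.08,
    calib_error_mean_deg = 1.57,
    age = c(7.7, 1.0), male_ratio = 16 / 19,
    kars_inattention = c(13.7, 6.0), kars_hyperactivity = c(8.7, 6.0),
    cars = c(18.7, 5.3), cdi = c(13.0, 6.5),
    staic_state = c(33.3, 6.9), staic_trait = c(30.3, 5.8)
  )
  do.call(group_params, utils::modifyList(base, list(...)))
}

#' Cohort specification for the synthetic-data generator
#'
#' @param n_adhd,n_td Number of participants per group.
#' @param adhd,td [group_params()] for each group.
#' @return A `gc_cohort_spec` list.
#' @examples
#' cohort_spec(n_adhd = 3, n_td = 3)
#' @export
cohort_spec <- function(n_adhd = 19, n_td = 27,
                        adhd = adhd_params(), td = td_params()) {
  stopifnot(
    is_scalar_number(n_adhd), n_adhd >= 0,
    is_scalar_number(n_td), n_td >= 0,
    inherits(adhd, "gc_group_params"), inherits(td, "gc_group_params")
  )
  structure(
    list(n_adhd = as.integer(n_adhd), n_td = as.integer(n_td),
         adhd = adhd, td = td),
    class = "gc_cohort_spec"
  )
}

#' Simulate questionnaire and demographic covariates
#'
#' Draws per-participant questionnaire scores from the group distributions,
#' clipped to each instrument's legal range with the location adjusted so
#' that the clipped mean matches the requested mean. The KARS total is the
#' sum of its two subscales.
#'
#' @param n Number of participants.
#' @param params A [group_params()] object.
#' @param seed Optional integer seed.
#' @return A tibble with `age`, `sex`, `kars_inattention`,
#'   `kars_hyperactivity`, `kars_total`, `cars`, `cdi`, `staic_state`,
#'   `staic_trait`.
#' @examples
#' simulate_questionnaires(5, td_params(), seed = 1)
#' @export
simulate_questionnaires <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "gc_group_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  draw <- function(key, lo, hi) {
    p <- params[[key]]
    rnorm_clipped(n, p[1], p[2], lo, hi)
  }
  inatt <- draw("kars_inattention", 0, 27)
  hyper <- draw("kars_hyperactivity", 0, 27)
  tibble::tibble(
    age = draw("age", 6, 10),
    sex = factor(ifelse(runif(n) < params$male_ratio, "male", "female"),
                 levels = c("male", "female")),
    kars_inattention = inatt,
    kars_hyperactivity = hyper,
    kars_total = inatt + hyper,
    cars = draw("cars", 15, 60),
    cdi = draw("cdi", 0, 54),
    staic_state = draw("staic_state", 20, 60),
    staic_trait = draw("staic_trait", 20, 60)
  )
}
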