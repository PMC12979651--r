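# trial-level feature columns and their aggregation rule
CONTINUOUS_FEATURES <- c(
  rt = "rt", nsacc = "n_saccades", sacc_len = "saccade_length_deg",
  sacc_vel = "saccade_velocity_deg_s", fix_dur_cue_soa = "fix_dur_cue_soa",
  sd_fix = "sd_fix_locations_deg", null_rate = "null_rate",
  per_fix_dur = "per_fixation_duration"
)
BINARY_FEATURES <- c(acc = "correct", rja = "rja", peripheral = "peripheral")

soa_label <- function(soa_ms) {
  format(soa_ms / 1000, trim = TRUE, drop0trailing = TRUE)
}

#' Collapse trial features to participant-by-condition cells
#'
#' Aggregates the per-trial feature table into one value per participant,
#' feature, cue type, SOA and congruency cell: medians for continuous
#' measures (robust to outliers), means for binary behaviour codes (so the
#' cell value is an occurrence rate). RT is aggregated regardless of
#' response accuracy; `rt_correct` (median RT over correct trials only) is
#' emitted as an additional feature.
#'
#' @param trial_features Output of [extract_features()].
#' @return A long tibble: `id`, `feature`, `cue_type`, `soa`, `congruency`,
#'   `value`. Cells with no defined trials carry `NA`.
#' @export
aggregate_conditions <- function(trial_features) {
  tf <- dplyr::mutate(trial_features, soa = soa_label(.data$soa_ms))
  med <- function(v) if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  avg <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)

  long_cont <- tf |>
    dplyr::select(dplyr::all_of(c("id", "cue_type", "soa", "congruency",
                                  unname(CONTINUOUS_FEATURES)))) |>
    tidyr::pivot_longer(dplyr::all_of(unname(CONTINUOUS_FEATURES)),
                        names_to = "feature") |>
    dplyr::mutate(feature = names(CONTINUOUS_FEATURES)[
      match(.data$feature, CONTINUOUS_FEATURES)]) |>
    dplyr::group_by(.data$id, .data$feature, .data$cue_type, .data$soa,
                    .data$congruency) |>
    dplyr::summarise(value = med(.data$value), .groups = "drop")

  long_bin <- tf |>
    dplyr::select(dplyr::all_of(c("id", "cue_type", "soa", "congruency",
                                  unname(BINARY_FEATURES)))) |>
    tidyr::pivot_longer(dplyr::all_of(unname(BINARY_FEATURES)),
                        names_to = "feature") |>
    dplyr::mutate(feature = names(BINARY_FEATURES)[
      match(.data$feature, BINARY_FEATURES)]) |>
    dplyr::group_by(.data$id, .data$feature, .data$cue_type, .data$soa,
                    .data$congruency) |>
    dplyr::summarise(value = avg(as.numeric(.data$value)), .groups = "drop")

  long_rtc <- tf |>
    dplyr::filter(!is.na(.data$correct), .data$correct) |>
    dplyr::group_by(.data$id, .data$cue_type, .data$soa, .data$congruency) |>
    dplyr::summarise(value = med(.data$rt), .groups = "drop") |>
    dplyr::mutate(feature = "rt_correct")

  dplyr::bind_rows(long_cont, long_bin, long_rtc) |>
    dplyr::arrange(.data$id, .data$feature, .data$cue_type, .data$soa,
                   .data$congruency)
}

#' Participant-level feature matrix
#'
#' Builds the wide per-participant feature matrix used for screening and
#' classification: one column per (feature, cue type, SOA, congruency)
#' cell named `feature.cue.soa.congruency` (e.g. `nsacc.social.0.25.cong`),
#' gaze-cueing-effect columns `gce_<feature>.<soa>` (incongruent minus
#' congruent, social cues), and whole-session summaries (`rt_sd`, total
#' and SD of the null-data rate, social per-fixation duration, overall
#' accuracy and RJA / peripheral-vision rates). Participant metadata is
#' joined when supplied.
#'
#' @param trial_features Output of [extract_features()].
#' @param participants Optional participant table (joined on `id`).
#' @return A wide tibble, one row per participant.
#' @export
aggregate_participants <- function(trial_features, participants = NULL) {
  long <- aggregate_conditions(trial_features)
  wide <- long |>
    dplyr::mutate(
      congruency = dplyr::recode(.data$congruency,
                                 congruent = "cong", incongruent = "incong"),
      col = paste(.data$feature, .data$cue_type, .data$soa, .data$congruency,
                  sep = ".")
    ) |>
    dplyr::select("id", "col", "value") |>
    tidyr::pivot_wider(names_from = "col", values_from = "value")

  gce <- long |>
    dplyr::filter(.data$cue_type == "social") |>
    tidyr::pivot_wider(names_from = "congruency", values_from = "value") |>
    dplyr::mutate(value = .data$incongruent - .data$congruent,
                  col = paste0("gce_", .data$feature, ".", .data$soa)) |>
    dplyr::select("id", "col", "value") |>
    tidyr::pivot_wider(names_from = "col", values_from = "value")

  med <- function(v) if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  totals <- trial_features |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      rt_sd = sd(.data$rt, na.rm = TRUE),
      null_rate_total = med(.data$null_rate),
      sd_null_rate = sd(.data$null_rate, na.rm = TRUE),
      acc_total = mean(.data$correct, na.rm = TRUE),
      per_fix_dur_social = med(.data$per_fixation_duration[
        .data$cue_type == "social"]),
      rja_rate_social = mean(.data$rja[.data$cue_type == "social"],
                             na.rm = TRUE),
      peripheral_rate_social = mean(.data$peripheral[.data$cue_type == "social"],
                                    na.rm = TRUE),
      .groups = "drop"
    )

  out <- wide |>
    dplyr::left_join(gce, by = "id") |>
    dplyr::left_join(totals, by = "id")
  if (!is.null(participants)) {
    out <- dplyr::left_join(participants, out, by = "id")
  }
  out
}

#' Gaze-cueing effect of one feature at one SOA
#'
#' The incongruent-minus-congruent contrast for a feature under social
#' cues at a given SOA, read off a participant matrix built by
#' [aggregate_participants()]. `NA` when either condition cell is missing.
#'
#' @param data Participant matrix.
#' @param feature Feature key, e.g. `"rt"` or `"nsacc"`.
#' @param soa SOA in seconds (`0.25`, `0.5` or `0.75`).
#' @return Numeric vector, one value per row of `data`.
#' @examples
#' df <- tibble::tibble(id = "p1", rt.social.0.5.cong = 0.40,
#'                      rt.social.0.5.incong = 0.52)
#' compute_gce(df, "rt", 0.5)
#' @export
compute_gce <- function(data, feature, soa) {
  soa <- format(soa, trim = TRUE, drop0trailing = TRUE)
  incong <- data[[paste(feature, "social", soa, "incong", sep = ".")]]
  cong <- data[[paste(feature, "social", soa, "cong", sep = ".")]]
  if (is.null(incong) || is.null(cong)) {
    stop("condition columns for ", feature, " at SOA ", soa,
         " not found", call. = FALSE)
  }
  incong - cong
}

#' Apply cohort eligibility filters
#'
#' Removes participants who fail the symptom-screening rules or the
#' eye-tracker calibration gate: ADHD rows with a KARS inattention score
#' at or below 5 (1 SD below the reference clinical mean), TD rows with
#' inattention at or above 10 or a KARS total at or above 18, any row with
#' a CARS total at or above 37 (autism risk), and any row whose
#' calibration validation failed (`calib_pass == FALSE`, when present).
#' Rows with missing screening covariates are retained but flagged.
#'
#' @param participants Participant table with `group`, `kars_inattention`,
#'   `kars_total`, `cars` (and optionally `calib_pass`).
#' @return The filtered tibble, with a logical `screen_flag` column for
#'   rows with missing covariates and an `"exclusions"` attribute (tibble
#'   of `id`, `reason`) recording each removal; also retrievable via
#'   [exclusion_log()].
#' @export
apply_eligibility_filters <- function(participants) {
  p <- participants
  need <- c("kars_inattention", "kars_total", "cars")
  missing_cov <- !complete.cases(p[, intersect(need, names(p)), drop = FALSE])

  reason <- rep(NA_character_, nrow(p))
  mark <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    ifelse(is.na(reason) & cond, why, reason)
  }
  reason <- mark(p$group == "ADHD" & p$kars_inattention <= 5,
                 "ADHD inattention <= 5")
  reason <- mark(p$group == "TD" & p$kars_inattention >= 10,
                 "TD inattention >= 10")
  reason <- mark(p$group == "TD" & p$kars_total >= 18, "TD KARS total >= 18")
  reason <- mark(p$cars >= 37, "CARS >= 37")
  if ("calib_pass" %in% names(p)) {
    reason <- mark(!p$calib_pass, "failed calibration validation")
  }

  excluded <- !is.na(reason)
  out <- p[!excluded, , drop = FALSE]
  out$screen_flag <- missing_cov[!excluded]
  attr(out, "exclusions") <- tibble::tibble(
    id = p$id[excluded], reason = reason[excluded]
  )
  out
}

#' @rdname apply_eligibility_filters
#' @param filtered The tibble returned by [apply_eligibility_filters()].
#' @export
exclusion_log <- function(filtered) {
  attr(filtered, "exclusions") %||%
    tibble::tibble(id = character(), reason = character())
}

#' Median-impute missing feature cells within group
#'
#' Missing condition cells (e.g. a participant with no valid trials in one
#' design cell) are imputed with the group-wise median before modelling;
#' group-comparison statistics elsewhere use complete cases. A logical
#' `<column>_imputed` flag is recorded in the `"imputed"` attribute.
#'
#' @param data Participant matrix with a `group` column.
#' @param cols Columns to impute (default: all numeric feature columns).
#' @return `data` with imputed values.
#' @export
impute_features <- function(data, cols = NULL) {
  if (is.null(cols)) {
    cols <- names(data)[vapply(data, is.numeric, TRUE)]
  }
  flags <- list()
  for (cl in cols) {
    miss <- !is.finite(data[[cl]])
    if (any(miss)) {
      for (g in unique(data$group)) {
        gi <- data$group == g
        m <- median(data[[cl]][gi & !miss], na.rm = TRUE)
        if (!is.finite(m)) m <- median(data[[cl]][!miss], na.rm = TRUE)
        data[[cl]][gi & miss] <- m
      }
      flags[[cl]] <- miss
    }
  }
  attr(data, "imputed") <- flags
  data
}
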