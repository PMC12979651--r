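#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated
#' object. Defaults reproduce the study conditions this package models:
#' 30 deg/s velocity threshold, Savitzky-Golay window 21 / order 9,
#' stepwise threshold 0.035, 5-fold cross-validation repeated 50 times,
#' SOAs of 250/500/750 ms, a 500 ms cue phase, 4 blocks of 36 trials,
#' 65 cm viewing distance and 300 Hz sampling.
#'
#' @param geometry A [screen_geometry()].
#' @param task A [task_config()].
#' @param cohort A [cohort_spec()].
#' @param aoi An [aoi_layout()].
#' @param velocity_threshold Saccade threshold in deg/s.
#' @param sg_window,sg_order Savitzky-Golay smoothing parameters.
#' @param min_event_duration_s Minimum event duration for segmentation.
#' @param alpha_screen LMM screening threshold.
#' @param alpha_final BH-adjusted retention threshold.
#' @param alpha_stepwise Stepwise entry/exit threshold.
#' @param cv_folds,cv_repeats Cross-validation settings.
#' @return A `gc_config` list.
#' @export
pipeline_config <- function(geometry = screen_geometry(),
                            task = task_config(),
                            cohort = cohort_spec(),
                            aoi = aoi_layout(),
                            velocity_threshold = 30,
                            sg_window = 21, sg_order = 9,
                            min_event_duration_s = 0.010,
                            alpha_screen = 0.15, alpha_final = 0.05,
                            alpha_stepwise = 0.035,
                            cv_folds = 5, cv_repeats = 50) {
  stopifnot(
    inherits(geometry, "gc_geometry"), inherits(task, "gc_task"),
    inherits(cohort, "gc_cohort_spec"), inherits(aoi, "gc_aoi"),
    velocity_threshold > 0, sg_window %% 2 == 1, sg_window > sg_order,
    alpha_screen > 0, alpha_screen < 1, alpha_final > 0, alpha_final < 1,
    alpha_stepwise > 0, alpha_stepwise < 1,
    cv_folds >= 2, cv_repeats >= 1
  )
  structure(
    list(geometry = geometry, task = task, cohort = cohort, aoi = aoi,
         velocity_threshold = velocity_threshold,
         sg_window = sg_window, sg_order = sg_order,
         min_event_duration_s = min_event_duration_s,
         alpha_screen = alpha_screen, alpha_final = alpha_final,
         alpha_stepwise = alpha_stepwise,
         cv_folds = cv_folds, cv_repeats = cv_repeats),
    class = "gc_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage end to end on a simulated cohort: generate
#' participants (schedules, responses, gaze streams), preprocess and
#' segment each trial's gaze, extract trial features, apply eligibility
#' filters, aggregate to the participant matrix, run the LMM +
#' Mann-Whitney/BH screening funnel, select features by stepwise logistic
#' regression, cross-validate the classifier and prune by importance.
#' Gaze streams are processed one participant at a time and discarded, so
#' memory stays flat in cohort size. Deterministic given `seed`.
#'
#' @param config A [pipeline_config()].
#' @param seed Master integer seed.
#' @param verbose Print per-stage progress.
#' @return A `gc_pipeline_result` list: `participants` (post-filter, with
#'   exclusion log attribute), `trial_features`, `participant_matrix`,
#'   `screening` (`gc_screen`), `stepwise` (selected features + trace),
#'   `cv` and `pruned` (`gc_cv_report`s), `config`, `seed`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(cohort = cohort_spec(n_adhd = 4, n_td = 4),
#'                        cv_repeats = 5)
#' res <- run_pipeline(cfg, seed = 1, verbose = FALSE)
#' glance(res$cv)
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         verbose = TRUE) {
  stopifnot(inherits(config, "gc_config"))
  say <- function(...) if (verbose) message("[gazecue] ", ...)
  t_start <- Sys.time()

  spec <- config$cohort
  n_total <- spec$n_adhd + spec$n_td
  seeds <- derive_seeds(seed, n_total + 2L)
  groups <- c(rep("ADHD", spec$n_adhd), rep("TD", spec$n_td))
  ids <- c(sprintf("adhd%02d", seq_len(spec$n_adhd)),
           sprintf("td%02d", seq_len(spec$n_td)))

  say("simulating and preprocessing ", n_total, " participants")
  parts <- vector("list", n_total)
  feats <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    p <- if (groups[i] == "ADHD") spec$adhd else spec$td
    sim <- simulate_participant(
      ids[i], groups[i], p, config$task, config$geometry, config$aoi,
      seed = seeds[i],
      first_cue_type = if (i %% 2L == 1L) "social" else "nonsocial"
    )
    parts[[i]] <- sim$participant
    feats[[i]] <- suppressWarnings(extract_features(
      sim$gaze, sim$trials, config$aoi, config$geometry,
      threshold_deg_s = config$velocity_threshold,
      min_duration_s = config$min_event_duration_s,
      window = config$sg_window, order = config$sg_order
    ))
  }
  participants <- dplyr::bind_rows(parts)
  trial_features <- dplyr::bind_rows(feats)

  participants <- apply_eligibility_filters(participants)
  excl <- exclusion_log(participants)
  if (nrow(excl)) {
    say(nrow(excl), " participant(s) excluded by eligibility filters")
    trial_features <- trial_features[
      trial_features$id %in% participants$id, , drop = FALSE]
  }

  say("aggregating participant matrix")
  pm <- aggregate_participants(trial_features, participants)
  cond_long <- aggregate_conditions(trial_features) |>
    dplyr::left_join(
      dplyr::select(participants, dplyr::all_of(
        c("id", "group", "age", "sex", "cars", "cdi",
          "staic_state", "staic_trait"))),
      by = "id"
    )

  say("screening features (LMM funnel + Mann-Whitney/BH)")
  screening <- suppressWarnings(screen_features(
    cond_long, pm, alpha_screen = config$alpha_screen,
    alpha_final = config$alpha_final))
  survivors <- screening$tests$feature[screening$tests$selected]
  say(length(survivors), " features survive the funnel")

  model_data <- impute_features(pm, cols = setdiff(
    names(pm)[vapply(pm, is.numeric, TRUE)],
    c("age", "cars", "cdi", "staic_state", "staic_trait",
      "kars_inattention", "kars_hyperactivity", "kars_total",
      "calib_error_mean")))

  selected <- if (length(survivors)) {
    stepwise_select(model_data, outcome = "group", candidates = survivors,
                    alpha = config$alpha_stepwise)
  } else character(0)
  say("stepwise selection kept ", length(selected), " feature(s): ",
      paste(selected, collapse = ", "))

  cv <- cross_validate(model_data, outcome = "group", features = selected,
                       k = config$cv_folds, repeats = config$cv_repeats,
                       seed = seeds[n_total + 1L])
  pruned <- if (length(selected) > 1) {
    prune_by_importance(cv, model_data, outcome = "group")
  } else cv
  say(sprintf("cross-validated AUC %.3f (pruned model: %.3f); elapsed %.1f s",
              cv$summary$auc, pruned$summary$auc,
              as.numeric(difftime(Sys.time(), t_start, units = "secs"))))

  structure(
    list(participants = participants, trial_features = trial_features,
         participant_matrix = pm, condition_long = cond_long,
         screening = screening, stepwise = selected,
         cv = cv, pruned = pruned, config = config, seed = seed),
    class = "gc_pipeline_result"
  )
}

#' @export
print.gc_pipeline_result <- function(x, ...) {
  cat("<gc_pipeline_result>\n")
  cat("  participants: ", nrow(x$participants), " (",
      sum(x$participants$group == "ADHD"), " ADHD / ",
      sum(x$participants$group == "TD"), " TD)\n", sep = "")
  cat("  screened features retained:", sum(x$screening$tests$selected), "\n")
  cat("  stepwise-selected:", paste(x$stepwise, collapse = ", "), "\n")
  s <- x$pruned$summary
  cat(sprintf("  final model: AUC %.3f, accuracy %.3f, kappa %.3f (%s)\n",
              s$auc, s$accuracy, s$kappa, kappa_label(s$kappa)))
  invisible(x)
}
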