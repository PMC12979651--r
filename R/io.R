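#' Write a simulated cohort to delimited text files
#'
#' Lays a cohort out on disk the way a recording session would be
#' archived: `participants.tsv`, `trials.tsv`, one gaze file per
#' participant under `gaze/<id>.tsv` (columns `time_s`, `x_norm`,
#' `y_norm`, `valid`), and a `manifest.txt` of key-value pairs describing
#' the generating configuration.
#'
#' @param cohort A `gc_cohort` from [simulate_cohort()] (with gaze kept).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gc_cohort"), !is.null(cohort$gaze))
  dir.create(file.path(dir, "gaze"), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$participants, file.path(dir, "participants.tsv"))
  readr::write_tsv(cohort$trials, file.path(dir, "trials.tsv"))
  for (pid in unique(cohort$gaze$id)) {
    g <- cohort$gaze[cohort$gaze$id == pid, , drop = FALSE]
    readr::write_tsv(
      tibble::tibble(trial = g$trial, time_s = g$t, x_norm = g$x,
                     y_norm = g$y, valid = as.integer(g$valid)),
      file.path(dir, "gaze", paste0(pid, ".tsv"))
    )
  }
  manifest <- c(
    paste0("package=gazecue"),
    paste0("seed=", cohort$seed),
    paste0("n_adhd=", cohort$spec$n_adhd),
    paste0("n_td=", cohort$spec$n_td),
    paste0("n_blocks=", cohort$config$n_blocks),
    paste0("trials_per_block=", cohort$config$trials_per_block),
    paste0("soa_levels_ms=", paste(cohort$config$soa_levels_ms, collapse = ",")),
    paste0("cue_phase_ms=", cohort$config$cue_phase_ms),
    paste0("sampling_rate_hz=", cohort$geometry$sampling_rate_hz),
    paste0("viewing_distance_cm=", cohort$geometry$viewing_distance_cm)
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `participants.tsv`, `trials.tsv` and a
#'   `gaze/` folder. Aborts naming the participant if a gaze file listed
#'   in the trial table is missing.
#' @return A `gc_cohort`-like list with `participants`, `trials`, `gaze`
#'   and the parsed `manifest`.
#' @export
read_cohort <- function(dir) {
  participants <- readr::read_tsv(file.path(dir, "participants.tsv"),
                                  show_col_types = FALSE)
  participants$group <- factor(participants$group, levels = c("ADHD", "TD"))
  if ("sex" %in% names(participants)) {
    participants$sex <- factor(participants$sex, levels = c("male", "female"))
  }
  trials <- readr::read_tsv(file.path(dir, "trials.tsv"),
                            show_col_types = FALSE)
  gaze <- purrr::map(unique(trials$id), function(pid) {
    path <- file.path(dir, "gaze", paste0(pid, ".tsv"))
    if (!file.exists(path)) {
      stop("gaze file missing for participant ", pid, ": ", path,
           call. = FALSE)
    }
    g <- readr::read_tsv(path, show_col_types = FALSE)
    tibble::tibble(id = pid, trial = g$trial, t = g$time_s, x = g$x_norm,
                   y = g$y_norm, valid = as.logical(g$valid))
  }) |> dplyr::bind_rows()

  manifest_path <- file.path(dir, "manifest.txt")
  manifest <- if (file.exists(manifest_path)) {
    kv <- strsplit(readLines(manifest_path), "=", fixed = TRUE)
    setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
             vapply(kv, `[`, "", 1))
  } else NULL
  list(participants = participants, trials = trials, gaze = gaze,
       manifest = manifest)
}
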