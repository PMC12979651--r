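#' Gaze-cueing task configuration
#'
#' Design parameters of the cueing task: a central cue (a face with averted
#' eyes in social blocks, an arrow in nonsocial blocks) points at one of the
#' four screen corners for `cue_phase_ms`, then after a randomized stimulus
#' onset asynchrony (SOA) a target dot appears in one corner together with a
#' distractor dot in another. Defaults follow the study design this package
#' models: 4 blocks of 36 trials, SOAs of 250/500/750 ms, a 500 ms cue
#' phase, stimuli centred 0.2 normalized units from the screen centre.
#'
#' @param n_blocks Number of blocks; cue type alternates between blocks.
#' @param trials_per_block Trials per block; must be divisible by
#'   `2 * length(soa_levels_ms)` so every SOA-by-congruency cell is balanced.
#' @param soa_levels_ms SOA levels in milliseconds.
#' @param cue_phase_ms Duration of the cue-pointing phase in milliseconds.
#' @param corner_offset Normalized distance of stimulus centres from the
#'   screen centre on each axis, in `(0, 0.5)`.
#' @param stimulus_diameter_px Stimulus diameter in pixels.
#' @param iti_s Inter-trial interval in seconds (fixation point between
#'   trials).
#' @param max_response_s Response deadline after target onset, in seconds.
#' @return A `gc_task` list.
#' @examples
#' task_config()
#' @export
task_config <- function(n_blocks = 4, trials_per_block = 36,
                        soa_levels_ms = c(250, 500, 750),
                        cue_phase_ms = 500, corner_offset = 0.2,
                        stimulus_diameter_px = 77,
                        iti_s = 1, max_response_s = 4) {
  stopifnot(
    is_scalar_number(n_blocks), n_blocks >= 1,
    is_scalar_number(trials_per_block), trials_per_block >= 1,
    is.numeric(soa_levels_ms), length(soa_levels_ms) >= 1, all(soa_levels_ms > 0),
    is_scalar_number(cue_phase_ms), cue_phase_ms > 0,
    is_scalar_number(corner_offset), corner_offset > 0, corner_offset < 0.5,
    is_scalar_number(max_response_s), max_response_s > 0
  )
  n_cells <- length(soa_levels_ms) * 2L
  if (trials_per_block %% n_cells != 0) {
    stop("`trials_per_block` (", trials_per_block,
         ") is not divisible by the number of SOA x congruency cells (",
         n_cells, "); the schedule cannot be balanced", call. = FALSE)
  }
  structure(
    list(
      n_blocks = as.integer(n_blocks),
      trials_per_block = as.integer(trials_per_block),
      soa_levels_ms = sort(unique(soa_levels_ms)),
      cue_phase_ms = cue_phase_ms,
      corner_offset = corner_offset,
      stimulus_diameter_px = stimulus_diameter_px,
      iti_s = iti_s,
      max_response_s = max_response_s
    ),
    class = "gc_task"
  )
}

#' Generate a balanced session schedule
#'
#' Builds the per-trial design of one session: within each block every
#' SOA-by-congruency cell appears equally often in random order, cue type is
#' constant within a block and alternates between blocks, and cue, target
#' and distractor corners are drawn uniformly. In congruent trials the
#' target appears in the cued corner and the distractor in one of the
#' remaining corners; in incongruent trials the distractor occupies the cued
#' corner and the target one of the others, so cue and target never
#' coincide and target and distractor never coincide.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @param first_cue_type Cue type of block 1 (`"social"` or `"nonsocial"`);
#'   alternated across participants in the cohort generator.
#' @return A tibble with one row per trial: `block`, `trial` (session-wide
#'   index), `cue_type`, `congruency`, `soa_ms`, `cue_quadrant`,
#'   `target_quadrant`, `distractor_quadrant`.
#' @examples
#' sched <- generate_session_schedule(task_config(), seed = 1)
#' table(sched$block, sched$congruency)
#' @export
generate_session_schedule <- function(config = task_config(), seed = NULL,
                                      first_cue_type = c("social", "nonsocial")) {
  stopifnot(inherits(config, "gc_task"))
  first_cue_type <- match.arg(first_cue_type)
  if (!is.null(seed)) set.seed(as.integer(seed))
  cue_types <- c("social", "nonsocial")
  if (first_cue_type == "nonsocial") cue_types <- rev(cue_types)

  per_cell <- config$trials_per_block %/% (length(config$soa_levels_ms) * 2L)
  cells <- tidyr::expand_grid(
    congruency = c("congruent", "incongruent"),
    soa_ms = config$soa_levels_ms,
    rep = seq_len(per_cell)
  )

  blocks <- purrr::map(seq_len(config$n_blocks), function(b) {
    design <- cells[sample.int(nrow(cells)), c("congruency", "soa_ms")]
    n <- nrow(design)
    cue_q <- sample(QUADRANTS, n, replace = TRUE)
    target_q <- character(n)
    distractor_q <- character(n)
    for (i in seq_len(n)) {
      if (design$congruency[i] == "congruent") {
        target_q[i] <- cue_q[i]
        distractor_q[i] <- sample(setdiff(QUADRANTS, target_q[i]), 1)
      } else {
        distractor_q[i] <- cue_q[i]
        target_q[i] <- sample(setdiff(QUADRANTS, cue_q[i]), 1)
      }
    }
    tibble::tibble(
      block = b,
      cue_type = cue_types[(b - 1L) %% 2L + 1L],
      congruency = design$congruency,
      soa_ms = design$soa_ms,
      cue_quadrant = cue_q,
      target_quadrant = target_q,
      distractor_quadrant = distractor_q
    )
  })

  dplyr::bind_rows(blocks) |>
    dplyr::mutate(trial = dplyr::row_number(), .after = "block")
}
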