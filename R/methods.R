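#' @export
print.gc_cv_report <- function(x, ...) {
  s <- x$summary
  cat("<gc_cv_report> ", x$k, "-fold CV x ", x$repeats, " repetitions, n = ",
      x$n, "\n", sep = "")
  cat("  features:", if (length(x$features))
    paste(x$features, collapse = ", ") else "(intercept only)", "\n")
  cat(sprintf("  AUC %.3f | accuracy %.3f | F1 %.3f (precision %.3f / recall %.3f) | kappa %.3f (%s)\n",
              s$auc, s$accuracy, s$f1, s$precision, s$recall, s$kappa,
              kappa_label(s$kappa)))
  invisible(x)
}

#' Tidy a cross-validation report
#'
#' @param x A `gc_cv_report`.
#' @param ... Unused.
#' @return A tibble of full-data logistic coefficients (term, estimate,
#'   Wald z, p).
#' @export
tidy.gc_cv_report <- function(x, ...) x$coefficients

#' Glance at a cross-validation report
#'
#' @param x A `gc_cv_report`.
#' @param ... Unused.
#' @return A one-row tibble of mean cross-validated metrics plus model
#'   size.
#' @export
glance.gc_cv_report <- function(x, ...) {
  dplyr::bind_cols(
    x$summary,
    tibble::tibble(n_features = length(x$features), n = x$n,
                   folds = x$k, repeats = x$repeats)
  )
}

#' Tidy a screening LMM
#'
#' @param x A `gc_lmm`.
#' @param ... Unused.
#' @return Tibble of fixed-effect terms with estimate, z and p.
#' @export
tidy.gc_lmm <- function(x, ...) x$fixed

#' Glance at a screening LMM
#'
#' @param x A `gc_lmm`.
#' @param ... Unused.
#' @return One-row tibble with marginal/conditional R-squared and the
#'   singularity flag.
#' @export
glance.gc_lmm <- function(x, ...) {
  tibble::tibble(r2m = x$r2m, r2c = x$r2c, singular = x$singular)
}

#' Plot per-repetition cross-validation metrics
#'
#' @param object A `gc_cv_report`.
#' @param ... Unused.
#' @return A ggplot: one box per metric across CV repetitions.
#' @export
autoplot.gc_cv_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_repetition,
    c("auc", "accuracy", "precision", "recall", "f1", "kappa"),
    names_to = "metric"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "value",
                  title = sprintf("%d-fold CV x %d repetitions",
                                  object$k, object$repeats)) +
    ggplot2::theme_minimal()
}

#' Plot a gaze trajectory
#'
#' Simple diagnostic view of one trial's gaze path in normalized screen
#' coordinates, with the cue AOI and the quadrant stimulus positions.
#'
#' @param gaze Gaze tibble for one trial (`t`, `x`, `y`, `valid`).
#' @param trial Optional one-row trial record; if given, the target and
#'   cued quadrant centres are marked.
#' @param aoi An [aoi_layout()].
#' @return A ggplot.
#' @export
plot_gaze_trajectory <- function(gaze, trial = NULL, aoi = aoi_layout()) {
  g <- gaze[gaze$valid, , drop = FALSE]
  circ <- tibble::tibble(
    theta = seq(0, 2 * pi, length.out = 120),
    x = aoi$cue_center[1] + aoi$cue_radius * cos(.data$theta),
    y = aoi$cue_center[2] + aoi$cue_radius * sin(.data$theta)
  )
  p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.3) +
    ggplot2::geom_path(data = circ, colour = "grey40", linetype = 2) +
    ggplot2::scale_y_reverse(limits = c(1, 0)) +
    ggplot2::xlim(0, 1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (normalized)", y = "y (normalized)") +
    ggplot2::theme_minimal()
  if (!is.null(trial)) {
    trial <- as.list(trial)
    marks <- tibble::as_tibble(quadrant_center(
      c(trial$target_quadrant, trial$cue_quadrant)))
    marks$role <- c("target", "cued quadrant")
    p <- p + ggplot2::geom_point(
      data = marks,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$role),
      size = 3, shape = 4, stroke = 1.5
    )
  }
  p
}
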