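#' Screen and viewing geometry
#'
#' Describes the display and viewing setup needed to convert normalized
#' screen coordinates into visual angle. Physical screen width and height
#' are derived from the diagonal and the pixel resolution assuming square
#' pixels.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param diagonal_inches Physical screen diagonal in inches.
#' @param viewing_distance_cm Eye-to-screen distance in cm (chin-rest
#'   stabilised in the task this package models).
#' @param sampling_rate_hz Eye-tracker sampling rate in Hz.
#'
#' @return A `gc_geometry` list with the inputs plus derived `width_cm` and
#'   `height_cm`.
#' @examples
#' geom <- screen_geometry()
#' geom$width_cm
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1080,
                            diagonal_inches = 23,
                            viewing_distance_cm = 65,
                            sampling_rate_hz = 300) {
  stopifnot(
    is_scalar_number(width_px), width_px > 0,
    is_scalar_number(height_px), height_px > 0,
    is_scalar_number(diagonal_inches), diagonal_inches > 0,
    is_scalar_number(viewing_distance_cm),
    is_scalar_number(sampling_rate_hz), sampling_rate_hz > 0
  )
  if (viewing_distance_cm <= 0) {
    stop("`viewing_distance_cm` must be positive", call. = FALSE)
  }
  diag_cm <- diagonal_inches * 2.54
  scale <- diag_cm / sqrt(width_px^2 + height_px^2)
  structure(
    list(
      width_px = width_px, height_px = height_px,
      diagonal_inches = diagonal_inches,
      viewing_distance_cm = viewing_distance_cm,
      sampling_rate_hz = sampling_rate_hz,
      width_cm = width_px * scale,
      height_cm = height_px * scale
    ),
    class = "gc_geometry"
  )
}

#' Visual angle between two on-screen points
#'
#' Converts the displacement between two points given in normalized screen
#' coordinates (`[0, 1]` on each axis, origin top-left) into degrees of
#' visual angle: the normalized offsets are mapped to centimetres through
#' the physical screen size, and the chord subtense is
#' `2 * atan(d / 2 / viewing_distance)`.
#'
#' @param x1,y1,x2,y2 Normalized coordinates (vectorised).
#' @param geometry A [screen_geometry()] object.
#' @return Angle(s) in degrees. Symmetric in its two points, zero iff the
#'   points coincide.
#' @examples
#' visual_angle(0.5, 0.5, 0.7, 0.5, screen_geometry())
#' @export
visual_angle <- function(x1, y1, x2, y2, geometry = screen_geometry()) {
  stopifnot(inherits(geometry, "gc_geometry"))
  dx <- (x2 - x1) * geometry$width_cm
  dy <- (y2 - y1) * geometry$height_cm
  d <- sqrt(dx^2 + dy^2)
  2 * atan2(d / 2, geometry$viewing_distance_cm) * 180 / pi
}

# signed per-axis visual angle from screen centre; used for fixation
# dispersion so that variance is computed on an angular scale
deg_from_center <- function(x, y, geometry) {
  list(
    x = 2 * atan2((x - 0.5) * geometry$width_cm / 2,
                  geometry$viewing_distance_cm) * 180 / pi,
    y = 2 * atan2((y - 0.5) * geometry$height_cm / 2,
                  geometry$viewing_distance_cm) * 180 / pi
  )
}
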