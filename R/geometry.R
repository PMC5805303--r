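#' Workspace geometry of the reaching/tracking task
#'
#' Describes the planar workspace: a home position at the origin, five radial
#' target directions (60, 75, 90, 105, 120 degrees, counter-clockwise positive
#' from the +x axis), targets at 12 cm from home, and the display sizes of
#' target, cursor and home disc. Angles are in degrees and positions in cm
#' throughout the package; the y axis points away from the body.
#'
#' @param home Numeric length-2, home position in cm. Default `c(0, 0)`.
#' @param target_angles Numeric vector of target directions in degrees.
#'   Must contain exactly 5 distinct values.
#' @param target_radius_cm Distance from home to every final target position.
#' @param target_diameter_cm,cursor_diameter_cm,home_diameter_cm Display
#'   diameters in cm.
#'
#' @return An object of class `"target_geometry"` (a list of the fields above).
#' @examples
#' geo <- target_geometry()
#' geo$target_angles
#' @export
target_geometry <- function(home = c(0, 0),
                            target_angles = c(60, 75, 90, 105, 120),
                            target_radius_cm = 12,
                            target_diameter_cm = 1.5,
                            cursor_diameter_cm = 1.0,
                            home_diameter_cm = 1.6) {
  stopifnot(is.numeric(home), length(home) == 2L, is.finite(home))
  target_angles <- as.numeric(target_angles)
  if (length(unique(target_angles)) != 5L)
    stop("'target_angles' must contain exactly 5 distinct directions")
  stopifnot(target_radius_cm > 0)
  structure(
    list(home = as.numeric(home),
         target_angles = target_angles,
         target_radius_cm = target_radius_cm,
         target_diameter_cm = target_diameter_cm,
         cursor_diameter_cm = cursor_diameter_cm,
         home_diameter_cm = home_diameter_cm),
    class = "target_geometry")
}

#' @export
print.target_geometry <- function(x, ...) {
  cat("Target geometry: 5 targets at {", paste(x$target_angles, collapse = ", "),
      "} deg, radius ", x$target_radius_cm, " cm from home (",
      paste(x$home, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Final target position for a direction
#'
#' @param angle_deg Target direction in degrees (CCW-positive from +x).
#' @param geometry A [target_geometry()] object.
#' @return Numeric length-2 position in cm.
#' @keywords internal
target_position <- function(angle_deg, geometry = target_geometry()) {
  geometry$home + geometry$target_radius_cm * unit_vec(angle_deg)
}

unit_vec <- function(angle_deg) {
  th <- angle_deg * pi / 180
  c(cos(th), sin(th))
}

#' Wrap angles to (-180, 180]
#'
#' @param x Angles in degrees.
#' @return Angles wrapped into the half-open interval (-180, 180].
#' @examples
#' wrap_angle(c(190, -190, 180, 360))
#' @export
wrap_angle <- function(x) {
  w <- x %% 360
  ifelse(w > 180, w - 360, w)
}

#' Rotate planar points about a pivot
#'
#' @param xy A length-2 vector or an n x 2 matrix of positions.
#' @param angle_deg Rotation angle in degrees, CCW-positive.
#' @param pivot Centre of rotation (default the origin).
#' @return Rotated positions, same shape as `xy`.
#' @export
rotate_xy <- function(xy, angle_deg, pivot = c(0, 0)) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  if (is.matrix(xy)) {
    sweep(sweep(xy, 2, pivot) %*% t(R), 2, pivot, `+`)
  } else {
    as.numeric(R %*% (xy - pivot) + pivot)
  }
}

#' Colour feedback band for a cursor-to-target distance
#'
#' Classifies the centre-to-centre cursor-to-target separation into the colour
#' band shown to participants during tracking: green when the cursor overlaps
#' the target (separation no more than the sum of the target and cursor radii,
#' 1.25 cm under the default geometry), yellow up to 4 cm, orange up to 8 cm,
#' red beyond.
#'
#' @param distance_cm Non-negative centre-to-centre distance(s) in cm.
#' @param geometry A [target_geometry()] object; sets the overlap threshold.
#' @return Character vector in `{"green","yellow","orange","red"}`.
#' @examples
#' feedback_color(c(0, 2, 5, 100))
#' @export
feedback_color <- function(distance_cm, geometry = target_geometry()) {
  if (any(!is.finite(distance_cm)) || any(distance_cm < 0))
    stop("'distance_cm' must be finite and non-negative")
  overlap <- (geometry$target_diameter_cm + geometry$cursor_diameter_cm) / 2
  out <- character(length(distance_cm))
  out[distance_cm <= overlap] <- "green"
  out[distance_cm > overlap & distance_cm <= 4] <- "yellow"
  out[distance_cm > 4 & distance_cm <= 8] <- "orange"
  out[distance_cm > 8] <- "red"
  out
}
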