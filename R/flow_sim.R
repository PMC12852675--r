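#' Simulate an optic flow field by pinhole projection
#'
#' Places a 3D cloud of stationary dots in the visual frustum and computes
#' their image motion under the camera trajectory implied by a viewing
#' geometry: the camera yaws at `omega_eye` while translating laterally at
#' `-pivot * omega_eye` (rad/s * cm), which puts the rotation pivot of the
#' resulting flow field at distance `pivot` in front of the eye. Image
#' velocities are obtained by finite-differencing exact perspective
#' projections across one display frame. Dots whose image position falls
#' within twice the object radius of the object center are removed,
#' mirroring the mask used in the experimental display to avoid local motion
#' interactions.
#'
#' This simulator is a validation and visualization layer for the
#' small-angle equation engine ([stationary_dot_flow()]); the projected flow
#' of a dot at physical distance `z` matches the engine at normalized depth
#' `dprime = f / z - 1` (see the methods vignette for why this, and not
#' `z / f - 1`, is the exact correspondence).
#'
#' @param geometry A [viewing_geometry()] object.
#' @param n_dots Number of dots before masking (>= 1).
#' @param depth_range Length-2 numeric: dot distances from the eye (cm);
#'   must be positive (in front of the eye).
#' @param fov Length-2 numeric, horizontal and vertical field of view (deg)
#'   within which dots are placed uniformly in image angle.
#' @param object_center Length-2 image position (deg) of the object aperture.
#' @param object_radius Object aperture radius (deg); dots within
#'   `2 * object_radius` of the center are masked out.
#' @param dt Finite-difference time step (s), one display frame by default.
#' @param seed Integer seed for dot placement.
#' @return A tibble with columns `dot_id`, `x_deg`, `y_deg` (image position),
#'   `vx_deg_s`, `vy_deg_s` (image velocity), `depth_cm` (distance from the
#'   eye) and `dprime` (normalized depth `f / z - 1`).
#' @examples
#' fld <- simulate_flow_field(viewing_geometry(geometry = "RT"), n_dots = 50, seed = 1)
#' @export
simulate_flow_field <- function(geometry, n_dots = 200,
                                depth_range = c(28.5, 114),
                                fov = c(85, 55),
                                object_center = c(10, 0), object_radius = 2.5,
                                dt = 1 / 60, seed = NULL) {
  stopifnot(inherits(geometry, "pf_geometry"), n_dots >= 1,
            length(depth_range) == 2L, all(depth_range > 0), dt > 0)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_flow_field(
      geometry, n_dots, depth_range, fov, object_center, object_radius, dt
    )))
  }
  f <- geometry$viewing_distance
  om <- geometry$omega_eye * pi / 180        # rad/s, rightward positive
  Tx <- -geometry$pivot * om                 # cm/s lateral camera velocity

  ax <- runif(n_dots, -fov[1] / 2, fov[1] / 2) * pi / 180
  ay <- runif(n_dots, -fov[2] / 2, fov[2] / 2) * pi / 180
  z <- runif(n_dots, min(depth_range), max(depth_range))
  X <- z * tan(ax)
  Y <- z * tan(ay)

  project <- function(t) {
    cx <- Tx * t
    phi <- om * t
    relx <- X - cx
    xc <- cos(phi) * relx - sin(phi) * z
    zc <- sin(phi) * relx + cos(phi) * z
    cbind(atan2(xc, zc), atan2(Y, zc)) * 180 / pi
  }
  p0 <- project(0)
  p1 <- project(dt)
  v <- (p1 - p0) / dt

  keep <- sqrt((p0[, 1] - object_center[1])^2 +
                 (p0[, 2] - object_center[2])^2) > 2 * object_radius
  out <- tibble::tibble(
    dot_id = seq_len(n_dots)[keep],
    x_deg = p0[keep, 1], y_deg = p0[keep, 2],
    vx_deg_s = v[keep, 1], vy_deg_s = v[keep, 2],
    depth_cm = z[keep],
    dprime = f / z[keep] - 1
  )
  if (nrow(out) == 0L) warning("flow field is empty after masking")
  out
}

#' Plot an optic flow field
#'
#' Arrow plot of image velocities colored by depth relative to fixation.
#'
#' @param field A tibble from [simulate_flow_field()].
#' @param arrow_scale Seconds of motion represented by each arrow.
#' @return A ggplot object.
#' @export
plot_flow_field <- function(field, arrow_scale = 0.25) {
  stopifnot(all(c("x_deg", "y_deg", "vx_deg_s", "vy_deg_s") %in% names(field)))
  ggplot2::ggplot(field, ggplot2::aes(
    x = .data$x_deg, y = .data$y_deg,
    xend = .data$x_deg + arrow_scale * .data$vx_deg_s,
    yend = .data$y_deg + arrow_scale * .data$vy_deg_s,
    colour = .data$dprime
  )) +
    ggplot2::geom_segment(arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))) +
    ggplot2::scale_colour_gradient2(low = "#b2182b", mid = "grey60", high = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)",
                  colour = "d'") +
    ggplot2::theme_minimal()
}
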