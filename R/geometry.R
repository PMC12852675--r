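#' Viewing geometry of combined eye rotation and translation
#'
#' Describes the eye's trajectory relative to the scene by the rotation pivot
#' of the optic flow field it produces. The pivot sits at distance `p` (cm) in
#' front of the cyclopean eye; normalized by viewing distance `f` it becomes
#' `p' = p / f`. `p' = 0` is a pure eye rotation (R geometry, pivot at the
#' eye); `p' = 1` places the pivot at fixation, the geometry of a lateral eye
#' translation with compensatory counter-rotation (R+T). The world-referenced
#' eye rotation `omega_eye` (deg/s, rightward positive) splits into a
#' component compensating the translation, `p' * omega_eye`, and a pursuit
#' component tracking the target, `(1 - p') * omega_eye`.
#'
#' @param pprime Normalized rotation pivot `p/f` (dimensionless). Use `0` for
#'   the R geometry and `1` for R+T, or supply `geometry` instead.
#' @param omega_eye World-referenced horizontal eye rotation velocity (deg/s,
#'   rightward positive).
#' @param viewing_distance Distance from the eye to the fixation plane (cm).
#' @param geometry Optional shorthand, `"R"` (`pprime = 0`) or `"RT"`
#'   (`pprime = 1`); ignored when `pprime` is given.
#'
#' @return An object of class `pf_geometry`: a list with fields
#'   `viewing_distance`, `pivot`, `pprime`, `omega_eye`,
#'   `omega_eye_translation` and `omega_eye_pursuit` (all numeric scalars).
#' @examples
#' viewing_geometry(geometry = "RT", omega_eye = 5)
#' @export
viewing_geometry <- function(pprime = NULL, omega_eye = 5, viewing_distance = 57,
                             geometry = c("R", "RT")) {
  if (is.null(pprime)) {
    geometry <- match.arg(geometry)
    pprime <- if (geometry == "R") 0 else 1
  }
  stopifnot(is.numeric(pprime), length(pprime) == 1L, is.finite(pprime),
            is.numeric(omega_eye), length(omega_eye) == 1L, is.finite(omega_eye),
            is.numeric(viewing_distance), viewing_distance > 0)
  structure(
    list(
      viewing_distance = viewing_distance,
      pivot = pprime * viewing_distance,
      pprime = pprime,
      omega_eye = omega_eye,
      omega_eye_translation = pprime * omega_eye,
      omega_eye_pursuit = (1 - pprime) * omega_eye
    ),
    class = "pf_geometry"
  )
}

#' @export
print.pf_geometry <- function(x, ...) {
  cat(sprintf(
    "<pf_geometry> p' = %.3g (pivot %.3g cm, f = %.3g cm), omega_eye = %.3g deg/s (T %.3g + P %.3g)\n",
    x$pprime, x$pivot, x$viewing_distance, x$omega_eye,
    x$omega_eye_translation, x$omega_eye_pursuit
  ))
  invisible(x)
}

check_finite <- function(...) {
  args <- list(...)
  nm <- names(args)
  for (i in seq_along(args)) {
    if (!is.numeric(args[[i]]) || any(!is.finite(args[[i]]))) {
      stop("`", nm[i], "` must be finite numeric", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Object motion in world coordinates from retinal motion
#'
#' Inverts the forward viewing-geometry model: for an object at normalized
#' depth `dprime` viewed under a flow field with normalized pivot `pprime`,
#' its scene-relative (world) angular velocity is
#' `omega_obj = omega_ret + (1 - (1 + dprime) * pprime) * omega_eye`,
#' applied to the horizontal component only (all real and simulated pursuit
#' is horizontal). At `pprime = 0` this is the classic coordinate
#' transformation `omega_obj = omega_ret + omega_eye`; at `pprime = 1` with a
#' stationary object it reduces to the motion-pursuit law.
#'
#' @param omega_ret Retinal angular velocity, deg/s: a length-2 vector
#'   `c(x, y)` or an n-by-2 matrix (x rightward, y upward).
#' @param omega_eye Horizontal world-referenced eye velocity (deg/s), scalar
#'   or length-n.
#' @param dprime Normalized object depth (dimensionless), scalar or length-n.
#' @param pprime Normalized rotation pivot (dimensionless), scalar or length-n.
#' @return Same shape as `omega_ret`: world-frame angular velocity (deg/s).
#' @examples
#' object_world_motion(c(3, 4), omega_eye = -3, dprime = 0.2, pprime = 0)
#' @export
object_world_motion <- function(omega_ret, omega_eye, dprime, pprime) {
  check_finite(omega_ret = omega_ret, omega_eye = omega_eye,
               dprime = dprime, pprime = pprime)
  vec <- is.null(dim(omega_ret))
  m <- if (vec) matrix(omega_ret, ncol = 2) else as.matrix(omega_ret)
  stopifnot(ncol(m) == 2L)
  m[, 1] <- m[, 1] + (1 - (1 + dprime) * pprime) * omega_eye
  if (vec && nrow(m) == 1L) c(m) else m
}

#' Relative depth from motion parallax
#'
#' The generalized motion-pursuit relation: given the horizontal retinal
#' velocity of an object, its horizontal world velocity, and the eye
#' velocity, the object's normalized depth is
#' `dprime = (omega_ret_x - omega_obj_x) / omega_eye`. With a stationary
#' object (`omega_obj_x = 0`) this is the motion-pursuit law
#' `dprime = omega_ret_x / omega_eye`. Depth is indeterminate without eye
#' rotation.
#'
#' @param omega_ret_x Horizontal retinal velocity (deg/s).
#' @param omega_obj_x Horizontal world velocity of the object (deg/s).
#' @param omega_eye Horizontal eye velocity (deg/s); must be nonzero.
#' @return Normalized depth (dimensionless), vectorized.
#' @examples
#' depth_from_parallax(2, 0, 4) # 0.5
#' @export
depth_from_parallax <- function(omega_ret_x, omega_obj_x = 0, omega_eye) {
  check_finite(omega_ret_x = omega_ret_x, omega_obj_x = omega_obj_x,
               omega_eye = omega_eye)
  if (any(omega_eye == 0)) {
    stop("depth is indeterminate without eye rotation (`omega_eye` = 0)",
         call. = FALSE)
  }
  (omega_ret_x - omega_obj_x) / omega_eye
}

#' Retinal flow of a stationary scene point
#'
#' Horizontal retinal velocity of a stationary point at normalized depth
#' `dprime` under a flow field with pivot `pprime`:
#' `omega_ret = -(1 - (1 + dprime) * pprime) * omega_eye`. At `pprime = 0`
#' the flow is `-omega_eye` for every depth (rotational flow is
#' depth-invariant); at `pprime = 1` it is `dprime * omega_eye`, so points on
#' opposite sides of the fixation plane move in opposite directions.
#'
#' @inheritParams depth_from_parallax
#' @param dprime Normalized depth (dimensionless).
#' @param pprime Normalized rotation pivot (dimensionless).
#' @return Horizontal retinal velocity (deg/s), vectorized.
#' @examples
#' stationary_dot_flow(c(-0.5, 0.5), pprime = 1, omega_eye = 5)
#' @export
stationary_dot_flow <- function(dprime, pprime, omega_eye) {
  check_finite(dprime = dprime, pprime = pprime, omega_eye = omega_eye)
  -(1 - (1 + dprime) * pprime) * omega_eye
}

#' Gaussian velocity profile of a stimulus trajectory
#'
#' Stimuli (object, background flow, pursuit target) move with a Gaussian
#' speed profile whose +/-3 standard deviations span the presentation, i.e.
#' `sigma = duration / 6`, centered at `duration / 2`. The sampled profile is
#' rescaled so that its discrete time-integral equals the requested
#' displacement exactly.
#'
#' @param displacement Total displacement (deg).
#' @param duration Presentation duration (s); must be positive.
#' @param sample_rate Sampling rate (Hz); at least `2 / duration`.
#' @return A tibble of class `pf_velocity_profile` with columns `time` (s,
#'   sample midpoints) and `velocity` (deg/s), and attributes `displacement`,
#'   `duration`, `sample_rate`.
#' @examples
#' vp <- gaussian_velocity_profile(2.67, 1, 60)
#' max(vp$velocity) # ~6.41 deg/s
#' @export
gaussian_velocity_profile <- function(displacement, duration, sample_rate = 60) {
  stopifnot(is.numeric(displacement), length(displacement) == 1L,
            is.finite(displacement))
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("`duration` must be a positive scalar", call. = FALSE)
  }
  stopifnot(sample_rate >= 2 / duration)
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 0.5) / sample_rate
  sigma <- duration / 6
  v <- exp(-(t - duration / 2)^2 / (2 * sigma^2))
  area <- sum(v) / sample_rate
  v <- if (displacement == 0) rep(0, n) else v * displacement / area
  out <- tibble::tibble(time = t, velocity = v)
  attr(out, "displacement") <- displacement
  attr(out, "duration") <- duration
  attr(out, "sample_rate") <- sample_rate
  class(out) <- c("pf_velocity_profile", class(out))
  out
}

#' Field of view of a flat display
#'
#' Horizontal and vertical field of view subtended by a flat monitor at a
#' given viewing distance, `2 * atan(extent / (2 * distance))` per axis.
#' The defaults are the 48-inch display and 57 cm distance used in the
#' psychophysical setup this package emulates, giving roughly 85 x 55 deg.
#'
#' @param width_cm,height_cm Display extent (cm).
#' @param distance_cm Viewing distance (cm).
#' @return Named numeric vector `c(horizontal, vertical)` in degrees.
#' @examples
#' display_field_of_view()
#' @export
display_field_of_view <- function(width_cm = 105.2, height_cm = 59.2,
                                  distance_cm = 57) {
  stopifnot(width_cm > 0, height_cm > 0, distance_cm > 0)
  c(horizontal = 2 * atan(width_cm / (2 * distance_cm)) * 180 / pi,
    vertical = 2 * atan(height_cm / (2 * distance_cm)) * 180 / pi)
}

#' Direction angle of a screen-velocity vector
#'
#' Directions follow the convention of the psychophysical task: upward is 0
#' degrees and angles increase clockwise, so rightward motion is +90 and
#' leftward is -90.
#'
#' @param vx,vy Horizontal (rightward positive) and vertical (upward
#'   positive) velocity components.
#' @return Direction in degrees in (-180, 180], vectorized; `NA` where both
#'   components are zero.
#' @export
direction_deg <- function(vx, vy) {
  out <- atan2(vx, vy) * 180 / pi
  out[vx == 0 & vy == 0] <- NA_real_
  out
}

#' Velocity components of a direction
#'
#' Inverse of [direction_deg()]: unit-speed components scaled by `speed`.
#'
#' @param direction Direction (deg; up = 0, clockwise positive).
#' @param speed Speed (deg/s).
#' @return A two-column matrix with columns `vx`, `vy`.
#' @export
direction_to_velocity <- function(direction, speed = 1) {
  th <- direction * pi / 180
  cbind(vx = speed * sin(th), vy = speed * cos(th))
}

#' Wrap angles to (-180, 180]
#' @param x Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_deg <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}
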