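#' Observer-model parameters
#'
#' The perceptual observer discounts retinal and eye velocity with gains
#' `g_ret` and `g_eye` (both in \[0, 1\]) and, for direction judgments,
#' combines them with weights `a_ret = g_ret * pprime` and
#' `a_eye = (1 - pprime) * g_eye` determined by the believed viewing
#' geometry. `a_ret` is the fraction of horizontal retinal motion explained
#' away as motion parallax; `a_eye` is the fraction of eye velocity added
#' back to retinal motion (the coordinate-transformation path). `g_pursuit`
#' is the executed pursuit gain used for retinal-slip correction.
#'
#' Weights may be given directly (as when fitted from data) or derived from
#' gains and a geometry `pprime`.
#'
#' @param g_ret,g_eye Perceptual gains in \[0, 1\].
#' @param pprime Believed normalized rotation pivot; used to derive the
#'   weights when `a_ret`/`a_eye` are not supplied.
#' @param a_ret,a_eye Direction-model weights in \[0, 1\]; override the
#'   derived values when supplied.
#' @param g_pursuit Executed pursuit gain (>= 0).
#' @return A list of class `pf_observer` with fields `g_ret`, `g_eye`,
#'   `a_ret`, `a_eye`, `g_pursuit`, `pprime`.
#' @examples
#' observer_params(g_ret = 1, g_eye = 1, pprime = 1) # full motion-parallax observer
#' @export
observer_params <- function(g_ret = 1, g_eye = 1, pprime = NULL,
                            a_ret = NULL, a_eye = NULL, g_pursuit = 1) {
  stopifnot(g_ret >= 0, g_ret <= 1, g_eye >= 0, g_eye <= 1, g_pursuit >= 0)
  if (is.null(a_ret)) {
    if (is.null(pprime)) stop("supply either `pprime` or both weights", call. = FALSE)
    a_ret <- g_ret * pprime
  }
  if (is.null(a_eye)) {
    if (is.null(pprime)) stop("supply either `pprime` or both weights", call. = FALSE)
    a_eye <- (1 - pprime) * g_eye
  }
  stopifnot(a_ret >= 0, a_ret <= 1, a_eye >= 0, a_eye <= 1)
  structure(list(g_ret = g_ret, g_eye = g_eye, a_ret = a_ret, a_eye = a_eye,
                 g_pursuit = g_pursuit, pprime = pprime),
            class = "pf_observer")
}

#' Correct intended velocities for pursuit slip
#'
#' Imperfect pursuit (gain < 1) leaves part of the intended eye movement as
#' retinal slip. Given the measured pursuit gain, the executed eye velocity
#' is `g_pursuit * omega_eye_x` and the actual horizontal retinal velocity is
#' `omega_ret_x + (1 - g_pursuit) * omega_eye_x`; vertical components are
#' untouched. The correction applies only to trials with real pursuit:
#' fixation trials (simulated eye movement) have no slip and pass through
#' unchanged.
#'
#' @param trials A tibble with columns `retinal_x`, `retinal_y`, `eye_x`
#'   (intended velocities, deg/s) and `eye_condition`
#'   (`"Pursuit"`/`"Fixation"`).
#' @param g_pursuit Measured pursuit gain (>= 0), scalar or per-trial.
#' @return The tibble with corrected columns `retinal_x`, `eye_x` (and the
#'   intended values preserved as `retinal_x_intended`, `eye_x_intended`).
#' @examples
#' tr <- tibble::tibble(retinal_x = 0, retinal_y = 2, eye_x = 6,
#'                      eye_condition = "Pursuit")
#' slip_correct(tr, g_pursuit = 0.5)
#' @export
slip_correct <- function(trials, g_pursuit = 1) {
  stopifnot(all(c("retinal_x", "retinal_y", "eye_x", "eye_condition") %in%
                  names(trials)), all(g_pursuit >= 0))
  pursuit <- trials$eye_condition == "Pursuit"
  out <- trials
  out$retinal_x_intended <- trials$retinal_x
  out$eye_x_intended <- trials$eye_x
  gp <- rep_len(g_pursuit, nrow(trials))
  out$eye_x <- ifelse(pursuit, gp * trials$eye_x, trials$eye_x)
  out$retinal_x <- ifelse(pursuit,
                          trials$retinal_x + (1 - gp) * trials$eye_x,
                          trials$retinal_x)
  out
}

#' Predicted world motion of the object
#'
#' The linear observer model of perceived object velocity: the horizontal
#' component is `(1 - a_ret) * retinal_x + a_eye * eye_x` (part of the
#' horizontal retinal motion is explained away as parallax, part of the eye
#' velocity is added back), and the vertical component is the retinal
#' vertical component unchanged. Perceived direction is the angle of this
#' vector (up = 0 deg, clockwise positive); it is undefined (NA) for a
#' zero-length predicted vector.
#'
#' @param retinal_x,retinal_y Slip-corrected retinal velocity components
#'   (deg/s), vectorized.
#' @param eye_x Slip-corrected horizontal eye velocity (deg/s).
#' @param params A [observer_params()] object (or anything with `a_ret`,
#'   `a_eye`).
#' @return A tibble with columns `world_x`, `world_y`, `direction` (deg).
#' @examples
#' predict_world_motion(2, 2, eye_x = 0, observer_params(a_ret = 1, a_eye = 0))
#' @export
predict_world_motion <- function(retinal_x, retinal_y, eye_x, params) {
  wx <- (1 - params$a_ret) * retinal_x + params$a_eye * eye_x
  wy <- retinal_y
  tibble::tibble(world_x = wx, world_y = wy,
                 direction = direction_deg(wx, wy))
}

#' Predicted relative depth from motion parallax
#'
#' The observer's depth estimate under the motion-parallax interpretation:
#' `dhat = (g_ret * retinal_x) / (g_eye * eye_x)`. When the denominator
#' vanishes (no attributed eye rotation, as in the pure-rotation geometry)
#' depth is ambiguous and `NA` is returned.
#'
#' @inheritParams predict_world_motion
#' @return Numeric vector of perceived normalized depth; `NA` where
#'   ambiguous.
#' @examples
#' predict_depth(2, 4, observer_params(g_ret = 1, g_eye = 1, pprime = 1))
#' @export
predict_depth <- function(retinal_x, eye_x, params) {
  den <- params$g_eye * eye_x
  out <- params$g_ret * retinal_x / den
  out[rep_len(den == 0, length(out))] <- NA_real_
  out
}

#' Observer-model prediction curves
#'
#' Vectorized application of the direction and depth predictors across a set
#' of retinal directions, for both eye-movement signs — the model curves
#' plotted against psychophysical reports. In the R geometry
#' (`pprime = 0`) the depth prediction is ambiguous (`NA`) and the direction
#' curve is biased toward the horizontal; in R+T (`pprime = 1`) the
#' direction curve collapses toward vertical and the depth sign tracks the
#' horizontal retinal component, inverting with eye direction.
#'
#' @param params A [observer_params()] object.
#' @param geometry `"R"`, `"RT"`, or `"none"` (control: no flow, weights 0).
#' @param eye_speed Eye speed (deg/s); both signs are generated.
#' @param retinal_speed Object retinal speed (deg/s).
#' @param directions Retinal directions (deg) within \[-90, 270\].
#' @return A tibble with columns `geometry`, `eye_dir` (-1/1),
#'   `direction_in`, `direction_out`, `depth_hat`, `p_far`
#'   (`pnorm(depth_hat / depth_sigma)`).
#' @param depth_sigma Depth-report noise used for the `p_far` column.
#' @export
prediction_curves <- function(params, geometry = c("RT", "R", "none"),
                              eye_speed = 5.3, retinal_speed = 2.67,
                              directions = seq(-90, 270, by = 30),
                              depth_sigma = 0.3) {
  geometry <- match.arg(geometry)
  stopifnot(all(directions >= -90 & directions <= 270))
  if (geometry == "none") {
    params <- observer_params(a_ret = 0, a_eye = 0,
                              g_ret = params$g_ret, g_eye = params$g_eye)
  }
  grid <- tidyr::expand_grid(eye_dir = c(-1, 1), direction_in = directions)
  v <- direction_to_velocity(grid$direction_in, retinal_speed)
  eye_x <- grid$eye_dir * eye_speed
  wm <- predict_world_motion(v[, "vx"], v[, "vy"], eye_x, params)
  dhat <- if (geometry == "RT") predict_depth(v[, "vx"], eye_x, params)
          else NA_real_
  tibble::tibble(
    geometry = geometry,
    eye_dir = grid$eye_dir,
    direction_in = grid$direction_in,
    direction_out = wm$direction,
    depth_hat = dhat,
    p_far = stats::pnorm(dhat / depth_sigma)
  )
}

#' Plot observer prediction curves
#'
#' @param curves Output of [prediction_curves()] (rows from one or more
#'   geometries may be bound together).
#' @param what `"direction"` or `"depth"`.
#' @return A ggplot object.
#' @export
plot_prediction_curves <- function(curves, what = c("direction", "depth")) {
  what <- match.arg(what)
  curves$eye <- factor(curves$eye_dir, c(-1, 1), c("leftward", "rightward"))
  if (what == "direction") {
    ggplot2::ggplot(curves, ggplot2::aes(.data$direction_in, .data$direction_out,
                                         colour = .data$geometry,
                                         linetype = .data$eye)) +
      ggplot2::geom_line() +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
      ggplot2::labs(x = "retinal direction (deg)", y = "predicted direction (deg)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(curves, ggplot2::aes(.data$direction_in, .data$p_far,
                                         colour = .data$geometry,
                                         linetype = .data$eye)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 0.5, colour = "grey70") +
      ggplot2::labs(x = "retinal direction (deg)", y = "P(report far)") +
      ggplot2::theme_minimal()
  }
}
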