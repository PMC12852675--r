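dog_kernel <- function(sample_rate, sd_s = 0.025) {
  # first-derivative-of-Gaussian filter; convolving position with it yields
  # the derivative of the Gaussian-smoothed position, i.e. smoothed velocity
  half <- ceiling(4 * sd_s * sample_rate)
  tau <- (-half:half) / sample_rate
  gprime <- -tau / sd_s^2 * stats::dnorm(tau, sd = sd_s)
  # stats::filter computes sum_k f[k] x[j + k - (m+1)/2]; matching the
  # convolution sum_i g'(tau_i) x_{j-i} dtau requires reversing the kernel
  rev(gprime) / sample_rate
}

filtered_velocity <- function(x, sample_rate, sd_s = 0.025) {
  as.numeric(stats::filter(x, dog_kernel(sample_rate, sd_s), sides = 2))
}

gauss_smooth <- function(x, sample_rate, sd_s) {
  half <- ceiling(3 * sd_s * sample_rate)
  k <- stats::dnorm((-half:half) / sample_rate, sd = sd_s)
  k <- k / sum(k)
  # linear-interpolate interior NAs so the kernel has full support
  if (anyNA(x)) {
    ok <- which(!is.na(x))
    if (length(ok) < 2) return(x)
    x <- stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
  }
  as.numeric(stats::filter(x, k, sides = 2))
}

#' Pursuit gain from eye-position traces
#'
#' Estimates smooth-pursuit gain from repeated traces of one condition.
#' Each gaze trace is differentiated by convolution with a
#' first-derivative-of-Gaussian window (SD 25 ms); samples exceeding the
#' velocity (40 deg/s) or acceleration (300 deg/s^2) thresholds are removed
#' to reject catch-up saccades and artifacts. The pointwise median velocity
#' is taken across traces and the gain is the ratio of its peak to the peak
#' of the target velocity. The target velocity is obtained by passing the
#' target position through the identical filter, so the smoothing
#' attenuation cancels in the ratio and the estimator is unbiased for
#' noise-free traces.
#'
#' Because the filter spreads a saccade over its support, samples within
#' `reject_pad` of any threshold violation are rejected too; otherwise the
#' smeared flanks of each saccade (just below threshold) would bias the
#' median velocity upward.
#'
#' @param traces Tibble with columns `trial_id`, `t_s`, `gaze_x_deg` and
#'   `target_x_deg` (equal sampling within trials, >= 250 Hz).
#' @param velocity_threshold,acceleration_threshold Rejection thresholds
#'   (deg/s, deg/s^2).
#' @param filter_sd Gaussian derivative SD (s).
#' @param reject_pad Half-width (s) of the rejection neighborhood around
#'   each threshold violation (the filter support, 4 SD, by default).
#' @return A list of class `pf_pursuit_gain`: `gain`, `peak_eye`,
#'   `peak_target`, `n_traces`, `prop_rejected` and the median velocity
#'   trace (`t_s`, `velocity`).
#' @examples
#' tr <- generate_eye_traces(5, g_pursuit = 0.8, noise_sd = 0, seed = 1)
#' compute_pursuit_gain(tr)$gain
#' @export
compute_pursuit_gain <- function(traces, velocity_threshold = 40,
                                 acceleration_threshold = 300,
                                 filter_sd = 0.025, reject_pad = 4 * filter_sd) {
  stopifnot(all(c("trial_id", "t_s", "gaze_x_deg", "target_x_deg") %in%
                  names(traces)))
  split_tr <- split(traces, traces$trial_id)
  t1 <- split_tr[[1]]$t_s
  fs <- 1 / stats::median(diff(t1))
  if (fs < 250) stop("sample rate must be >= 250 Hz", call. = FALSE)

  pad_n <- round(reject_pad * fs)
  vmat <- vapply(split_tr, function(d) {
    v <- filtered_velocity(d$gaze_x_deg, fs, filter_sd)
    a <- c(NA, diff(v)) * fs
    bad <- which(abs(v) > velocity_threshold |
                   abs(a) > acceleration_threshold)
    if (length(bad) && pad_n > 0) {
      bad <- unique(pmin(pmax(rep(bad, each = 2 * pad_n + 1) +
                                (-pad_n):pad_n, 1L), length(v)))
    }
    v[bad] <- NA
    v
  }, numeric(length(t1)))
  rejected <- mean(is.na(vmat[is.finite(vmat[, 1]) | TRUE, ]))
  med <- apply(vmat, 1, stats::median, na.rm = TRUE)
  if (all(is.na(med))) stop("no pursuit data left after thresholding",
                            call. = FALSE)
  target_v <- filtered_velocity(split_tr[[1]]$target_x_deg, fs, filter_sd)
  # smooth both traces identically before peak extraction so residual
  # velocity noise does not inflate the maximum of the median trace; the
  # attenuation cancels in the ratio
  med <- gauss_smooth(med, fs, filter_sd)
  target_v <- gauss_smooth(target_v, fs, filter_sd)
  peak_eye <- max(abs(med), na.rm = TRUE)
  peak_target <- max(abs(target_v), na.rm = TRUE)
  if (peak_target == 0) stop("target does not move", call. = FALSE)
  structure(list(gain = peak_eye / peak_target, peak_eye = peak_eye,
                 peak_target = peak_target, n_traces = length(split_tr),
                 prop_rejected = rejected,
                 median_trace = tibble::tibble(t_s = t1, velocity = med)),
            class = "pf_pursuit_gain")
}

#' @export
print.pf_pursuit_gain <- function(x, ...) {
  cat(sprintf("<pf_pursuit_gain> gain = %.3f (peak eye %.2f / target %.2f deg/s, %d traces)\n",
              x$gain, x$peak_eye, x$peak_target, x$n_traces))
  invisible(x)
}

#' Fixation check on a single eye trace
#'
#' A trial passes if gaze never leaves a rectangular window around the
#' (possibly moving) target for longer than the tolerance. Defaults match
#' the offline analysis criterion (10 x 10 deg window, 100 ms); the online
#' criterion of the direction-report experiment used a +/-5 deg window.
#'
#' @param trace Tibble with `t_s`, `gaze_x_deg`, `gaze_y_deg`,
#'   `target_x_deg` (and optionally `target_y_deg`, else 0).
#' @param window_half_width Half-width of the square window (deg).
#' @param max_violation Longest tolerated excursion (ms).
#' @return `TRUE` if fixation was maintained.
#' @export
fixation_check <- function(trace, window_half_width = 5, max_violation = 100) {
  ty <- if ("target_y_deg" %in% names(trace)) trace$target_y_deg else 0
  gy <- if ("gaze_y_deg" %in% names(trace)) trace$gaze_y_deg else 0
  outside <- abs(trace$gaze_x_deg - trace$target_x_deg) > window_half_width |
    abs(gy - ty) > window_half_width
  if (!any(outside)) return(TRUE)
  r <- rle(outside)
  dt <- stats::median(diff(trace$t_s))
  max_run <- max(r$lengths[r$values]) * dt * 1000
  max_run <= max_violation
}
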