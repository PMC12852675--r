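#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. Used for circular report noise on
#' direction judgments.
#'
#' @param n Number of draws.
#' @param mu Mean direction (deg).
#' @param kappa Concentration (> 0).
#' @return Angles in degrees, wrapped to (-180, 180].
#' @export
rvonmises_deg <- function(n, mu = 0, kappa = 20) {
  stopifnot(kappa > 0, n >= 0)
  if (n == 0) return(numeric(0))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    ff <- (1 + r * z) / (r + z)
    cc <- kappa * (r - ff)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(ff)
      i <- i + 1L
    }
  }
  wrap_deg(mu + out * 180 / pi)
}

#' Psychophysical experiment design
#'
#' Trial grid of the two tasks this package emulates. The direction
#' estimation task (`"Exp1"`) spans retinal directions -90 to 270 deg in 30
#' deg steps; the depth discrimination task (`"Exp2"`) spans -90 to 90 deg
#' in 15 deg steps (directions beyond 90 deg differ only in their vertical
#' component, which carries no depth information). Viewing-geometry
#' conditions (R, R+T and, in Exp1, a no-background control) are crossed
#' with eye conditions (Pursuit, Fixation) and both eye-movement signs.
#'
#' @param experiment `"Exp1"` or `"Exp2"`.
#' @param directions Retinal directions (deg); defaults per experiment.
#' @param reps Repetitions per cell (7 for Exp1, 20 for Exp2 by default).
#' @param geometries Geometry conditions to include.
#' @param eye_conditions Eye-movement conditions to include.
#' @param eye_speed Mean eye speed (deg/s) over the 1-s presentation.
#' @param retinal_speed Mean object retinal speed (deg/s).
#' @return A list of class `pf_design`.
#' @export
experiment_design <- function(experiment = c("Exp1", "Exp2"),
                              directions = NULL, reps = NULL,
                              geometries = NULL,
                              eye_conditions = c("Fixation", "Pursuit"),
                              eye_speed = 5.3, retinal_speed = 2.67) {
  experiment <- match.arg(experiment)
  if (is.null(directions)) {
    directions <- if (experiment == "Exp1") seq(-90, 270, by = 30)
                  else seq(-90, 90, by = 15)
  }
  if (is.null(reps)) reps <- if (experiment == "Exp1") 7L else 20L
  if (is.null(geometries)) {
    geometries <- if (experiment == "Exp1") c("R", "RT", "none") else c("R", "RT")
  }
  structure(list(experiment = experiment, directions = directions,
                 reps = as.integer(reps), geometries = geometries,
                 eye_conditions = eye_conditions,
                 eye_speed = eye_speed, retinal_speed = retinal_speed),
            class = "pf_design")
}

#' Synthetic observer specification
#'
#' A generative twin of the perceptual observer model: per-geometry
#' direction weights, depth gains, circular report noise, a Bernoulli depth
#' link, and a prior for the depth-ambiguous pure-rotation geometry.
#' Defaults reflect the group tendencies of the emulated study (R:
#' `a_eye` ~ 0.4, `a_ret` ~ 0; R+T: `a_ret` ~ 0.3, `a_eye` ~ 0.1).
#'
#' @param a_ret,a_eye Named numeric vectors of direction weights per
#'   geometry (`R`, `RT`, `none`).
#' @param g_ret,g_eye Depth gains used in the R+T geometry.
#' @param report_kappa von Mises concentration of direction-report noise.
#' @param depth_sigma Internal noise of the depth decision (normalized depth
#'   units); P(far) = pnorm(dhat / depth_sigma).
#' @param lapse Probability of a uniform random direction report.
#' @param depth_prior_near P(report "near") when depth is ambiguous.
#' @param g_pursuit True executed pursuit gain in Pursuit conditions.
#' @param participant_id Label attached to generated trials.
#' @return A list of class `pf_synth_observer`.
#' @export
synthetic_observer <- function(a_ret = c(R = 0, RT = 0.3, none = 0),
                               a_eye = c(R = 0.4, RT = 0.1, none = 0),
                               g_ret = 1, g_eye = 1,
                               report_kappa = 20, depth_sigma = 0.3,
                               lapse = 0.02, depth_prior_near = 0.8,
                               g_pursuit = 1, participant_id = "s01") {
  stopifnot(report_kappa > 0, depth_sigma > 0,
            lapse >= 0, lapse <= 1,
            depth_prior_near >= 0, depth_prior_near <= 1, g_pursuit >= 0,
            all(c("R", "RT") %in% names(a_ret)),
            all(c("R", "RT") %in% names(a_eye)))
  structure(list(a_ret = a_ret, a_eye = a_eye, g_ret = g_ret, g_eye = g_eye,
                 report_kappa = report_kappa, depth_sigma = depth_sigma,
                 lapse = lapse, depth_prior_near = depth_prior_near,
                 g_pursuit = g_pursuit, participant_id = participant_id),
            class = "pf_synth_observer")
}

#' Generate synthetic psychophysical trials
#'
#' Simulates one observer performing an experiment. Intended stimulus
#' velocities follow the design; in Pursuit conditions the executed eye
#' velocity is `g_pursuit` times the intended one and the residual appears
#' as retinal slip, exactly as the slip-correction model assumes. Direction
#' reports are the observer-model prediction plus von Mises noise, replaced
#' by a uniform direction with probability `lapse`. Depth reports are
#' Bernoulli with P(far) = pnorm(dhat / depth_sigma) where the
#' motion-parallax interpretation applies (R+T), and follow the observer's
#' near prior where depth is ambiguous (R geometry).
#'
#' @param design An [experiment_design()].
#' @param observer A [synthetic_observer()].
#' @param seed Integer seed.
#' @return A tibble with one row per trial: `participant_id`, `experiment`,
#'   `geometry`, `eye_condition`, `eye_dir`, `retinal_dir_deg`,
#'   `retinal_speed_deg_s`, intended velocity components (`retinal_x`,
#'   `retinal_y`, `eye_x`), `reported_direction` (Exp1, else `NA`),
#'   `depth_report` (`"near"`/`"far"`, Exp2, else `NA`) and `valid`.
#' @export
generate_trials <- function(design, observer = synthetic_observer(),
                            seed = NULL) {
  stopifnot(inherits(design, "pf_design"), inherits(observer, "pf_synth_observer"))
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_trials(design, observer)))
  }
  grid <- tidyr::expand_grid(
    geometry = design$geometries,
    eye_condition = design$eye_conditions,
    eye_dir = c(-1, 1),
    retinal_dir_deg = design$directions,
    rep = seq_len(design$reps)
  )
  grid <- grid[sample.int(nrow(grid)), ]  # randomized trial order
  n <- nrow(grid)
  v <- direction_to_velocity(grid$retinal_dir_deg, design$retinal_speed)
  eye_int <- grid$eye_dir * design$eye_speed

  # executed (physical) velocities: pursuit gain < 1 leaves slip on the retina
  pursuit <- grid$eye_condition == "Pursuit"
  gp <- observer$g_pursuit
  eye_exec <- ifelse(pursuit, gp * eye_int, eye_int)
  ret_x_exec <- ifelse(pursuit, v[, "vx"] + (1 - gp) * eye_int, v[, "vx"])

  a_ret <- unname(observer$a_ret[grid$geometry])
  a_eye <- unname(observer$a_eye[grid$geometry])
  wx <- (1 - a_ret) * ret_x_exec + a_eye * eye_exec
  wy <- v[, "vy"]
  pred_dir <- direction_deg(wx, wy)
  pred_dir[is.na(pred_dir)] <- 0

  out <- tibble::tibble(
    participant_id = observer$participant_id,
    experiment = design$experiment,
    geometry = grid$geometry,
    eye_condition = grid$eye_condition,
    eye_dir = grid$eye_dir,
    retinal_dir_deg = grid$retinal_dir_deg,
    retinal_speed_deg_s = design$retinal_speed,
    eye_speed_deg_s = design$eye_speed,
    retinal_x = v[, "vx"], retinal_y = v[, "vy"], eye_x = eye_int,
    reported_direction = NA_real_, depth_report = NA_character_,
    valid = TRUE
  )
  if (design$experiment == "Exp1") {
    noise <- rvonmises_deg(n, 0, observer$report_kappa)
    rep_dir <- wrap_deg(pred_dir + noise)
    lapses <- stats::runif(n) < observer$lapse
    rep_dir[lapses] <- stats::runif(sum(lapses), -180, 180)
    out$reported_direction <- rep_dir
  } else {
    dhat <- ifelse(grid$geometry == "RT",
                   observer$g_ret * ret_x_exec / (observer$g_eye * eye_exec),
                   NA_real_)
    p_far <- ifelse(is.na(dhat), 1 - observer$depth_prior_near,
                    stats::pnorm(dhat / observer$depth_sigma))
    out$depth_report <- ifelse(stats::runif(n) < p_far, "far", "near")
  }
  out
}

#' Generate a synthetic cohort of observers
#'
#' Draws per-participant observer parameters around the defaults of
#' [synthetic_observer()] so group-level statistics can be exercised.
#'
#' @param n_observers Cohort size.
#' @param design An [experiment_design()].
#' @param sd Between-observer standard deviation of the weights (truncated
#'   to \[0, 1\]).
#' @param seed Integer seed.
#' @return A tibble of trials for all observers.
#' @export
generate_cohort <- function(n_observers = 10, design = experiment_design("Exp1"),
                            sd = 0.1, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_cohort(n_observers, design, sd)))
  }
  purrr::map_dfr(seq_len(n_observers), function(i) {
    clamp <- function(x) pmin(1, pmax(0, x))
    obs <- synthetic_observer(
      a_ret = c(R = clamp(stats::rnorm(1, 0.02, sd / 2)),
                RT = clamp(stats::rnorm(1, 0.3, sd)),
                none = 0),
      a_eye = c(R = clamp(stats::rnorm(1, 0.4, sd)),
                RT = clamp(stats::rnorm(1, 0.1, sd / 2)),
                none = 0),
      participant_id = sprintf("s%02d", i)
    )
    generate_trials(design, obs)
  })
}

#' Generate synthetic pursuit eye traces
#'
#' Gaze follows the pursuit target with gain `g_pursuit`, plus smoothed
#' positional noise and optional injected catch-up saccades (rapid
#' position steps whose velocity exceeds the 40 deg/s rejection threshold
#' of the pursuit-gain pipeline). A 250-ms stationary padding flanks the
#' 1-s pursuit ramp so filter edges fall outside the movement.
#'
#' @param n_trials Number of traces.
#' @param g_pursuit True pursuit gain.
#' @param noise_sd Positional noise SD (deg) after smoothing.
#' @param saccade_rate Expected catch-up saccades per second.
#' @param saccade_min_amp Minimum saccade amplitude (deg). Injected
#'   saccades are position steps over ~16 ms; after the 25-ms
#'   derivative-of-Gaussian filter of the gain pipeline, a step of A deg
#'   peaks near `15 * A` deg/s and `360 * A` deg/s^2, so amplitudes of
#'   1.2 deg and above reliably cross the rejection thresholds.
#' @param displacement Target displacement (deg) over `duration`.
#' @param duration Pursuit duration (s).
#' @param sample_rate Sampling rate (Hz).
#' @param seed Integer seed.
#' @return A tibble with columns `trial_id`, `t_s`, `gaze_x_deg`,
#'   `gaze_y_deg`, `target_x_deg`.
#' @export
generate_eye_traces <- function(n_trials = 20, g_pursuit = 0.8, noise_sd = 0.05,
                                saccade_rate = 0, saccade_min_amp = 1.2,
                                displacement = 5.3,
                                duration = 1, sample_rate = 1000, seed = NULL) {
  stopifnot(g_pursuit >= 0)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_eye_traces(
      n_trials, g_pursuit, noise_sd, saccade_rate, saccade_min_amp,
      displacement, duration, sample_rate
    )))
  }
  pad <- round(0.25 * sample_rate)
  vp <- gaussian_velocity_profile(displacement, duration, sample_rate)
  target <- c(rep(0, pad), cumsum(vp$velocity) / sample_rate,
              rep(displacement, pad))
  nt <- length(target)
  t_s <- (seq_len(nt) - 1) / sample_rate
  smooth_noise <- function(n, sd) {
    if (sd == 0) return(rep(0, n))
    k <- stats::dnorm(seq(-3, 3, length.out = 51))
    k <- k / sum(k)
    x <- stats::rnorm(n + 50)
    y <- stats::filter(x, k, sides = 2)
    y <- y[!is.na(y)][seq_len(n)]
    y * sd / stats::sd(y)
  }
  purrr::map_dfr(seq_len(n_trials), function(i) {
    gaze <- g_pursuit * target + smooth_noise(nt, noise_sd)
    n_sac <- stats::rpois(1, saccade_rate * duration)
    if (n_sac > 0) {
      for (j in seq_len(n_sac)) {
        at <- sample(seq(pad + 50, pad + round(duration * sample_rate) - 50), 1)
        amp <- (target[at] - gaze[at])          # catch-up toward the target
        amp <- sign(amp + 1e-9) * max(abs(amp), saccade_min_amp)
        ramp_n <- round(0.016 * sample_rate)    # ~16 ms saccade
        ramp <- seq(0, amp, length.out = ramp_n)
        gaze[at:(at + ramp_n - 1)] <- gaze[at:(at + ramp_n - 1)] + ramp
        gaze[(at + ramp_n):nt] <- gaze[(at + ramp_n):nt] + amp
      }
    }
    tibble::tibble(trial_id = i, t_s = t_s, gaze_x_deg = gaze,
                   gaze_y_deg = smooth_noise(nt, noise_sd),
                   target_x_deg = target)
  })
}

#' Generate synthetic spike counts on a joint velocity grid
#'
#' Poisson generative twin of the parametric joint retinal-by-eye velocity
#' tuning model: expected counts are `firing rate * count_window` at every
#' cell of the velocity grid.
#'
#' @param true_params A [mt_params()] object or list of them (one per
#'   neuron).
#' @param grid Velocity grid (deg/s) applied to both axes.
#' @param trials_per_cell Repeats per grid cell.
#' @param count_window Spike-count window (s).
#' @param seed Integer seed.
#' @return A tibble with columns `neuron_id`, `v_retina`, `v_eye`, `trial`,
#'   `count`.
#' @export
generate_mt_neurons <- function(true_params, grid = -10:10,
                                trials_per_cell = 20, count_window = 1,
                                seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_mt_neurons(
      true_params, grid, trials_per_cell, count_window
    )))
  }
  if (inherits(true_params, "pf_mt_params")) true_params <- list(true_params)
  purrr::imap_dfr(true_params, function(p, id) {
    cells <- tidyr::expand_grid(v_retina = grid, v_eye = grid,
                                trial = seq_len(trials_per_cell))
    lam <- mt_firing_rate(cells$v_retina, cells$v_eye, p) * count_window
    tibble::tibble(neuron_id = id, cells,
                   count = stats::rpois(nrow(cells), lam))
  })
}
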