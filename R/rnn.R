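#' Initialize recurrent-network parameters
#'
#' Three input units (object retinal velocity, near-dot flow, far-dot
#' flow), `n_units` fully connected recurrent units, two linear outputs
#' (world-frame horizontal object velocity and depth). Recurrent weights
#' are Gaussian with SD `1 / sqrt(n_units)` (spectral radius near 1);
#' input/output weights Gaussian with SD 0.1; biases zero.
#'
#' @param n_units Number of recurrent units.
#' @param tau Time constant (s).
#' @param dt Integration step (s).
#' @param seed Integer seed.
#' @return A list of class `pf_rnn` with weight matrices `W_in` (n x 3),
#'   `W_rec` (n x n), `W_out` (2 x n), biases `b_rec`, `b_out`, and the
#'   timing config.
#' @export
rnn_init <- function(n_units = 64, tau = 0.1, dt = 0.01, seed = NULL) {
  stopifnot(dt < tau)
  if (!is.null(seed)) return(withr::with_seed(seed, rnn_init(n_units, tau, dt)))
  structure(list(
    W_in = matrix(stats::rnorm(n_units * 3, 0, 0.1), n_units, 3),
    W_rec = matrix(stats::rnorm(n_units^2, 0, 1 / sqrt(n_units)), n_units),
    W_out = matrix(stats::rnorm(2 * n_units, 0, 0.1), 2, n_units),
    b_rec = rep(0, n_units), b_out = rep(0, 2),
    n_units = n_units, tau = tau, dt = dt,
    n_pre = round(0.5 / dt), n_stim = round(1 / dt), n_post = round(0.5 / dt),
    loss_history = NULL
  ), class = "pf_rnn")
}

#' @export
print.pf_rnn <- function(x, ...) {
  trained <- if (is.null(x$loss_history)) "untrained" else
    sprintf("trained %d epochs, final loss %.3f", length(x$loss_history),
            mean(utils::tail(x$loss_history, 20)))
  cat(sprintf("<pf_rnn> %d units, tau = %g s, dt = %g s (%s)\n",
              x$n_units, x$tau, x$dt, trained))
  invisible(x)
}

#' Generate one network task trial
#'
#' A trial is 500 ms of input noise, 1 s of stimulus plus noise, and 500 ms
#' of noise; the loss mask covers only the final 500 ms. Retinal and eye
#' velocities are drawn uniformly from -10..10 (arbitrary units). In the R
#' geometry both background dots carry the depth-invariant rotational flow
#' `-omega_eye`, the object moves in the world, the motion target is the
#' coordinate transformation `omega_ret + omega_eye`, and the depth target
#' is 0 (depth is ambiguous in a rotational flow field; 0 is its symmetric
#' resolution). In R+T the object is stationary at depth
#' `dprime ~ U(-1, 1)`: its retinal motion is pure parallax
#' `dprime * omega_eye`, the motion target is 0 and the depth target is
#' `dprime`. The two background dots sit at fixed depths -0.5 and +0.5, so
#' their flows have opposite signs. (With a freely moving object in R+T the
#' depth target would be unidentifiable from the inputs: any retinal motion
#' could be object motion; the stationary-object regime is what makes
#' motion parallax a depth cue.) Supplying `omega_obj` overrides the
#' stationary object in R+T, shifting the retinal input accordingly.
#'
#' @param geometry `"R"` or `"RT"`.
#' @param omega_eye,omega_obj,dprime Optional fixed values (drawn if NULL).
#' @param noise_sd Input noise SD (0.5 as in training).
#' @param rnn A `pf_rnn` (for the timing config).
#' @param seed Integer seed.
#' @return A list with `input` (T x 3 matrix), `target` (length 2),
#'   `mask` (length-T logical), and the drawn `omega_eye`, `omega_obj`,
#'   `dprime`.
#' @export
make_rnn_trial <- function(geometry = c("R", "RT"), omega_eye = NULL,
                           omega_obj = NULL, dprime = NULL, noise_sd = 0.5,
                           rnn = rnn_init(seed = 1), seed = NULL) {
  geometry <- match.arg(geometry)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, make_rnn_trial(
      geometry, omega_eye, omega_obj, dprime, noise_sd, rnn
    )))
  }
  if (is.null(omega_eye)) omega_eye <- stats::runif(1, -10, 10)
  if (geometry == "R") {
    dprime <- 0
    if (is.null(omega_obj)) {
      ret <- stats::runif(1, -10, 10)
      omega_obj <- ret + omega_eye
    } else {
      ret <- omega_obj - omega_eye
    }
    bg <- c(-omega_eye, -omega_eye)
    target <- c(omega_obj, 0)
  } else {
    if (is.null(dprime)) dprime <- stats::runif(1, -1, 1)
    if (is.null(omega_obj)) omega_obj <- 0
    ret <- omega_obj + dprime * omega_eye
    bg <- c(-0.5, 0.5) * omega_eye
    target <- c(omega_obj, dprime)
  }
  T_ <- rnn$n_pre + rnn$n_stim + rnn$n_post
  stim <- seq(rnn$n_pre + 1, rnn$n_pre + rnn$n_stim)
  input <- matrix(stats::rnorm(T_ * 3, 0, noise_sd), T_, 3)
  input[stim, ] <- input[stim, ] +
    matrix(c(ret, bg), nrow = length(stim), ncol = 3, byrow = TRUE)
  mask <- seq_len(T_) > rnn$n_pre + rnn$n_stim
  list(input = input, target = target, mask = mask, geometry = geometry,
       omega_eye = omega_eye, omega_obj = omega_obj, dprime = dprime)
}

#' One Euler step of the network dynamics
#'
#' `x <- x + (dt/tau) * (-x + W_rec %*% tanh(x) + b_rec + W_in %*% u)`,
#' output `z = W_out %*% tanh(x) + b_out`.
#'
#' @param state Recurrent state vector (length `n_units`).
#' @param input Input vector (length 3).
#' @param rnn A `pf_rnn`.
#' @return A list with the next `state` and the `output` (length 2).
#' @export
rnn_step <- function(state, input, rnn) {
  if (any(!is.finite(state))) stop("network state diverged", call. = FALSE)
  a <- rnn$dt / rnn$tau
  state <- (1 - a) * state +
    a * (drop(rnn$W_rec %*% tanh(state)) + rnn$b_rec +
           drop(rnn$W_in %*% input))
  list(state = state,
       output = drop(rnn$W_out %*% tanh(state)) + rnn$b_out)
}

#' Train the network on the motion and depth tasks
#'
#' Backpropagation through time with Adam on the squared-error loss of the
#' two outputs during the final 500 ms of each trial (see [make_rnn_trial()]
#' for the trial structure). Trials mix the two geometries at random within
#' each batch. Deterministic under a fixed
#' seed (up to floating-point reassociation in the BLAS).
#'
#' @param rnn A `pf_rnn` from [rnn_init()] (fresh weights initialized with
#'   `seed` if omitted).
#' @param epochs Training epochs (one batch each). The package's default
#'   configuration is a scaled-down 5,000 epochs; the full-scale run of the
#'   study this emulates used 50,000.
#' @param batch Batch size.
#' @param lr Adam learning rate.
#' @param noise_sd Input noise SD.
#' @param seed Integer seed (weights, trials).
#' @return The trained `pf_rnn`, with `loss_history` filled in.
#' @export
rnn_train <- function(rnn = NULL, epochs = 5000, batch = 64, lr = 1e-3,
                      noise_sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    if (is.null(rnn)) rnn <- rnn_init()
    out <- rnn_train_cpp(rnn$W_in, rnn$W_rec, rnn$W_out, rnn$b_rec, rnn$b_out,
                         as.integer(epochs), as.integer(batch), lr,
                         rnn$tau, rnn$dt, rnn$n_pre, rnn$n_stim, rnn$n_post,
                         noise_sd, 10, -0.5, 0.5)
    rnn$W_in <- out$W_in; rnn$W_rec <- out$W_rec; rnn$W_out <- out$W_out
    rnn$b_rec <- drop(out$b_rec); rnn$b_out <- drop(out$b_out)
    rnn$loss_history <- drop(out$loss_history)
    rnn
  })
}

probe_inputs <- function(rnn, ret, near, far, noise_sd = 0) {
  # build an input cube (3 x batch x T) for vectors of per-trial signals
  T_ <- rnn$n_pre + rnn$n_stim + rnn$n_post
  B <- length(ret)
  U <- array(stats::rnorm(3 * B * T_, 0, noise_sd), c(3, B, T_))
  stim <- seq(rnn$n_pre + 1, rnn$n_pre + rnn$n_stim)
  sig <- rbind(ret, near, far)
  U[, , stim] <- U[, , stim] + array(sig, c(3, B, length(stim)))
  U
}

bg_flows <- function(geometry, omega_eye) {
  if (geometry == "R") rbind(-omega_eye, -omega_eye)
  else rbind(-0.5 * omega_eye, 0.5 * omega_eye)
}

#' Probe the trained network with the psychophysical task battery
#'
#' Replays the human experiments through the network: retinal directions
#' -90..90 deg in 12 deg steps at retinal speed 2, eye speed three times
#' that, both eye signs, both geometries, noise-free inputs. The network
#' sees only horizontal components; its reported direction is the angle of
#' (estimated horizontal world speed, veridical vertical component).
#' Outputs are averaged over the response window (final 500 ms).
#'
#' @param rnn A trained `pf_rnn`.
#' @param directions Probe retinal directions (deg).
#' @param retinal_speed Probe retinal speed (input units).
#' @param eye_mult Eye speed as a multiple of `retinal_speed`.
#' @param noise_sd Probe input noise SD (0 = deterministic curves).
#' @return A tibble with `geometry`, `eye_dir`, `direction_in`,
#'   `motion_out` (horizontal world-velocity estimate), `depth_out`,
#'   `direction_est` (deg).
#' @export
probe_psychometrics <- function(rnn, directions = seq(-90, 90, by = 12),
                                retinal_speed = 2, eye_mult = 3,
                                noise_sd = 0) {
  grid <- tidyr::expand_grid(geometry = c("R", "RT"), eye_dir = c(-1, 1),
                             direction_in = directions)
  ret_x <- retinal_speed * sin(grid$direction_in * pi / 180)
  ret_y <- retinal_speed * cos(grid$direction_in * pi / 180)
  eye <- grid$eye_dir * eye_mult * retinal_speed
  bg <- matrix(0, 2, nrow(grid))
  for (i in seq_len(nrow(grid))) bg[, i] <- bg_flows(grid$geometry[i], eye[i])
  U <- probe_inputs(rnn, ret_x, bg[1, ], bg[2, ], noise_sd)
  Z <- rnn_forward_cpp(rnn$W_in, rnn$W_rec, rnn$W_out, rnn$b_rec, rnn$b_out,
                       U, rnn$tau, rnn$dt)
  mask <- seq_len(dim(Z)[3]) > rnn$n_pre + rnn$n_stim
  zbar <- apply(Z[, , mask, drop = FALSE], c(1, 2), mean)
  tibble::tibble(
    geometry = grid$geometry, eye_dir = grid$eye_dir,
    direction_in = grid$direction_in,
    motion_out = zbar[1, ], depth_out = zbar[2, ],
    direction_est = direction_deg(zbar[1, ], ret_y)
  )
}

#' Joint retinal-by-eye velocity tuning maps of the recurrent units
#'
#' Activation of every recurrent unit at the final trial time point, mapped
#' over the full grid of retinal and eye velocity combinations under one
#' geometry (noise-free probing).
#'
#' @param rnn A trained `pf_rnn`.
#' @param geometry `"R"` or `"RT"` (sets the background-dot inputs).
#' @param grid Velocity grid (default -10..10 step 1).
#' @return A 3-D array `length(grid) x length(grid) x n_units`; rows index
#'   retinal velocity, columns eye velocity.
#' @export
rnn_tuning_maps <- function(rnn, geometry = c("R", "RT"), grid = -10:10) {
  geometry <- match.arg(geometry)
  cells <- tidyr::expand_grid(v_ret = grid, v_eye = grid)
  bg <- bg_flows(geometry, cells$v_eye)
  U <- probe_inputs(rnn, cells$v_ret, bg[1, ], bg[2, ], noise_sd = 0)
  Rfin <- rnn_final_activation_cpp(rnn$W_in, rnn$W_rec, rnn$b_rec, U,
                                   rnn$tau, rnn$dt)
  ng <- length(grid)
  out <- array(0, c(ng, ng, rnn$n_units),
               dimnames = list(grid, grid, NULL))
  for (u in seq_len(rnn$n_units)) {
    out[, , u] <- matrix(Rfin[u, ], ng, ng, byrow = TRUE)  # rows v_ret
  }
  out
}

#' Fourier tuning-shift metric of a joint velocity tuning map
#'
#' Quantifies diagonal structure in a joint retinal-by-eye velocity tuning
#' profile as the normalized product of inertia of its 2-D Fourier power
#' spectrum: after removing the map mean, power below -10 dB of the peak is
#' zeroed and the metric is
#' `100 * sum(kx * ky * P) / sum(|kx * ky| * P)` over origin-centered
#' frequencies. A unit tuned to world velocity (activation a function of
#' `v_ret + v_eye`, a ridge along the negative diagonal of the map)
#' concentrates power on the `kx = ky` line and scores +100; a
#' retina-centered (separable) map scores 0; the mirrored ridge scores
#' -100. The metric is invariant to multiplicative rescaling of the map.
#'
#' @param map A square numeric matrix (rows retinal velocity, columns eye
#'   velocity).
#' @param threshold_db Power threshold below the spectral peak (dB).
#' @return Percent tuning shift in \[-100, 100\]; `NA` (with a warning)
#'   when no off-axis power survives the threshold.
#' @examples
#' grid <- -10:10
#' ridge <- outer(grid, grid, function(r, e) exp(-(r + e)^2 / 8))
#' tuning_shift(ridge) # close to +100
#' @export
tuning_shift <- function(map, threshold_db = -10) {
  stopifnot(is.matrix(map), nrow(map) == ncol(map), all(is.finite(map)))
  n <- nrow(map)
  P <- Mod(stats::fft(map - mean(map)))^2
  k <- ifelse(seq_len(n) - 1 <= n %/% 2, seq_len(n) - 1, seq_len(n) - 1 - n)
  if (max(P) == 0) {
    warning("flat map: tuning shift undefined")
    return(NA_real_)
  }
  P[P < max(P) * 10^(threshold_db / 10)] <- 0
  KX <- matrix(k, n, n)
  KY <- matrix(k, n, n, byrow = TRUE)
  den <- sum(abs(KX * KY) * P)
  # no surviving off-axis power means no diagonal structure at all
  if (den == 0) return(0)
  100 * sum(KX * KY * P) / den
}

#' Tuning-shift distribution across recurrent units
#'
#' @param rnn A trained `pf_rnn`.
#' @param geometry `"R"` or `"RT"`.
#' @param grid Velocity grid.
#' @return Numeric vector of per-unit shifts (NA for flat units).
#' @export
tuning_shift_distribution <- function(rnn, geometry = c("R", "RT"),
                                      grid = -10:10) {
  geometry <- match.arg(geometry)
  maps <- rnn_tuning_maps(rnn, geometry, grid)
  apply(maps, 3, function(m) {
    suppressWarnings(tuning_shift(m))
  })
}

#' Plot a joint velocity tuning map
#'
#' @param map A square matrix (rows retinal velocity, columns eye velocity)
#'   with dimnames giving the grid, e.g. one slice of [rnn_tuning_maps()].
#' @return A ggplot object.
#' @export
plot_tuning_map <- function(map) {
  grid_r <- as.numeric(rownames(map) %||% seq_len(nrow(map)))
  grid_e <- as.numeric(colnames(map) %||% seq_len(ncol(map)))
  d <- tibble::tibble(
    v_retina = rep(grid_r, each = length(grid_e)),
    v_eye = rep(grid_e, times = length(grid_r)),
    activation = as.vector(t(map))
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$v_eye, .data$v_retina,
                                  fill = .data$activation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "eye velocity", y = "retinal velocity") +
    ggplot2::theme_minimal()
}
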