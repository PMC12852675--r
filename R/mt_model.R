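#' Parameters of the joint retinal-by-eye velocity tuning model
#'
#' Ten parameters of the parametric firing-rate model
#' `lambda = A * [g(v_eye) * f(v_retina + w * v_eye) + o(v_eye)]^+ + B`:
#' `A` (amplitude, spikes/s), `B` (baseline, spikes/s), `w` (tuning-shift
#' weight on eye velocity, in \[-1, 1\]; 0 = retina-centered, 1 =
#' world-centered), `alpha` (slope of the multiplicative gain
#' `g(v) = 2 / (1 + exp(-alpha v))`), `sigma`, `delta`, `s`, `kappa`, `phi`
#' (log-Gaussian speed tuning with offset, and von Mises direction tuning,
#' of `f`), and `beta` (slope of the additive modulation
#' `o(v) = 2 / (1 + exp(-beta v)) - 1`).
#'
#' @param A,B Amplitude and baseline (spikes/s, >= 0).
#' @param w Eye-velocity weight in \[-1, 1\].
#' @param alpha Gain slope (per deg/s).
#' @param sigma Log-speed tuning width (> 0).
#' @param delta Speed offset (deg/s, >= 0).
#' @param s Preferred speed (deg/s, >= 0).
#' @param kappa Direction concentration (>= 0).
#' @param phi Preferred direction (rad; horizontal axis, so effectively
#'   +pi/2 or -pi/2 for 1D velocities).
#' @param beta Additive modulation slope (per deg/s).
#' @return A list of class `pf_mt_params`.
#' @export
mt_params <- function(A = 30, B = 5, w = 0, alpha = 0.05, sigma = 1,
                      delta = 1, s = 4, kappa = 1.5, phi = pi / 2,
                      beta = 0.1) {
  stopifnot(A >= 0, B >= 0, w >= -1, w <= 1, sigma > 0, delta >= 0, s >= 0,
            kappa >= 0)
  structure(list(A = A, B = B, w = w, alpha = alpha, sigma = sigma,
                 delta = delta, s = s, kappa = kappa, phi = phi, beta = beta),
            class = "pf_mt_params")
}

#' Firing rate of the joint velocity tuning model
#'
#' Evaluates the model of [mt_params()] on signed 1D velocities. The
#' direction of a signed scalar velocity is +90 deg (rightward) for
#' positive values and -90 deg for negative values; at exactly zero the
#' direction term is evaluated at +90 deg (the speed term dominates there).
#' Rectification is applied before scaling by `A`, so the rate never falls
#' below `B`.
#'
#' @param v_retina,v_eye Signed velocities (deg/s), vectorized.
#' @param params A [mt_params()] object.
#' @return Firing rate (spikes/s).
#' @examples
#' mt_firing_rate(4, 0, mt_params(s = 4)) # A + B at preferred speed
#' @export
mt_firing_rate <- function(v_retina, v_eye, params) {
  p <- params
  vs <- v_retina + p$w * v_eye
  g <- 2 / (1 + exp(-p$alpha * v_eye))
  o <- 2 / (1 + exp(-p$beta * v_eye)) - 1
  theta <- ifelse(vs < 0, -pi / 2, pi / 2)
  f <- exp(-(log((abs(vs) + p$delta) / (p$s + p$delta)))^2 / (2 * p$sigma^2)) *
    exp(p$kappa * (cos(theta - p$phi) - 1))
  p$A * pmax(g * f + o, 0) + p$B
}

mt_par_vec <- function(p) {
  c(A = p$A, B = p$B, w = p$w, alpha = p$alpha, sigma = p$sigma,
    delta = p$delta, s = p$s, kappa = p$kappa, phi = p$phi, beta = p$beta)
}

mt_vec_par <- function(v) {
  mt_params(A = v[1], B = v[2], w = v[3], alpha = v[4], sigma = v[5],
            delta = v[6], s = v[7], kappa = v[8], phi = v[9], beta = v[10])
}

#' Fit the joint tuning model to spike counts by Poisson maximum likelihood
#'
#' Multi-start bounded optimization (L-BFGS-B) of the Poisson negative
#' log-likelihood of spike counts on a retinal-by-eye velocity grid under
#' the [mt_firing_rate()] model. Starting points combine data-driven
#' heuristics (baseline and amplitude from the extreme cell means,
#' preferred speed and direction from the peak cell) with jittered restarts
#' over the shift weight. Bounds keep the speed-tuning factors numerically
#' stable (`sigma >= 0.05`, `delta >= 0.01`).
#'
#' @param counts Tibble with columns `v_retina`, `v_eye`, `count`
#'   (nonnegative integers); a `trial` column may repeat cells. The grid
#'   must have at least 5 levels per axis.
#' @param count_window Spike-count window (s) relating rates to counts.
#' @param n_starts Number of optimization starts.
#' @param seed Integer seed for start jitter.
#' @return An object of class `pf_mt_fit`: `params` (a `pf_mt_params`),
#'   `nll`, `convergence`, `n_starts`, `n_obs`. Has `tidy()`/`glance()`
#'   methods.
#' @export
fit_mt_poisson <- function(counts, count_window = 1, n_starts = 10,
                           seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, fit_mt_poisson(counts, count_window,
                                                 n_starts)))
  }
  stopifnot(all(c("v_retina", "v_eye", "count") %in% names(counts)),
            all(counts$count >= 0))
  if (length(unique(counts$v_retina)) < 5 || length(unique(counts$v_eye)) < 5) {
    stop("grid must cover >= 5 levels per axis", call. = FALSE)
  }
  if (all(counts$count == 0)) {
    warning("all counts are zero: degenerate fit")
  }
  # the Poisson likelihood depends on trials within a cell only through
  # their count sum, so collapse to one term per grid cell
  agg <- dplyr::summarise(dplyr::group_by(counts, .data$v_retina, .data$v_eye),
                          k_sum = sum(.data$count), n_rep = dplyr::n(),
                          .groups = "drop")
  vr <- agg$v_retina; ve <- agg$v_eye
  nll <- function(par) {
    lam <- mt_firing_rate(vr, ve, mt_vec_par(par)) * count_window
    lam <- pmax(lam, 1e-9)
    sum(agg$n_rep * lam - agg$k_sum * log(lam))
  }
  cellm <- dplyr::summarise(dplyr::group_by(counts, .data$v_retina, .data$v_eye),
                            m = mean(.data$count), .groups = "drop")
  peak <- cellm[which.max(cellm$m), ]
  b0 <- max(stats::quantile(cellm$m, 0.05) / count_window, 0.1)
  a0 <- max((max(cellm$m) - b0 * count_window) / count_window, 0.5)
  s0 <- max(abs(peak$v_retina), 0.5)
  phi0 <- if (peak$v_retina >= 0) pi / 2 else -pi / 2
  vmax <- max(abs(c(vr, ve)))

  base <- c(A = a0, B = b0, w = 0, alpha = 0.05, sigma = 1, delta = 1,
            s = s0, kappa = 1.5, phi = phi0, beta = 0)
  lower <- c(1e-6, 1e-9, -1, -2, 0.05, 0.01, 0.05, 0, -pi, -2)
  upper <- c(20 * (a0 + b0), 5 * (a0 + b0), 1, 2, 5, 20, 4 * vmax, 20, pi, 2)
  starts <- list(base,
                 replace(base, "w", 0.5), replace(base, "w", -0.5),
                 replace(base, c("sigma", "w"), c(0.4, 0.25)))
  while (length(starts) < n_starts) {
    j <- base * exp(stats::rnorm(10, 0, 0.2))
    j["w"] <- stats::runif(1, -1, 1)
    j["phi"] <- sample(c(pi / 2, -pi / 2), 1)
    j["beta"] <- stats::rnorm(1, 0, 0.1)
    j <- pmin(pmax(j, lower + 1e-8), upper - 1e-8)
    starts <- c(starts, list(j))
  }
  best <- NULL
  for (st in starts[seq_len(min(n_starts, length(starts)))]) {
    f <- tryCatch(stats::optim(st, nll, method = "L-BFGS-B", lower = lower,
                               upper = upper, control = list(maxit = 300)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)
  structure(list(params = mt_vec_par(best$par), nll = best$value,
                 convergence = best$convergence, n_starts = n_starts,
                 n_obs = nrow(counts)),
            class = "pf_mt_fit")
}

#' @export
print.pf_mt_fit <- function(x, ...) {
  cat(sprintf("<pf_mt_fit> w = %.3f, A = %.1f, B = %.1f, NLL = %.1f (n = %d)\n",
              x$params$w, x$params$A, x$params$B, x$nll, x$n_obs))
  invisible(x)
}

#' @export
tidy.pf_mt_fit <- function(x, ...) {
  v <- mt_par_vec(x$params)
  tibble::tibble(term = names(v), estimate = unname(v))
}

#' @export
glance.pf_mt_fit <- function(x, ...) {
  tibble::tibble(nll = x$nll, convergence = x$convergence, n_obs = x$n_obs)
}

#' Noise-free rate map of a tuning model on a velocity grid
#'
#' Convenience for relating the fitted shift weight `w` to the Fourier
#' tuning-shift metric: evaluates [mt_firing_rate()] on the full grid and
#' returns the matrix (retinal velocity in rows, eye velocity in columns)
#' that [tuning_shift()] accepts.
#'
#' @param params A [mt_params()] object.
#' @param grid Velocity grid (deg/s).
#' @return A matrix with `length(grid)` rows and columns.
#' @export
mt_rate_map <- function(params, grid = -10:10) {
  outer(grid, grid, function(vr, ve) mt_firing_rate(vr, ve, params))
}
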