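#' Cumulative-Gaussian psychometric function
#'
#' `psi(x) = gamma + (1 - lambda - gamma) * pnorm(C * (x - m) / w)` with
#' `C = qnorm(0.95) - qnorm(0.05)` (~3.2897), so `w` is the width of the
#' central 90% of the underlying Gaussian. `gamma` and `lambda` are the
#' guess and lapse rates at the low and high stimulus ends. A negative `w`
#' encodes a decreasing function (e.g. the opposite eye-movement
#' direction).
#'
#' @param x Stimulus level (retinal direction, deg).
#' @param m Midpoint (deg).
#' @param w Width (deg); sign carries curve polarity.
#' @param lambda,gamma Lapse and guess rates.
#' @return P(report "far"), vectorized.
#' @export
psychometric_prob <- function(x, m, w, lambda = 0, gamma = 0) {
  C <- stats::qnorm(0.95) - stats::qnorm(0.05)
  gamma + (1 - lambda - gamma) * stats::pnorm(C * (x - m) / w)
}

#' Fit a psychometric function to binary depth reports
#'
#' Maximum-likelihood fit of the cumulative-Gaussian psychometric function
#' ([psychometric_prob()]) with lapse and guess rates bounded in
#' \[0, `lapse_max`\]. Internally the curve is parameterized by its midpoint
#' and the probit slope `b = C / w` (unbounded, sign free), so increasing
#' and decreasing curves are fit in one pass. The reported `slope` is the
#' derivative of the fitted function at its midpoint,
#' `(1 - lambda - gamma) * C / (w * sqrt(2 * pi))`, in probability per
#' degree; its sign follows the curve polarity. Bootstrap CIs resample
#' responses within each stimulus level.
#'
#' @param directions Stimulus levels (deg), one per trial.
#' @param responses Binary responses, 1 = "far" (or a character vector of
#'   `"near"`/`"far"`).
#' @param lapse_max Upper bound for `lambda` and `gamma`.
#' @param bootstrap_n Bootstrap resamples for CIs (0 to skip).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `pf_psychfit`: `m`, `w` (signed), `width`
#'   (`abs(w)`), `lambda`, `gamma`, `slope`, `loglik`, `boundary` (TRUE
#'   when the responses were all identical), `boot`, and the per-level
#'   summary `data`. Has `tidy()`/`glance()` methods.
#' @examples
#' x <- rep(seq(-90, 90, 15), each = 20)
#' y <- rbinom(length(x), 1, psychometric_prob(x, 10, 30, 0.02, 0.02))
#' fit_psychometric(x, y, bootstrap_n = 0)
#' @export
fit_psychometric <- function(directions, responses, lapse_max = 0.1,
                             bootstrap_n = 0, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, fit_psychometric(
      directions, responses, lapse_max, bootstrap_n
    )))
  }
  if (is.character(responses) || is.factor(responses)) {
    responses <- as.integer(as.character(responses) == "far")
  }
  stopifnot(length(directions) == length(responses),
            all(responses %in% c(0, 1)))
  keep <- is.finite(directions) & is.finite(responses)
  x <- directions[keep]; y <- responses[keep]
  if (length(unique(x)) < 3) {
    stop("need at least 3 stimulus levels", call. = FALSE)
  }
  C <- stats::qnorm(0.95) - stats::qnorm(0.05)

  if (length(unique(y)) == 1L) {
    warning("all responses identical: boundary fit, slope reported as 0")
    return(structure(list(m = NA_real_, w = NA_real_, width = NA_real_,
                          lambda = 0, gamma = 0, slope = 0,
                          loglik = 0, boundary = TRUE, boot = NULL,
                          data = level_summary(x, y)),
                     class = "pf_psychfit"))
  }

  nll <- function(par) {
    p <- par[4] + (1 - par[3] - par[4]) * stats::pnorm(par[2] * (x - par[1]))
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  span <- diff(range(x))
  g <- tryCatch(
    stats::glm(y ~ x, family = stats::binomial("probit"))$coefficients,
    warning = function(w) suppressWarnings(
      stats::glm(y ~ x, family = stats::binomial("probit"))$coefficients
    ))
  b0 <- if (is.finite(g[2]) && g[2] != 0) unname(g[2]) else 0.02
  m0 <- if (is.finite(g[2]) && g[2] != 0) unname(-g[1] / g[2]) else stats::median(x)
  m0 <- min(max(m0, min(x) - span), max(x) + span)
  starts <- list(c(m0, b0, 0.02, 0.02),
                 c(stats::median(x), sign(b0) * C / span, 0.02, 0.02),
                 c(m0, sign(b0) * 3 * C / span, 0.02, 0.02),
                 c(m0, -b0, 0.02, 0.02))
  lower <- c(min(x) - 2 * span, -50, 0, 0)
  upper <- c(max(x) + 2 * span, 50, lapse_max, lapse_max)
  # m and the probit slope live on very different scales; without parscale
  # the line search overshoots the slope and lands on a steep-step local
  # optimum with the lapse terms absorbing the tails
  pscale <- c(max(span / 10, 1), max(abs(b0), C / span), 0.02, 0.02)
  best <- NULL
  for (s in starts) {
    f <- tryCatch(stats::optim(s, nll, method = "L-BFGS-B",
                               lower = lower, upper = upper,
                               control = list(maxit = 500, parscale = pscale)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  # derivative-free polish, clamped back into the box
  pol <- tryCatch(stats::optim(best$par, function(p) {
    nll(pmin(pmax(p, lower), upper))
  }, method = "Nelder-Mead", control = list(maxit = 400, parscale = pscale)),
  error = function(e) NULL)
  if (!is.null(pol) && pol$value < best$value) {
    pol$par <- pmin(pmax(pol$par, lower), upper)
    best <- pol
  }
  par <- best$par
  w <- C / par[2]
  lam <- par[3]; gam <- par[4]
  slope <- (1 - lam - gam) * C / (w * sqrt(2 * pi))

  boot <- NULL
  if (bootstrap_n > 0) {
    boot <- purrr::map_dfr(seq_len(bootstrap_n), function(b) {
      yb <- unlist(lapply(split(y, x), function(v) sample(v, replace = TRUE)))
      xb <- unlist(lapply(split(x, x), identity))
      fb <- fit_psychometric(xb, yb, lapse_max, bootstrap_n = 0)
      tibble::tibble(m = fb$m, w = fb$w, lambda = fb$lambda,
                     gamma = fb$gamma, slope = fb$slope)
    })
  }
  structure(list(m = par[1], w = w, width = abs(w), lambda = lam, gamma = gam,
                 slope = slope, loglik = -best$value, boundary = FALSE,
                 boot = boot, data = level_summary(x, y)),
            class = "pf_psychfit")
}

level_summary <- function(x, y) {
  d <- tibble::tibble(direction = x, response = y)
  dplyr::summarise(dplyr::group_by(d, .data$direction),
                   n = dplyr::n(), p_far = mean(.data$response),
                   .groups = "drop")
}

#' @export
print.pf_psychfit <- function(x, ...) {
  if (x$boundary) {
    cat("<pf_psychfit> boundary fit (all responses identical)\n")
  } else {
    cat(sprintf(
      "<pf_psychfit> m = %.2f deg, w = %.2f deg, lambda = %.3f, gamma = %.3f, slope = %.4f /deg\n",
      x$m, x$w, x$lambda, x$gamma, x$slope))
  }
  invisible(x)
}

#' @export
tidy.pf_psychfit <- function(x, conf_level = 0.95, ...) {
  out <- tibble::tibble(term = c("m", "w", "lambda", "gamma", "slope"),
                        estimate = c(x$m, x$w, x$lambda, x$gamma, x$slope))
  if (!is.null(x$boot)) {
    p <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
    qs <- purrr::map(out$term, ~ stats::quantile(x$boot[[.x]], p, na.rm = TRUE))
    out$conf.low <- purrr::map_dbl(qs, 1)
    out$conf.high <- purrr::map_dbl(qs, 2)
  }
  out
}

#' @export
glance.pf_psychfit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, boundary = x$boundary,
                 n_trials = sum(x$data$n), n_levels = nrow(x$data))
}

#' Plot a fitted psychometric function
#'
#' @param fit A `pf_psychfit`.
#' @return A ggplot object with per-level proportions and the fitted curve.
#' @export
plot_psychometric <- function(fit) {
  stopifnot(inherits(fit, "pf_psychfit"))
  xx <- seq(min(fit$data$direction), max(fit$data$direction), length.out = 200)
  curve <- tibble::tibble(
    direction = xx,
    p_far = psychometric_prob(xx, fit$m, fit$w, fit$lambda, fit$gamma)
  )
  ggplot2::ggplot(fit$data, ggplot2::aes(.data$direction, .data$p_far)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_line(data = curve, colour = "#2166ac") +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::labs(x = "retinal direction (deg)", y = "P(report far)") +
    ggplot2::theme_minimal()
}
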