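cosine_error <- function(a_ret, a_eye, ret_x, ret_y, eye_x, reported) {
  pred <- atan2((1 - a_ret) * ret_x + a_eye * eye_x, ret_y)
  mean(1 - cos(pred - reported * pi / 180))
}

fit_weights_once <- function(ret_x, ret_y, eye_x, reported, alpha,
                             n_starts = 4) {
  obj <- function(z) {
    a <- stats::plogis(z)
    cosine_error(a[1], a[2], ret_x, ret_y, eye_x, reported) +
      alpha * (a[1] + a[2])
  }
  starts <- list(stats::qlogis(c(0.05, 0.05)), stats::qlogis(c(0.5, 0.5)),
                 stats::qlogis(c(0.9, 0.1)), stats::qlogis(c(0.1, 0.9)),
                 stats::qlogis(c(0.9, 0.9)))[seq_len(max(2, n_starts))]
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  a <- stats::plogis(best$par)
  list(a_ret = a[1], a_eye = a[2], value = best$value)
}

#' Fit the linear observer model to direction reports
#'
#' Estimates the retinal and eye-velocity weights of the linear observer
#' model from single-trial direction reports by minimizing the mean cosine
#' error between predicted and reported directions,
#' `mean(1 - cos(pred - reported)) + alpha * (a_ret + a_eye)`,
#' with both weights bounded in \[0, 1\] via a logistic reparameterization
#' and multi-start Nelder-Mead. The L1 penalty `alpha` is chosen by
#' k-fold cross-validation on the unpenalized cosine error; confidence
#' intervals come from resampling trials with replacement.
#'
#' Trials must already be slip-corrected (see [slip_correct()]) when they
#' come from real-pursuit conditions.
#'
#' @param trials Tibble with columns `retinal_x`, `retinal_y`, `eye_x`
#'   (deg/s) and `reported_direction` (deg); rows with `valid == FALSE` are
#'   dropped if a `valid` column is present.
#' @param alpha_grid Candidate L1 penalties (log-spaced 1e-4..1 by default).
#' @param cv_folds Number of cross-validation folds.
#' @param bootstrap_n Bootstrap resamples for CIs (0 to skip).
#' @param seed Integer seed controlling fold assignment and bootstrap.
#' @return An object of class `pf_observer_fit` with elements `a_ret`,
#'   `a_eye`, `alpha`, `objective`, `cv` (tibble of per-alpha CV error),
#'   `boot` (tibble of resampled weights) and `n_trials`. Has
#'   [generics::tidy()] and [generics::glance()] methods.
#' @examples
#' des <- experiment_design("Exp1", geometries = "RT", reps = 2)
#' tr <- generate_trials(des, seed = 1)
#' fit_linear_observer(tr, bootstrap_n = 0, seed = 1)
#' @export
fit_linear_observer <- function(trials,
                                alpha_grid = 10^seq(-4, 0, length.out = 8),
                                cv_folds = 5, bootstrap_n = 500, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, fit_linear_observer(
      trials, alpha_grid, cv_folds, bootstrap_n
    )))
  }
  if ("valid" %in% names(trials)) trials <- trials[trials$valid, ]
  trials <- trials[is.finite(trials$reported_direction), ]
  n <- nrow(trials)
  if (length(unique(trials$retinal_dir_deg %||% trials$retinal_x)) < 2 ||
      length(unique(sign(trials$eye_x))) < 2) {
    stop("underdetermined design: need >= 2 retinal directions and both eye signs",
         call. = FALSE)
  }
  rx <- trials$retinal_x; ry <- trials$retinal_y; ex <- trials$eye_x
  rep_dir <- trials$reported_direction

  folds <- sample(rep_len(seq_len(cv_folds), n))
  cv <- purrr::map_dbl(alpha_grid, function(al) {
    mean(purrr::map_dbl(seq_len(cv_folds), function(k) {
      tr <- folds != k
      f <- fit_weights_once(rx[tr], ry[tr], ex[tr], rep_dir[tr], al,
                            n_starts = 3)
      cosine_error(f$a_ret, f$a_eye, rx[!tr], ry[!tr], ex[!tr], rep_dir[!tr])
    }))
  })
  alpha <- alpha_grid[which.min(cv)]
  fit <- fit_weights_once(rx, ry, ex, rep_dir, alpha, n_starts = 5)

  boot <- NULL
  if (bootstrap_n > 0) {
    boot <- purrr::map_dfr(seq_len(bootstrap_n), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      f <- fit_weights_once(rx[idx], ry[idx], ex[idx], rep_dir[idx], alpha,
                            n_starts = 2)
      tibble::tibble(a_ret = f$a_ret, a_eye = f$a_eye)
    })
  }
  structure(list(
    a_ret = fit$a_ret, a_eye = fit$a_eye, alpha = alpha,
    objective = fit$value,
    cv = tibble::tibble(alpha = alpha_grid, cv_error = cv),
    boot = boot, n_trials = n
  ), class = "pf_observer_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pf_observer_fit <- function(x, ...) {
  cat(sprintf("<pf_observer_fit> a_ret = %.3f, a_eye = %.3f (alpha = %.2g, n = %d)\n",
              x$a_ret, x$a_eye, x$alpha, x$n_trials))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pf_observer_fit <- function(x, conf_level = 0.95, ...) {
  out <- tibble::tibble(term = c("a_ret", "a_eye"),
                        estimate = c(x$a_ret, x$a_eye))
  if (!is.null(x$boot)) {
    p <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
    out$conf.low <- c(stats::quantile(x$boot$a_ret, p[1]),
                      stats::quantile(x$boot$a_eye, p[1]))
    out$conf.high <- c(stats::quantile(x$boot$a_ret, p[2]),
                       stats::quantile(x$boot$a_eye, p[2]))
  }
  out
}

#' @export
glance.pf_observer_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, objective = x$objective,
                 cv_error = min(x$cv$cv_error), n_trials = x$n_trials)
}

#' Fold and pool trials for visualization
#'
#' Reflects trials with retinal direction in (90, 270) about the horizontal
#' axis (both stimulus and report) and mirrors rightward-eye trials about
#' the vertical axis, so all conditions plot in a common leftward-pursuit
#' frame with directions in \[-90, 90\]. Pooling is for visualization only;
#' model fitting always uses the full range of motion.
#'
#' @param trials A trial tibble (Exp1 schema, see [generate_trials()]).
#' @return The folded tibble (columns `retinal_dir_deg`,
#'   `reported_direction`, `retinal_x`, `eye_x`, `eye_dir` adjusted).
#' @export
fold_and_pool <- function(trials) {
  out <- trials
  refl <- !is.na(out$retinal_dir_deg) &
    out$retinal_dir_deg > 90 & out$retinal_dir_deg < 270
  out$retinal_dir_deg[refl] <- wrap_deg(180 - out$retinal_dir_deg[refl])
  if ("reported_direction" %in% names(out)) {
    out$reported_direction[refl] <- wrap_deg(180 - out$reported_direction[refl])
  }
  if ("retinal_y" %in% names(out)) out$retinal_y[refl] <- -out$retinal_y[refl]

  mirr <- out$eye_dir > 0
  out$retinal_dir_deg[mirr] <- wrap_deg(-out$retinal_dir_deg[mirr])
  if ("reported_direction" %in% names(out)) {
    out$reported_direction[mirr] <- wrap_deg(-out$reported_direction[mirr])
  }
  if ("retinal_x" %in% names(out)) out$retinal_x[mirr] <- -out$retinal_x[mirr]
  if ("eye_x" %in% names(out)) out$eye_x[mirr] <- -out$eye_x[mirr]
  out$eye_dir[mirr] <- -1
  out
}
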