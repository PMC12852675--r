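#' Paired group statistics: Wilcoxon signed-rank with Hodges-Lehmann estimate
#'
#' The group-level analysis bundle used throughout: a two-sided Wilcoxon
#' signed-rank test on paired per-participant values, the normal-approximation
#' Z (signed by the direction of the effect), the Hodges-Lehmann location
#' estimate (median of Walsh averages of the paired differences) with its
#' distribution-free confidence interval, and the effect size
#' `r_W = Z / sqrt(n)`.
#'
#' @param x,y Paired numeric vectors (`y` omitted if `x` already holds
#'   differences). `n >= 5` pairs required.
#' @param conf_level Confidence level for the Hodges-Lehmann interval.
#' @return A tibble with columns `n`, `z`, `p`, `hl_estimate`, `conf.low`,
#'   `conf.high`, `effect_r`.
#' @examples
#' group_stats(c(1, 2, 3, 4, 5, 7), c(0, 1, 1, 2, 4, 5))
#' @export
group_stats <- function(x, y = NULL, conf_level = 0.95) {
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  n <- length(d)
  stopifnot(n >= 5)
  walsh <- outer(d, d, "+")[upper.tri(matrix(0, n, n), diag = TRUE)] / 2
  walsh <- sort(walsh)
  hl <- stats::median(walsh)
  M <- length(walsh)
  k <- stats::qsignrank((1 - conf_level) / 2, n)
  ci <- if (k >= 1) c(walsh[k], walsh[M - k + 1]) else range(walsh)

  dz <- d[d != 0]
  if (length(dz) == 0) {
    warning("all paired differences are zero: test statistic undefined")
    return(tibble::tibble(n = n, z = 0, p = 1, hl_estimate = hl,
                          conf.low = ci[1], conf.high = ci[2], effect_r = 0))
  }
  r <- rank(abs(dz))
  w_pos <- sum(r[dz > 0])
  nz <- length(dz)
  mu <- nz * (nz + 1) / 4
  ties <- table(r)
  sig <- sqrt(nz * (nz + 1) * (2 * nz + 1) / 24 -
                sum(ties^3 - ties) / 48)
  z <- (w_pos - mu) / sig
  p <- suppressWarnings(
    stats::wilcox.test(d, exact = (nz < 50 && !any(duplicated(abs(dz)))))$p.value
  )
  tibble::tibble(n = n, z = z, p = p, hl_estimate = hl,
                 conf.low = ci[1], conf.high = ci[2],
                 effect_r = z / sqrt(n))
}

#' Compare two tuning-shift (or other) distributions
#'
#' Rank-based comparison of two independent samples: two-sided
#' Mann-Whitney U, normal-approximation Z, and the difference of medians
#' `median(shifts_a) - median(shifts_b)`.
#'
#' @param shifts_a,shifts_b Independent numeric samples (n >= 3 each).
#' @return A tibble with `u`, `z`, `p`, `delta_median`, `n_a`, `n_b`.
#' @export
shift_distribution_compare <- function(shifts_a, shifts_b) {
  a <- shifts_a[is.finite(shifts_a)]
  b <- shifts_b[is.finite(shifts_b)]
  if (length(a) < 3 || length(b) < 3) {
    stop("need at least 3 observations per group", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  u <- unname(wt$statistic)
  na <- length(a); nb <- length(b)
  mu <- na * nb / 2
  allr <- rank(c(a, b))
  ties <- table(allr)
  sig <- sqrt(na * nb / 12 * ((na + nb + 1) -
                                sum(ties^3 - ties) / ((na + nb) * (na + nb - 1))))
  z <- (u - mu) / sig
  tibble::tibble(u = u, z = z, p = wt$p.value,
                 delta_median = stats::median(a) - stats::median(b),
                 n_a = na, n_b = nb)
}

probit_slope <- function(direction, response) {
  f <- suppressWarnings(
    stats::glm(response ~ direction, family = stats::binomial("probit"))
  )
  unname(f$coefficients[2])
}

#' Per-participant permutation test for slope differences between geometries
#'
#' Tests whether the magnitude of the depth psychometric slope differs
#' between the R+T and R viewing geometries for one participant. The
#' observed statistic is `|slope_RT| - |slope_R|`; the null distribution is
#' built by permuting geometry labels across trials and refitting. Inside
#' the permutation loop slopes are estimated by a probit GLM (the
#' lapse-free fast path of the psychometric family), which preserves the
#' ranking of slope magnitudes at a fraction of the cost of the full MLE.
#'
#' @param trials_r,trials_rt Tibbles with columns `direction` (deg) and
#'   `response` (0/1, far = 1), one per geometry.
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param seed Integer seed.
#' @return A tibble with `statistic` (observed `|slope_RT| - |slope_R|`),
#'   `p` (two-sided permutation p-value) and `n_perm`.
#' @export
participant_permutation_test <- function(trials_r, trials_rt, n_perm = 1000,
                                         seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed, participant_permutation_test(trials_r, trials_rt, n_perm)
    ))
  }
  if (n_perm < 100) warning("fewer than 100 permutations: p-value is coarse")
  x <- c(trials_r$direction, trials_rt$direction)
  y <- c(trials_r$response, trials_rt$response)
  is_rt <- rep(c(FALSE, TRUE), c(nrow(trials_r), nrow(trials_rt)))
  stat <- function(lab) {
    abs(probit_slope(x[lab], y[lab])) - abs(probit_slope(x[!lab], y[!lab]))
  }
  obs <- stat(is_rt)
  perms <- vapply(seq_len(n_perm), function(i) stat(sample(is_rt)), numeric(1))
  p <- (1 + sum(abs(perms) >= abs(obs))) / (n_perm + 1)
  tibble::tibble(statistic = obs, p = p, n_perm = n_perm)
}
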