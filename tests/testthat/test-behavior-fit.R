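make_reports <- function(trials, a_ret, a_eye) {
  # noiseless reports from a known weight pair
  wx <- (1 - a_ret) * trials$retinal_x + a_eye * trials$eye_x
  d <- direction_deg(wx, trials$retinal_y)
  d[is.na(d)] <- 0
  dplyr::mutate(trials, reported_direction = d)
}

test_that("noiseless observers are recovered at the weight extremes", {
  des <- tiny_exp1(geometries = "RT", reps = 3)
  base <- generate_trials(des, known_observer(), seed = 1)
  # identity observer: reports equal retinal direction -> both weights 0
  f0 <- fit_linear_observer(make_reports(base, 0, 0), bootstrap_n = 0, seed = 2)
  expect_lt(f0$a_ret + f0$a_eye, 0.05)
  # full coordinate-transformation observer -> (0, 1)
  f1 <- fit_linear_observer(make_reports(base, 0, 1), bootstrap_n = 0, seed = 3)
  expect_lt(abs(f1$a_ret - 0), 0.05)
  expect_lt(abs(f1$a_eye - 1), 0.05)
})

test_that("weights are recovered under report noise within tolerance", {
  des <- tiny_exp1(geometries = "RT", reps = 7)
  errs <- purrr::map_dfr(1:6, function(i) {
    obs <- known_observer(a_ret_rt = 0.8, a_eye_rt = 0.1, kappa = 20)
    trl <- dplyr::filter(generate_trials(des, obs, seed = 100 + i),
                         geometry == "RT")
    f <- fit_linear_observer(trl, bootstrap_n = 0, seed = 200 + i)
    tibble::tibble(e_ret = abs(f$a_ret - 0.8), e_eye = abs(f$a_eye - 0.1))
  })
  expect_lt(median(errs$e_ret), 0.1)
  expect_lt(median(errs$e_eye), 0.1)
})

test_that("degenerate designs and bounds are handled", {
  des <- tiny_exp1(reps = 2)
  trl <- generate_trials(des, known_observer(), seed = 4)
  one_dir <- dplyr::filter(trl, retinal_dir_deg == 0, geometry == "RT")
  expect_error(fit_linear_observer(one_dir, seed = 1), "underdetermined")
  f <- fit_linear_observer(dplyr::filter(trl, geometry == "RT"),
                           bootstrap_n = 20, seed = 5)
  expect_true(f$a_ret >= 0 && f$a_ret <= 1)
  expect_true(f$a_eye >= 0 && f$a_eye <= 1)
  td <- tidy(f)
  expect_equal(td$term, c("a_ret", "a_eye"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_equal(glance(f)$n_trials, nrow(dplyr::filter(trl, geometry == "RT")))
})

test_that("psychometric function has the stated analytic properties", {
  C <- qnorm(0.95) - qnorm(0.05)
  expect_equal(C, 3.289707, tolerance = 1e-6)
  # midpoint property
  expect_equal(psychometric_prob(10, 10, 30, 0.04, 0.02),
               0.02 + (1 - 0.04 - 0.02) / 2)
  # limits respect guess and lapse
  expect_equal(psychometric_prob(1e6, 10, 30, 0.04, 0.02), 1 - 0.04)
  expect_equal(psychometric_prob(-1e6, 10, 30, 0.04, 0.02), 0.02)
})

test_that("psychometric fitting recovers generating parameters", {
  x <- rep(seq(-90, 90, 15), each = 20)
  fits <- purrr::map_dfr(1:20, function(i) {
    withr::with_seed(300 + i, {
      y <- rbinom(length(x), 1, psychometric_prob(x, 10, 30, 0.02, 0.02))
      f <- fit_psychometric(x, y)
      tibble::tibble(m = f$m, w = f$w, slope = f$slope)
    })
  })
  expect_lt(abs(median(fits$m) - 10), 5)
  expect_lt(abs(median(fits$w) - 30) / 30, 0.2)
  expect_true(all(fits$slope > 0))
})

test_that("psychometric slope is antisymmetric under eye-sign flip", {
  des <- tiny_exp2(reps = 20)
  trl <- generate_trials(des, synthetic_observer(), seed = 6)
  rt <- dplyr::filter(trl, geometry == "RT")
  fl <- fit_psychometric(rt$retinal_dir_deg[rt$eye_dir == -1],
                         rt$depth_report[rt$eye_dir == -1])
  fr <- fit_psychometric(rt$retinal_dir_deg[rt$eye_dir == 1],
                         rt$depth_report[rt$eye_dir == 1])
  expect_true(fl$slope * fr$slope < 0)
  expect_lt(abs(abs(fl$slope) - abs(fr$slope)) / abs(fr$slope), 0.6)
})

test_that("boundary responses are flagged with zero slope", {
  x <- rep(seq(-90, 90, 15), each = 5)
  expect_warning(f <- fit_psychometric(x, rep(1, length(x))), "boundary")
  expect_equal(f$slope, 0)
  expect_true(f$boundary)
  expect_error(fit_psychometric(c(1, 1, 2, 2), c(0, 1, 0, 1)), "3 stimulus levels")
})

test_that("pursuit gain recovers known gains and ignores position offsets", {
  for (g in c(0.7, 1.0)) {
    tr <- generate_eye_traces(5, g_pursuit = g, noise_sd = 0, seed = 7)
    expect_equal(compute_pursuit_gain(tr)$gain, g, tolerance = 1e-3)
  }
  tr <- generate_eye_traces(5, g_pursuit = 0.8, noise_sd = 0, seed = 8)
  shifted <- dplyr::mutate(tr, gaze_x_deg = gaze_x_deg + 3.7)
  expect_equal(compute_pursuit_gain(shifted)$gain,
               compute_pursuit_gain(tr)$gain, tolerance = 1e-12)
  # saccade injection leaves the estimate nearly unchanged
  sac <- generate_eye_traces(20, g_pursuit = 0.8, noise_sd = 0.05,
                             saccade_rate = 2, seed = 9)
  expect_equal(compute_pursuit_gain(sac)$gain, 0.8, tolerance = 0.03)
  expect_error(compute_pursuit_gain(
    generate_eye_traces(2, 0.8, 0, sample_rate = 100, seed = 1)
  ), "250")
})

test_that("fixation check tolerates brief excursions only", {
  t_s <- seq(0, 1, by = 0.001)
  base <- tibble::tibble(t_s = t_s, gaze_x_deg = 0, gaze_y_deg = 0,
                         target_x_deg = 0)
  expect_true(fixation_check(base))
  exc <- base
  exc$gaze_x_deg[t_s > 0.4 & t_s <= 0.55] <- 8   # 150 ms at 8 deg
  expect_false(fixation_check(exc, window_half_width = 5, max_violation = 100))
  brief <- base
  brief$gaze_x_deg[t_s > 0.4 & t_s <= 0.45] <- 8  # 50 ms
  expect_true(fixation_check(brief, window_half_width = 5, max_violation = 100))
})

test_that("folding reflects and mirrors trials into the common frame", {
  tr <- tibble::tibble(
    retinal_dir_deg = c(120, 30), reported_direction = c(110, 30),
    retinal_x = direction_to_velocity(c(120, 30))[, 1],
    retinal_y = direction_to_velocity(c(120, 30))[, 2],
    eye_x = c(-5, 5), eye_dir = c(-1, 1)
  )
  fold <- fold_and_pool(tr)
  expect_equal(fold$retinal_dir_deg, c(60, -30))
  expect_equal(fold$reported_direction, c(70, -30))
  expect_true(all(fold$eye_dir == -1))
  # idempotent on the folded set
  expect_equal(fold_and_pool(fold), fold)
})

test_that("paired group statistics match the reference implementation", {
  withr::with_seed(10, {
    x <- rnorm(9, 0.4); y <- rnorm(9)
    gs <- group_stats(x, y)
    wt <- wilcox.test(x, y, paired = TRUE, conf.int = TRUE)
    expect_equal(gs$p, wt$p.value)
    expect_equal(gs$hl_estimate, unname(wt$estimate))
    expect_equal(c(gs$conf.low, gs$conf.high), wt$conf.int,
                 ignore_attr = TRUE)
  })
  # constant difference: HL estimate is that constant
  gs <- group_stats(c(4, 5, 6, 7, 8, 9), c(1, 2, 3, 4, 5, 6))
  expect_equal(gs$hl_estimate, 3)
  expect_warning(gs0 <- group_stats(rep(1, 6), rep(1, 6)), "zero")
  expect_equal(gs0$p, 1)
  expect_equal(gs0$hl_estimate, 0)
})

test_that("tuning-shift distribution comparison behaves at the null and under shift", {
  expect_equal(shift_distribution_compare(c(1, 2, 3), c(2, 3, 4))$delta_median, -1)
  withr::with_seed(11, {
    p_null <- replicate(40, {
      shift_distribution_compare(rnorm(20), rnorm(20))$p
    })
    expect_gt(mean(p_null > 0.05), 0.8)     # null calibration
    p_shift <- replicate(20, {
      shift_distribution_compare(rnorm(64, 1), rnorm(64))$p
    })
    expect_gt(mean(p_shift < 0.05), 0.9)    # power at delta = 1 SD, n = 64
  })
  expect_error(shift_distribution_compare(1:2, 1:5), "3 observations")
})

test_that("participant permutation test is calibrated and powered", {
  des <- tiny_exp2(reps = 10)
  trl <- generate_trials(des, synthetic_observer(), seed = 12)
  resp <- function(d) dplyr::transmute(d, direction = retinal_dir_deg,
                                       response = as.integer(depth_report == "far"))
  r_tr <- resp(dplyr::filter(trl, geometry == "R", eye_dir == 1))
  rt_tr <- resp(dplyr::filter(trl, geometry == "RT", eye_dir == 1))
  # strongly separated conditions: significant
  res <- participant_permutation_test(r_tr, rt_tr, n_perm = 199, seed = 13)
  expect_lt(res$p, 0.05)
  expect_gt(res$statistic, 0)
  # same condition against itself: null p is uniform, so its median over
  # replicate splits stays away from the tail
  half <- nrow(rt_tr) %/% 2
  p0 <- sapply(1:5, function(i) {
    idx <- withr::with_seed(50 + i, sample(nrow(rt_tr)))
    participant_permutation_test(rt_tr[idx[1:half], ],
                                 rt_tr[idx[(half + 1):nrow(rt_tr)], ],
                                 n_perm = 100, seed = 60 + i)$p
  })
  expect_gt(median(p0), 0.1)
  expect_warning(participant_permutation_test(r_tr, rt_tr, n_perm = 50,
                                              seed = 15), "100")
})
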