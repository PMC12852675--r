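test_that("world-motion formula reproduces its closed-form special cases", {
  # pure rotation: coordinate transformation, depth plays no role
  expect_equal(object_world_motion(c(3, 4), omega_eye = -3, dprime = 0.7,
                                   pprime = 0), c(0, 4))
  # fixation-pivot geometry, stationary object with d' = ret/eye
  expect_equal(object_world_motion(c(2, 0), omega_eye = 4, dprime = 0.5,
                                   pprime = 1), c(0, 0))
  # direct substitution: coefficient 1 - (1+1)*0.5 = 0
  expect_equal(object_world_motion(c(2, 1), omega_eye = 4, dprime = 1,
                                   pprime = 0.5), c(2, 1))
  expect_error(object_world_motion(c(NA, 1), 1, 0, 0), "finite")
})

test_that("reduction identities hold on random draws and round trips invert", {
  withr::with_seed(42, {
    n <- 1000
    ret <- cbind(runif(n, -10, 10), runif(n, -10, 10))
    eye <- runif(n, -10, 10)
    dp <- runif(n, -1, 1)
    # p' = 0 reduces to ret + eye regardless of depth
    w0 <- object_world_motion(ret, eye, dp, 0)
    expect_equal(w0[, 1], ret[, 1] + eye)
    expect_equal(w0[, 2], ret[, 2])
    # p' = 1, stationary object: parallax ratio inverts exactly
    ret_stat <- stationary_dot_flow(dp, 1, eye)
    expect_equal(depth_from_parallax(ret_stat, 0, eye), dp)
    # full round trip at random pivots: forward Eq then inverse
    pp <- runif(n, 0, 1)
    ret_x <- 5 - (1 - (1 + dp) * pp) * eye   # retinal x of object with world vx = 5
    w <- object_world_motion(cbind(ret_x, 0), eye, dp, pp)
    expect_equal(w[, 1], rep(5, n))
  })
})

test_that("depth from parallax handles its special and error cases", {
  expect_equal(depth_from_parallax(2, 0, 4), 0.5)
  expect_equal(depth_from_parallax(2, 2, 4), 0)
  expect_equal(depth_from_parallax(-3, 1, 8), -0.5)
  expect_error(depth_from_parallax(2, 0, 0), "indeterminate")
})

test_that("stationary-dot flow is depth-invariant at p'=0 and signed at p'=1", {
  expect_equal(stationary_dot_flow(c(-1, 0, 2.5), 0, 5), rep(-5, 3))
  expect_equal(stationary_dot_flow(-0.5, 1, 5), -2.5)
  expect_equal(stationary_dot_flow(0.5, 1, 5), 2.5)
  expect_equal(stationary_dot_flow(0.25, 0.5, 8), -3)
})

test_that("gaussian velocity profile integrates exactly and is symmetric", {
  vp <- gaussian_velocity_profile(2.67, 1, 60)
  expect_equal(sum(vp$velocity) / 60, 2.67, tolerance = 1e-12)
  expect_equal(mean(vp$velocity), 2.67)                     # mean = D / T
  # discrete peak sits half a sample off the profile center at 60 Hz
  expect_equal(max(vp$velocity), 2.67 * 6 / (0.9973002 * sqrt(2 * pi)),
               tolerance = 2e-3)                            # ~6.41 deg/s
  expect_equal(vp$velocity, rev(vp$velocity))               # v(t) = v(T - t)
  expect_true(all(gaussian_velocity_profile(0, 1, 60)$velocity == 0))
  expect_error(gaussian_velocity_profile(1, -1, 60), "positive")
  # displacement stays exact across sample rates
  for (fs in c(60, 250, 1000)) {
    expect_equal(sum(gaussian_velocity_profile(3, 1, fs)$velocity) / fs, 3)
  }
})

test_that("display field of view matches the experimental setup", {
  fov <- display_field_of_view()
  expect_equal(unname(fov["horizontal"]), 85.4, tolerance = 0.01)
  expect_equal(unname(fov["vertical"]), 54.9, tolerance = 0.01)
})

test_that("direction conventions are up-zero clockwise-positive", {
  expect_equal(direction_deg(0, 1), 0)    # up
  expect_equal(direction_deg(1, 0), 90)   # right
  expect_equal(direction_deg(0, -1), 180) # down
  expect_equal(direction_deg(-1, 0), -90) # left
  expect_true(is.na(direction_deg(0, 0)))
  v <- direction_to_velocity(c(0, 90, 45), 2)
  expect_equal(v[, "vx"], c(0, 2, sqrt(2)), tolerance = 1e-12)
  expect_equal(v[, "vy"], c(2, 0, sqrt(2)), tolerance = 1e-12)
  expect_equal(wrap_deg(c(190, -190, 180, 540)), c(-170, 170, 180, 180))
})

test_that("viewing geometry decomposes eye velocity by the pivot", {
  g <- viewing_geometry(pprime = 0.5, omega_eye = 6, viewing_distance = 57)
  expect_equal(g$pivot, 28.5)
  expect_equal(g$omega_eye_translation + g$omega_eye_pursuit, g$omega_eye)
  expect_equal(viewing_geometry(geometry = "R")$pprime, 0)
  expect_equal(viewing_geometry(geometry = "RT")$pprime, 1)
  # pure rotation has no translation-compensating component
  expect_equal(viewing_geometry(geometry = "R", omega_eye = 5)$omega_eye_translation, 0)
})
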