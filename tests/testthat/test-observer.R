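test_that("slip correction redistributes unexecuted pursuit onto the retina", {
  tr <- tibble::tibble(retinal_x = 0, retinal_y = 2, eye_x = 6,
                       eye_condition = "Pursuit")
  half <- slip_correct(tr, 0.5)
  expect_equal(half$eye_x, 3)
  expect_equal(half$retinal_x, 3)
  expect_equal(half$retinal_y, 2)

  ident <- slip_correct(tr, 1)
  expect_equal(ident$eye_x, 6)
  expect_equal(ident$retinal_x, 0)

  none <- slip_correct(tr, 0)
  expect_equal(none$eye_x, 0)
  expect_equal(none$retinal_x, 6)   # all intended motion lands on the retina

  # fixation trials are untouched (simulated eye movement has no slip)
  fx <- slip_correct(dplyr::mutate(tr, eye_condition = "Fixation"), 0.5)
  expect_equal(fx$eye_x, 6)
  expect_equal(fx$retinal_x, 0)
  # the sum retinal + eye is conserved by the correction
  expect_equal(half$retinal_x + half$eye_x, tr$retinal_x + tr$eye_x)
})

test_that("predicted world motion follows the weight model", {
  # full parallax attribution: vertical percept
  p <- predict_world_motion(2, 2, 0, observer_params(a_ret = 1, a_eye = 0))
  expect_equal(c(p$world_x, p$world_y), c(0, 2))
  expect_equal(p$direction, 0)
  # full coordinate transformation
  p <- predict_world_motion(0, 2, 2, observer_params(a_ret = 0, a_eye = 1))
  expect_equal(c(p$world_x, p$world_y), c(2, 2))
  expect_equal(p$direction, 45)
  # cancellation: 0.5*4 + 0.25*(-8) = 0
  p <- predict_world_motion(4, 1, -8, observer_params(a_ret = 0.5, a_eye = 0.25))
  expect_equal(c(p$world_x, p$world_y), c(0, 1))
  # zero predicted vector: direction reported missing
  p <- predict_world_motion(0, 0, 0, observer_params(a_ret = 0, a_eye = 0))
  expect_true(is.na(p$direction))
  # identity on retinal motion at zero weights (control condition)
  withr::with_seed(1, {
    rx <- runif(20, -5, 5); ry <- runif(20, -5, 5); ex <- runif(20, -8, 8)
    p <- predict_world_motion(rx, ry, ex, observer_params(a_ret = 0, a_eye = 0))
    expect_equal(p$world_x, rx)
    expect_equal(p$world_y, ry)
  })
})

test_that("weights derived from gains and pivot match the gain form", {
  withr::with_seed(2, {
    for (i in 1:20) {
      gr <- runif(1); ge <- runif(1); pp <- runif(1)
      rx <- runif(1, -5, 5); ry <- runif(1, -5, 5); ex <- runif(1, -8, 8)
      par <- observer_params(g_ret = gr, g_eye = ge, pprime = pp)
      expect_equal(par$a_ret, gr * pp)
      expect_equal(par$a_eye, (1 - pp) * ge)
      # gain form of the world-motion equation computed directly
      direct <- (1 - gr * pp) * rx + (1 - pp) * ge * ex
      expect_equal(predict_world_motion(rx, ry, ex, par)$world_x, direct)
    }
  })
})

test_that("predicted depth is the gained parallax ratio with antisymmetry", {
  par <- observer_params(g_ret = 1, g_eye = 1, pprime = 1)
  expect_equal(predict_depth(2, 4, par), 0.5)
  expect_equal(predict_depth(0, 4, par), 0)
  expect_equal(predict_depth(-4, 4, observer_params(g_ret = 0.5, g_eye = 1,
                                                    pprime = 1)), -0.5)
  expect_true(is.na(predict_depth(2, 0, par)))   # ambiguous without eye motion
  withr::with_seed(3, {
    rx <- runif(30, -5, 5); ex <- runif(30, 0.5, 8)
    d <- predict_depth(rx, ex, par)
    expect_equal(predict_depth(-rx, ex, par), -d)
    expect_equal(predict_depth(rx, -ex, par), -d)
    expect_equal(predict_depth(-rx, -ex, par), d)
  })
})

test_that("prediction curves show the geometry-specific biases", {
  dirs <- seq(-80, 80, by = 10)
  # R geometry, full gain: strong horizontal bias toward the eye direction
  cr <- prediction_curves(observer_params(g_ret = 1, g_eye = 1, pprime = 0),
                          geometry = "R", eye_speed = 8, retinal_speed = 2,
                          directions = dirs)
  left <- cr[cr$eye_dir == -1, ]
  expect_true(all(left$direction_out < left$direction_in))
  expect_true(all(abs(left$direction_out + 90) < 45))  # saturating near -90
  expect_true(all(is.na(cr$depth_hat)))                # depth ambiguous in R
  # R+T, full gain: all horizontal motion explained away, reports vertical
  crt <- prediction_curves(observer_params(g_ret = 1, g_eye = 1, pprime = 1),
                           geometry = "RT", directions = dirs)
  expect_true(all(abs(crt$direction_out) < 1e-8))
  # depth-sign curve inverts when eye direction flips
  pf <- tidyr::pivot_wider(crt[, c("eye_dir", "direction_in", "p_far")],
                           names_from = "eye_dir", values_from = "p_far")
  expect_equal(pf$`-1`, 1 - pf$`1`, tolerance = 1e-10)
  # control condition: identity on direction
  cn <- prediction_curves(observer_params(a_ret = 0, a_eye = 0),
                          geometry = "none", directions = dirs)
  expect_equal(cn$direction_out, cn$direction_in)
})
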