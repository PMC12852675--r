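test_that("task trials encode the two geometries correctly", {
  net <- rnn_init(seed = 1)
  # R geometry, noise off: both background channels carry identical flow
  tr <- make_rnn_trial("R", omega_eye = 4, omega_obj = 1, noise_sd = 0,
                       rnn = net, seed = 2)
  stim <- which(!tr$mask & seq_along(tr$mask) > net$n_pre)
  expect_equal(unique(tr$input[stim, 2]), unique(tr$input[stim, 3]))
  expect_equal(unique(tr$input[stim, 2]), -4)
  expect_equal(tr$input[stim[1], 1], 1 - 4)    # retinal = obj - eye
  expect_equal(tr$target, c(1, 0))
  # RT geometry: background channels are opposite and half the eye speed
  tr <- make_rnn_trial("RT", omega_eye = 4, omega_obj = 0, dprime = 0.5,
                       noise_sd = 0, rnn = net, seed = 3)
  expect_equal(unique(tr$input[stim, 2]), -2)
  expect_equal(unique(tr$input[stim, 3]), 2)
  expect_equal(tr$input[stim[1], 1], 2)        # obj + d' * eye
  expect_equal(tr$target, c(0, 0.5))
  # pre/stim/post epochs: 500/1000/500 ms, mask covers the last 500 ms only
  expect_equal(c(net$n_pre, net$n_stim, net$n_post), c(50, 100, 50))
  expect_equal(sum(tr$mask), net$n_post)
  expect_true(all(which(tr$mask) > net$n_pre + net$n_stim))
})

test_that("single Euler steps match hand computation", {
  net <- rnn_init(n_units = 2, seed = 4)
  # zero weights: geometric decay by (1 - dt/tau) = 0.9
  net0 <- net
  net0$W_in[] <- 0; net0$W_rec[] <- 0; net0$W_out[] <- 0
  net0$b_rec[] <- 0; net0$b_out[] <- 0
  s <- c(2, -1)
  out <- rnn_step(s, c(0, 0, 0), net0)
  expect_equal(out$state, 0.9 * s)
  expect_equal(out$output, c(0, 0))
  # W_rec = 0, constant input: state converges to W_in u + b_rec
  netc <- net
  netc$W_rec[] <- 0
  u <- c(1, -2, 0.5)
  x <- rep(0, 2)
  for (i in 1:400) x <- rnn_step(x, u, netc)$state
  expect_equal(x, drop(netc$W_in %*% u) + netc$b_rec, tolerance = 1e-8)
  # one generic step against explicit arithmetic
  x0 <- c(0.3, -0.2)
  ref <- x0 + (net$dt / net$tau) *
    (-x0 + net$W_rec %*% tanh(x0) + net$b_rec + net$W_in %*% u)
  st <- rnn_step(x0, u, net)
  expect_equal(st$state, drop(ref))
  expect_equal(st$output, drop(net$W_out %*% tanh(ref)) + net$b_out)
  expect_error(rnn_step(c(NaN, 1), u, net), "diverged")
})

test_that("compiled forward pass matches the scripted single-step dynamics", {
  net <- rnn_init(n_units = 8, seed = 5)
  T_ <- 30
  withr::with_seed(6, U <- array(rnorm(3 * 2 * T_), c(3, 2, T_)))
  Z <- pivotflow:::rnn_forward_cpp(net$W_in, net$W_rec, net$W_out,
                                   net$b_rec, net$b_out, U, net$tau, net$dt)
  for (b in 1:2) {
    x <- rep(0, 8)
    for (t in 1:T_) {
      st <- rnn_step(x, U[, b, t], net)
      x <- st$state
      expect_equal(Z[, b, t], st$output, tolerance = 1e-12)
    }
  }
})

test_that("Euler integration approaches the leak fixed point as dt shrinks", {
  errs <- sapply(c(0.02, 0.01, 0.005), function(dt) {
    net <- rnn_init(n_units = 4, dt = dt, seed = 7)
    net$W_rec <- 0.3 * net$W_rec
    u <- c(0.5, -0.3, 0.2)
    x <- rep(0, 4)
    for (i in seq_len(round(3 / dt))) x <- rnn_step(x, u, net)$state
    # fixed point of tau dx/dt = 0: x* = W_rec tanh(x*) + b + W_in u
    max(abs(-x + drop(net$W_rec %*% tanh(x)) + net$b_rec +
              drop(net$W_in %*% u)))
  })
  expect_true(all(errs < 1e-6))
})

test_that("tuning-shift metric is calibrated on constructed maps", {
  ridge <- ridge_map(sign = +1)        # activation a function of v_ret + v_eye
  expect_gt(tuning_shift(ridge), 90)
  expect_equal(tuning_shift(ridge_map(sign = -1)), -tuning_shift(ridge))
  expect_lt(abs(tuning_shift(separable_map())), 1e-8)
  # invariant to multiplicative rescaling; bounded for arbitrary maps
  expect_equal(tuning_shift(ridge * 37.5), tuning_shift(ridge))
  withr::with_seed(8, {
    for (i in 1:20) {
      m <- matrix(rnorm(21^2), 21)
      s <- suppressWarnings(tuning_shift(m))
      if (is.finite(s)) expect_true(s >= -100 && s <= 100)
    }
  })
  expect_warning(tuning_shift(matrix(1, 21, 21)), "flat")
})

test_that("short training reduces the loss and is reproducible", {
  net1 <- rnn_train(epochs = 150, batch = 32, seed = 9)
  expect_lt(mean(tail(net1$loss_history, 10)),
            0.5 * mean(head(net1$loss_history, 10)))
  net2 <- rnn_train(epochs = 150, batch = 32, seed = 9)
  expect_equal(net1$loss_history, net2$loss_history)
  expect_equal(net1$W_rec, net2$W_rec)
  # probes run on any network and produce the full battery
  pr <- probe_psychometrics(net1)
  expect_equal(nrow(pr), 2 * 2 * 16)
  expect_true(all(is.finite(pr$motion_out)))
  maps <- rnn_tuning_maps(net1, "R")
  expect_equal(dim(maps), c(21, 21, 64))
})
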