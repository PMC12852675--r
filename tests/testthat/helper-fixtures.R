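# small designs and canned observers shared across test files

tiny_exp1 <- function(geometries = "RT", reps = 7) {
  experiment_design("Exp1", geometries = geometries, reps = reps)
}

tiny_exp2 <- function(reps = 20) {
  experiment_design("Exp2", reps = reps)
}

# an observer with known weights in a single geometry, low noise
known_observer <- function(a_ret_rt = 0.8, a_eye_rt = 0.1, kappa = 20,
                           lapse = 0) {
  synthetic_observer(
    a_ret = c(R = 0, RT = a_ret_rt, none = 0),
    a_eye = c(R = 0.4, RT = a_eye_rt, none = 0),
    report_kappa = kappa, lapse = lapse
  )
}

# deterministic ridge / separable maps for the tuning-shift metric
ridge_map <- function(grid = -10:10, sign = +1, width = 8) {
  outer(grid, grid, function(r, e) exp(-(r + sign * e)^2 / width))
}

separable_map <- function(grid = -10:10) {
  outer(exp(-grid^2 / 20), exp(-grid^2 / 10))
}
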