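Package: pivotflow
Title: Viewing-Geometry Models of Object Motion and Depth Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models and analysis tools for perception of object motion and
    depth during combined eye rotation and translation. Implements a
    geometric forward model linking retinal velocity, eye velocity, depth
    and the rotation pivot of the optic flow field; a pinhole-projection
    optic-flow simulator; a gain/weight observer model of perceived motion
    direction and motion-parallax depth with circular-error fitting;
    cumulative-Gaussian psychometric fitting; smooth-pursuit gain
    estimation from eye traces; nonparametric group statistics; a
    task-trained continuous-time recurrent network with a Fourier
    tuning-shift metric; and a parametric joint retinal-by-eye velocity
    tuning model for simulated neurons fit by Poisson maximum likelihood.
    Synthetic-data generators emulate the psychophysical designs so every
    pipeline stage runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
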