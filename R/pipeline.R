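#' @keywords internal
#' @importFrom rlang .data
#' @importFrom Rcpp sourceCpp
#' @useDynLib pivotflow, .registration = TRUE
"_PACKAGE"

pipeline_defaults <- function() {
  list(
    seed = 1L,
    stages = c("synth_behavior", "fit_behavior"),
    synth_behavior = list(experiment = "Exp1", n_observers = 3, reps = 7),
    fit_behavior = list(bootstrap_n = 0, cv_folds = 5),
    fit_psychometric = list(bootstrap_n = 0, reps = 20),
    pursuit_gain = list(n_trials = 10, g_pursuit = 0.8, noise_sd = 0.05,
                        saccade_rate = 0),
    flow_sim = list(pprime = 1, omega_eye = 5, n_dots = 200),
    rnn = list(epochs = 500, batch = 64, lr = 1e-3),
    mt = list(n_neurons = 2, trials_per_cell = 10, w = 0.5, n_starts = 4)
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), rejects unknown keys, fills
#' defaults, and derives a logged sub-seed for every randomized stage from
#' the global seed.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated config list of class `pf_config` with a `sub_seeds`
#'   entry.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- utils::modifyList(defaults, config)
  bad <- setdiff(out$stages, setdiff(names(defaults), c("seed", "stages")))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stage_names <- setdiff(names(defaults), c("seed", "stages"))
  out$sub_seeds <- stats::setNames(
    (as.integer(out$seed) * 101L + seq_along(stage_names) * 7919L) %% .Machine$integer.max,
    stage_names
  )
  class(out) <- "pf_config"
  out
}

run_stage <- function(stage, config, out_dir) {
  seed <- config$sub_seeds[[stage]]
  files <- character(0)
  if (stage == "synth_behavior") {
    p <- config$synth_behavior
    des <- experiment_design(p$experiment, reps = p$reps)
    trials <- generate_cohort(p$n_observers, des, seed = seed)
    files <- file.path(out_dir, "trials.csv")
    utils::write.csv(trials, files, row.names = FALSE)
  } else if (stage == "fit_behavior") {
    p <- config$fit_behavior
    trials <- utils::read.csv(file.path(out_dir, "trials.csv"))
    fits <- trials |>
      dplyr::filter(.data$geometry != "none") |>
      dplyr::group_by(.data$participant_id, .data$geometry,
                      .data$eye_condition) |>
      dplyr::group_modify(~ tidy(fit_linear_observer(
        .x, cv_folds = p$cv_folds, bootstrap_n = p$bootstrap_n, seed = seed
      ))) |>
      dplyr::ungroup()
    files <- file.path(out_dir, "observer_fits.csv")
    utils::write.csv(fits, files, row.names = FALSE)
  } else if (stage == "fit_psychometric") {
    p <- config$fit_psychometric
    des <- experiment_design("Exp2", reps = p$reps)
    trials <- generate_trials(des, seed = seed)
    fits <- trials |>
      dplyr::filter(.data$geometry == "RT") |>
      dplyr::group_by(.data$eye_dir) |>
      dplyr::group_modify(~ tidy(fit_psychometric(
        .x$retinal_dir_deg, .x$depth_report, bootstrap_n = p$bootstrap_n,
        seed = seed
      ))) |>
      dplyr::ungroup()
    files <- file.path(out_dir, "psychometric_fits.csv")
    utils::write.csv(fits, files, row.names = FALSE)
  } else if (stage == "pursuit_gain") {
    p <- config$pursuit_gain
    traces <- generate_eye_traces(p$n_trials, p$g_pursuit, p$noise_sd,
                                  p$saccade_rate, seed = seed)
    g <- compute_pursuit_gain(traces)
    files <- file.path(out_dir, "pursuit_gain.json")
    jsonlite::write_json(list(gain = g$gain, n_traces = g$n_traces),
                         files, auto_unbox = TRUE, digits = NA)
  } else if (stage == "flow_sim") {
    p <- config$flow_sim
    geom <- viewing_geometry(pprime = p$pprime, omega_eye = p$omega_eye)
    fld <- simulate_flow_field(geom, n_dots = p$n_dots, seed = seed)
    files <- file.path(out_dir, "flow_field.csv")
    utils::write.csv(fld, files, row.names = FALSE)
  } else if (stage == "rnn") {
    p <- config$rnn
    net <- rnn_train(epochs = p$epochs, batch = p$batch, lr = p$lr,
                     seed = seed)
    probes <- probe_psychometrics(net)
    shifts <- tibble::tibble(
      unit = seq_len(net$n_units),
      shift_R = tuning_shift_distribution(net, "R"),
      shift_RT = tuning_shift_distribution(net, "RT")
    )
    files <- c(file.path(out_dir, "rnn_probes.csv"),
               file.path(out_dir, "rnn_shifts.csv"),
               file.path(out_dir, "rnn_checkpoint.json"))
    utils::write.csv(probes, files[1], row.names = FALSE)
    utils::write.csv(shifts, files[2], row.names = FALSE)
    jsonlite::write_json(
      list(W_in = net$W_in, W_rec = net$W_rec, W_out = net$W_out,
           b_rec = net$b_rec, b_out = net$b_out, tau = net$tau, dt = net$dt,
           seed = seed, epochs = p$epochs),
      files[3], digits = NA)
  } else if (stage == "mt") {
    p <- config$mt
    pars <- replicate(p$n_neurons, mt_params(w = p$w), simplify = FALSE)
    counts <- generate_mt_neurons(pars, trials_per_cell = p$trials_per_cell,
                                  seed = seed)
    fits <- counts |>
      dplyr::group_by(.data$neuron_id) |>
      dplyr::group_modify(~ tidy(fit_mt_poisson(.x, n_starts = p$n_starts,
                                                seed = seed))) |>
      dplyr::ungroup()
    files <- file.path(out_dir, "mt_fits.csv")
    utils::write.csv(fits, files, row.names = FALSE)
  }
  files
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, writing each stage's outputs to
#' `out_dir` plus a manifest with the config, derived sub-seeds, and MD5
#' digests of every file produced (re-running an identical config
#' reproduces identical digests for deterministic stages). A stage failure
#' aborts with the failing stage named; outputs of earlier stages are
#' preserved.
#'
#' @param config A [pipeline_config()], list, or YAML path.
#' @param out_dir Output directory (created if missing).
#' @return The manifest (list), invisibly written to
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("pivotflow_run")) {
  config <- if (inherits(config, "pf_config")) config else pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_files <- character(0)
  for (stage in config$stages) {
    res <- tryCatch(run_stage(stage, config, out_dir), error = function(e) e)
    if (inherits(res, "error")) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(res)), call. = FALSE)
    }
    all_files <- c(all_files, res)
  }
  digests <- if (length(all_files)) {
    stats::setNames(unname(tools::md5sum(all_files)), basename(all_files))
  } else NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("pivotflow")),
    seed = config$seed,
    sub_seeds = as.list(config$sub_seeds[config$stages]),
    stages = config$stages,
    file_digests = as.list(digests),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Validate a trial-table CSV
#'
#' Schema, range and invariant checks on a trial table in the package's
#' exchange format: required columns present, directions within the design
#' ranges, velocities finite, exactly one response column populated per
#' row.
#'
#' @param x Path to a CSV file, or a data frame.
#' @return A tibble of problems (`row`, `problem`); zero rows when valid.
#' @export
validate_trial_table <- function(x) {
  d <- if (is.character(x)) utils::read.csv(x) else as.data.frame(x)
  problems <- tibble::tibble(row = integer(0), problem = character(0))
  add <- function(rows, msg) {
    if (length(rows)) {
      problems <<- dplyr::bind_rows(problems,
                                    tibble::tibble(row = rows, problem = msg))
    }
  }
  required <- c("participant_id", "experiment", "geometry", "eye_condition",
                "eye_dir", "retinal_dir_deg", "reported_direction",
                "depth_report", "valid")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    return(tibble::tibble(row = NA_integer_,
                          problem = paste("missing columns:",
                                          paste(missing_cols, collapse = ", "))))
  }
  add(which(!d$geometry %in% c("R", "RT", "none")), "unknown geometry")
  add(which(!d$eye_condition %in% c("Pursuit", "Fixation")),
      "unknown eye condition")
  add(which(!d$eye_dir %in% c(-1, 1)), "eye_dir must be -1 or 1")
  add(which(d$retinal_dir_deg < -90 | d$retinal_dir_deg > 270),
      "retinal direction outside [-90, 270]")
  has_dir <- !is.na(d$reported_direction)
  has_depth <- !is.na(d$depth_report) & d$depth_report != ""
  add(which(has_dir & has_depth), "both response columns populated")
  add(which(!has_dir & !has_depth), "no response recorded")
  add(which(has_depth & !d$depth_report %in% c("near", "far", "")),
      "depth_report must be 'near' or 'far'")
  problems
}
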