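#' Trajectory CSV input/output
#'
#' The canonical exchange format for simulated trajectories: a header row and
#' the columns \code{time_ms, V_mV, h, w, I_applied}, one row per integration
#' sample, serialized at full double precision (17 significant digits).
#'
#' @param traj a [simulate_tc()] trajectory.
#' @param path CSV file path.
#' @return \code{load_trajectory}: a \code{tc_trajectory}.
#' @export
save_trajectory <- function(traj, path) {
  cols <- c("time_ms", "V_mV", "h", "w", "I_applied")
  stopifnot(all(cols %in% names(traj)))
  write_csv17(as.data.frame(traj)[cols], path)
  invisible(path)
}

#' @rdname save_trajectory
#' @export
load_trajectory <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_ms", "V_mV", "h", "w", "I_applied")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("malformed trajectory CSV ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  if (nrow(df) < 2) stop("trajectory CSV has fewer than 2 rows")
  dts <- diff(df$time_ms)
  if (any(dts <= 0) || diff(range(dts)) > 1e-9 * max(dts)) {
    stop("trajectory times must be uniformly increasing")
  }
  structure(df, dt = dts[1], class = c("tc_trajectory", "data.frame"))
}

#' Estimate-trace CSV + JSON sidecar input/output
#'
#' Traces are written as CSV with columns \code{time_ms, Iext_hat, V_hat,
#' h_hat, w_hat, innovation}; a JSON sidecar (same path with
#' \code{.json} appended) stores the filter configuration scalars.
#'
#' @param trace an [ukf_estimate()] trace.
#' @param path CSV file path.
#' @return \code{load_trace}: data.frame of the trace columns with the
#'   sidecar parsed into attribute \code{sidecar}.
#' @export
save_trace <- function(trace, path) {
  cols <- c("time_ms", "Iext_hat", "V_hat", "h_hat", "w_hat", "innovation")
  stopifnot(all(cols %in% names(trace)))
  write_csv17(as.data.frame(trace)[cols], path)
  cfg <- attr(trace, "config")
  if (!is.null(cfg)) {
    side <- list(dt_ms = cfg$dt, R = cfg$R, Q_diag = diag(cfg$Q),
                 clamp_gates = cfg$clamp_gates,
                 model = if (inherits(cfg$model$gating, "cetc_set"))
                   "cetc" else "original")
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname save_trace
#' @export
load_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_ms", "Iext_hat", "V_hat", "h_hat", "w_hat", "innovation")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("malformed trace CSV ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    attr(df, "sidecar") <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  df
}

write_csv17 <- function(df, path) {
  fmt <- lapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = 17, format = "g") else col
  })
  utils::write.csv(as.data.frame(fmt), path, row.names = FALSE, quote = FALSE)
}

# Known keys of the JSON run configuration, with unit-bearing names.
run_config_keys <- c("mode", "dt_ms", "duration_ms", "seed",
                     "stimulus_kind", "rho_sm_ms", "delta_sm_ms",
                     "i_sm_pA_per_um2", "rate_hz", "cv",
                     "gpi_level_pA_per_um2",
                     "noise_kind", "noise_strength_mV",
                     "ukf_Q", "ukf_R", "burn_in_ms",
                     "filter_model", "n_segments", "out_dir")

#' Load / save a run configuration
#'
#' Run configurations are flat JSON objects with unit-bearing key names
#' (e.g. \code{"dt_ms"}, \code{"i_sm_pA_per_um2"}). Unknown keys are
#' rejected so typos fail loudly rather than silently falling back to
#' defaults.
#'
#' @param path JSON file path.
#' @return \code{load_run_config}: named list of configuration values.
#' @export
load_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown)) {
    stop("unknown run-config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  cfg
}

#' @rdname load_run_config
#' @param config named list with keys from the published set.
#' @export
save_run_config <- function(config, path) {
  unknown <- setdiff(names(config), run_config_keys)
  if (length(unknown)) {
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
  }
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Canned small inputs for examples and tests
#'
#' Deterministic miniature objects generated in code: short clean and noisy
#' trajectories in both regimes, a toy SPD matrix, and a toy piecewise-linear
#' function. Everything is rebuilt from the seed at call time; nothing is
#' stored on disk.
#'
#' @param name one of \code{"normal_short"}, \code{"parkinsonian_short"},
#'   \code{"noisy_observation"}, \code{"spd4"}, \code{"toy_plf"}.
#' @param seed RNG seed.
#' @return the requested object.
#' @export
make_fixture <- function(name = c("normal_short", "parkinsonian_short",
                                  "noisy_observation", "spd4", "toy_plf"),
                         seed = 1) {
  name <- match.arg(name)
  set.seed(seed)
  p <- tc_parameters()
  switch(name,
    normal_short = simulate_tc(p, gpi_spec("normal"), duration = 100),
    parkinsonian_short = simulate_tc(p, gpi_spec("parkinsonian"),
                                     duration = 100),
    noisy_observation = contaminate(
      simulate_tc(p, gpi_spec("normal"), duration = 100),
      noise_spec("gaussian", 1)),
    spd4 = {
      A <- matrix(stats::rnorm(16), 4)
      crossprod(A) + diag(4)
    },
    toy_plf = piecewise_linear(slopes = c(0.5, -0.25, 1),
                               intercepts = 0.2,
                               breakpoints = c(-1, 1),
                               domain = c(-3, 3)))
}
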