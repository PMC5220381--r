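#' Run one estimation experiment
#'
#' Simulates the "plant" (always the original closed-form model) in the given
#' regime under a square-wave sensorimotor drive, contaminates the voltage
#' with observation noise, runs the unscented Kalman filter (internal model
#' per \code{config}; CETC by default), and scores per-variable
#' \eqn{CF_{rmse}} against the clean truth after burn-in.
#'
#' @param mode \code{"normal"} or \code{"parkinsonian"}.
#' @param noise a [noise_spec()].
#' @param config a [ukf_config()].
#' @param seed RNG seed for the noise draw (and any stochastic stimulus).
#' @param duration simulated time (ms); default 2000 (2 s).
#' @param dt step (ms).
#' @param sm sensorimotor [stimulus_spec()].
#' @param plant plant parameters, default [tc_parameters()] (original model).
#' @param burn_in_ms settling time excluded from error scores, default 100.
#' @param truth optional precomputed clean trajectory (reused across
#'   repetitions of sweeps — the plant is deterministic given the stimulus).
#' @return Object of class \code{experiment_result}: list with the clean
#'   \code{truth} trajectory, the \code{obs} observation, the estimate
#'   \code{trace}, named \code{cf} (= CF_rmse for V, h, w), the per-variable
#'   absolute-error series \code{abs_err}, and the config snapshot.
#' @export
run_estimation <- function(mode = c("normal", "parkinsonian"),
                           noise = noise_spec("gaussian", 1),
                           config = ukf_config(), seed = 1,
                           duration = 2000, dt = 0.01,
                           sm = stimulus_spec("square_wave"),
                           plant = tc_parameters(), burn_in_ms = 100,
                           truth = NULL) {
  mode <- match.arg(mode)
  set.seed(seed)
  if (is.null(truth)) {
    truth <- simulate_tc(plant, gpi_spec(mode), sm, duration, dt)
  }
  obs <- contaminate(truth, noise)
  trace <- ukf_estimate(obs$V_obs, config)
  score_result(mode, truth, obs, trace, config, seed, burn_in_ms)
}

score_result <- function(mode, truth, obs, trace, config, seed, burn_in_ms) {
  tm <- truth$time_ms
  cf <- c(V = cf_rmse(trace$V_hat, truth$V_mV, tm, burn_in_ms),
          h = cf_rmse(trace$h_hat, truth$h, tm, burn_in_ms),
          w = cf_rmse(trace$w_hat, truth$w, tm, burn_in_ms))
  abs_err <- data.frame(time_ms = tm,
                        V = abs(trace$V_hat - truth$V_mV),
                        h = abs(trace$h_hat - truth$h),
                        w = abs(trace$w_hat - truth$w))
  structure(list(mode = mode, truth = truth, obs = obs, trace = trace,
                 cf = cf, abs_err = abs_err, config = config, seed = seed,
                 burn_in_ms = burn_in_ms),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> mode = %s, %d samples\n",
              x$mode, nrow(x$truth)))
  cat(sprintf("  CF_rmse: V = %.4f mV, h = %.5f, w = %.5f (burn-in %g ms)\n",
              x$cf[["V"]], x$cf[["h"]], x$cf[["w"]], x$burn_in_ms))
  invisible(x)
}

#' Sweep the filter noise covariances Q and R
#'
#' Runs repeated estimation experiments over a grid of process-noise (Q) and
#' observation-noise (R) settings, reusing one clean plant trajectory per
#' mode (the plant is deterministic; only the observation noise is redrawn
#' per repetition). Summaries use Tukey five-number statistics.
#'
#' @param Q_values,R_values numeric vectors; the grid is their cross product.
#' @param reps repetitions per cell, default 20.
#' @param mode regime of the plant.
#' @param noise observation noise applied to the plant voltage.
#' @param seed base seed; rep r of cell i uses \code{seed + 7919*i + r}.
#' @param duration,dt,sm,plant,burn_in_ms forwarded to [run_estimation()].
#' @return data.frame of class \code{qr_sweep} with one row per run:
#'   \code{Q, R, rep, cf_V, cf_h, cf_w}.
#' @export
sweep_qr <- function(Q_values, R_values, reps = 20,
                     mode = "normal", noise = noise_spec("gaussian", 1),
                     seed = 1, duration = 2000, dt = 0.01,
                     sm = stimulus_spec("square_wave"),
                     plant = tc_parameters(), burn_in_ms = 100) {
  stopifnot(reps >= 1)
  truth <- simulate_tc(plant, gpi_spec(mode), sm, duration, dt)
  grid <- expand.grid(Q = Q_values, R = R_values)
  rows <- vector("list", nrow(grid) * reps)
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    cfg <- ukf_config(Q = grid$Q[i], R = grid$R[i], dt = dt)
    for (r in seq_len(reps)) {
      res <- run_estimation(mode, noise, cfg, seed = seed + 7919L * i + r,
                            duration = duration, dt = dt, sm = sm,
                            plant = plant, burn_in_ms = burn_in_ms,
                            truth = truth)
      k <- k + 1L
      rows[[k]] <- data.frame(Q = grid$Q[i], R = grid$R[i], rep = r,
                              cf_V = res$cf[["V"]], cf_h = res$cf[["h"]],
                              cf_w = res$cf[["w"]])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("qr_sweep", "data.frame")
  out
}

#' Sweep observation-noise kind and strength
#'
#' @param kinds noise kinds (see [noise_spec()]).
#' @param strengths amplitude scale values (mV).
#' @param reps repetitions per cell.
#' @param modes plant regimes to include.
#' @param Q,R filter covariances (scalar Q expands to \code{Q * I}).
#' @inheritParams sweep_qr
#' @return data.frame of class \code{noise_sweep} with one row per run:
#'   \code{mode, kind, strength, rep, cf_V, cf_h, cf_w}.
#' @export
sweep_noise <- function(kinds = c("gaussian", "industrial_50",
                                  "odd_harmonic_150", "high_freq_350",
                                  "mixed"),
                        strengths = c(0, 1, 2, 4), reps = 20,
                        modes = c("normal", "parkinsonian"),
                        Q = 5e-5, R = 5, seed = 1, duration = 2000,
                        dt = 0.01, sm = stimulus_spec("square_wave"),
                        plant = tc_parameters(), burn_in_ms = 100) {
  cfg <- ukf_config(Q = Q, R = R, dt = dt)
  rows <- list()
  cell <- 0L
  for (mode in modes) {
    truth <- simulate_tc(plant, gpi_spec(mode), sm, duration, dt)
    for (kind in kinds) {
      for (s in strengths) {
        cell <- cell + 1L
        # deterministic noise kinds at phase 0 are identical across reps;
        # repetitions matter for the gaussian component
        nrep <- if (kind %in% c("gaussian", "mixed") && s > 0) reps else 1L
        for (r in seq_len(nrep)) {
          res <- run_estimation(mode, noise_spec(kind, s), cfg,
                                seed = seed + 7919L * cell + r,
                                duration = duration, dt = dt, sm = sm,
                                plant = plant, burn_in_ms = burn_in_ms,
                                truth = truth)
          rows[[length(rows) + 1L]] <-
            data.frame(mode = mode, kind = kind, strength = s, rep = r,
                       cf_V = res$cf[["V"]], cf_h = res$cf[["h"]],
                       cf_w = res$cf[["w"]])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("noise_sweep", "data.frame")
  out
}

#' Median summary of a sweep
#'
#' @param sweep a [sweep_qr()] or [sweep_noise()] result.
#' @return data.frame of per-cell medians and Tukey hinges of the three
#'   per-variable error statistics.
#' @export
sweep_summary <- function(sweep) {
  keys <- intersect(c("mode", "kind", "strength", "Q", "R"), names(sweep))
  agg <- function(v) {
    s <- stats::aggregate(sweep[[v]], sweep[keys], function(x) {
      fn <- stats::fivenum(x)
      c(median = fn[3], lower_hinge = fn[2], upper_hinge = fn[4])
    })
    cbind(s[keys], stats::setNames(as.data.frame(s$x),
                                   paste0(v, c("_median", "_lo", "_hi"))))
  }
  out <- agg("cf_V")
  for (v in c("cf_h", "cf_w")) {
    out <- merge(out, agg(v), by = keys, sort = TRUE)
  }
  out[do.call(order, out[keys]), , drop = FALSE]
}

#' Double-blind estimation experiment
#'
#' Emulates estimation on a recording whose generating parameters are
#' unknown: the plant's conductances and sigmoid half-voltages are jittered
#' by a seeded uniform perturbation (default +/-10\%), the injected current
#' is an irregular gamma pulse train (default 30 Hz mean rate, CV 0.2,
#' 5 pA/um^2 for 5 ms) on top of the regime's pallidal level, and the filter
#' runs the unperturbed default (CETC) model seeing only the noisy voltage.
#' The true injected current is returned for scoring the reconstructed
#' \eqn{I_{ext}}.
#'
#' @param seed RNG seed (plant perturbation, stimulus and noise draws).
#' @param mode plant regime; defaults pair with the operating points
#'   \code{R = 1, Q = 0.005} (normal) and \code{R = 0.5, Q = 0.5}
#'   (Parkinsonian).
#' @param R,Q filter covariances; \code{NULL} selects the per-mode default.
#' @param perturb relative plant perturbation amplitude.
#' @param noise_sd observation-noise standard deviation (mV).
#' @param duration,dt simulation length and step (ms).
#' @return An \code{experiment_result} with extra fields
#'   \code{true_current} (the injected current series) and
#'   \code{plant_params}.
#' @export
double_blind <- function(seed = 1, mode = c("normal", "parkinsonian"),
                         R = NULL, Q = NULL, perturb = 0.1, noise_sd = 1,
                         duration = 2000, dt = 0.01) {
  mode <- match.arg(mode)
  if (is.null(R)) R <- if (mode == "normal") 1 else 0.5
  if (is.null(Q)) Q <- if (mode == "normal") 0.005 else 0.5
  set.seed(seed)
  plant <- perturb_parameters(tc_parameters(), perturb)
  sm <- stimulus_spec("gamma_pulse_train", rate = 30, cv = 0.2,
                      i_sm = 5, delta_sm = 5)
  gpi <- gpi_spec(mode)
  truth <- simulate_tc(plant, gpi, sm, duration, dt)
  obs <- contaminate(truth, noise_spec("gaussian", noise_sd))
  cfg <- ukf_config(Q = Q, R = R, dt = dt)
  trace <- ukf_estimate(obs$V_obs, cfg)
  res <- score_result(mode, truth, obs, trace, cfg, seed, burn_in_ms = 100)
  res$true_current <- truth$I_applied
  res$plant_params <- plant
  res
}

#' Jitter plant parameters for a double-blind run
#'
#' Multiplies the four conductances by independent uniform factors in
#' \code{[1 - amount, 1 + amount]} and shifts the four sigmoid half-voltages
#' by uniform offsets of up to \code{amount} times their slope factor.
#'
#' @param params a [tc_parameters()] with closed-form gating.
#' @param amount relative perturbation (default 0.1).
#' @return perturbed \code{tc_parameters}.
#' @export
perturb_parameters <- function(params, amount = 0.1) {
  stopifnot(inherits(params$gating, "gating_set"))
  m <- params$membrane
  fac <- stats::runif(4, 1 - amount, 1 + amount)
  g <- params$gating$par
  shift <- function(sig) stats::runif(1, -amount, amount) * sig
  tc_parameters(
    c_m = m[["c_m"]],
    g_l = m[["g_l"]] * fac[1], e_l = m[["e_l"]],
    g_na = m[["g_na"]] * fac[2], e_na = m[["e_na"]],
    g_k = m[["g_k"]] * fac[3], e_k = m[["e_k"]],
    g_t = m[["g_t"]] * fac[4], e_t = m[["e_t"]],
    gating = gating_functions(
      theta_m = g[["theta_m"]] + shift(g[["sigma_m"]]),
      theta_p = g[["theta_p"]] + shift(g[["sigma_p"]]),
      theta_h = g[["theta_h"]] + shift(g[["sigma_h"]]),
      theta_w = g[["theta_w"]] + shift(g[["sigma_w"]])))
}

#' Baseline-plateau error of the reconstructed injected current
#'
#' Between stimulus pulses the true injected current sits on the pallidal
#' plateau; this helper averages the filter's \eqn{I_{ext}} estimate over
#' those plateau samples (after burn-in, excluding a settling margin after
#' each pulse) and reports the absolute deviation from the true level.
#'
#' @param result a [double_blind()] result.
#' @param settle_ms margin excluded after each pulse (ms).
#' @return list: \code{level} (true plateau), \code{estimate} (mean
#'   reconstructed current on the plateau), \code{bias} (absolute error).
#' @export
iext_plateau_error <- function(result, settle_ms = 10) {
  tm <- result$truth$time_ms
  cur <- result$true_current
  level <- min(cur) # the pallidal baseline; pulses are positive
  on_plateau <- cur == level & tm >= result$burn_in_ms
  # exclude a settling margin after every departure from the plateau
  dt <- tm[2] - tm[1]
  k <- ceiling(settle_ms / dt)
  off <- which(cur != level)
  if (length(off)) {
    bad <- unique(pmin(rep(off, each = k) + seq_len(k), length(cur)))
    on_plateau[bad] <- FALSE
  }
  est <- mean(result$trace$Iext_hat[on_plateau])
  list(level = level, estimate = est, bias = abs(est - level))
}

#' Write an experiment or sweep to disk
#'
#' Serializes results as CSV (time series, sweep tables) plus a JSON summary
#' and a manifest naming every file written.
#'
#' @param x an \code{experiment_result}, \code{qr_sweep} or
#'   \code{noise_sweep}.
#' @param dir output directory (created if missing).
#' @param name base name for the files.
#' @return invisibly, the manifest list.
#' @export
report <- function(x, dir, name = "experiment") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  add <- function(fname) files <<- c(files, fname)
  pth <- function(f) file.path(dir, f)
  if (inherits(x, "experiment_result")) {
    save_trajectory(x$truth, pth(paste0(name, "_truth.csv")))
    add(paste0(name, "_truth.csv"))
    utils::write.csv(data.frame(time_ms = x$obs$time_ms,
                                V_obs = x$obs$V_obs),
                     pth(paste0(name, "_obs.csv")), row.names = FALSE)
    add(paste0(name, "_obs.csv"))
    save_trace(x$trace, pth(paste0(name, "_trace.csv")))
    add(paste0(name, "_trace.csv"))
    summ <- list(mode = x$mode, seed = x$seed, burn_in_ms = x$burn_in_ms,
                 cf_rmse = as.list(x$cf))
  } else if (inherits(x, c("qr_sweep", "noise_sweep"))) {
    utils::write.csv(as.data.frame(x), pth(paste0(name, "_runs.csv")),
                     row.names = FALSE)
    add(paste0(name, "_runs.csv"))
    utils::write.csv(sweep_summary(x), pth(paste0(name, "_summary.csv")),
                     row.names = FALSE)
    add(paste0(name, "_summary.csv"))
    summ <- list(kind = class(x)[1], n_runs = nrow(x))
  } else if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    summ <- list(empty = TRUE)
  } else {
    stop("report: unsupported object")
  }
  jsonlite::write_json(summ, pth(paste0(name, "_summary.json")),
                       auto_unbox = TRUE, digits = NA)
  add(paste0(name, "_summary.json"))
  manifest <- list(name = name, files = sort(files),
                   package_version = as.character(utils::packageVersion("thalatrack")))
  jsonlite::write_json(manifest, pth(paste0(name, "_manifest.json")),
                       auto_unbox = TRUE)
  invisible(manifest)
}
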