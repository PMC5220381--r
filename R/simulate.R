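#' Simulate the reduced TC relay neuron
#'
#' Integrates the three-variable model with forward Euler at step \code{dt}
#' under a pallidal input ([gpi_spec()]) and a sensorimotor stimulus
#' ([stimulus_spec()]). The initial state defaults to the rest state found by
#' relaxation under the constant components of the inputs ([rest_state()]).
#'
#' @param params a [tc_parameters()] (original closed forms or a CETC set from
#'   [build_cetc()]).
#' @param gpi a [gpi_spec()]; selects the normal or Parkinsonian regime.
#' @param sm a [stimulus_spec()].
#' @param duration simulated time (ms).
#' @param dt integration step (ms), default 0.01.
#' @param init optional [neuron_state()] initial condition.
#' @return Object of class \code{tc_trajectory}: a data.frame with columns
#'   \code{time_ms, V_mV, h, w, I_applied} and attributes \code{dt},
#'   \code{mode}.
#' @examples
#' p <- tc_parameters()
#' tr <- simulate_tc(p, duration = 200)
#' length(detect_spikes(tr))
#' @export
simulate_tc <- function(params, gpi = gpi_spec("normal"),
                        sm = stimulus_spec("square_wave"),
                        duration = 1000, dt = 0.01, init = NULL) {
  stopifnot(duration > 0, dt > 0)
  times <- seq(0, duration, by = dt)
  i_app <- gpi_current(gpi, times) + sm_current(sm, times, dt)
  if (is.null(init)) init <- rest_state(params, gpi)
  sts <- .cpp_simulate(as_cpp_model(params), as.numeric(i_app),
                       as.numeric(init), dt)
  out <- data.frame(time_ms = times, V_mV = sts[, 1], h = sts[, 2],
                    w = sts[, 3], I_applied = i_app)
  structure(out, dt = dt, mode = gpi$mode,
            class = c("tc_trajectory", "data.frame"))
}

#' Rest state of the model under constant inputs
#'
#' Relaxes the model for \code{relax_ms} (default 5000 ms) from a
#' hyperpolarized guess under the constant (time-averaged) input level and
#' returns the final state. Results are cached per parameter/input pair
#' within a session.
#'
#' @inheritParams simulate_tc
#' @param relax_ms relaxation horizon (ms).
#' @return a [neuron_state()].
#' @export
rest_state <- function(params, gpi = gpi_spec("normal"), relax_ms = 5000,
                       dt = 0.02) {
  lev <- mean_gpi_level(gpi$level, gpi$period, gpi$duty)
  key <- paste0(paste(signif(unlist(params$membrane), 10), collapse = ","),
                "|", class(params$gating)[1], "|", signif(lev, 10))
  hit <- .rest_cache[[key]]
  if (!is.null(hit)) return(hit)
  v0 <- -65
  init <- c(v0, tc_f(params, 4, v0), tc_f(params, 7, v0))
  nst <- ceiling(relax_ms / dt)
  sts <- .cpp_simulate(as_cpp_model(params), rep(lev, nst + 1), init, dt)
  st <- neuron_state(sts[nst + 1, 1], sts[nst + 1, 2], sts[nst + 1, 3])
  .rest_cache[[key]] <- st
  st
}
.rest_cache <- new.env(parent = emptyenv())

#' @export
print.tc_trajectory <- function(x, ...) {
  cat(sprintf("<tc_trajectory> %d samples, dt = %g ms, %.1f ms, mode = %s\n",
              nrow(x), attr(x, "dt"), x$time_ms[nrow(x)],
              attr(x, "mode") %||% "?"))
  cat(sprintf("  V in [%.1f, %.1f] mV; %d spike(s) at -20 mV threshold\n",
              min(x$V_mV), max(x$V_mV), length(detect_spikes(x))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
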