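#' Instantaneous state of the reduced TC relay neuron
#'
#' @param v membrane potential (mV), finite.
#' @param h sodium inactivation gate in [0, 1].
#' @param w T-type calcium gate in [0, 1].
#' @return named numeric vector of class \code{neuron_state}.
#' @export
neuron_state <- function(v, h, w) {
  stopifnot(is.finite(v), is.finite(h), is.finite(w),
            h >= 0, h <= 1, w >= 0, w <= 1)
  structure(c(V = v, h = h, w = w), class = "neuron_state")
}

#' Ionic currents of the reduced TC relay neuron
#'
#' Computes the four membrane currents (pA/um^2) at a given state:
#' leak \eqn{I_L = g_L (V - E_L)}, sodium
#' \eqn{I_{Na} = g_{Na} f_1(V) h (V - E_{Na})} with
#' \eqn{f_1 = m_\infty^3}, potassium
#' \eqn{I_K = g_K f_3(h) (V - E_K)} with \eqn{f_3 = (0.75(1-h))^4}
#' (activation tied to sodium inactivation by the model reduction), and the
#' low-threshold T-type calcium current
#' \eqn{I_T = g_T f_2(V) w (V - E_T)} with \eqn{f_2 = p_\infty^2}.
#'
#' @param state a [neuron_state()].
#' @param params a [tc_parameters()] (original or CETC function set).
#' @return named numeric vector \code{c(I_L, I_Na, I_K, I_T)}.
#' @export
ionic_currents <- function(state, params) {
  if (!all(is.finite(state))) stop("ionic_currents: non-finite state (diverged integration?)")
  m <- params$membrane
  v <- state[["V"]]; h <- state[["h"]]; w <- state[["w"]]
  c(I_L = m[["g_l"]] * (v - m[["e_l"]]),
    I_Na = m[["g_na"]] * tc_f(params, 1, v) * h * (v - m[["e_na"]]),
    I_K = m[["g_k"]] * tc_f(params, 3, h) * (v - m[["e_k"]]),
    I_T = m[["g_t"]] * tc_f(params, 2, v) * w * (v - m[["e_t"]]))
}

#' Time derivatives of the reduced TC model
#'
#' \eqn{dV/dt = (-I_L - I_{Na} - I_K - I_T + i_{gpi} + i_{sm}) / C_m};
#' \eqn{dh/dt = a_h(V)(1-h) - b_h(V) h};
#' \eqn{dw/dt = (w_\infty(V) - w)/\tau_w(V)}. Intrinsic currents subtract
#' from \eqn{dV/dt}; the sensorimotor drive \code{i_sm} adds, and the
#' pallidal input \code{i_gpi} is passed signed (negative = hyperpolarizing,
#' the Parkinsonian regime).
#'
#' @inheritParams ionic_currents
#' @param i_gpi pallidal (GPi) input current (pA/um^2, signed).
#' @param i_sm sensorimotor input current (pA/um^2).
#' @return named numeric vector \code{c(dV, dh, dw)} (per ms).
#' @export
tc_derivatives <- function(state, i_gpi, i_sm, params) {
  if (!all(is.finite(c(state, i_gpi, i_sm)))) {
    stop("tc_derivatives: non-finite input")
  }
  d <- .cpp_derivatives(as_cpp_model(params),
                        as.numeric(state), i_gpi + i_sm)
  c(dV = d[1], dh = d[2], dw = d[3])
}

#' One forward-Euler step of the reduced TC model
#'
#' Advances the state by \code{dt} ms with the explicit Euler update
#' \eqn{x_{k+1} = x_k + \Delta t \, \dot x_k}; gate variables are clamped to
#' [0, 1] after the step.
#'
#' @inheritParams tc_derivatives
#' @param dt time step (ms), > 0; the default integration step elsewhere in
#'   the package is 0.01 ms, which is stable for these kinetics.
#' @return a [neuron_state()].
#' @export
euler_step <- function(state, i_gpi, i_sm, dt, params) {
  stopifnot(dt > 0)
  d <- tc_derivatives(state, i_gpi, i_sm, params)
  v <- state[["V"]] + dt * d[["dV"]]
  h <- min(max(state[["h"]] + dt * d[["dh"]], 0), 1)
  w <- min(max(state[["w"]] + dt * d[["dw"]], 0), 1)
  if (!is.finite(v)) stop("euler_step: V diverged")
  neuron_state(v, h, w)
}

#' Steady-state ionic currents over a voltage grid
#'
#' Evaluates [ionic_currents()] at each grid voltage with the slow variables
#' pinned to their voltage steady states, \eqn{h = h_\infty(V)},
#' \eqn{w = w_\infty(V)} — the standard current-voltage view used to compare
#' the original and cost-efficient function sets.
#'
#' @param v_grid numeric vector of voltages (mV).
#' @param params a [tc_parameters()].
#' @return data.frame with columns \code{V, h, w, I_L, I_Na, I_K, I_T}.
#' @export
steady_state_currents <- function(v_grid, params) {
  m <- params$membrane
  h <- tc_f(params, 4, v_grid)
  w <- tc_f(params, 7, v_grid)
  data.frame(
    V = v_grid, h = h, w = w,
    I_L = m[["g_l"]] * (v_grid - m[["e_l"]]),
    I_Na = m[["g_na"]] * tc_f(params, 1, v_grid) * h * (v_grid - m[["e_na"]]),
    I_K = m[["g_k"]] * tc_f(params, 3, h) * (v_grid - m[["e_k"]]),
    I_T = m[["g_t"]] * tc_f(params, 2, v_grid) * w * (v_grid - m[["e_t"]]))
}

#' Detect spikes in a voltage trace
#'
#' A spike is an upward crossing of \code{threshold}; crossings closer than
#' \code{merge_ms} to the previous accepted spike are treated as the same
#' event (refractory merge).
#'
#' @param traj a trajectory from [simulate_tc()], or a data.frame with
#'   \code{time_ms} and \code{V_mV} columns.
#' @param threshold detection threshold (mV), default -20.
#' @param merge_ms refractory merge window (ms), default 2.
#' @return numeric vector of spike times (ms), possibly empty.
#' @export
detect_spikes <- function(traj, threshold = -20, merge_ms = 2) {
  v <- traj$V_mV
  t <- traj$time_ms
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  if (length(up) == 0) return(numeric(0))
  times <- t[up]
  keep <- times[1]
  for (tt in times[-1]) {
    if (tt - keep[length(keep)] >= merge_ms) keep <- c(keep, tt)
  }
  keep
}
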