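#' Sensorimotor stimulus specification
#'
#' Describes the excitatory sensorimotor drive to the TC cell. Kinds:
#' \describe{
#'   \item{\code{square_wave}}{pulses of amplitude \code{i_sm} lasting
#'     \code{delta_sm} ms at the start of every \code{rho_sm} ms period (the
#'     Heaviside-window form; defaults 25 ms period, 20\% duty, 5 pA/um^2).}
#'   \item{\code{gamma_pulse_train}}{monophasic pulses of amplitude
#'     \code{i_sm} and duration \code{delta_sm}, inter-pulse onset intervals
#'     gamma-distributed with mean \code{1000/rate} ms and coefficient of
#'     variation \code{cv} — an irregular cortical drive.}
#'   \item{\code{constant}}{a constant current \code{i_sm}.}
#'   \item{\code{none}}{zero drive.}
#' }
#'
#' @param kind stimulus kind, see above.
#' @param rho_sm square-wave period (ms).
#' @param delta_sm pulse duration (ms); must satisfy 0 < delta_sm < rho_sm for
#'   the square wave.
#' @param i_sm amplitude (pA/um^2). With \eqn{C_m = 1} pF/um^2 a current
#'   density in pA/um^2 and a rate in mV/ms are numerically interchangeable.
#' @param rate mean pulse rate (Hz) of the gamma train.
#' @param cv coefficient of variation of inter-pulse intervals.
#' @return Object of class \code{stimulus_spec}.
#' @export
stimulus_spec <- function(kind = c("square_wave", "gamma_pulse_train",
                                   "constant", "none"),
                          rho_sm = 25, delta_sm = 5, i_sm = 5,
                          rate = 30, cv = 0.2) {
  kind <- match.arg(kind)
  if (kind == "square_wave") stopifnot(delta_sm > 0, delta_sm < rho_sm)
  if (kind == "gamma_pulse_train") stopifnot(rate > 0, cv > 0)
  structure(list(kind = kind, rho_sm = rho_sm, delta_sm = delta_sm,
                 i_sm = i_sm, rate = rate, cv = cv),
            class = "stimulus_spec")
}

#' Square-wave sensorimotor current
#'
#' \eqn{I_{SM}(t) = i_{SM}} during the first \eqn{\delta_{SM}} ms of each
#' \eqn{\rho_{SM}} ms period, else 0 (product of Heaviside steps).
#'
#' @param t time(s) in ms (vectorized).
#' @param spec a [stimulus_spec()] with \code{kind = "square_wave"}.
#' @return current (pA/um^2), same length as \code{t}.
#' @export
sm_square_wave <- function(t, spec) {
  stopifnot(inherits(spec, "stimulus_spec"), spec$kind == "square_wave")
  phase <- t %% spec$rho_sm
  spec$i_sm * as.numeric(phase >= 0 & phase < spec$delta_sm)
}

#' Gamma-distributed pulse-train sensorimotor current
#'
#' Pulse onsets are separated by gamma-distributed intervals with mean
#' \code{1000/rate} ms and coefficient of variation \code{cv} (shape
#' \eqn{1/cv^2}, scale \eqn{mean \cdot cv^2}); each onset starts a monophasic
#' pulse of amplitude \code{i_sm} lasting \code{delta_sm} ms. The series is
#' sampled on \code{seq(0, duration, dt)} and is reproducible under
#' \code{set.seed()}. Overlapping pulses (duration comparable to the mean
#' interval) are merged with a warning.
#'
#' @param spec a [stimulus_spec()] with \code{kind = "gamma_pulse_train"}.
#' @param duration series length (ms).
#' @param dt sample spacing (ms).
#' @return numeric vector of length \code{duration/dt + 1}.
#' @export
sm_gamma_pulse_train <- function(spec, duration, dt) {
  stopifnot(inherits(spec, "stimulus_spec"),
            spec$kind == "gamma_pulse_train", duration > 0, dt > 0)
  mean_iv <- 1000 / spec$rate
  if (spec$delta_sm >= mean_iv) {
    warning("pulse duration >= mean inter-pulse interval: overlapping pulses merged")
  }
  shape <- 1 / spec$cv^2
  scale <- mean_iv * spec$cv^2
  # draw enough intervals to cover the duration with margin
  n_guess <- ceiling(duration / mean_iv * 1.5) + 20
  onsets <- cumsum(stats::rgamma(n_guess, shape = shape, scale = scale))
  while (sum(onsets <= duration) == length(onsets)) {
    onsets <- c(onsets, onsets[length(onsets)] +
                  cumsum(stats::rgamma(n_guess, shape = shape, scale = scale)))
  }
  onsets <- onsets[onsets <= duration]
  times <- seq(0, duration, by = dt)
  out <- numeric(length(times))
  if (spec$i_sm != 0) {
    for (on in onsets) {
      i0 <- ceiling(on / dt) + 1L
      i1 <- min(floor((on + spec$delta_sm) / dt) + 1L, length(times))
      if (i0 <= i1) out[i0:i1] <- spec$i_sm
    }
  }
  out
}

#' Pallidal (GPi) input specification
#'
#' The inhibitory current from the globus pallidus internus selects the
#' functional regime of the cell: \code{normal} applies no net pallidal
#' current, while \code{parkinsonian} applies phasic hyperpolarizing
#' inhibition (default -1.5 pA/um^2 for the first 60\% of a 100 ms cycle —
#' the low-frequency oscillatory pallidal drive of the Parkinsonian basal
#' ganglia), calibrated once so the cell answers with T-current rebound
#' bursts instead of faithful single-spike relay. \code{custom} takes an
#' explicit level; a constant Parkinsonian level can be obtained with
#' \code{gpi_spec("custom", level = -1.5)}.
#'
#' @param mode one of \code{"normal"}, \code{"parkinsonian"}, \code{"custom"}.
#' @param level constant current level (pA/um^2); negative = hyperpolarizing.
#' @param period,duty optional phasic inhibition: \code{level} is applied for
#'   \code{duty} fraction of each \code{period} ms cycle, else 0.
#' @return Object of class \code{gpi_spec}.
#' @export
gpi_spec <- function(mode = c("normal", "parkinsonian", "custom"),
                     level = NULL, period = NULL, duty = NULL) {
  mode <- match.arg(mode)
  if (is.null(level)) {
    level <- switch(mode, normal = 0, parkinsonian = -1.5,
                    custom = stop("custom gpi_spec needs `level`"))
    if (mode == "parkinsonian" && is.null(period)) {
      period <- 100
      duty <- 0.6
    }
  }
  if (!is.null(period)) stopifnot(period > 0, duty > 0, duty < 1)
  if (mode == "parkinsonian" && mean_gpi_level(level, period, duty) >= 0) {
    stop("parkinsonian GPi input must be net hyperpolarizing (negative mean)")
  }
  structure(list(mode = mode, level = level, period = period, duty = duty),
            class = "gpi_spec")
}

mean_gpi_level <- function(level, period, duty) {
  if (is.null(period)) level else level * duty
}

#' GPi input current over a time grid
#' @param spec a [gpi_spec()].
#' @param t times (ms).
#' @return current series (pA/um^2).
#' @export
gpi_current <- function(spec, t) {
  stopifnot(inherits(spec, "gpi_spec"))
  if (is.null(spec$period)) {
    rep(spec$level, length(t))
  } else {
    phase <- t %% spec$period
    spec$level * as.numeric(phase < spec$duty * spec$period)
  }
}

# sample any stimulus kind on a time grid (RNG used only by the gamma train)
sm_current <- function(spec, times, dt) {
  switch(spec$kind,
         square_wave = sm_square_wave(times, spec),
         gamma_pulse_train = sm_gamma_pulse_train(
           spec, times[length(times)], dt),
         constant = rep(spec$i_sm, length(times)),
         none = numeric(length(times)))
}
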