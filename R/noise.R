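#' Observation-noise specification
#'
#' The robustness studies contaminate the observed membrane potential with
#' one of five processes: Gaussian white noise, mains ("industrial")
#' interference at 50 Hz, its odd harmonic at 150 Hz, high-frequency
#' interference at 350 Hz, or the mixture of all four. "Strength" is a
#' single amplitude axis: the standard deviation (mV) of the Gaussian
#' component and the amplitude (mV) of each sinusoid. Sinusoid phases
#' default to 0.
#'
#' @param kind one of \code{"gaussian"}, \code{"industrial_50"},
#'   \code{"odd_harmonic_150"}, \code{"high_freq_350"}, \code{"mixed"}.
#' @param strength amplitude scale (mV), >= 0.
#' @param phase sinusoid phase offset (radians).
#' @return Object of class \code{noise_spec}.
#' @export
noise_spec <- function(kind = c("gaussian", "industrial_50",
                                "odd_harmonic_150", "high_freq_350", "mixed"),
                       strength = 1, phase = 0) {
  kind <- match.arg(kind)
  stopifnot(strength >= 0)
  structure(list(kind = kind, strength = strength, phase = phase),
            class = "noise_spec")
}

#' Generate an observation-noise series
#'
#' Gaussian noise draws i.i.d. \code{N(0, strength^2)} samples (reproducible
#' under \code{set.seed()}); sinusoids are
#' \eqn{strength \cdot \sin(2\pi f t + \phi)} with \eqn{f} in Hz and \eqn{t}
#' in ms; \code{mixed} is the elementwise sum of the four components at the
#' same strength.
#'
#' @param spec a [noise_spec()].
#' @param times uniform sample instants (ms).
#' @return numeric noise series (mV).
#' @export
generate_noise <- function(spec, times) {
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$strength == 0) return(numeric(length(times)))
  sinus <- function(f_hz) {
    spec$strength * sin(2 * pi * f_hz * times / 1000 + spec$phase)
  }
  switch(spec$kind,
         gaussian = stats::rnorm(length(times), 0, spec$strength),
         industrial_50 = sinus(50),
         odd_harmonic_150 = sinus(150),
         high_freq_350 = sinus(350),
         mixed = stats::rnorm(length(times), 0, spec$strength) +
           sinus(50) + sinus(150) + sinus(350))
}

#' Contaminate a simulated trajectory with observation noise
#'
#' Adds a generated noise series to the trajectory's membrane potential; the
#' clean trajectory is retained alongside for scoring.
#'
#' @param traj a [simulate_tc()] trajectory.
#' @param spec a [noise_spec()].
#' @return Object of class \code{tc_observation}: list with \code{time_ms},
#'   \code{V_obs}, the \code{noise} series and the \code{truth} trajectory.
#' @export
contaminate <- function(traj, spec) {
  noise <- generate_noise(spec, traj$time_ms)
  structure(list(time_ms = traj$time_ms, V_obs = traj$V_mV + noise,
                 noise = noise, truth = traj, spec = spec),
            class = "tc_observation")
}

#' @export
print.tc_observation <- function(x, ...) {
  cat(sprintf("<tc_observation> %d samples, noise = %s (strength %g mV)\n",
              length(x$V_obs), x$spec$kind, x$spec$strength))
  invisible(x)
}
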