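#' Gating function set of the reduced TC relay neuron
#'
#' The reduced thalamocortical (TC) relay cell keeps three dynamical variables:
#' the membrane potential \eqn{V}, the sodium inactivation gate \eqn{h} and the
#' T-type calcium gate \eqn{w}. Sodium activation is slaved to its steady state
#' \eqn{m_\infty(V)} and potassium activation is tied to \eqn{1-h}, so all of
#' the voltage dependence is carried by seven scalar maps: the steady-state
#' sigmoids \eqn{h_\infty, m_\infty, p_\infty, w_\infty}, the opening/closing
#' rates \eqn{a_h, b_h} of the sodium gate, and the time constant
#' \eqn{\tau_w} of the calcium gate. Each sigmoid is parameterized by a
#' half-activation voltage \code{theta} (mV) and slope factor \code{sigma}
#' (mV); increasing maps use \eqn{1/(1+e^{-(V-\theta)/\sigma})}, decreasing
#' maps \eqn{1/(1+e^{(V-\theta)/\sigma})}.
#'
#' Defaults are the published Terman/Rubin--Terman TC relay cell constants.
#' Every constant is exposed so an alternative parameterization (or a
#' perturbed "plant" for double-blind experiments) can be substituted.
#'
#' @param theta_m,sigma_m half-voltage and slope of sodium activation
#'   \eqn{m_\infty} (increasing).
#' @param pow_na exponent applied to \eqn{m_\infty} in the sodium current.
#' @param theta_p,sigma_p half-voltage and slope of T-type calcium activation
#'   \eqn{p_\infty} (increasing).
#' @param pow_t exponent applied to \eqn{p_\infty} in the T current.
#' @param c_k,pow_k the potassium activation term is \eqn{(c_K (1-h))^{p_K}}.
#'   The default \code{c_k = 1} uses the plain \eqn{(1-h)^4} form, which
#'   yields multi-spike rebound bursts on release from hyperpolarization; the
#'   source model's \code{c_k = 0.75} variant weakens the spike
#'   after-hyperpolarization enough that rebound responses collapse to a
#'   single spike riding a plateau. Both are supported.
#' @param theta_h,sigma_h half-voltage and slope of \eqn{h_\infty} (decreasing).
#' @param theta_w,sigma_w half-voltage and slope of \eqn{w_\infty} (decreasing).
#' @param a_h_scale,a_h_theta,a_h_sigma sodium-gate opening rate
#'   \eqn{a_h(V) = a \exp(-(V-\theta)/\sigma)} (ms^-1).
#' @param b_h_scale,b_h_theta,b_h_sigma sodium-gate closing rate
#'   \eqn{b_h(V) = b/(1+e^{-(V-\theta)/\sigma})} (ms^-1).
#' @param tau_w_scale,tau_w_base,tau_w_theta,tau_w_sigma calcium-gate time
#'   constant \eqn{\tau_w(V) = s (b + \exp(-(V-\theta)/\sigma))} (ms).
#'
#' @return An object of class \code{gating_set}: a list of vectorized closures
#'   \code{h_inf, m_inf, p_inf, w_inf, a_h, b_h, tau_w} plus the parameter
#'   vector used by the compiled integrator.
#' @seealso [tc_parameters()], [build_cetc()]
#' @export
gating_functions <- function(theta_m = -37, sigma_m = 7, pow_na = 3,
                             theta_p = -60, sigma_p = 6.2, pow_t = 2,
                             c_k = 1, pow_k = 4,
                             theta_h = -41, sigma_h = 4,
                             theta_w = -84, sigma_w = 4,
                             a_h_scale = 0.128, a_h_theta = -46, a_h_sigma = 18,
                             b_h_scale = 4, b_h_theta = -23, b_h_sigma = 5,
                             tau_w_scale = 0.15, tau_w_base = 28,
                             tau_w_theta = -25, tau_w_sigma = 10.5) {
  par <- c(theta_m, sigma_m, pow_na, theta_p, sigma_p, pow_t, c_k, pow_k,
           theta_h, sigma_h, theta_w, sigma_w,
           a_h_scale, a_h_theta, a_h_sigma, b_h_scale, b_h_theta, b_h_sigma,
           tau_w_scale, tau_w_base, tau_w_theta, tau_w_sigma)
  names(par) <- c("theta_m", "sigma_m", "pow_na", "theta_p", "sigma_p",
                  "pow_t", "c_k", "pow_k", "theta_h", "sigma_h", "theta_w",
                  "sigma_w", "a_h_scale", "a_h_theta", "a_h_sigma",
                  "b_h_scale", "b_h_theta", "b_h_sigma", "tau_w_scale",
                  "tau_w_base", "tau_w_theta", "tau_w_sigma")
  stopifnot(is.finite(par), sigma_m > 0, sigma_p > 0, sigma_h > 0,
            sigma_w > 0, a_h_sigma > 0, b_h_sigma > 0,
            tau_w_scale > 0, tau_w_base > 0, tau_w_sigma > 0)
  sig_up <- function(theta, sigma) {
    force(theta); force(sigma)
    function(v) 1 / (1 + exp(-(v - theta) / sigma))
  }
  sig_dn <- function(theta, sigma) {
    force(theta); force(sigma)
    function(v) 1 / (1 + exp((v - theta) / sigma))
  }
  out <- list(
    m_inf = sig_up(theta_m, sigma_m),
    p_inf = sig_up(theta_p, sigma_p),
    h_inf = sig_dn(theta_h, sigma_h),
    w_inf = sig_dn(theta_w, sigma_w),
    a_h = function(v) a_h_scale * exp(-(v - a_h_theta) / a_h_sigma),
    b_h = function(v) b_h_scale / (1 + exp(-(v - b_h_theta) / b_h_sigma)),
    tau_w = function(v) tau_w_scale * (tau_w_base + exp(-(v - tau_w_theta) / tau_w_sigma)),
    par = par
  )
  class(out) <- "gating_set"
  out
}

#' @export
print.gating_set <- function(x, ...) {
  cat("<gating_set> closed-form TC gating functions\n")
  cat("  m_inf: theta", x$par[["theta_m"]], "sigma", x$par[["sigma_m"]],
      " (pow", x$par[["pow_na"]], ")\n")
  cat("  h_inf: theta", x$par[["theta_h"]], "sigma", x$par[["sigma_h"]], "\n")
  cat("  p_inf: theta", x$par[["theta_p"]], "sigma", x$par[["sigma_p"]],
      " (pow", x$par[["pow_t"]], ")\n")
  cat("  w_inf: theta", x$par[["theta_w"]], "sigma", x$par[["sigma_w"]], "\n")
  invisible(x)
}

#' Membrane parameters of the reduced TC relay neuron
#'
#' Conductance densities are in mS/cm^2 (numerically pA/um^2 per mV of driving
#' force), reversal potentials in mV, capacitance density in pF/um^2. Defaults
#' are the Terman/Rubin--Terman TC relay cell constants with \eqn{C_m = 1}.
#'
#' @param c_m membrane capacitance density (pF/um^2), must be > 0.
#' @param g_l,e_l leak conductance and reversal.
#' @param g_na,e_na sodium conductance and reversal.
#' @param g_k,e_k potassium conductance and reversal.
#' @param g_t,e_t T-type calcium conductance and reversal.
#' @param gating a [gating_functions()] set, or a CETC function set produced by
#'   [build_cetc()].
#'
#' @return Object of class \code{tc_parameters}.
#' @examples
#' p <- tc_parameters()
#' ionic_currents(neuron_state(-65, 0.6, 0.1), p)
#' @export
tc_parameters <- function(c_m = 1, g_l = 0.05, e_l = -70,
                          g_na = 3, e_na = 50, g_k = 5, e_k = -90,
                          g_t = 5, e_t = 0, gating = gating_functions()) {
  stopifnot(c_m > 0, g_l >= 0, g_na >= 0, g_k >= 0, g_t >= 0,
            e_na > e_k)
  membrane <- c(c_m = c_m, g_l = g_l, e_l = e_l, g_na = g_na, e_na = e_na,
                g_k = g_k, e_k = e_k, g_t = g_t, e_t = e_t)
  if (!inherits(gating, c("gating_set", "cetc_set"))) {
    stop("`gating` must be a gating_set or cetc_set")
  }
  structure(list(membrane = membrane, gating = gating),
            class = "tc_parameters")
}

#' @export
print.tc_parameters <- function(x, ...) {
  m <- x$membrane
  cat("<tc_parameters> reduced TC relay neuron\n")
  cat(sprintf("  C_m = %g pF/um^2\n", m[["c_m"]]))
  cat(sprintf("  g_L = %g (E_L = %g)  g_Na = %g (E_Na = %g)\n",
              m[["g_l"]], m[["e_l"]], m[["g_na"]], m[["e_na"]]))
  cat(sprintf("  g_K = %g (E_K = %g)  g_T = %g (E_T = %g)\n",
              m[["g_k"]], m[["e_k"]], m[["g_t"]], m[["e_t"]]))
  cat("  functions:", if (inherits(x$gating, "cetc_set"))
    "piecewise-linear (CETC)" else "closed-form (original)", "\n")
  invisible(x)
}

# Internal: pack parameters into the list the compiled core consumes.
as_cpp_model <- function(params) {
  stopifnot(inherits(params, "tc_parameters"))
  if (inherits(params$gating, "cetc_set")) {
    list(membrane = unname(params$membrane), kind = 1L,
         plf = lapply(params$gating$tables, plf_matrix))
  } else {
    list(membrane = unname(params$membrane), kind = 0L,
         gating = unname(params$gating$par))
  }
}

# Internal: evaluate the model's i-th voltage/h-dependent term f1..f8 through
# the same code path the integrator uses (works for both function sets).
tc_f <- function(params, which, x) {
  .cpp_gating_eval(as_cpp_model(params), as.integer(which), as.numeric(x))
}
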