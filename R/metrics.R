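#' Approximation-error criteria for a linearized function
#'
#' Three criteria compare a linearized (piecewise-linear, "modified") function
#' against the original nonlinear one over \code{M} uniformly spaced sample
#' points on \code{domain}:
#' \describe{
#'   \item{\code{err_cf}}{root-mean-square deviation
#'     \eqn{\sqrt{\frac{1}{M}\sum_i (f_{lin,i}-f_{ori,i})^2}}.}
#'   \item{\code{nerr_cf}}{\code{err_cf} normalized by the range
#'     \eqn{f_{max}-f_{min}} of the modified function, in percent.}
#'   \item{\code{mae_cf}}{mean absolute error
#'     \eqn{\frac{1}{M}\sum_i |f_{lin,i}-f_{ori,i}|}.}
#' }
#' \code{f_lin} and \code{f_ori} may be functions (evaluated on the uniform
#' grid) or numeric vectors of length \code{M} already sampled on it.
#' For any sample set \code{mae_cf <= err_cf} (Jensen).
#'
#' @param f_lin linearized function or sampled values.
#' @param f_ori original function or sampled values.
#' @param domain length-2 interval sampled uniformly.
#' @param M number of sample points (>= 2).
#' @return nonnegative scalar (\code{nerr_cf}: percent).
#' @export
err_cf <- function(f_lin, f_ori, domain = c(-120, 20), M = 1000) {
  s <- sample_pair(f_lin, f_ori, domain, M)
  sqrt(mean((s$lin - s$ori)^2))
}

#' @rdname err_cf
#' @export
nerr_cf <- function(f_lin, f_ori, domain = c(-120, 20), M = 1000) {
  s <- sample_pair(f_lin, f_ori, domain, M)
  rng <- max(s$lin) - min(s$lin)
  if (rng <= 0) stop("nerr_cf: degenerate range (f_max == f_min)")
  100 * sqrt(mean((s$lin - s$ori)^2)) / rng
}

#' @rdname err_cf
#' @export
mae_cf <- function(f_lin, f_ori, domain = c(-120, 20), M = 1000) {
  stopifnot(M >= 1)
  s <- sample_pair(f_lin, f_ori, domain, M, min_M = 1)
  mean(abs(s$lin - s$ori))
}

sample_pair <- function(f_lin, f_ori, domain, M, min_M = 2) {
  stopifnot(M >= min_M)
  x <- seq(domain[1], domain[2], length.out = M)
  as_samples <- function(f) {
    if (is.function(f)) f(x)
    else if (inherits(f, "plf")) plf_evaluate(f, x)
    else {
      stopifnot(length(f) == M)
      as.numeric(f)
    }
  }
  lin <- as_samples(f_lin)
  ori <- as_samples(f_ori)
  stopifnot(all(is.finite(lin)), all(is.finite(ori)))
  list(x = x, lin = lin, ori = ori)
}

#' Root-mean-square estimation error after a burn-in period
#'
#' The estimation-quality statistic used throughout the filtering
#' experiments: \eqn{CF_{rmse} = \sqrt{\frac{1}{n}\sum_i (x_{est,i} -
#' x_{tru,i})^2}} over the samples at or after \code{burn_in_ms}. The burn-in
#' removes the filter's settling transient (default 100 ms), which would
#' otherwise dominate the error of a converged filter.
#'
#' @param estimates,truth numeric series of equal length.
#' @param times sample times in ms (defaults to index-based, i.e. no burn-in
#'   unless \code{burn_in_ms} is in samples).
#' @param burn_in_ms samples with \code{times < burn_in_ms} are discarded.
#' @return nonnegative scalar.
#' @export
cf_rmse <- function(estimates, truth, times = NULL, burn_in_ms = 0) {
  stopifnot(length(estimates) == length(truth))
  keep <- if (is.null(times)) rep(TRUE, length(truth))
          else times >= burn_in_ms
  if (!any(keep)) stop("cf_rmse: no samples remain after burn-in")
  sqrt(mean((estimates[keep] - truth[keep])^2))
}
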