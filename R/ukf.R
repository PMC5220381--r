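#' Cholesky factor with escalating diagonal jitter
#'
#' Lower-triangular \eqn{L} with \eqn{L L^T = P}. If \code{P} is not
#' numerically positive definite, a diagonal jitter starting at 1e-10 and
#' escalating tenfold up to 1e-4 is added before giving up — the covariance
#' repair policy used inside the filter.
#'
#' @param P symmetric matrix.
#' @return lower-triangular matrix; attribute \code{jitter} records the
#'   jitter level used (0 if none).
#' @export
cholesky_factor <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (max(abs(P - t(P))) > 1e-8 * (1 + max(abs(P)))) {
    stop("cholesky_factor: matrix is not symmetric")
  }
  jit <- 0
  repeat {
    L <- tryCatch(t(chol(P + jit * diag(nrow(P)))), error = function(e) NULL)
    if (!is.null(L)) {
      attr(L, "jitter") <- jit
      return(L)
    }
    jit <- if (jit == 0) 1e-10 else jit * 10
    if (jit > 1e-4) stop("cholesky_factor: not factorizable after maximum jitter (filter divergence)")
  }
}

#' Symmetric 2N sigma-point set
#'
#' The filter uses the symmetric sigma set without a central point: the 2N
#' points \eqn{\bar x \pm (\sqrt{N P})_{col\,j}} with equal weights
#' \eqn{1/(2N)} (for the 4-dimensional augmented state this is 8 points —
#' one per parallel model evaluation unit in a hardware realization). The
#' set reproduces the generating mean and covariance exactly.
#'
#' @param mean numeric vector (length N).
#' @param P covariance matrix (N x N, SPD).
#' @return list with \code{points} (2N x N matrix) and \code{weights}.
#' @export
generate_sigma_points <- function(mean, P) {
  N <- length(mean)
  L <- cholesky_factor(P)
  off <- sqrt(N) * L
  pts <- rbind(matrix(mean, N, N, byrow = TRUE) + t(off),
               matrix(mean, N, N, byrow = TRUE) - t(off))
  list(points = pts, weights = rep(1 / (2 * N), 2 * N))
}

#' A priori moments of a transformed sigma set
#'
#' Weighted mean and outer-product scatter of the propagated points, plus
#' additive process noise \code{Q}.
#'
#' @param points matrix of transformed sigma points (rows).
#' @param weights sigma weights.
#' @param Q process-noise covariance (matrix, or scalar expanded to
#'   \code{Q * I}).
#' @return list \code{mean}, \code{cov}.
#' @export
ukf_predict <- function(points, weights, Q = 0) {
  N <- ncol(points)
  if (length(Q) == 1) Q <- diag(Q, N)
  m <- colSums(points * weights)
  d <- sweep(points, 2, m)
  P <- crossprod(d * weights, d) # sum_i w_i d_i d_i^T
  list(mean = m, cov = P + Q)
}

#' Measurement update of the filter
#'
#' Scalar-observation Kalman update: gain \eqn{K = P_{xy}/(P_{yy}+R)},
#' posterior mean \eqn{\bar x + K (y - \hat y)}, posterior covariance
#' \eqn{P - K P_{xy}^T}, re-symmetrized.
#'
#' @param prior_mean,prior_cov a priori moments.
#' @param y_hat predicted observation mean.
#' @param P_xy state-observation cross covariance (vector).
#' @param P_yy predicted observation variance (before adding \code{R}).
#' @param y observed value.
#' @param R observation-noise variance (> 0 together with \code{P_yy}).
#' @return list \code{mean}, \code{cov}, \code{gain}, \code{innovation}.
#' @export
ukf_update <- function(prior_mean, prior_cov, y_hat, P_xy, P_yy, y, R) {
  S <- P_yy + R
  stopifnot(S > 0)
  K <- P_xy / S
  inn <- y - y_hat
  m <- prior_mean + K * inn
  P <- prior_cov - tcrossprod(K, P_xy)
  P <- (P + t(P)) / 2
  list(mean = m, cov = P, gain = K, innovation = inn)
}

#' Generic unscented Kalman filter with a linear scalar observation
#'
#' Reference R implementation of the 2N-sigma-point filter for an arbitrary
#' propagation map \code{f} and observation row \code{C}: used for
#' correctness checks (on linear dynamics this filter is algebraically exact)
#' and as the slow-path oracle for the compiled TC filter.
#'
#' @param obs numeric vector of scalar observations.
#' @param f propagation function: takes a state vector, returns the next one.
#' @param C observation row vector.
#' @param Q process-noise covariance (scalar or matrix).
#' @param R scalar observation variance.
#' @param P0 initial covariance.
#' @param x0 initial mean.
#' @return list with matrices \code{mean} (T x N), \code{cov_diag},
#'   \code{gain}, vector \code{innovation}, and \code{P_final}.
#' @export
ukf_filter <- function(obs, f, C, Q, R, P0, x0) {
  N <- length(x0)
  if (length(Q) == 1) Q <- diag(Q, N)
  x <- x0
  P <- P0
  T_ <- length(obs)
  mean_out <- matrix(NA_real_, T_, N)
  covd_out <- matrix(NA_real_, T_, N)
  gain_out <- matrix(NA_real_, T_, N)
  innov <- numeric(T_)
  for (t in seq_len(T_)) {
    sp <- generate_sigma_points(x, P)
    prop <- t(apply(sp$points, 1, f))
    pr <- ukf_predict(prop, sp$weights, Q)
    # the observation is the linear row C of the state, so the predicted
    # observation moments follow exactly from the a priori moments
    # (including Q) rather than from a second pass over the points
    y_hat <- sum(C * pr$mean)
    P_xy <- as.numeric(pr$cov %*% C)
    P_yy <- as.numeric(t(C) %*% pr$cov %*% C)
    up <- ukf_update(pr$mean, pr$cov, y_hat, P_xy, P_yy, obs[t], R)
    x <- up$mean
    P <- up$cov
    mean_out[t, ] <- x
    covd_out[t, ] <- diag(P)
    gain_out[t, ] <- up$gain
    innov[t] <- up$innovation
  }
  list(mean = mean_out, cov_diag = covd_out, gain = gain_out,
       innovation = innov, P_final = P)
}

#' Filter configuration for TC hidden-property estimation
#'
#' @param Q process-noise covariance: a scalar or a full 4x4 matrix. A
#'   scalar expands to \code{diag(Q, Q, 0, 1e-8)}: process noise drives the
#'   random-walk parameter \eqn{I_{ext}} and absorbs model error in the
#'   voltage equation; the fast sodium gate is slaved to voltage and gets
#'   none (injecting white noise into the weakly observable gates directly
#'   inflates hidden-state error), while the slow calcium gate carries a
#'   small fixed regularization floor that keeps its marginal variance
#'   alive. Default 5e-5, the operating point used for the square-wave
#'   estimation studies.
#' @param R observation-noise variance (mV^2), default 5.
#' @param P0 initial covariance (4x4 SPD), default identity.
#' @param x0 initial augmented state \code{[I_ext, V, h, w]}; default
#'   \code{c(0, first observation, 0.5, 0.1)}.
#' @param dt model/observation time step (ms).
#' @param model the filter's internal [tc_parameters()]; defaults to the
#'   cost-efficient (CETC) function set built from the default constants —
#'   the model a hardware realization would run. May differ from the plant.
#' @param clamp_gates clamp the gate components of sigma points to [0, 1].
#' @return Object of class \code{ukf_config}.
#' @export
ukf_config <- function(Q = 5e-5, R = 5, P0 = diag(4), x0 = NULL, dt = 0.01,
                       model = NULL, clamp_gates = TRUE) {
  if (length(Q) == 1) {
    Q <- diag(c(Q, Q, 0, 0))
    Q[4, 4] <- 1e-8
  }
  stopifnot(identical(dim(Q), c(4L, 4L)), identical(dim(P0), c(4L, 4L)),
            R > 0, max(abs(Q - t(Q))) < 1e-12, max(abs(P0 - t(P0))) < 1e-12)
  if (is.null(model)) model <- default_cetc_params()
  structure(list(Q = Q, R = R, P0 = P0, x0 = x0, dt = dt, model = model,
                 clamp_gates = clamp_gates),
            class = "ukf_config")
}

# default CETC filter model, built once per session
default_cetc_params <- function() {
  if (is.null(.model_cache$cetc)) {
    .model_cache$cetc <- build_cetc(tc_parameters())
  }
  .model_cache$cetc
}
.model_cache <- new.env(parent = emptyenv())

#' Estimate TC hidden properties from a noisy voltage series
#'
#' Runs the joint state/parameter unscented Kalman filter over the augmented
#' state \eqn{x = [I_{ext}, V, h, w]}: the injected current is carried as a
#' random-walk parameter, \eqn{(V, h, w)} advance one forward-Euler step of
#' the filter's internal model per observation (each sigma point driven by
#' its own \eqn{I_{ext}}), and the observation row \eqn{C = [0\,1\,0\,0]}
#' selects the membrane potential. One predict/update cycle is performed per
#' observation sample.
#'
#' @param obs noisy voltage observations (mV), uniformly sampled at
#'   \code{config$dt}, or an observation object from [contaminate()].
#' @param config a [ukf_config()].
#' @return Object of class \code{estimate_trace}: a data.frame with columns
#'   \code{time_ms, Iext_hat, V_hat, h_hat, w_hat, innovation}; posterior
#'   covariance diagonals and Kalman gains are attached as attributes
#'   \code{cov_diag} and \code{gain}.
#' @export
ukf_estimate <- function(obs, config = ukf_config()) {
  stopifnot(inherits(config, "ukf_config"))
  if (inherits(obs, "tc_observation")) obs <- obs$V_obs
  obs <- as.numeric(obs)
  x0 <- config$x0 %||% c(0, obs[1], 0.5, 0.1)
  res <- .cpp_ukf(as_cpp_model(config$model), obs, config$dt, config$Q,
                  config$R, config$P0, as.numeric(x0), config$clamp_gates)
  out <- data.frame(time_ms = seq(0, by = config$dt,
                                  length.out = length(obs)),
                    Iext_hat = res$mean[, 1], V_hat = res$mean[, 2],
                    h_hat = res$mean[, 3], w_hat = res$mean[, 4],
                    innovation = res$innovation)
  structure(out, cov_diag = res$cov_diag, gain = res$gain,
            P_final = res$P_final, config = config,
            class = c("estimate_trace", "data.frame"))
}

#' @export
print.estimate_trace <- function(x, ...) {
  cat(sprintf("<estimate_trace> %d steps, dt = %g ms\n",
              nrow(x), attr(x, "config")$dt))
  cat(sprintf("  final estimate: Iext = %.3f, V = %.2f, h = %.3f, w = %.3f\n",
              x$Iext_hat[nrow(x)], x$V_hat[nrow(x)], x$h_hat[nrow(x)],
              x$w_hat[nrow(x)]))
  invisible(x)
}
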