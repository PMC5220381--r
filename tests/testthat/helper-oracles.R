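# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (plain scalar loops, textbook formulas).

# textbook Kalman filter for x' = A x + w, y = C x + v, scalar observation
kalman_filter_linear <- function(obs, A, C, Q, R, P0, x0) {
  n <- length(x0)
  x <- x0
  P <- P0
  out <- matrix(NA_real_, length(obs), n)
  for (t in seq_along(obs)) {
    xp <- as.numeric(A %*% x)
    Pp <- A %*% P %*% t(A) + Q
    PC <- as.numeric(Pp %*% C)
    S <- sum(C * PC) + R
    K <- PC / S
    x <- xp + K * (obs[t] - sum(C * xp))
    P <- Pp - tcrossprod(K, PC)
    P <- (P + t(P)) / 2
    out[t, ] <- x
  }
  out
}

# scalar-loop RMS / MAE over a uniform grid (oracle for the error criteria)
rms_loop <- function(f_lin, f_ori, domain, M) {
  x <- seq(domain[1], domain[2], length.out = M)
  acc <- 0
  for (i in seq_len(M)) acc <- acc + (f_lin(x[i]) - f_ori(x[i]))^2
  sqrt(acc / M)
}
mae_loop <- function(f_lin, f_ori, domain, M) {
  x <- seq(domain[1], domain[2], length.out = M)
  acc <- 0
  for (i in seq_len(M)) acc <- acc + abs(f_lin(x[i]) - f_ori(x[i]))
  acc / M
}

# brute-force per-point segment lookup for a piecewise-linear object
plf_bruteforce <- function(plf, x) {
  sapply(x, function(v) {
    vc <- min(max(v, plf$domain[1]), plf$domain[2])
    j <- NA
    for (i in rev(seq_along(plf$K))) {
      if (vc >= plf$lo[i]) { j <- i; break }
    }
    plf$K[j] * vc + plf$C[j]
  })
}

# closed-form default gating maps written out independently of the package
ref_gating <- list(
  m_inf = function(v) 1 / (1 + exp(-(v + 37) / 7)),
  h_inf = function(v) 1 / (1 + exp((v + 41) / 4)),
  p_inf = function(v) 1 / (1 + exp(-(v + 60) / 6.2)),
  w_inf = function(v) 1 / (1 + exp((v + 84) / 4)),
  a_h = function(v) 0.128 * exp(-(v + 46) / 18),
  b_h = function(v) 4 / (1 + exp(-(v + 23) / 5)),
  tau_w = function(v) 0.15 * (28 + exp(-(v + 25) / 10.5))
)

# hand computation of the four membrane currents at a state (default params)
ref_currents <- function(v, h, w) {
  c(I_L = 0.05 * (v + 70),
    I_Na = 3 * ref_gating$m_inf(v)^3 * h * (v - 50),
    I_K = 5 * (1 * (1 - h))^4 * (v + 90),
    I_T = 5 * ref_gating$p_inf(v)^2 * w * (v - 0))
}
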