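test_that("cholesky_factor reproduces known factors and repairs near-SPD", {
  expect_equal(cholesky_factor(diag(4)), diag(4), ignore_attr = TRUE)
  L <- cholesky_factor(matrix(c(4, 2, 2, 5), 2))
  expect_equal(L, matrix(c(2, 1, 0, 2), 2), ignore_attr = TRUE)
  expect_equal(L %*% t(L), matrix(c(4, 2, 2, 5), 2), ignore_attr = TRUE)
  set.seed(5)
  A <- matrix(rnorm(16), 4)
  P <- crossprod(A) + diag(4)
  L4 <- cholesky_factor(P)
  expect_lt(max(abs(L4 %*% t(L4) - P)), 1e-10)
  # a singular PSD matrix factors after jitter
  S <- tcrossprod(c(1, 1, 0, 0))
  Lj <- cholesky_factor(S)
  expect_gt(attr(Lj, "jitter"), 0)
  expect_error(cholesky_factor(matrix(c(1, 2, 3, 4), 2)), "symmetric")
  expect_error(cholesky_factor(-diag(3)), "jitter")
})

test_that("sigma sets reproduce their generating moments exactly", {
  s1 <- generate_sigma_points(0, matrix(1))
  expect_setequal(as.numeric(s1$points), c(1, -1))
  # diagonal covariance: axis offsets are +/- sqrt(N * a_i)
  P <- diag(c(1, 4, 9, 16))
  s4 <- generate_sigma_points(rep(0, 4), P)
  expect_equal(sort(abs(s4$points[s4$points != 0])),
               sort(rep(sqrt(4 * c(1, 4, 9, 16)), 2)))
  # moment reconstruction for random SPD inputs
  set.seed(6)
  for (rep in 1:5) {
    A <- matrix(rnorm(16), 4)
    P <- crossprod(A) + 0.5 * diag(4)
    m <- rnorm(4)
    s <- generate_sigma_points(m, P)
    expect_equal(sum(s$weights), 1)
    expect_equal(colSums(s$points * s$weights), m, tolerance = 1e-10)
    d <- sweep(s$points, 2, m)
    expect_equal(crossprod(d * s$weights, d), P, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("predict and update behave at their degenerate limits", {
  pts <- matrix(rep(c(1, 2, 3, 4), each = 8), 8)
  w <- rep(1 / 8, 8)
  pr0 <- ukf_predict(pts, w, Q = 0)
  expect_equal(pr0$mean, c(1, 2, 3, 4))
  expect_equal(pr0$cov, matrix(0, 4, 4))
  expect_equal(ukf_predict(pts, w, Q = 0.3)$cov, diag(0.3, 4))
  # random set vs loop recomputation
  set.seed(8)
  pts2 <- matrix(rnorm(32), 8)
  pr <- ukf_predict(pts2, w, Q = 0)
  mref <- colMeans(pts2)
  Cref <- matrix(0, 4, 4)
  for (i in 1:8) Cref <- Cref + tcrossprod(pts2[i, ] - mref) / 8
  expect_equal(pr$mean, mref)
  expect_equal(pr$cov, Cref)
  # zero innovation leaves the mean; R -> Inf kills the gain
  up <- ukf_update(c(1, 2), diag(2), y_hat = 2, P_xy = c(0.5, 1),
                   P_yy = 1, y = 2, R = 1)
  expect_equal(up$mean, c(1, 2))
  up2 <- ukf_update(c(1, 2), diag(2), 2, c(0.5, 1), 1, y = 10, R = 1e12)
  expect_equal(up2$mean, c(1, 2), tolerance = 1e-9)
  # scalar linear system: gain equals the textbook p/(p + R)
  up3 <- ukf_update(0, matrix(2), 0, 2, 2, y = 1, R = 3)
  expect_equal(up3$gain, 2 / 5)
  expect_equal(up3$mean, 2 / 5, ignore_attr = TRUE)
})

test_that("the sigma-point filter matches an exact Kalman filter on a
           linear-Gaussian system", {
  set.seed(42)
  A <- matrix(c(0.9, 0.1, 0, 0,
                -0.05, 0.95, 0.1, 0,
                0, -0.1, 0.9, 0.05,
                0, 0, 0.1, 0.85), 4, 4, byrow = TRUE)
  C <- c(0, 1, 0, 0)
  Q <- diag(0.01, 4); R <- 0.5; P0 <- diag(4); x0 <- c(1, 0, -1, 0.5)
  x <- x0
  obs <- numeric(1000)
  for (t in seq_along(obs)) {
    x <- A %*% x + rnorm(4, 0, 0.1)
    obs[t] <- x[2] + rnorm(1, 0, sqrt(R))
  }
  ukf <- ukf_filter(obs, function(s) as.numeric(A %*% s), C, Q, R, P0, x0)
  kf <- kalman_filter_linear(obs, A, C, Q, R, P0, x0)
  expect_lt(max(abs(ukf$mean - kf)), 1e-6)
})

test_that("the compiled TC filter equals the reference R filter", {
  set.seed(7)
  p <- tc_parameters()
  cfg <- ukf_config(Q = 5e-5, R = 5, model = p, clamp_gates = FALSE)
  tr <- simulate_tc(p, gpi_spec("normal"), stimulus_spec("square_wave"),
                    duration = 3)
  obs <- tr$V_mV + rnorm(nrow(tr))
  est <- ukf_estimate(obs, cfg)
  dt <- 0.01
  fprop <- function(s) {
    d <- tc_derivatives(c(s[2], s[3], s[4]), s[1], 0, p)
    c(s[1], s[2] + dt * d[[1]],
      min(max(s[3] + dt * d[[2]], 0), 1),
      min(max(s[4] + dt * d[[3]], 0), 1))
  }
  ref <- ukf_filter(obs, fprop, c(0, 1, 0, 0), cfg$Q, cfg$R, diag(4),
                    c(0, obs[1], 0.5, 0.1))
  expect_lt(max(abs(as.matrix(est[, 2:5]) - ref$mean)), 1e-9)
  expect_lt(max(abs(est$innovation - ref$innovation)), 1e-9)
  # posterior covariances stay symmetric PSD
  expect_true(all(attr(est, "cov_diag") > -1e-8))
  expect_equal(attr(est, "P_final"), t(attr(est, "P_final")))
  expect_gte(min(eigen(attr(est, "P_final"))$values), -1e-8)
})

test_that("a matched noiseless filter locks onto the trajectory", {
  p <- tc_parameters()
  tr <- simulate_tc(p, gpi_spec("normal"), stimulus_spec("none"),
                    duration = 200)
  init <- rest_state(p)
  cfg <- ukf_config(Q = 0 * diag(4), R = 1e-4, model = p,
                    x0 = c(0, init[["V"]], init[["h"]], init[["w"]]),
                    P0 = 1e-6 * diag(4))
  est <- ukf_estimate(tr$V_mV, cfg)
  expect_lt(cf_rmse(est$V_hat, tr$V_mV), 1e-3)
  expect_lt(cf_rmse(est$h_hat, tr$h), 1e-3)
  expect_lt(cf_rmse(est$w_hat, tr$w), 1e-3)
})

test_that("cf_rmse matches its definition and burn-in semantics", {
  expect_equal(cf_rmse(1:10, 1:10), 0)
  expect_equal(cf_rmse(1:10 + 2, 1:10), 2)
  set.seed(9)
  a <- rnorm(500); b <- rnorm(500)
  expect_equal(cf_rmse(a, b), sqrt(sum((a - b)^2) / 500))
  tms <- seq(0, 499)
  expect_equal(cf_rmse(a, b, tms, burn_in_ms = 100),
               sqrt(mean((a[101:500] - b[101:500])^2)))
  expect_error(cf_rmse(a, b, tms, burn_in_ms = 1000), "burn-in")
})

test_that("a piecewise-constant injected current is recovered per plateau", {
  p <- tc_parameters()
  dt <- 0.01
  times <- seq(0, 1000, by = dt)
  i_true <- ifelse(times < 500, 0.5, -1)
  init <- rest_state(p)
  sts <- thalatrack:::.cpp_simulate(thalatrack:::as_cpp_model(p), i_true,
                                    as.numeric(init), dt)
  set.seed(10)
  obs <- sts[, 1] + rnorm(length(times), 0, 1)
  # matched internal model isolates parameter recovery from reduction bias
  est <- ukf_estimate(obs, ukf_config(Q = 5e-4, R = 5, model = p))
  seg1 <- times >= 300 & times < 500
  seg2 <- times >= 800
  expect_lt(abs(mean(est$Iext_hat[seg1]) - 0.5), 0.5)
  expect_lt(abs(mean(est$Iext_hat[seg2]) + 1), 0.5)
})
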