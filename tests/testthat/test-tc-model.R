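test_that("ionic currents vanish at reversal potentials and closed gates", {
  p <- tc_parameters(g_na = 0, g_k = 0, g_t = 0)
  cur <- ionic_currents(neuron_state(-70, 0.5, 0.5), p) # V = E_L
  expect_equal(unname(cur), c(0, 0, 0, 0))
  # h = 1 closes the potassium pathway (f3 is a power of 1 - h)
  p2 <- tc_parameters()
  cur2 <- ionic_currents(neuron_state(-55, 1, 0.2), p2)
  expect_equal(cur2[["I_K"]], 0)
  expect_error(ionic_currents(structure(c(V = NaN, h = 0.5, w = 0.5),
                                        class = "neuron_state"),
                              p2), "non-finite")
})

test_that("ionic currents match an independent hand computation", {
  p <- tc_parameters()
  v <- -65
  h <- ref_gating$h_inf(v)
  w <- ref_gating$w_inf(v)
  got <- ionic_currents(neuron_state(v, h, w), p)
  expect_equal(unname(got), unname(ref_currents(v, h, w)), tolerance = 1e-12)
  # and at a depolarized, mid-gate state
  got2 <- ionic_currents(neuron_state(-30, 0.3, 0.6), p)
  expect_equal(unname(got2), unname(ref_currents(-30, 0.3, 0.6)),
               tolerance = 1e-12)
})

test_that("derivatives vanish at gate equilibria and match closed forms", {
  p <- tc_parameters()
  v <- -58
  a <- ref_gating$a_h(v)
  b <- ref_gating$b_h(v)
  st <- neuron_state(v, a / (a + b), ref_gating$w_inf(v))
  d <- tc_derivatives(st, 0, 0, p)
  expect_equal(d[["dh"]], 0, tolerance = 1e-14)
  expect_equal(d[["dw"]], 0, tolerance = 1e-14)
  # full triple against independent evaluation
  st2 <- neuron_state(-50, 0.4, 0.2)
  d2 <- tc_derivatives(st2, 0, 0, p)
  cur <- ref_currents(-50, 0.4, 0.2)
  expect_equal(d2[["dV"]], -sum(cur), tolerance = 1e-12)
  expect_equal(d2[["dh"]], a_ <- ref_gating$a_h(-50) * 0.6 -
                 ref_gating$b_h(-50) * 0.4, tolerance = 1e-12)
  expect_equal(d2[["dw"]], (ref_gating$w_inf(-50) - 0.2) /
                 ref_gating$tau_w(-50), tolerance = 1e-12)
  # the applied currents enter with opposite roles
  d3 <- tc_derivatives(st2, -1, 5, p)
  expect_equal(d3[["dV"]] - d2[["dV"]], 4, tolerance = 1e-12)
})

test_that("euler_step is the forward-Euler update with gate clamping", {
  p <- tc_parameters()
  st <- neuron_state(-60, 0.5, 0.1)
  d <- tc_derivatives(st, 0, 0, p)
  stepped <- euler_step(st, 0, 0, 0.01, p)
  expect_equal(stepped[["V"]], st[["V"]] + 0.01 * d[["dV"]])
  expect_equal(stepped[["h"]], st[["h"]] + 0.01 * d[["dh"]])
  expect_equal(stepped[["w"]], st[["w"]] + 0.01 * d[["dw"]])
  # chaining two steps equals a two-iteration reference loop
  ref <- c(-60, 0.5, 0.1)
  for (k in 1:2) {
    dv <- tc_derivatives(ref, 0, 2, p)
    ref <- ref + 0.01 * c(dv[["dV"]], dv[["dh"]], dv[["dw"]])
  }
  two <- euler_step(euler_step(st, 0, 2, 0.01, p), 0, 2, 0.01, p)
  expect_equal(unname(unclass(two)), ref, tolerance = 1e-12)
})

test_that("square-wave stimulus has the stated period, duty and amplitude", {
  spec <- stimulus_spec("square_wave", rho_sm = 25, delta_sm = 5, i_sm = 5)
  expect_equal(sm_square_wave(2, spec), 5)
  expect_equal(sm_square_wave(10, spec), 0)
  expect_equal(sm_square_wave(27, spec), 5) # second period, offset 2
  # duty ratio over a fine grid is 20%
  tt <- seq(0, 250 - 0.01, by = 0.01)
  expect_equal(mean(sm_square_wave(tt, spec) > 0), 0.2, tolerance = 1e-3)
})

test_that("gamma pulse train has the stated rate and interval CV", {
  spec <- stimulus_spec("gamma_pulse_train", rate = 30, cv = 0.2,
                        i_sm = 5, delta_sm = 5)
  set.seed(11)
  s <- sm_gamma_pulse_train(spec, duration = 1e5, dt = 0.05)
  onsets <- which(diff(c(0, s > 0)) == 1) * 0.05
  iv <- diff(onsets)
  expect_equal(mean(iv), 1000 / 30, tolerance = 0.05)
  expect_equal(sd(iv) / mean(iv), 0.2, tolerance = 0.15)
  # determinism and the zero-amplitude degenerate case
  set.seed(4); a <- sm_gamma_pulse_train(spec, 1000, 0.01)
  set.seed(4); b <- sm_gamma_pulse_train(spec, 1000, 0.01)
  expect_identical(a, b)
  spec0 <- stimulus_spec("gamma_pulse_train", rate = 30, cv = 0.2, i_sm = 0)
  set.seed(4)
  expect_true(all(sm_gamma_pulse_train(spec0, 1000, 0.01) == 0))
})

test_that("steady-state current table uses voltage-pinned gates", {
  p <- tc_parameters()
  grid <- seq(-110, 10, length.out = 1000)
  tab <- steady_state_currents(grid, p)
  # independent scalar-loop recomputation
  for (i in c(1, 250, 500, 999)) {
    v <- grid[i]
    ref <- ref_currents(v, ref_gating$h_inf(v), ref_gating$w_inf(v))
    expect_equal(unlist(tab[i, c("I_L", "I_Na", "I_K", "I_T")]),
                 ref, tolerance = 1e-10, ignore_attr = TRUE)
  }
  # I_K is ~0 where h_inf ~ 1 (deep hyperpolarization)
  expect_lt(abs(tab$I_K[1]), 1e-6)
})

test_that("spike detection counts programmed crossings and merges doublets", {
  flat <- data.frame(time_ms = seq(0, 99, 1), V_mV = rep(-60, 100))
  expect_length(detect_spikes(flat), 0)
  tri <- data.frame(time_ms = seq(0, 20, 0.1),
                    V_mV = -60 + 50 * pmax(0, 1 - abs(seq(0, 20, 0.1) - 10) / 3))
  expect_length(detect_spikes(tri), 1)
  tt <- seq(0, 100, 0.1)
  v <- rep(-60, length(tt))
  for (ct in c(20, 50, 80)) v[abs(tt - ct) < 1] <- 0
  expect_equal(detect_spikes(data.frame(time_ms = tt, V_mV = v)),
               c(20, 50, 80) - 0.9, tolerance = 0.2)
  # two crossings inside the merge window count once
  v2 <- rep(-60, length(tt))
  v2[abs(tt - 20) < 0.4] <- 0
  v2[abs(tt - 21) < 0.4] <- 0
  expect_length(detect_spikes(data.frame(time_ms = tt, V_mV = v2)), 1)
})

test_that("gates stay in [0,1] and the rest state is an equilibrium", {
  p <- tc_parameters()
  tr <- simulate_tc(p, gpi_spec("parkinsonian"),
                    stimulus_spec("square_wave"), duration = 500)
  expect_true(all(tr$h >= 0 & tr$h <= 1))
  expect_true(all(tr$w >= 0 & tr$w <= 1))
  expect_true(all(is.finite(tr$V_mV)))
  st <- rest_state(p)
  d <- tc_derivatives(st, 0, 0, p)
  expect_lt(sqrt(sum(d^2)), 1e-6)
})

test_that("halving dt shrinks the trace difference (first-order integrator)", {
  p <- tc_parameters()
  init <- rest_state(p)
  sim <- function(dt) simulate_tc(p, gpi_spec("normal"),
                                  stimulus_spec("constant", i_sm = 1),
                                  duration = 50, dt = dt, init = init)
  t1 <- sim(0.02)
  t2 <- sim(0.01)
  t3 <- sim(0.005)
  # compare on the coarse grid (subthreshold drive: errors are smooth)
  e12 <- max(abs(t1$V_mV - t2$V_mV[seq(1, nrow(t2), 2)]))
  e23 <- max(abs(t2$V_mV[seq(1, nrow(t2), 2)] -
                   t3$V_mV[seq(1, nrow(t3), 4)]))
  expect_lt(e23, e12)
  expect_equal(e12 / e23, 2, tolerance = 0.5)
})

test_that("normal mode relays pulses as single spikes; parkinsonian bursts", {
  p <- tc_parameters()
  rho <- 25
  trn <- simulate_tc(p, gpi_spec("normal"), stimulus_spec("square_wave"),
                     duration = 1000)
  sp <- detect_spikes(trn)
  onsets <- seq(0, 1000 - rho, by = rho)
  per_pulse <- sapply(onsets, function(o) sum(sp >= o & sp < o + rho))
  expect_gte(mean(per_pulse == 1), 0.9)
  trp <- simulate_tc(p, gpi_spec("parkinsonian"),
                     stimulus_spec("square_wave"), duration = 1000)
  spp <- detect_spikes(trp)
  grp <- cumsum(c(1, diff(spp) > 25))
  expect_gte(sum(table(grp) >= 2), 1) # burst events: >=2 spikes within 25 ms
})
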