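test_that("piecewise-linear evaluation: identity, tie-break, brute force", {
  ident <- piecewise_linear(slopes = 1, intercepts = 0, domain = c(-10, 10))
  expect_equal(plf_evaluate(ident, c(-3, 0, 7.5)), c(-3, 0, 7.5))
  # a breakpoint query resolves to the right-hand segment
  steps <- piecewise_linear(slopes = c(0, 0), intercepts = c(0, 1),
                            breakpoints = 0, domain = c(-10, 10),
                            check_continuity = FALSE)
  expect_equal(plf_evaluate(steps, 0), 1)
  expect_equal(plf_evaluate(steps, -1e-9), 0)
  # random 5-segment function against a per-point segment search
  set.seed(2)
  kn <- sort(runif(4, -90, 0))
  sl <- rnorm(5)
  plf <- piecewise_linear(sl, intercepts = 0.3, breakpoints = kn,
                          domain = c(-120, 20))
  x <- runif(100, -130, 30) # includes out-of-domain clamping
  expect_equal(plf_evaluate(plf, x), plf_bruteforce(plf, x))
  # discontinuous coefficient sets are rejected
  expect_error(piecewise_linear(c(1, 1), c(0, 5), breakpoints = 0,
                                domain = c(-1, 1)), "discontinuity")
})

test_that("shift-add slope quantization is exact for representable values", {
  q <- quantize_slope(0.75)
  expect_identical(q$value, 0.75) # 2^-1 + 2^-2
  expect_length(q$shifts, 2)
  expect_identical(quantize_slope(1)$value, 1)
  expect_length(quantize_slope(1)$shifts, 1)
  expect_identical(quantize_slope(0)$value, 0)
  # k = 0.3 against exhaustive enumeration over <= 3 terms
  shifts <- -8:3
  vals <- 0
  for (n in 1:3) {
    combs <- combn(length(shifts), n)
    for (j in seq_len(ncol(combs))) {
      pw <- 2^shifts[combs[, j]]
      sgn <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
      vals <- c(vals, as.numeric(sgn %*% pw))
    }
  }
  best <- min(abs(vals - 0.3))
  got <- quantize_slope(0.3, max_terms = 3, shift_range = c(-8, 3))
  expect_equal(abs(got$value - 0.3), best, tolerance = 1e-14)
  # reconstruction from the stored terms is bit-exact
  expect_identical(sum(got$signs * 2^got$shifts), got$value)
})

test_that("error criteria match definitions and an independent loop", {
  f <- function(x) sin(x / 20)
  g <- function(x) sin(x / 20) + 0.25
  dom <- c(-120, 20)
  expect_equal(err_cf(f, f, dom, 100), 0)
  expect_equal(err_cf(g, f, dom, 100), 0.25)
  expect_equal(mae_cf(g, f, dom, 100), 0.25)
  # offset on a function of range ~2 -> NERR = 100 * 0.25 / range
  x <- seq(dom[1], dom[2], length.out = 1000)
  expect_equal(nerr_cf(g, f, dom, 1000),
               100 * 0.25 / (max(g(x)) - min(g(x))))
  expect_error(nerr_cf(function(x) 0 * x, function(x) 0 * x, dom, 10),
               "degenerate")
  # arbitrary pair vs scalar-loop oracle
  h1 <- function(x) exp(x / 60) * cos(x / 15)
  h2 <- function(x) exp(x / 60)
  expect_equal(err_cf(h1, h2, dom, 1000), rms_loop(h1, h2, dom, 1000))
  expect_equal(mae_cf(h1, h2, dom, 1000), mae_loop(h1, h2, dom, 1000))
  # MAE <= RMS always
  expect_lte(mae_cf(h1, h2, dom, 1000), err_cf(h1, h2, dom, 1000))
})

test_that("fit_piecewise recovers exactly representable shapes", {
  lin <- fit_piecewise(function(x) 0.5 * x + 0.1, c(-4, 4), n_segments = 1)
  expect_equal(unname(lin$K), 0.5)
  expect_lt(attr(lin, "err_cf"), 1e-12)
  vee <- fit_piecewise(abs, c(-1, 1), n_segments = 2)
  expect_lt(attr(vee, "err_cf"), 1e-9)
  expect_setequal(round(vee$K, 6), c(-1, 1))
})

test_that("refining the fit never increases the RMS error", {
  sig <- function(x) 1 / (1 + exp(-x))
  errs <- sapply(c(1, 2, 4, 8, 12), function(n)
    attr(fit_piecewise(sig, c(-10, 10), n_segments = n), "err_cf"))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[4], errs[1]) # 8 segments strictly beat 1 on a sigmoid
})

test_that("fitted slopes always admit their shift-add budget", {
  f <- function(x) 1 / (1 + exp(-(x + 60) / 6.2))^2
  plf <- fit_piecewise(f, c(-120, 20), n_segments = 8)
  for (i in seq_along(plf$K)) {
    sa <- plf$shift_add[[i]]
    expect_lte(length(sa$shifts), 3)
    expect_identical(sum(sa$signs * 2^sa$shifts), unname(plf$K[i]))
  }
})

test_that("the CETC set approximates all eight functions below 2% NERR", {
  cet <- build_cetc(tc_parameters())
  rep_ <- approximation_report(cet)
  expect_identical(rep_$fn, paste0("f", 1:8))
  expect_true(all(rep_$err_cf >= 0 & rep_$mae >= 0))
  expect_true(all(rep_$mae <= rep_$err_cf))
  expect_lte(mean(rep_$nerr_cf_pct), 2.0)
  # shift-add exactness of every stored slope
  for (tab in cet$gating$tables) {
    for (i in seq_along(tab$K)) {
      sa <- tab$shift_add[[i]]
      expect_identical(sum(sa$signs * 2^sa$shifts), unname(tab$K[i]))
    }
  }
})

test_that("explicit coefficient tables round-trip and give a zero-error set", {
  cet <- build_cetc(tc_parameters())
  csv <- tempfile(fileext = ".csv")
  write_plf_tables(cet, csv)
  tab <- read_plf_tables(csv)
  cet2 <- build_cetc(tc_parameters(), tables = tab)
  # rebuilt from its own tables: identical function values
  x <- seq(-119, 19, length.out = 200)
  for (i in c(1, 4, 7, 8)) {
    expect_equal(plf_evaluate(cet2$gating$tables[[i]], x),
                 plf_evaluate(cet$gating$tables[[i]], x), tolerance = 1e-12)
  }
  bad <- tab[tab$function_name != "f5", ]
  expect_error(build_cetc(tc_parameters(), tables = bad), "f5")
})

test_that("CETC preserves the original dynamics within stated thresholds", {
  p <- tc_parameters()
  cet <- build_cetc(p)
  sm <- stimulus_spec("square_wave")
  tr_o <- simulate_tc(p, gpi_spec("normal"), sm, duration = 500)
  tr_c <- simulate_tc(cet, gpi_spec("normal"), sm, duration = 500)
  expect_identical(length(detect_spikes(tr_o)), length(detect_spikes(tr_c)))
  # per-variable RMS deviation on a 10,000-sample window; pointwise RMS is
  # dominated by sub-ms spike-timing jitter, hence the wide V threshold
  a <- simulate_tc(p, gpi_spec("normal"), sm, duration = 100)
  b <- simulate_tc(cet, gpi_spec("normal"), sm, duration = 100)
  expect_lt(cf_rmse(b$V_mV, a$V_mV), 20)
  expect_lt(cf_rmse(b$h, a$h), 0.2)
  expect_lt(cf_rmse(b$w, a$w), 0.05)
  # Parkinsonian-mode deviations may exceed normal-mode ones (burst timing
  # is more sensitive); the thresholds are correspondingly wider
  ap <- simulate_tc(p, gpi_spec("parkinsonian"), sm, duration = 100)
  bp <- simulate_tc(cet, gpi_spec("parkinsonian"), sm, duration = 100)
  expect_lt(cf_rmse(bp$V_mV, ap$V_mV), 25)
  expect_lt(cf_rmse(bp$h, ap$h), 0.3)
  expect_lt(cf_rmse(bp$w, ap$w), 0.3)
})
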