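test_that("the substitution equation reproduces its worked examples", {
  expect_equal(substitution_velocity(0, 8e-3), 1500)
  # printed lags are rounded to 3 significant figures, hence the 0.2% band
  expect_equal(substitution_velocity(-2.79e-6, 8e-3, 1500), 3147,
               tolerance = 2e-3)
  expect_equal(substitution_velocity(-1.72e-6, 8e-3, 1500), 2211,
               tolerance = 2e-3)
  # exact back-substitution values
  expect_equal(substitution_velocity(-2.79e-6, 8e-3, 1500), 3145.478,
               tolerance = 1e-6)
  expect_equal(substitution_velocity(-1.72e-6, 8e-3, 1500), 2214.022,
               tolerance = 1e-6)
  expect_error(substitution_velocity(-6e-6, 8e-3, 1500), "nonphysical")
})

test_that("the substitution equation is monotone and self-inverse", {
  dts <- seq(-2e-6, 4e-6, length.out = 50)
  v <- substitution_velocity(dts, 8e-3)
  expect_true(all(diff(v) < 0))          # strictly decreasing in delta_t
  for (V in c(1001, 1450, 2211, 3514, 3999)) {
    dt_V <- 8e-3 / V - 8e-3 / 1500
    expect_equal(substitution_velocity(dt_V, 8e-3, 1500), V)
  }
})

test_that("the Hilbert envelope recovers amplitude modulation", {
  dt <- 1e-8
  t <- (0:4095) * dt
  s <- sin(2 * pi * 5e6 * t)
  env <- envelope(s)
  mid <- 500:3500
  expect_lt(max(abs(env[mid] - 1)), 0.02)         # constant for a pure tone
  A <- 1 + 0.5 * sin(2 * pi * 2e5 * t)
  env2 <- envelope(A * sin(2 * pi * 5e6 * t))
  expect_lt(max(abs(env2[mid] - A[mid]) / A[mid]), 0.02)
  expect_equal(envelope(numeric(128)), numeric(128))
  expect_true(all(envelope(s) >= abs(s) - 1e-9))  # envelope bounds the signal
})

test_that("group delay recovers exact and sub-sample shifts", {
  dt <- 1e-9
  tp <- derive_time_params(0.1, 5e-5, 1500, 4e-6)
  s <- make_source_signal("single_cycle", 2e6, tp)
  s <- c(numeric(800), s[1:(length(s) - 800)])    # keep support interior
  same <- group_delay(s, s, dt)
  expect_equal(same$delta_t, 0)
  expect_equal(same$peak_correlation, 1)
  shifted <- c(numeric(25), s[1:(length(s) - 25)])
  est <- group_delay(shifted, s, dt)
  expect_equal(est$delta_t, 25 * dt)              # integer lag is exact
  expect_equal(est$peak_correlation, 1, tolerance = 1e-9)
  expect_error(group_delay(numeric(512), s[1:512], dt), "zero-variance")
})

test_that("phase delay recovers a pure spectral delay at any carrier", {
  tp <- derive_time_params(0.1, 5e-5, 1500, 2e-5)
  ref <- make_source_signal("single_cycle", 500e3, tp)
  ref <- delay_signal(ref, tp$dt, 3e-6)           # causal margin
  tau <- 1.2345e-6
  sig <- delay_signal(ref, tp$dt, tau)
  for (fc in c(2.5e5, 5e5, 7.5e5)) {
    est <- phase_delay(sig, ref, tp$dt, fc)
    expect_equal(est$delta_t, tau, tolerance = 1e-6)
  }
  expect_equal(phase_delay(ref, ref, tp$dt, 5e5)$delta_t, 0)
  expect_error(phase_delay(sig, ref, tp$dt, 1e12), "resolvable")
  # group and phase estimators agree on a delayed copy
  g <- group_delay(sig, ref, tp$dt)
  p <- phase_delay(sig, ref, tp$dt, 5e5)
  expect_equal(g$delta_t, p$delta_t, tolerance = tp$dt / abs(p$delta_t))
})

test_that("steady-state phase comes from late-time peak timing, wrapped", {
  f <- 500e3
  dt <- 2e-9
  dur <- 4e-5
  t <- (0:(dur / dt)) * dt
  ref <- sin(2 * pi * f * t)
  expect_equal(steady_state_phase(ref, ref, dt, f, dur), 0)
  quarter <- delay_signal(ref, dt, 1 / (4 * f))
  expect_equal(steady_state_phase(quarter, ref, dt, f, dur), pi / 2,
               tolerance = 1e-6)
  full <- delay_signal(ref, dt, 1 / f)
  ph <- steady_state_phase(full, ref, dt, f, dur)
  expect_lt(min(ph, 2 * pi - ph), 1e-6)           # wraps to 0
  expect_error(steady_state_phase(ref[1:100], ref[1:100], dt, f, dur),
               "window")
})

test_that("plane statistics use the population standard deviation", {
  expect_equal(plane_statistics(matrix(3, 4, 4)), c(mean = 3, std = 0))
  expect_equal(plane_statistics(c(2, 6)), c(mean = 4, std = 2))
  set.seed(11)
  v <- matrix(rnorm(64, 2000, 50), 8, 8)
  st <- plane_statistics(v)
  expect_equal(st[["mean"]], sum(v) / 64)
  expect_equal(st[["std"]], sqrt(sum((v - mean(v))^2) / 64))
  expect_error(plane_statistics(numeric(0)), "empty")
})

test_that("phase histograms are probability-normalized with a circular
           two-bin Goodman criterion", {
  h1 <- phase_histogram(matrix(1.2, 64, 64))
  expect_equal(sum(h1$bins$probability), 1)
  expect_equal(sum(h1$bins$probability > 0), 1L)
  expect_true(h1$goodman_pass)
  set.seed(21)
  h2 <- phase_histogram(matrix(runif(65536, 0, 2 * pi), 256, 256))
  expect_equal(sum(h2$bins$probability), 1)
  expect_lt(max(abs(h2$bins$probability - 1 / 16)), 0.01)
  expect_false(h2$goodman_pass)
  # a distribution straddling the wrap seam still passes via circular bins
  seam <- c(rep(0.05, 50), rep(2 * pi - 0.05, 50))
  expect_true(phase_histogram(seam)$goodman_pass)
})

test_that("histogram mean shifts are invariant to the applied offset", {
  set.seed(31)
  a <- runif(4096, 1, 1.6)
  b <- runif(4096, 2.1, 2.7)
  shift_at <- function(off) {
    ma <- sum(tidy(phase_histogram(a, offset = off))$probability *
                (0:15 + 0.5) * 2 * pi / 16)
    mb <- sum(tidy(phase_histogram(b, offset = off))$probability *
                (0:15 + 0.5) * 2 * pi / 16)
    (mb - ma) %% (2 * pi)
  }
  expect_equal(shift_at(0.7), shift_at(0), tolerance = 0.05)
  expect_equal(shift_at(1.9), shift_at(0), tolerance = 0.05)
})
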