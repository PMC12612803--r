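test_that("the CFL condition fixes the time discretization", {
  tp <- derive_time_params(0.035, 5e-5, 3514, 20e-6)
  expect_equal(tp$dt, 0.035 * 5e-5 / 3514)
  expect_equal(tp$dt, 4.98e-10, tolerance = 1e-3)
  expect_equal(tp$n_steps, 40160L)    # 20 us at the 500 kHz step exactly
  expect_error(derive_time_params(1.5, 5e-5, 3514, 20e-6), "stability")
  expect_error(derive_time_params(1, 5e-5, 3514, 20e-6), "stability")
})

test_that("source waveforms match their definitions", {
  tp <- derive_time_params(0.1, 5e-5, 1500, 1e-5)
  t <- (seq_len(tp$n_steps) - 1) * tp$dt
  s1 <- make_source_signal("single_cycle", 500e3, tp)
  expect_true(all(s1[t >= 2e-6] == 0))          # support is one period
  expect_true(any(s1[t < 2e-6] != 0))
  expect_equal(s1[t < 2e-6], sin(2 * pi * 500e3 * t[t < 2e-6]))
  expect_lt(abs(sum(s1) * tp$dt), 1e-12)        # full sine period integrates to 0
  s2 <- make_source_signal("continuous", 500e3, tp)
  expect_equal(s2, sin(2 * pi * 500e3 * t))
  i_quarter <- which.min(abs(t - 0.5e-6))       # quarter period: sin = 1
  expect_equal(s2[i_quarter], 1, tolerance = 1e-4)
})

test_that("a pulse crosses water at the speed of sound", {
  med <- small_water_1d(z_mm = 3.2, pad = 0.5)
  src <- source_spec("single_cycle", 500e3)
  rec <- run_simulation(med, src, cfl = 0.3, duration = 6e-6)
  sig <- make_source_signal("single_cycle", 500e3,
                            derive_time_params(0.3, 5e-5, 1500, 6e-6))
  est <- group_delay(record_trace(rec), sig, rec$dt)
  dist <- (dim(med$sound_speed)[3] - 1) * 0.05e-3
  expect_equal(est$delta_t, dist / 1500, tolerance = 1e-3)
})

test_that("the scheme is linear and deterministic", {
  med <- bone_medium_1d()
  r1 <- run_simulation(med, source_spec("single_cycle", 500e3, amplitude = 1),
                       cfl = 0.035, duration = 4e-6)
  r2 <- run_simulation(med, source_spec("single_cycle", 500e3, amplitude = 2),
                       cfl = 0.035, duration = 4e-6)
  expect_equal(2 * r1$pressure, r2$pressure)
  r3 <- run_simulation(med, source_spec("single_cycle", 500e3, amplitude = 1),
                       cfl = 0.035, duration = 4e-6)
  expect_identical(r1$pressure, r3$pressure)
})

test_that("a transversely uniform 3D run reduces exactly to 1D", {
  build <- function(dimensionality) {
    ph <- generate_phantom(phantom_spec(0.3, 0, extent = c(0.8, 0.8, 1.6),
                                        dimensionality = dimensionality))
    build_medium(ph, front_water = 0.5, back_water = 0.5)
  }
  src <- source_spec("single_cycle", 500e3)
  r3 <- run_simulation(build(3), src, cfl = 0.035, duration = 4e-6)
  r1 <- run_simulation(build(1), src, cfl = 0.035, duration = 4e-6)
  tr3 <- record_trace(r3); tr1 <- record_trace(r1)
  expect_lt(max(abs(tr3 - tr1)) / max(abs(tr1)), 1e-6)
  # at transverse wavenumber zero the 3D operators equal the 1D operators,
  # so the whole plane stays uniform
  expect_equal(max(apply(r3$pressure, 3, sd)), 0)
})

test_that("the water-only reference is spatially uniform and medium-blind", {
  ph <- generate_phantom(phantom_spec(0.3, 0.3, extent = c(1.6, 1.6, 1.6),
                                      dimensionality = 2, seed = 2,
                                      porosity_tolerance = 0.05))
  med <- build_medium(ph, front_water = 0.5, back_water = 0.5)
  src <- source_spec("single_cycle", 500e3)
  ref <- run_reference(med, src, cfl = 0.035, duration = 4e-6)
  peak <- max(abs(ref$pressure))
  expect_lte(max(apply(ref$pressure, 3, sd)), 1e-10 * peak)
  # any phantom with the same geometry and discretization shares the reference
  ph2 <- generate_phantom(phantom_spec(0.6, 0.5, extent = c(1.6, 1.6, 1.6),
                                       dimensionality = 2, seed = 9,
                                       porosity_tolerance = 0.1))
  ref2 <- run_reference(build_medium(ph2, front_water = 0.5,
                                     back_water = 0.5),
                        src, cfl = 0.035, duration = 4e-6)
  expect_identical(ref$pressure, ref2$pressure)
  # a different source frequency gives a different reference
  ref3 <- run_reference(med, source_spec("single_cycle", 250e3),
                        cfl = 0.035, duration = 4e-6)
  expect_false(identical(ref$pressure, ref3$pressure))
})

test_that("energy is conserved in a lossless periodic box", {
  med <- small_water_1d(z_mm = 3.2, pad = 0)
  src <- source_spec("single_cycle", 500e3)
  tp <- derive_time_params(0.3, 5e-5, 1500, 1.25e-5)  # > 1000 post-source steps
  rec <- run_simulation(med, src, time = tp, pml_size = 0,
                        track_energy = TRUE)
  E <- rec$energy
  after <- E[(seq_along(E) - 1) * tp$dt > 2.2e-6]     # source off after 2 us
  expect_gt(length(after), 1000)
  expect_lt((max(after) - min(after)) / max(after), 1e-3)
})

test_that("plane-wave amplitude decays as the power-law absorption predicts", {
  med <- small_water_1d(z_mm = 6.4, pad = 0.5)
  lossy <- med; lossy$attenuation_1mhz[] <- 50
  src <- source_spec("continuous", 500e3)
  tp <- derive_time_params(0.035, 5e-5, 1500, 2e-5)
  steady_amp <- function(m) {
    tr <- record_trace(run_simulation(m, src, time = tp))
    max(abs(tr[(length(tr) - 2000):length(tr)]))
  }
  ratio <- steady_amp(lossy) / steady_amp(med)
  L <- (dim(med$sound_speed)[3] - 1) * 0.05e-3
  alpha_fc <- absorption_prefactor(50, 500e3) * 0.5^2   # = 50 * 0.5 Np/m
  expect_equal(ratio, exp(-alpha_fc * L), tolerance = 1e-2)
})

test_that("an unstable time step is reported with the failing step", {
  med <- small_water_1d(z_mm = 1.6, pad = 0)
  tp <- structure(list(cfl = 2, dt = 2 * 5e-5 / 1500, n_steps = 4000L,
                       duration = 4000 * 2 * 5e-5 / 1500),
                  class = "time_params")
  expect_error(run_simulation(med, source_spec("single_cycle", 500e3),
                              time = tp, pml_size = 0),
               "instability.*step")
})
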