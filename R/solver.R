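#' Time discretization from a CFL number
#'
#' The time step follows the Courant-Friedrichs-Lewy condition
#' `dt = cfl * dx / c_max`, taking the fastest material in the grid so that
#' the stability bound is governed by the stiffest medium.
#'
#' @param cfl CFL number in `(0, 1)`.
#' @param dx Voxel size in m.
#' @param c_max Maximum sound speed in the grid, m/s.
#' @param duration Simulated duration in s.
#' @return A `time_params` list with `cfl`, `dt` (s), `n_steps` and
#'   `duration`.
#' @export
derive_time_params <- function(cfl, dx, c_max, duration) {
  if (!is.numeric(cfl) || cfl <= 0 || cfl >= 1)
    stop("stability error: cfl must lie in (0, 1)", call. = FALSE)
  stopifnot(dx > 0, c_max > 0, duration > 0)
  dt <- cfl * dx / c_max
  structure(list(cfl = cfl, dt = dt,
                 n_steps = as.integer(ceiling(duration / dt)),
                 duration = duration),
            class = "time_params")
}

#' Plane-wave excitation
#'
#' @param kind `"single_cycle"` (one full period of a sine, then zero; used
#'   for group and phase velocity) or `"continuous"` (a sine over the whole
#'   duration; used for the steady-state phase).
#' @param center_frequency Centre frequency in Hz.
#' @param amplitude Source amplitude in Pa (arbitrary; everything measured
#'   downstream is amplitude-invariant in this linear regime).
#' @return A `source_spec` list.
#' @export
source_spec <- function(kind = c("single_cycle", "continuous"),
                        center_frequency, amplitude = 1) {
  kind <- match.arg(kind)
  stopifnot(center_frequency > 0)
  structure(list(kind = kind, center_frequency = center_frequency,
                 amplitude = amplitude),
            class = "source_spec")
}

#' Sampled source waveform
#'
#' @param kind `"single_cycle"` or `"continuous"`.
#' @param f_c Centre frequency in Hz.
#' @param time A `time_params` from [derive_time_params()].
#' @return Unit-amplitude pressure series of length `n_steps`.
#' @export
make_source_signal <- function(kind = c("single_cycle", "continuous"),
                               f_c, time) {
  kind <- match.arg(kind)
  stopifnot(inherits(time, "time_params"), f_c > 0)
  t <- (seq_len(time$n_steps) - 1) * time$dt
  s <- sin(2 * pi * f_c * t)
  if (kind == "single_cycle") s[t >= 1 / f_c] <- 0
  s
}

#' Propagate a plane wave through a medium
#'
#' Integrates the linear first-order acoustic equations (momentum, mass
#' conservation, equation of state with exponent-2 power-law absorption and
#' no dispersion term) with spectral spatial gradients on staggered grids and
#' the k-space temporal correction evaluated at `c_ref`. The plane source is
#' injected additively at the front interior plane; a split-field absorbing
#' layer closes both z ends while the transverse axes are periodic, so a
#' uniform source remains a plane wave. Pressure is recorded at every point
#' of the last interior transverse plane (in the water behind the phantom).
#'
#' The medium maps (and the source plane, with peak restoration) are
#' Blackman-smoothed on the PML-extended computational grid before stepping,
#' mirroring the configuration the measured velocities were validated
#' against; disable via `smooth_medium_maps` / `smooth_source` to study the
#' sharp-interface problem.
#'
#' @param medium A `medium_maps` from [build_medium()].
#' @param source A `source_spec`.
#' @param cfl CFL number (ignored when `time` is given).
#' @param duration Simulated duration in s; defaults to 20 us for pulsed and
#'   80 us for continuous sources.
#' @param time Optional `time_params` overriding `cfl`/`duration`.
#' @param c_ref Reference sound speed (m/s) of the k-space correction;
#'   the minimum material speed (marrow) minimizes numerical dispersion.
#' @param c_max Speed used in the CFL bound; defaults to the unsmoothed
#'   grid maximum.
#' @param pml_size Absorbing layer thickness in voxels at each z end
#'   (0 disables it, making z periodic).
#' @param pml_alpha Absorbing layer strength in Np/voxel.
#' @param smooth_medium_maps,smooth_source Blackman smoothing switches.
#' @param track_energy Also return the total acoustic energy per step
#'   (diagnostic; meaningful for lossless periodic runs).
#' @return A `field_record`: `pressure` array `(nx, ny, n_steps)` at the
#'   measurement plane, `dt`, `f_c`, source `kind`, and run metadata.
#' @export
run_simulation <- function(medium, source, cfl = 0.3, duration = NULL,
                           time = NULL, c_ref = 1450, c_max = NULL,
                           pml_size = 20, pml_alpha = 2,
                           smooth_medium_maps = TRUE, smooth_source = TRUE,
                           track_energy = FALSE) {
  stopifnot(inherits(medium, "medium_maps"), inherits(source, "source_spec"))
  dims <- dim(medium$sound_speed)
  dx <- medium$voxel_size * 1e-3
  if (is.null(c_max)) c_max <- max(medium$sound_speed)
  if (is.null(duration))
    duration <- if (source$kind == "single_cycle") 20e-6 else 80e-6
  if (is.null(time)) time <- derive_time_params(cfl, dx, c_max, duration)
  stopifnot(inherits(time, "time_params"))

  # extend along z into the absorbing layer by edge replication (water)
  P <- pml_size
  if (P > 0) {
    zidx <- c(rep(1L, P), seq_len(dims[3]), rep(dims[3], P))
    ext <- function(a) a[, , zidx, drop = FALSE]
  } else ext <- function(a) a
  c0 <- ext(medium$sound_speed)
  rho0 <- ext(medium$density)
  att <- ext(medium$attenuation_1mhz)
  if (!medium$smoothed && smooth_medium_maps) {
    c0 <- smooth_field(c0)
    rho0 <- smooth_field(rho0)
    att <- smooth_field(att)
  }
  # exponent-2 loss coefficient: alpha(omega) = alpha0 * omega^2,
  # tau = -2 * alpha0 * c0 with alpha0 in Np (rad/s)^-2 m^-1
  pref <- absorption_prefactor(att, source$center_frequency,
                               medium$power_law_exponent)
  alpha0 <- pref / (2 * pi * 1e6)^2
  tau <- -2 * alpha0 * c0

  sig <- source$amplitude * make_source_signal(source$kind,
                                               source$center_frequency, time)
  amp <- matrix(1, dims[1], dims[2])
  if (smooth_source && (dims[1] > 1 || dims[2] > 1))
    amp <- smooth_field(amp, restore_peak = TRUE)

  z_src <- P             # 0-based: first interior plane
  z_rec <- P + dims[3] - 1L   # last interior plane
  out <- kspace_run_cpp(c0, rho0, tau, dx, time$dt, time$n_steps,
                        sig, amp, z_src, z_rec, c_ref,
                        P, pml_alpha, track_energy)
  structure(list(pressure = out$record,
                 dt = time$dt, n_steps = time$n_steps,
                 f_c = source$center_frequency, kind = source$kind,
                 energy = out$energy,
                 meta = list(cfl = time$cfl, duration = time$duration,
                             c_ref = c_ref, c_max = c_max,
                             pml_size = P, pml_alpha = pml_alpha,
                             dims = dims, voxel_size = medium$voxel_size,
                             smoothed_medium = medium$smoothed || smooth_medium_maps,
                             porosity = medium$phantom_porosity,
                             pore_diameter = medium$pore_diameter)),
            class = "field_record")
}

#' Water-only reference run
#'
#' Runs [run_simulation()] on an all-water medium of the same geometry. For a
#' plane source the water-only pressure is spatially uniform over the
#' measurement plane, so one reference serves every phantom at the same
#' frequency, grid and time discretization.
#'
#' @inheritParams run_simulation
#' @param ... Passed to [run_simulation()].
#' @return A `field_record`.
#' @export
run_reference <- function(medium, source, ..., c_max = NULL) {
  # the reference must share the phantom run's time discretization, so the
  # CFL bound uses the original medium's fastest material, not water
  if (is.null(c_max)) c_max <- max(medium$sound_speed)
  run_simulation(water_medium(medium), source, ..., c_max = c_max)
}

#' @export
print.field_record <- function(x, ...) {
  d <- dim(x$pressure)
  cat(sprintf("<field_record> %dx%d plane, %d steps of %.3g ns (%s, %g kHz)\n",
              d[1], d[2], d[3], x$dt * 1e9, x$kind, x$f_c / 1e3))
  invisible(x)
}

#' Pressure trace at one measurement-plane pixel
#'
#' @param record A `field_record`.
#' @param i,j Pixel indices (default the plane centre).
#' @return Numeric time series.
#' @export
record_trace <- function(record, i = NULL, j = NULL) {
  d <- dim(record$pressure)
  if (is.null(i)) i <- (d[1] + 1) %/% 2
  if (is.null(j)) j <- (d[2] + 1) %/% 2
  as.vector(record$pressure[i, j, ])
}
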