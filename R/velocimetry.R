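#' Substitution-method velocity
#'
#' Through-transmission velocity from the delay of a sample-path signal
#' relative to an equal water path:
#' `V = C_w / (1 + C_w * delta_t / d)`.
#' A negative `delta_t` (earlier arrival than water) gives `V > C_w`.
#'
#' @param delta_t Time difference signal minus reference in s (scalar or
#'   array), from [group_delay()], [phase_delay()] or your own estimator.
#' @param thickness Sample thickness `d` in m.
#' @param water_speed Speed of sound in water `C_w`, m/s.
#' @return Velocity in m/s, same shape as `delta_t`.
#' @export
substitution_velocity <- function(delta_t, thickness, water_speed = 1500) {
  stopifnot(thickness > 0, water_speed > 0)
  den <- 1 + water_speed * delta_t / thickness
  if (any(den <= 0))
    stop("nonphysical delay: 1 + C_w * delta_t / d must be positive",
         call. = FALSE)
  water_speed / den
}

# 1D FFT with stats::fft semantics, FFTW-backed so arbitrary (prime) record
# lengths stay O(n log n)
fft1 <- function(x, inverse = FALSE)
  as.vector(fft1_cpp(as.complex(x), inverse))

#' Signal envelope via the analytic signal
#'
#' Magnitude of the analytic signal (Hilbert-transform envelope).
#'
#' @param x Real series.
#' @return Non-negative envelope, same length.
#' @export
envelope <- function(x) {
  stopifnot(is.numeric(x))
  n <- length(x)
  X <- fft1(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft1(X * h, inverse = TRUE) / n)
}

# map angles into (-pi, pi]
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- y[y <= -pi] + 2 * pi
  y
}

# parabolic vertex offset from three samples around a discrete peak
parabolic_offset <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (abs(den) < .Machine$double.eps) return(0)
  off <- 0.5 * (ym1 - yp1) / den
  max(min(off, 0.5), -0.5)
}

#' Group delay from envelope cross-correlation
#'
#' Normalized cross-correlation of the two Hilbert envelopes; the time lag at
#' the correlation maximum (refined by three-point parabolic interpolation)
#' is the group delay. Negative `delta_t` means the signal arrives earlier
#' than the reference. The peak correlation value quantifies envelope
#' distortion: 1 for an undistorted (shifted, scaled) copy.
#'
#' @param signal,reference Equal-length real series with sample interval
#'   `dt`.
#' @param dt Sample interval in s.
#' @param refine Apply sub-sample parabolic refinement of the peak lag.
#' @return A `delay_estimate`: list with `delta_t` (s), `method = "group"`,
#'   `peak_correlation`.
#' @export
group_delay <- function(signal, reference, dt, refine = TRUE) {
  stopifnot(length(signal) == length(reference), dt > 0)
  a <- envelope(signal)
  b <- envelope(reference)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("undefined correlation: zero-variance envelope", call. = FALSE)
  n <- length(a)
  # circular correlation at the record length: both records are quiet at
  # their ends, and a delayed copy then yields an exactly symmetric peak
  cc <- Re(fft1(fft1(a) * Conj(fft1(b)), inverse = TRUE)) / n / (na * nb)
  # cc[l + 1] = sum_t a(t) b(t - l); lags beyond n/2 alias to negative
  l <- 0:(n - 1)
  lags <- ifelse(l <= n / 2, l, l - n)
  ix <- which.max(cc)
  lag <- lags[ix]
  peak <- cc[ix]
  if (refine) {
    im1 <- (ix - 2) %% n + 1
    ip1 <- ix %% n + 1
    off <- parabolic_offset(cc[im1], cc[ix], cc[ip1])
    lag <- lag + off
    peak <- max(peak, cc[ix] - 0.25 * (cc[im1] - cc[ip1]) * off)
  }
  structure(list(delta_t = lag * dt, method = "group",
                 peak_correlation = min(peak, 1)),
            class = "delay_estimate")
}

#' Phase delay from the unwrapped Fourier phase difference
#'
#' Both series are zero-padded to four times their length to increase the
#' frequency resolution, transformed, and the per-bin phase difference is
#' taken from the complex-conjugate product of the reference and signal
#' spectra. The phase difference is unwrapped by accumulating increments
#' (each mapped into `(-pi, pi]`) starting from the Fourier coefficient
#' adjacent to DC; the delay is the unwrapped difference at the bin nearest
#' the carrier, `delta_t = delta_phi(f_c) / (2 pi f_c)`. The whole acquired
#' signal is used (no time windowing), so reflections from pores and from
#' the planar sample faces contribute to the estimate; this is deliberate
#' and is what makes the method fully automatic.
#'
#' @inheritParams group_delay
#' @param f_c Carrier frequency in Hz; must be resolvable
#'   (`df <= f_c < Nyquist`).
#' @param pad_factor Zero-padding factor (default 4).
#' @return A `delay_estimate` with `delta_t` (s) and `method = "phase"`.
#' @export
phase_delay <- function(signal, reference, dt, f_c, pad_factor = 4) {
  stopifnot(length(signal) == length(reference), dt > 0)
  n <- length(signal)
  N <- pad_factor * n
  df <- 1 / (N * dt)
  kbin <- round(f_c / df) + 1          # 1-based bin nearest the carrier
  if (kbin < 2 || (kbin - 1) * df >= 1 / (2 * dt))
    stop("f_c outside the resolvable band", call. = FALSE)
  S <- fft1(c(signal, rep(0, N - n)))
  R <- fft1(c(reference, rep(0, N - n)))
  ph <- Arg(R[1:kbin] * Conj(S[1:kbin]))
  # cumulative sum of wrapped increments, anchored at the first non-DC bin
  un <- cumsum(wrap_phase(c(ph[2], diff(ph[-1]))))
  dphi <- un[kbin - 1]
  structure(list(delta_t = dphi / (2 * pi * f_c), method = "phase",
                 peak_correlation = NULL),
            class = "delay_estimate")
}

#' @export
print.delay_estimate <- function(x, ...) {
  cat(sprintf("<delay_estimate> %s: delta_t = %.4g us%s\n", x$method,
              x$delta_t * 1e6,
              if (!is.null(x$peak_correlation))
                sprintf(" (peak corr %.3f)", x$peak_correlation) else ""))
  invisible(x)
}

#' Steady-state phase from late-time peak timing
#'
#' For continuous-wave records: finds the first local maximum after
#' `window_start` of the simulated duration in the signal and in the
#' water-only reference (with parabolic sub-sample refinement), converts the
#' peak time difference to phase by the angular frequency, and wraps to
#' `[0, 2 pi)`.
#'
#' @inheritParams group_delay
#' @param f_c Source frequency in Hz.
#' @param duration Simulated duration in s.
#' @param window_start Fraction of the duration after which to search
#'   (default 0.9, i.e. transients are assumed decayed).
#' @param refine Parabolic sub-sample peak refinement.
#' @return Steady-state phase in radians, in `[0, 2 pi)`.
#' @export
steady_state_phase <- function(signal, reference, dt, f_c, duration,
                               window_start = 0.9, refine = TRUE) {
  stopifnot(length(signal) == length(reference), dt > 0, f_c > 0)
  if (length(signal) * dt < window_start * duration)
    stop("records do not cover the search window", call. = FALSE)
  if ((1 - window_start) * duration < 1 / f_c)
    stop("search window shorter than one source period; increase duration",
         call. = FALSE)
  peak_time <- function(s) {
    i0 <- max(2L, ceiling(window_start * duration / dt) + 1L)
    n <- length(s)
    for (i in i0:(n - 1)) {
      if (s[i] > s[i - 1] && s[i] >= s[i + 1]) {
        off <- if (refine) parabolic_offset(s[i - 1], s[i], s[i + 1]) else 0
        return((i - 1 + off) * dt)
      }
    }
    stop("no local maximum in the steady-state window", call. = FALSE)
  }
  ph <- 2 * pi * f_c * (peak_time(signal) - peak_time(reference))
  ph %% (2 * pi)
}

#' Mean and population standard deviation over a measurement plane
#'
#' @param field Numeric vector, matrix or field object with `values`.
#' @return Named vector `c(mean, std)`; `std` uses the n-denominator.
#' @export
plane_statistics <- function(field) {
  v <- if (is.list(field) && !is.null(field$values)) field$values else field
  v <- as.vector(v)
  if (length(v) == 0) stop("empty field", call. = FALSE)
  m <- mean(v)
  c(mean = m, std = sqrt(mean((v - m)^2)))
}

#' Per-pixel velocity field over the measurement plane
#'
#' Applies [group_delay()] or [phase_delay()] at every pixel of a recorded
#' plane against the (spatially uniform) water reference trace, then the
#' substitution equation.
#'
#' @param record Phantom-path `field_record` from [run_simulation()].
#' @param reference Water-only `field_record` from [run_reference()], same
#'   discretization.
#' @param method `"group"` or `"phase"`.
#' @param thickness Phantom thickness in m (default 8 mm).
#' @param water_speed Water sound speed in m/s.
#' @return A `velocity_field`: `values` matrix (m/s), `mean`, `std`
#'   (population), `method`, `f_c`, and for the group method the mean
#'   `peak_correlation`.
#' @export
velocity_field <- function(record, reference, method = c("group", "phase"),
                           thickness = 8e-3, water_speed = 1500) {
  method <- match.arg(method)
  stopifnot(inherits(record, "field_record"),
            inherits(reference, "field_record"),
            isTRUE(all.equal(record$dt, reference$dt)))
  ref <- record_trace(reference)       # uniform over the plane
  d <- dim(record$pressure)
  vals <- matrix(NA_real_, d[1], d[2])
  pc <- if (method == "group") matrix(NA_real_, d[1], d[2]) else NULL
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    sig <- record$pressure[i, j, ]
    est <- if (method == "group") group_delay(sig, ref, record$dt)
           else phase_delay(sig, ref, record$dt, record$f_c)
    vals[i, j] <- substitution_velocity(est$delta_t, thickness, water_speed)
    if (method == "group") pc[i, j] <- est$peak_correlation
  }
  st <- plane_statistics(vals)
  structure(list(values = vals, mean = st[["mean"]], std = st[["std"]],
                 method = method, f_c = record$f_c,
                 peak_correlation = if (!is.null(pc)) mean(pc) else NULL),
            class = "velocity_field")
}

#' Per-pixel steady-state phase field
#'
#' @inheritParams velocity_field
#' @return A `phase_field`: `values` matrix in radians `[0, 2 pi)`, `mean`,
#'   `std`, `f_c`.
#' @export
phase_field <- function(record, reference) {
  stopifnot(inherits(record, "field_record"), record$kind == "continuous")
  ref <- record_trace(reference)
  d <- dim(record$pressure)
  vals <- matrix(NA_real_, d[1], d[2])
  for (j in seq_len(d[2])) for (i in seq_len(d[1]))
    vals[i, j] <- steady_state_phase(record$pressure[i, j, ], ref,
                                     record$dt, record$f_c,
                                     record$meta$duration)
  st <- plane_statistics(vals)
  structure(list(values = vals, mean = st[["mean"]], std = st[["std"]],
                 f_c = record$f_c),
            class = "phase_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %s at %g kHz: %.0f +/- %.0f m/s over %s pixels\n",
              x$method, x$f_c / 1e3, x$mean, x$std,
              paste(dim(x$values), collapse = "x")))
  invisible(x)
}

#' @export
print.phase_field <- function(x, ...) {
  cat(sprintf("<phase_field> %g kHz: %.2f +/- %.2f rad over %s pixels\n",
              x$f_c / 1e3, x$mean, x$std,
              paste(dim(x$values), collapse = "x")))
  invisible(x)
}

#' Steady-state phase histogram with the Goodman criterion
#'
#' Probability-normalized histogram of the (offset, re-wrapped) phases with
#' 16 bins of width `2 pi / 16` (one sixteenth of a period). The Goodman
#' criterion for adequate phased-array focusing corresponds to a phase spread
#' of two bins (`2 pi / 8`): the histogram passes when at least 95% of the
#' probability mass lies within two circularly adjacent bins.
#'
#' @param phases A `phase_field` or numeric phases in radians.
#' @param offset Constant phase offset in radians applied before re-wrapping
#'   (used to keep a distribution away from the wrap seam; offset-invariant
#'   statistics are unaffected).
#' @param bin_width Bin width in radians; must divide `2 pi` evenly.
#' @return A `phase_histogram`: tibble `bins` with `lower`, `upper`,
#'   `probability`, plus `goodman_pass`, `bin_width`, `offset`.
#' @export
phase_histogram <- function(phases, offset = 0, bin_width = 2 * pi / 16) {
  v <- if (is.list(phases) && !is.null(phases$values)) phases$values else phases
  v <- as.vector(v)
  nb <- round(2 * pi / bin_width)
  if (abs(nb * bin_width - 2 * pi) > 1e-9)
    stop("bin_width must divide 2*pi evenly", call. = FALSE)
  vv <- (v + offset) %% (2 * pi)
  idx <- pmin(floor(vv / bin_width), nb - 1)
  counts <- tabulate(idx + 1, nbins = nb)
  prob <- counts / length(vv)
  pair <- prob + prob[c(2:nb, 1)]      # circularly adjacent bin pairs
  structure(list(bins = tibble::tibble(lower = (0:(nb - 1)) * bin_width,
                                       upper = (1:nb) * bin_width,
                                       probability = prob),
                 goodman_pass = max(pair) >= 0.95,
                 bin_width = bin_width, offset = offset),
            class = "phase_histogram")
}

#' @export
print.phase_histogram <- function(x, ...) {
  cat(sprintf("<phase_histogram> %d bins of %.3f rad, Goodman %s\n",
              nrow(x$bins), x$bin_width,
              if (x$goodman_pass) "pass" else "fail"))
  invisible(x)
}
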