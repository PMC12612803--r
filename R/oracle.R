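#' Layer stack constructor
#'
#' A planar stack of lossy fluid layers at normal incidence, bounded by water
#' half-spaces on both sides. Layers are rows of a tibble, front to back.
#'
#' @param sound_speed Sound speeds in m/s.
#' @param density Densities in kg/m^3.
#' @param prefactor Exponent-2 absorption pre-factors in Np m^-1 MHz^-2
#'   (recycled).
#' @param thickness Layer thicknesses in m (recycled).
#' @return A tibble with one row per layer.
#' @export
layer_stack <- function(sound_speed, density, prefactor = 0, thickness) {
  out <- tibble::tibble(sound_speed = sound_speed, density = density,
                        prefactor = prefactor, thickness = thickness)
  stopifnot(nrow(out) >= 1, all(out$sound_speed > 0), all(out$density > 0),
            all(out$prefactor >= 0 | abs(out$prefactor) < 1e-6),
            all(out$thickness > 0))
  out
}

#' Layer stack matching a medium's z profile
#'
#' Converts the (optionally smoothed) axial property profile of a
#' `medium_maps` object into one thin layer per voxel, so the analytic
#' transfer-matrix model sees exactly the material profile the solver
#' propagates through. Only meaningful for transversely uniform media; the
#' profile is taken at the first transverse pixel.
#'
#' @param medium A `medium_maps`.
#' @param center_frequency Centre frequency in Hz (fixes the exponent-2
#'   pre-factor from the 1 MHz attenuation map).
#' @return A tibble of per-voxel layers.
#' @export
layers_from_medium <- function(medium, center_frequency) {
  stopifnot(inherits(medium, "medium_maps"))
  dz <- medium$voxel_size * 1e-3
  cs <- medium$sound_speed[1, 1, ]
  rs <- medium$density[1, 1, ]
  ps <- absorption_prefactor(medium$attenuation_1mhz[1, 1, ],
                             center_frequency)
  tibble::tibble(sound_speed = cs, density = rs,
                 prefactor = pmax(ps, 0), thickness = rep(dz, length(cs)))
}

# complex wavenumber and characteristic impedance per layer at frequencies f
layer_kz <- function(layer_row, f) {
  w <- 2 * pi * f
  alpha <- layer_row$prefactor * (f / 1e6)^2
  k <- w / layer_row$sound_speed - 1i * alpha
  list(k = k, Z = layer_row$density * w / k)
}

#' Transmission and reflection of a layer stack
#'
#' Complex pressure transmission and reflection coefficients at normal
#' incidence through the stack, computed by a numerically stable
#' back-to-front Airy recursion (only decaying exponentials appear, so
#' arbitrarily lossy layers are safe). The transmission is referenced to an
#' all-water path of the same total length, matching the substitution
#' method's reference convention; set `relative = FALSE` for the absolute
#' coefficient including the propagation delay through the stack.
#'
#' @param layers A [layer_stack()] tibble.
#' @param frequency Frequencies in Hz (vector; must be positive).
#' @param water Sound speed and density of the bounding half-spaces.
#' @param relative Reference against an equal-length all-water path.
#' @return A tibble with columns `frequency`, `transmission`, `reflection`
#'   (complex).
#' @export
layered_coefficients <- function(layers, frequency,
                                 water = list(sound_speed = 1500,
                                              density = 1000),
                                 relative = TRUE) {
  if (any(frequency <= 0)) stop("frequency must be positive", call. = FALSE)
  nf <- length(frequency)
  Zw <- rep(water$density * water$sound_speed + 0i, nf)
  N <- nrow(layers)
  kz <- lapply(seq_len(N), function(j) layer_kz(layers[j, ], frequency))
  Zof <- function(i) if (i == 0 || i == N + 1) Zw else kz[[i]]$Z
  # base: last interface, into the back half-space
  Za <- Zof(N); Zb <- Zof(N + 1)
  R <- (Zb - Za) / (Zb + Za)
  T <- 2 * Zb / (Za + Zb)
  for (i in N:1) {
    Za <- Zof(i - 1); Zb <- Zof(i)
    r <- (Zb - Za) / (Zb + Za)
    tf <- 2 * Zb / (Za + Zb)
    tb <- 2 * Za / (Za + Zb)
    E2 <- exp(-2i * kz[[i]]$k * layers$thickness[i])
    den <- 1 + r * R * E2
    T <- tf * exp(-1i * kz[[i]]$k * layers$thickness[i]) * T / den
    R <- r + tf * tb * R * E2 / den
  }
  if (relative) {
    L <- sum(layers$thickness)
    T <- T / exp(-2i * pi * frequency * L / water$sound_speed)
  }
  tibble::tibble(frequency = frequency, transmission = T, reflection = R)
}

#' Complex transmission coefficient of a layer stack
#'
#' @inheritParams layered_coefficients
#' @return Complex vector, one element per frequency.
#' @export
layered_transmission <- function(layers, frequency,
                                 water = list(sound_speed = 1500,
                                              density = 1000),
                                 relative = TRUE) {
  layered_coefficients(layers, frequency, water, relative)$transmission
}

# Hermitian-symmetric frequency response over n DFT bins; fun(f) is evaluated
# at positive frequencies only, T(0) = 1.
freq_response <- function(n, dt, fun) {
  H <- complex(real = rep(1, n))
  kmax <- (n - 1) %/% 2
  if (kmax >= 1) {
    Tk <- fun((1:kmax) / (n * dt))
    H[2:(kmax + 1)] <- Tk
    H[n:(n - kmax + 1)] <- Conj(Tk)
  }
  if (n %% 2 == 0) H[n / 2 + 1] <- Re(fun((n / 2) / (n * dt)))
  H
}

#' Analytic received signal through a layer stack
#'
#' Multiplies the source spectrum by the stack's transmission per frequency
#' bin (Hermitian-symmetric, DC gain 1) and inverse-transforms: the analytic
#' "received at the measurement plane" series for transversely uniform
#' problems. The filtering is circular, so the input should be a causal
#' record with enough leading quiet time to absorb any phase advance through
#' fast layers (a water-only reference record satisfies this); with
#' `relative = FALSE` the full propagation delay through the stack is
#' included instead.
#'
#' @param source Real pressure series (typically a water-only reference).
#' @param dt Sample interval in s.
#' @param layers A [layer_stack()] tibble.
#' @inheritParams layered_coefficients
#' @return Real series of the same length.
#' @export
synthesize_received_signal <- function(source, dt, layers,
                                       water = list(sound_speed = 1500,
                                                    density = 1000),
                                       relative = TRUE) {
  n <- length(source)
  H <- freq_response(n, dt, function(f)
    layered_transmission(layers, f, water, relative))
  Re(fft1(fft1(source) * H, inverse = TRUE)) / n
}

#' Delay a series by a non-integer number of samples (spectral)
#'
#' Circular spectral delay; useful for constructing exact pure-delay test
#' pairs for the velocimetry estimators.
#'
#' @param x Real series.
#' @param dt Sample interval in s.
#' @param delay Delay in s (positive delays shift later).
#' @return Real series of the same length.
#' @export
delay_signal <- function(x, dt, delay) {
  n <- length(x)
  H <- freq_response(n, dt, function(f) exp(-2i * pi * f * delay))
  Re(fft1(fft1(x) * H, inverse = TRUE)) / n
}
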