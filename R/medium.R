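#' Acoustic properties of the constituent materials
#'
#' Nominal properties of water, red marrow and cortical bone: sound speed
#' (m/s), linear attenuation at 1 MHz (Np/m) and density (kg/m^3).
#'
#' @return A tibble with one row per material.
#' @export
material_table <- function() {
  tibble::tibble(
    material = c("water", "red_marrow", "cortical_bone"),
    sound_speed = c(1500, 1450, 3514),
    attenuation_1mhz = c(0, 12.55, 54.55),
    density = c(1000, 1029, 1908))
}

#' Power-law absorption pre-factor at a source centre frequency
#'
#' The materials are treated as dispersionless: the power-law exponent is
#' fixed at 2, for which the dispersion correction mandated by the
#' Kramers-Kronig relation vanishes. A linear attenuation law `a1 * f[MHz]`
#' defined at 1 MHz is re-expressed as the quadratic law
#' `prefactor * f[MHz]^2` by dividing the pre-factor by the centre frequency
#' in MHz, so the two laws agree exactly at `center_frequency`.
#'
#' @param attenuation_at_1mhz Linear attenuation at 1 MHz in Np/m (scalar or
#'   array).
#' @param center_frequency Source centre frequency in Hz.
#' @param exponent Power-law exponent; only 2 is supported.
#' @return Pre-factor in Np m^-1 MHz^-2, same shape as the input.
#' @export
absorption_prefactor <- function(attenuation_at_1mhz, center_frequency,
                                 exponent = 2) {
  if (!isTRUE(all.equal(exponent, 2)))
    stop("unsupported configuration: power-law exponent must be 2",
         call. = FALSE)
  if (center_frequency <= 0)
    stop("center_frequency must be positive", call. = FALSE)
  attenuation_at_1mhz / (center_frequency / 1e6)
}

#' Embed a phantom in the water-padded simulation grid
#'
#' Builds co-registered maps of sound speed, density and attenuation at 1 MHz
#' over the simulation grid: a front water layer, the phantom (cortical /
#' marrow per label), and a back water layer along z. With the default
#' geometry (12.8 x 12.8 x 8 mm phantom, 0.05 mm voxels, 0.5 / 2.3 mm water)
#' the grid is 256 x 256 x 216 voxels and the phantom occupies z indices
#' 10-169 (0-based).
#'
#' @param phantom A `phantom_volume` from [generate_phantom()].
#' @param materials Material property table, by default [material_table()].
#' @param front_water,back_water Water layer thicknesses in mm; must be
#'   integer multiples of the voxel size.
#' @return A `medium_maps` object: arrays `sound_speed` (m/s), `density`
#'   (kg/m^3), `attenuation_1mhz` (Np/m) over the grid, the voxel size (mm),
#'   the power-law exponent (2), cached `c_min`/`c_max`, and the phantom's
#'   z-index range.
#' @export
build_medium <- function(phantom, materials = material_table(),
                         front_water = 0.5, back_water = 2.3) {
  stopifnot(inherits(phantom, "phantom_volume"))
  vox <- phantom$spec$voxel_size
  nzf <- front_water / vox
  nzb <- back_water / vox
  if (abs(nzf - round(nzf)) > 1e-8 || abs(nzb - round(nzb)) > 1e-8)
    stop("water layers must be integer multiples of the voxel size",
         call. = FALSE)
  nzf <- as.integer(round(nzf)); nzb <- as.integer(round(nzb))
  dp <- dim(phantom$labels)
  nz <- nzf + dp[3] + nzb
  mat <- function(name, col) {
    v <- materials[[col]][match(name, materials$material)]
    if (anyNA(v)) stop("material table is missing ", name, call. = FALSE)
    v
  }
  grab <- function(col) {
    a <- array(mat("water", col), dim = c(dp[1], dp[2], nz))
    block <- array(mat("cortical_bone", col), dim = dp)
    block[phantom$labels] <- mat("red_marrow", col)
    a[, , (nzf + 1):(nzf + dp[3])] <- block
    a
  }
  cs <- grab("sound_speed")
  structure(list(sound_speed = cs,
                 density = grab("density"),
                 attenuation_1mhz = grab("attenuation_1mhz"),
                 voxel_size = vox,
                 power_law_exponent = 2,
                 c_min = min(cs), c_max = max(cs),
                 phantom_z = c(nzf + 1L, nzf + dp[3]),  # 1-based inclusive
                 front_water = front_water, back_water = back_water,
                 phantom_porosity = phantom$achieved_porosity,
                 pore_diameter = phantom$spec$pore_diameter,
                 smoothed = FALSE),
            class = "medium_maps")
}

#' All-water medium with the same geometry as an existing one
#'
#' Used for the substitution-method reference run: every voxel takes the
#' water constants, the grid is unchanged.
#'
#' @param medium A `medium_maps` object.
#' @param materials Material property table.
#' @return A `medium_maps` object.
#' @export
water_medium <- function(medium, materials = material_table()) {
  w <- materials[materials$material == "water", ]
  out <- medium
  out$sound_speed[] <- w$sound_speed
  out$density[] <- w$density
  out$attenuation_1mhz[] <- w$attenuation_1mhz
  out$c_min <- w$sound_speed; out$c_max <- w$sound_speed
  out$phantom_porosity <- NA_real_
  out$pore_diameter <- NA_real_
  out
}

#' @export
print.medium_maps <- function(x, ...) {
  cat(sprintf("<medium_maps> %s voxels at %g mm, c in [%g, %g] m/s%s\n",
              paste(dim(x$sound_speed), collapse = "x"), x$voxel_size,
              x$c_min, x$c_max, if (x$smoothed) ", smoothed" else ""))
  invisible(x)
}

#' Spectral Blackman smoothing of a gridded field
#'
#' Multiplies the field's discrete Fourier spectrum by a separable, centred
#' Blackman taper on every axis and inverse-transforms. The taper equals 1 at
#' DC (the grid mean is conserved) and 0 at Nyquist. With `restore_peak` the
#' output is rescaled so its maximum magnitude matches the input's.
#'
#' Smoothing the property maps suppresses Gibbs oscillations, staircasing and
#' aliasing from the voxelized material interfaces, at the cost of blurring
#' each interface over a few voxels.
#'
#' @param x Numeric vector, matrix or array.
#' @param restore_peak Rescale the result to the input's peak magnitude.
#' @return Smoothed field of the same shape.
#' @export
smooth_field <- function(x, restore_peak = FALSE) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (any(d < 1)) stop("invalid grid", call. = FALSE)
  W <- array(1, dim = d)
  for (ax in seq_along(d)) {
    n <- d[ax]
    if (n == 1) next
    m <- 0:(n - 1)
    m <- ifelse(m <= n / 2, m, m - n)   # signed bin offset from DC
    w <- 0.42 + 0.5 * cos(2 * pi * m / n) + 0.08 * cos(4 * pi * m / n)
    W <- sweep(W, ax, w, `*`)
  }
  xs <- Re(fft(fft(array(x, dim = d)) * W, inverse = TRUE)) / prod(d)
  if (restore_peak) {
    pk <- max(abs(xs))
    if (pk > 0) xs <- xs * (max(abs(x)) / pk)
  }
  if (is.null(dim(x))) xs <- as.vector(xs)
  xs
}

#' Blackman-smooth all property maps of a medium
#'
#' Applies [smooth_field()] (peak restoration off) to the sound speed,
#' density and attenuation maps. Intended to be called on the PML-extended
#' computational grid; [run_simulation()] does this automatically.
#'
#' @param medium A `medium_maps` object.
#' @return The smoothed medium (flagged `smoothed = TRUE`; `c_min`/`c_max`
#'   keep the unsmoothed material extrema used for time stepping).
#' @export
smooth_medium <- function(medium) {
  medium$sound_speed <- smooth_field(medium$sound_speed)
  medium$density <- smooth_field(medium$density)
  medium$attenuation_1mhz <- smooth_field(medium$attenuation_1mhz)
  medium$smoothed <- TRUE
  medium
}
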