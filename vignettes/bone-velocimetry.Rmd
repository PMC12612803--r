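---
title: "Through-transmission velocimetry in porous bone phantoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Through-transmission velocimetry in porous bone phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Transcranial focused ultrasound must cross the skull, whose speed of sound is
far higher than soft tissue's and varies point to point. Treatment planning
estimates acoustic properties from CT, but a clinical CT voxel (about 0.5 mm)
averages over the trabecular microstructure — marrow-filled pores of 0.1-0.6
mm embedded in cortical bone. Two voxels with identical average composition
(identical porosity, hence identical Hounsfield units) can have different
effective sound speeds if their pore sizes differ, because scattering depends
on the pore size relative to the wavelength. This package quantifies that
effect with an in-silico through-transmission experiment: digital phantoms
with controlled porosity and pore diameter, full-wave plane-wave propagation,
and the substitution method for velocity.

`porespeed` provides the whole pipeline as composable pieces: phantom
generation (`phantom_spec()`, `generate_phantom()`), acoustic property maps
(`build_medium()`), the wave solver (`run_simulation()`, `run_reference()`),
velocimetry (`group_delay()`, `phase_delay()`, `steady_state_phase()`,
`substitution_velocity()`), an independent analytic transfer-matrix model
(`layered_transmission()`), and sweep orchestration (`run_sweep()`).

## Digital phantoms

A phantom is a voxel block (default 12.8 x 12.8 x 8 mm at 0.05 mm isotropic
resolution) of cortical bone into which spherical red-marrow pores of one
diameter are carved at uniformly random centres, overlap allowed, until the
marrow volume fraction (the porosity) first reaches its target. Overlap
produces connected, irregular marrow spaces from simple primitives, which is
closer to trabecular geometry than packed disjoint spheres.

Construction choices where more than one reasonable rule exists:

* **Voxelization.** A voxel belongs to a pore when its centre lies strictly
  inside the sphere, with a relative epsilon (`1e-9`) so that centres exactly
  at the radius are excluded regardless of floating-point rounding. A sphere
  of diameter `2 * voxel_size` centred on a voxel centre therefore covers
  exactly one voxel.
* **Boundaries.** Pores are clipped at all six faces; pore geometry does not
  wrap around. Only the propagating field is transversely periodic, and a
  clipped pore at a face is as physical as an interior one.
* **Stopping rule.** Placement stops at the first crossing of the target, so
  achieved porosity always overshoots by less than one pore's marginal
  volume. The achieved value is recorded and used downstream; the spec's
  `porosity_tolerance` (default 0.005 absolute) bounds the accepted
  overshoot. Small grids with coarse pores need a looser tolerance because
  one pore can add several percent porosity.
* **Reproducibility.** Each phantom draws from its own seeded RNG stream;
  the spec plus seed determines the volume bit-for-bit.

The default porosity list spans 2.5% to 80% in eleven steps
(2.5, 5, 10, 15, 20, 25, 30, 40, 50, 65, 80%) covering cortical through
highly trabecular compositions; the exact intermediate values are a package
choice. One phantom per (diameter, porosity) cell is the default, with the
seed list as the replicate knob.

## Material model and property maps

Three fluids, each with a sound speed (m/s), density (kg/m^3) and linear
attenuation at 1 MHz (Np/m):

| material | c | attenuation @1 MHz | density |
|---|---|---|---|
| water | 1500 | 0 | 1000 |
| red marrow | 1450 | 12.55 | 1029 |
| cortical bone | 3514 | 54.55 | 1908 |

`build_medium()` embeds the phantom between water layers (0.5 mm in front,
2.3 mm behind by default, giving a 256 x 256 x 216 voxel grid in 3D) and
assigns each voxel exactly one material's constants.

**Absorption convention.** The solver uses a frequency power law
`alpha(f) = a * f^y` with the exponent fixed at `y = 2`, for which the
dispersion term required by the Kramers-Kronig relation vanishes: the
constituent materials are dispersionless by construction, so any dispersion
in the measured velocities is attributable to the microstructure. The
quadratic pre-factor is tied to each source's centre frequency,
`a = alpha_1MHz / f_c[MHz]`, so the quadratic law agrees with the linear
1 MHz law exactly at `f_c` (`absorption_prefactor()`).

**Smoothing.** All three property maps are smoothed by multiplying their
discrete spectra with a separable centred Blackman taper (`smooth_field()`),
which suppresses Gibbs oscillations and staircasing at voxelized interfaces.
The taper is defined directly in the frequency domain,
`0.42 + 0.5 cos(2 pi m / N) + 0.08 cos(4 pi m / N)` at signed bin offset `m`,
so it is exactly 1 at DC (the map mean is conserved) and 0 at Nyquist.
Medium maps are smoothed without peak restoration; the source plane is
smoothed with peak restoration (a no-op for a uniform plane source). This
smoothing is not cosmetic: it blurs each bone-water interface over a few
voxels and advances the transmitted phase by roughly 40 ns relative to sharp
interfaces in the bone-only slab, which is what brings the measured bone-only
phase velocities to their reference values. Cross-checks against the analytic
layered model therefore must use the same (smoothed, per-voxel) profile.

## The k-space solver

`run_simulation()` integrates the linear first-order acoustic equations
(momentum, mass conservation, pressure-density closure with the exponent-2
loss term) on staggered spatial grids with spectral derivatives and the
k-space temporal correction `sinc(c_ref |k| dt / 2)`. Implementation
decisions:

* **Reference speed.** `c_ref` defaults to 1450 m/s, the minimum material
  speed (marrow): this minimizes numerical dispersion in the slow material at
  the cost of a stricter stability bound.
* **Time step.** `dt = CFL * dx / c_max` with `c_max` the unsmoothed grid
  maximum (3514 m/s when bone is present) — the stability bound belongs to
  the fastest material. The CFL map is frequency-dependent
  (0.024, 0.035, 0.06, 0.08 at 250, 500, 750, 1000 kHz), smaller at lower
  frequencies where the minimum-speed reference requires it. Record lengths
  are 20 us for pulsed and 80 us for continuous runs; convergence of both
  choices is tested (`cfl_convergence()`, `duration_convergence()`).
* **Boundaries.** Transverse axes are periodic, so a uniform plane source
  stays a plane wave exactly; a 20-voxel split-field absorbing layer with
  2.0 Np/voxel strength closes both z ends. The damping ramp is quartic —
  only the thickness and strength are contractual, and the convergence and
  reference-uniformity tests bound the ramp's influence.
* **Source.** The plane source is injected additively into the split
  densities at the first interior plane. Everything measured downstream is
  invariant to the injection scale (the estimators are ratios or phase
  differences against a reference run with the identical source).
* **Measurement.** Pressure is recorded at every pixel of the last interior
  transverse plane, in the water behind the phantom.
* **Degenerate axes.** 1D and 2D runs use the same stepping code with
  degenerate axes. A transversely uniform 3D problem reduces to 1D exactly
  (to floating-point round-off): at transverse wavenumber zero the 3D
  operators equal the 1D operators. This is verified to `1e-6` relative and
  justifies running transversely uniform cases (bone-only slabs) in 1D.
  2D phantom runs are used for scaled trend and convergence checks; their
  velocity magnitudes are not comparable to 3D because disks scatter
  differently from spheres.
* **Numerics.** Spatial spectra are real-to-complex FFTs (FFTW, measured
  plans cached per geometry). At Nyquist bins the staggered derivative
  operator takes its real value `-/+ |k_N| sinc(...)` — the half-voxel shift
  makes the Nyquist derivative well defined. The discrete leapfrog energy
  (potential at integer steps, kinetic from the product of consecutive
  half-step velocities) is conserved to machine precision in a lossless
  periodic box, which the tests assert.

## Velocimetry

All velocities come from the substitution method: a time difference
`delta_t` between the phantom-path signal and an equal-length water path
gives `V = C_w / (1 + C_w delta_t / d)` with `d` the phantom thickness
(8 mm) and `C_w = 1500` m/s. A faster-than-water sample has `delta_t < 0`.

* **Group delay** (`group_delay()`): the lag at the maximum of the
  normalized cross-correlation of the two Hilbert envelopes. The correlation
  is circular at the record length — both records are quiet at their ends,
  and a delayed copy then produces an exactly symmetric peak, so the
  parabolic sub-sample refinement is exact for pure delays. The peak value
  (1 for an undistorted copy) quantifies envelope distortion by multipath
  scattering.
* **Phase delay** (`phase_delay()`): both records are zero-padded to four
  times their length; the per-bin phase difference comes from
  `Arg(R conj(S))`; unwrapping accumulates increments mapped into
  `(-pi, pi]` starting at the first non-DC bin (the phase difference tends
  to 0 at DC, which anchors the absolute branch); `delta_t` is the unwrapped
  difference at the bin nearest the carrier divided by `2 pi f_c`, with no
  interpolation across bins. The entire record is used deliberately — no
  time window isolates the direct arrival — so reverberations inside the
  sample contribute. This makes the estimator fully automatic, and it is
  also why a bone-only slab shows a frequency-dependent apparent phase
  velocity (3277 to 3583 m/s from 250 kHz to 1 MHz with these settings)
  even though the material itself is dispersionless: slab-face reflections
  interfere with the direct arrival. The sign convention makes later
  arrivals positive, matching the group estimator.
* **Steady-state phase** (`steady_state_phase()`): for continuous sources,
  the first local maximum after 90% of the duration is found in the signal
  and the reference (parabolic refinement), and the peak-time difference
  times the angular frequency, wrapped to `[0, 2 pi)`, is the phase. The
  wrap interval is chosen so reported plane means are positive radians.
  Sub-sample refinement matters little at the sub-nanosecond time steps used
  here but is recorded and switchable.
* **Plane statistics** use the population (n-denominator) standard
  deviation; with 65k plane pixels the n vs n-1 distinction is far below
  every tolerance in use.
* **Phase histograms** (`phase_histogram()`) use 16 bins of `2 pi / 16` (one
  sixteenth of a period). The Goodman criterion for adequate phased-array
  focusing corresponds to two bins (`2 pi / 8`); a field passes when at
  least 95% of the probability mass falls in two circularly adjacent bins.
  A constant offset may be applied before re-wrapping to keep a distribution
  away from the wrap seam; only offset-invariant quantities (mean shifts,
  spreads) should be compared across frequencies.

## The analytic cross-check

`layered_coefficients()` implements normal-incidence transmission and
reflection through a stack of lossy fluid layers between water half-spaces,
with complex wavenumber `k = 2 pi f / c - i alpha(f)` and impedance
`Z = rho omega / k`. The recursion runs back to front in Airy form, so only
decaying exponentials appear and arbitrarily lossy layers are numerically
safe; transmission is referenced against an equal-length all-water path to
match the substitution convention, with `T(0) = 1` at DC.
`synthesize_received_signal()` filters a reference record through `T(f)`
per DFT bin to produce the analytic received signal for transversely uniform
problems — the independent pathway used by the tests to validate solver plus
estimator end to end (agreement within 1%, typically 0.2%). Because the
filter is circular, its input should be a causal record with leading quiet
time (a water reference trace qualifies); feeding it the raw source series
would wrap phase-advanced energy to the end of the record.

## Problem sizes and what the tests show

The shipped tests and the acceptance script run at desk scale: bone-only
slabs in 1D-equivalent mode at the full axial geometry and all four
frequencies; microstructure trends on 2D phantoms (2.4 mm transverse, 4 mm
slab, 500 kHz, 12 us, three seeds); convergence on a 2D 50%-porosity
phantom at full axial geometry; 3D only on a small transversely uniform
fixture. These sizes were chosen so the whole suite completes in minutes
while still exercising every code path at full fidelity in the axial
dimension. The full-scale 3D sweep (77 phantoms, four frequencies) uses the
identical code through `run_sweep(sweep_config())` and runs for hours; its
plane-statistics magnitudes (group velocities 3147 to 2211 m/s across
0.1-0.6 mm pores at 25% porosity and 500 kHz) are not asserted by the desk
tests, which check instead the trends that generate them: velocity strictly
decreasing with porosity, non-increasing with pore diameter, and the two
estimators' exact identities.

What the synthetic phantoms do not model — and hence what passing tests do
not show about real skulls: depth-dependent porosity, the three-layer
cortical/trabecular macrostructure, non-spherical or polydisperse pores,
anisotropy, elastic shear-wave conversion and poroelastic (fast/slow wave)
effects. The fluid model is a reasonable approximation for normally incident
plane waves; oblique incidence would need an elastic treatment.

## Degenerate inputs and failure modes

Non-positive pore diameters, porosities outside `[0, 1)`, extents that are
not voxel multiples, CFL numbers outside `(0, 1)`, unsupported power-law
exponents, carriers outside the resolvable band, zero-variance envelopes and
steady-state windows shorter than one source period are all rejected with
informative errors. A diverging run reports the step at which pressure
became non-finite. A sweep cell that fails is warned about and skipped;
completed cells are cached by configuration hash and a resume with a
different configuration is refused.
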