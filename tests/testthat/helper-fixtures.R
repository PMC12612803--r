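# Shared fixtures, memoized so expensive simulations run once per test session.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# full-geometry 1D-equivalent all-cortical slab (water 0.5 | bone 8 | water 2.3 mm)
bone_medium_1d <- function() {
  fixture("bone_medium_1d", function()
    build_medium(generate_phantom(phantom_spec(0.3, 0, dimensionality = 1))))
}

# pulsed bone-slab run + water reference at one of the four study frequencies,
# with the standard settings (20 us, frequency-matched CFL)
bone_run_1d <- function(f_c) {
  fixture(paste0("bone_run_", f_c), function() {
    med <- bone_medium_1d()
    src <- source_spec("single_cycle", f_c)
    cfl <- cfl_for_frequency(f_c)
    list(rec = run_simulation(med, src, cfl = cfl),
         ref = run_reference(med, src, cfl = cfl),
         med = med)
  })
}

# small 1D water-only medium for fast propagation checks
small_water_1d <- function(z_mm = 3.2, pad = 0.5) {
  ph <- generate_phantom(phantom_spec(0.3, 0, extent = c(0.8, 0.8, z_mm),
                                      dimensionality = 1))
  water_medium(build_medium(ph, front_water = pad, back_water = pad))
}

# scaled 2D phantom cell used by the microstructure trend checks:
# 2.4 mm transverse, 4 mm slab, 500 kHz, 12 us record
trend_cell_2d <- function(pore_diameter, porosity, seed) {
  key <- sprintf("trend_%g_%g_%d", pore_diameter, porosity, seed)
  fixture(key, function() {
    ph <- generate_phantom(phantom_spec(pore_diameter, porosity,
                                        extent = c(2.4, 2.4, 4),
                                        dimensionality = 2, seed = seed,
                                        porosity_tolerance = 0.05))
    med <- build_medium(ph, front_water = 0.5, back_water = 1.5)
    src <- source_spec("single_cycle", 500e3)
    ref <- fixture("trend_ref", function()
      run_reference(med, src, cfl = 0.035, duration = 1.2e-5))
    rec <- run_simulation(med, src, cfl = 0.035, duration = 1.2e-5)
    list(group = velocity_field(rec, ref, "group", thickness = 4e-3),
         phase = velocity_field(rec, ref, "phase", thickness = 4e-3))
  })
}

# brute-force lattice count of voxel centres strictly inside a sphere
brute_force_sphere_count <- function(center, diameter, spec) {
  dims <- spec$dims
  vox <- spec$voxel_size
  cnt <- 0L
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
    for (i in seq_len(dims[1])) {
      cc <- (c(i, j, k) - 0.5) * vox
      d2 <- sum((cc[spec$active_axes] - center[spec$active_axes])^2)
      if (d2 < (diameter / 2)^2 * (1 - 1e-9)) cnt <- cnt + 1L
    }
  cnt
}
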