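#' CFL number for a source frequency
#'
#' Lower frequencies need smaller CFL numbers for stability with the
#' minimum-speed k-space reference; the default map covers the four standard
#' therapy-band frequencies.
#'
#' @param frequency Frequency in Hz.
#' @param map Named vector, names are frequencies in Hz.
#' @return CFL number.
#' @export
cfl_for_frequency <- function(frequency,
                              map = c(`250000` = 0.024, `500000` = 0.035,
                                      `750000` = 0.06, `1000000` = 0.08)) {
  key <- format(round(frequency), scientific = FALSE)
  if (!key %in% names(map))
    stop("no CFL entry for frequency ", frequency, " Hz; extend the map",
         call. = FALSE)
  unname(map[key])
}

#' Sweep configuration
#'
#' Describes a full factorial experiment over pore diameters, porosities,
#' frequencies and source kinds. The defaults are the full-scale 3D study
#' conditions; reduced-dimensionality desk-scale sweeps are obtained by
#' overriding `dimensionality`, `extent` and the lists.
#'
#' @param pore_diameters Pore diameters in mm.
#' @param porosities Target porosities (fractions). Eleven values spanning
#'   2.5\% to 80\% by default.
#' @param frequencies Source centre frequencies in Hz.
#' @param source_kinds `"single_cycle"` and/or `"continuous"`.
#' @param methods Velocity methods measured for pulsed cells (`"group"`,
#'   `"phase"`); continuous cells always measure the steady-state phase.
#' @param cfl_map Named CFL-per-frequency vector, see [cfl_for_frequency()].
#' @param durations Durations in s per source kind.
#' @param dimensionality Phantom/simulation dimensionality (1, 2 or 3).
#' @param extent Phantom extent in mm.
#' @param voxel_size Voxel size in mm.
#' @param seeds Phantom seeds; one phantom per (diameter, porosity, seed).
#' @param porosity_tolerance Phantom porosity tolerance.
#' @param front_water,back_water Water padding in mm.
#' @param water_speed Reference water speed for the substitution equation.
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(pore_diameters = c(0.1, 0.2, 0.3, 0.4, 0.6),
                         porosities = c(0.025, 0.05, 0.1, 0.15, 0.2, 0.25,
                                        0.3, 0.4, 0.5, 0.65, 0.8),
                         frequencies = c(250e3, 500e3, 750e3, 1e6),
                         source_kinds = "single_cycle",
                         methods = c("group", "phase"),
                         cfl_map = c(`250000` = 0.024, `500000` = 0.035,
                                     `750000` = 0.06, `1000000` = 0.08),
                         durations = c(single_cycle = 20e-6,
                                       continuous = 80e-6),
                         dimensionality = 3,
                         extent = c(12.8, 12.8, 8), voxel_size = 0.05,
                         seeds = 1L, porosity_tolerance = 0.005,
                         front_water = 0.5, back_water = 2.3,
                         water_speed = 1500) {
  missing_f <- setdiff(format(round(frequencies), scientific = FALSE),
                       names(cfl_map))
  if (length(missing_f))
    stop("cfl_map does not cover frequencies: ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  stopifnot(all(methods %in% c("group", "phase")))
  structure(list(pore_diameters = pore_diameters, porosities = porosities,
                 frequencies = frequencies, source_kinds = source_kinds,
                 methods = methods,
                 cfl_map = cfl_map, durations = durations,
                 dimensionality = dimensionality, extent = extent,
                 voxel_size = voxel_size, seeds = as.integer(seeds),
                 porosity_tolerance = porosity_tolerance,
                 front_water = front_water, back_water = back_water,
                 water_speed = water_speed),
            class = "sweep_config")
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Run a full phantom / frequency / method sweep
#'
#' For every cell: generate the phantom, build and smooth the medium, run
#' the water reference (cached per frequency, kind and discretization), run
#' the phantom simulation, and measure the requested quantities. Pulsed
#' sources yield group- and phase-velocity rows; continuous sources yield a
#' steady-state-phase row. Per-cell failures are caught, reported as warnings
#' and skipped, so one bad cell does not lose the sweep.
#'
#' With `cache_dir`, completed cells are written as CSV keyed by a content
#' hash of the configuration and cell coordinates, and reruns skip them; a
#' manifest records the configuration hash and a resume with a different
#' configuration is refused.
#'
#' @param config A [sweep_config()].
#' @param cache_dir Optional directory for resumable per-cell caching.
#' @param verbose Print per-cell progress.
#' @return A tibble with one row per (phantom, frequency, method):
#'   `phantom_id`, `pore_diameter`, `nominal_porosity`, `achieved_porosity`,
#'   `seed`, `frequency`, `source_kind`, `method`, `mean`, `std`,
#'   `peak_correlation`, `n_spheres`, `elapsed_s`, `config_hash`, `cached`.
#' @export
run_sweep <- function(config, cache_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  chash <- config_hash(config)
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- file.path(cache_dir, "manifest.json")
    if (file.exists(manifest)) {
      prev <- jsonlite::read_json(manifest)
      if (!identical(prev$config_hash, chash))
        stop("cache_dir belongs to a different configuration; refusing to resume",
             call. = FALSE)
    } else jsonlite::write_json(list(config_hash = chash), manifest,
                                auto_unbox = TRUE)
  }
  thickness <- config$extent[3] * 1e-3
  ref_cache <- new.env(parent = emptyenv())
  cells <- tidyr::expand_grid(seed = config$seeds,
                              pore_diameter = config$pore_diameters,
                              porosity = config$porosities,
                              frequency = config$frequencies,
                              source_kind = config$source_kinds)
  phantom_key <- ""
  medium <- NULL; phantom <- NULL
  rows <- purrr::pmap(cells, function(seed, pore_diameter, porosity,
                                      frequency, source_kind) {
    cell_id <- rlang::hash(list(chash, seed, pore_diameter, porosity,
                                frequency, source_kind))
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, paste0("cell-", cell_id, ".csv"))
    if (!is.null(cache_dir) && file.exists(cache_file)) {
      out <- tibble::as_tibble(utils::read.csv(cache_file))
      out$cached <- TRUE
      return(out)
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      pk <- paste(seed, pore_diameter, porosity)
      if (!identical(pk, phantom_key)) {
        spec <- phantom_spec(pore_diameter, porosity, extent = config$extent,
                             voxel_size = config$voxel_size,
                             dimensionality = config$dimensionality,
                             seed = seed,
                             porosity_tolerance = config$porosity_tolerance)
        phantom <<- generate_phantom(spec)
        medium <<- build_medium(phantom, front_water = config$front_water,
                                back_water = config$back_water)
        phantom_key <<- pk
      }
      src <- source_spec(if (source_kind == "single_cycle") "single_cycle"
                         else "continuous", frequency)
      cfl <- cfl_for_frequency(frequency, config$cfl_map)
      dur <- config$durations[[source_kind]]
      rkey <- paste(source_kind, frequency, cfl, dur,
                    paste(dim(medium$sound_speed), collapse = "x"))
      if (is.null(ref_cache[[rkey]]))
        ref_cache[[rkey]] <- run_reference(medium, src, cfl = cfl,
                                           duration = dur)
      ref <- ref_cache[[rkey]]
      rec <- run_simulation(medium, src, cfl = cfl, duration = dur)
      el <- proc.time()[["elapsed"]] - t0
      base <- tibble::tibble(
        phantom_id = sprintf("d%.2g-p%.3g-s%d", pore_diameter, porosity, seed),
        pore_diameter = pore_diameter, nominal_porosity = porosity,
        achieved_porosity = phantom$achieved_porosity, seed = seed,
        frequency = frequency, source_kind = source_kind,
        n_spheres = phantom$n_spheres_placed, elapsed_s = el,
        config_hash = chash, cached = FALSE)
      if (source_kind == "single_cycle") {
        gs <- lapply(config$methods, function(m)
          glance(velocity_field(rec, ref, m, thickness = thickness,
                                water_speed = config$water_speed)))
        dplyr::bind_cols(dplyr::bind_rows(gs)[, c("method", "mean", "std",
                                                  "peak_correlation")],
                         base[rep(1, length(config$methods)), ])
      } else {
        g <- glance(phase_field(rec, ref))
        dplyr::bind_cols(g[, c("method", "mean", "std", "peak_correlation")],
                         base)
      }
    }, error = function(e) {
      warning(sprintf("cell (d=%g, p=%g, f=%g, %s, seed %d) failed: %s",
                      pore_diameter, porosity, frequency, source_kind, seed,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(res) && !is.null(cache_dir))
      utils::write.csv(res[setdiff(names(res), "cached")], cache_file,
                       row.names = FALSE)
    if (verbose && !is.null(res))
      message(sprintf("done d=%g p=%g f=%g kHz %s", pore_diameter, porosity,
                      frequency / 1e3, source_kind))
    res
  })
  dplyr::bind_rows(rows)
}

#' Time-step convergence test
#'
#' Runs one phantom/frequency case at the nominal CFL and at `cfl / factor`,
#' and reports the plane-averaged percentage difference in the measured
#' velocities per method, `100 * |V_fine - V_coarse| / V_fine`.
#'
#' @param medium A `medium_maps`.
#' @param frequency Source frequency in Hz.
#' @param cfl Nominal CFL (default from [cfl_for_frequency()]).
#' @param factor Refinement factor for the fine run.
#' @param methods Velocity methods to compare.
#' @param thickness Phantom thickness in m.
#' @param duration Pulse record duration in s.
#' @return Tibble with `method` and `percent_difference`.
#' @export
cfl_convergence <- function(medium, frequency, cfl = NULL, factor = 2,
                            methods = c("group", "phase"),
                            thickness = 8e-3, duration = 20e-6) {
  if (is.null(cfl)) cfl <- cfl_for_frequency(frequency)
  src <- source_spec("single_cycle", frequency)
  one <- function(cc) {
    rec <- run_simulation(medium, src, cfl = cc, duration = duration)
    ref <- run_reference(medium, src, cfl = cc, duration = duration)
    lapply(methods, function(m)
      velocity_field(rec, ref, m, thickness = thickness))
  }
  coarse <- one(cfl)
  fine <- one(cfl / factor)
  tibble::tibble(
    method = methods,
    percent_difference = purrr::map2_dbl(fine, coarse, function(f, c)
      100 * mean(abs(f$values - c$values) / f$values)))
}

#' Record-duration convergence test for the steady-state phase
#'
#' Runs a continuous-wave case at `duration` and `factor * duration` and
#' reports the maximum percentage difference of the steady-state phase
#' across the measurement plane (angular differences taken on the circle).
#'
#' @param medium A `medium_maps`.
#' @param frequency Source frequency in Hz.
#' @param duration Base duration in s.
#' @param factor Duration multiplier for the long run.
#' @param cfl CFL number (default from [cfl_for_frequency()]).
#' @return Maximum percentage difference (scalar).
#' @export
duration_convergence <- function(medium, frequency = 250e3,
                                 duration = 80e-6, factor = 2, cfl = NULL) {
  if (is.null(cfl)) cfl <- cfl_for_frequency(frequency)
  src <- source_spec("continuous", frequency)
  one <- function(dur) {
    rec <- run_simulation(medium, src, cfl = cfl, duration = dur)
    ref <- run_reference(medium, src, cfl = cfl, duration = dur)
    phase_field(rec, ref)
  }
  short <- one(duration)
  long <- one(factor * duration)
  dphi <- abs(wrap_phase(long$values - short$values))
  max(100 * dphi / abs(long$values))
}

#' Figures and summaries from a sweep table
#'
#' Produces the velocity-versus-porosity figure per method (one line per
#' pore diameter, one panel per frequency, standard-deviation error bars)
#' and, when requested, writes a deterministic CSV summary and JSON
#' manifest.
#'
#' @param table Result tibble from [run_sweep()].
#' @param out_dir Optional output directory for `summary.csv`,
#'   `manifest.json` and PDF figures.
#' @return List with `summary` (the table) and `plots` (named list of
#'   ggplots).
#' @export
make_report <- function(table, out_dir = NULL) {
  stopifnot(nrow(table) > 0)
  plots <- list()
  for (m in c("group", "phase")) {
    sub <- dplyr::filter(table, .data$method == m)
    if (nrow(sub) == 0) {
      warning("no rows for method '", m, "'; panel skipped", call. = FALSE)
      next
    }
    plots[[m]] <- plot_velocity_porosity(sub) +
      ggplot2::labs(title = paste(m, "velocity"))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(table[order(table$phantom_id, table$frequency,
                                 table$method), ],
                     file.path(out_dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(list(n_rows = nrow(table),
                              config_hash = unique(table$config_hash)),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    for (nm in names(plots))
      ggplot2::ggsave(file.path(out_dir, paste0("velocity_", nm, ".pdf")),
                      plots[[nm]], width = 7, height = 5)
  }
  list(summary = table, plots = plots)
}

#' Velocity-porosity curves from a sweep table
#'
#' @param table Sweep rows for one method.
#' @return A ggplot: mean velocity against achieved porosity, coloured by
#'   pore diameter, faceted by frequency, with plane-standard-deviation
#'   error bars.
#' @export
plot_velocity_porosity <- function(table) {
  ggplot2::ggplot(table,
                  ggplot2::aes(.data$achieved_porosity, .data$mean,
                               colour = factor(.data$pore_diameter),
                               group = factor(.data$pore_diameter))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$std,
                                        ymax = .data$mean + .data$std),
                           width = 0.01) +
    ggplot2::facet_wrap(~ .data$frequency, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "porosity", y = "velocity (m/s)",
                  colour = "pore diameter (mm)")
}
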