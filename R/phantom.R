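#' Specification of a porous bone phantom
#'
#' A phantom is a voxelized block of cortical bone into which spherical
#' red-marrow pores of a single diameter are carved at random positions,
#' overlapping freely, until a target porosity (marrow volume fraction) is
#' reached. All lengths are in millimetres.
#'
#' @param pore_diameter Pore diameter in mm. Must be positive and at least
#'   twice the voxel size so that every pore covers at least one voxel centre.
#' @param target_porosity Target marrow volume fraction in `[0, 1)`.
#' @param extent Physical extent of the phantom in mm, a length-3 vector
#'   `(x, y, z)`. Must be an integer multiple of `voxel_size` on every axis.
#'   Axes beyond `dimensionality` are collapsed to a single voxel.
#' @param voxel_size Isotropic voxel edge length in mm.
#' @param dimensionality 1, 2 or 3. Lower-dimensional phantoms use segment and
#'   disk analogues of the spherical pore and are intended for reduced-scale
#'   runs; their velocity magnitudes are not comparable to 3D (disks scatter
#'   differently from spheres).
#' @param seed Integer seed; phantom generation is bit-reproducible for a
#'   fixed spec and seed.
#' @param porosity_tolerance Maximum allowed absolute deviation of the
#'   achieved porosity from the target. Porosity grows in jumps of one pore's
#'   marginal volume, so small grids with coarse pores need a looser tolerance.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(pore_diameter, target_porosity,
                         extent = c(12.8, 12.8, 8), voxel_size = 0.05,
                         dimensionality = 3, seed = 1L,
                         porosity_tolerance = 0.005) {
  stopifnot(length(extent) == 3, voxel_size > 0,
            dimensionality %in% 1:3, porosity_tolerance >= 0)
  if (!is.numeric(pore_diameter) || pore_diameter <= 0)
    stop("pore_diameter must be positive", call. = FALSE)
  if (pore_diameter < 2 * voxel_size)
    stop("pore_diameter must be at least twice the voxel size", call. = FALSE)
  if (target_porosity < 0 || target_porosity >= 1)
    stop("target_porosity must lie in [0, 1)", call. = FALSE)
  n_vox <- extent / voxel_size
  if (any(abs(n_vox - round(n_vox)) > 1e-8))
    stop("extent must be an integer multiple of voxel_size on every axis",
         call. = FALSE)
  # active axes are x (1), y (2), z (3) reduced from the left: 1D keeps z
  active <- switch(dimensionality, `1` = 3L, `2` = c(1L, 3L), `3` = 1:3)
  dims <- rep(1L, 3)
  dims[active] <- as.integer(round(n_vox[active]))
  structure(list(pore_diameter = pore_diameter,
                 target_porosity = target_porosity,
                 extent = extent, voxel_size = voxel_size,
                 dimensionality = as.integer(dimensionality),
                 dims = dims, active_axes = active,
                 seed = as.integer(seed),
                 porosity_tolerance = porosity_tolerance),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dD, %g mm pores, target porosity %.3f\n",
              x$dimensionality, x$pore_diameter, x$target_porosity))
  cat(sprintf("  grid %s voxels at %g mm, seed %d\n",
              paste(x$dims, collapse = "x"), x$voxel_size, x$seed))
  invisible(x)
}

#' Voxelize a sphere on a phantom grid
#'
#' Returns the indices of all voxels whose centres lie strictly within
#' `diameter / 2` of `center`. In 2D and 1D the disk and segment analogues are
#' used (distance is measured over the active axes only). Pores are clipped at
#' the grid faces; there is no transverse wrap-around of the pore geometry.
#'
#' @param center Sphere centre in mm, length 3 (components on inactive axes
#'   are ignored).
#' @param diameter Sphere diameter in mm, must be positive.
#' @param spec A [phantom_spec()] providing the grid geometry.
#' @return An integer matrix with one row per covered voxel and columns
#'   `(i, j, k)` of 1-based array indices.
#' @export
rasterize_sphere <- function(center, diameter, spec) {
  if (!is.numeric(diameter) || length(diameter) != 1 || diameter <= 0)
    stop("diameter must be a positive number", call. = FALSE)
  stopifnot(length(center) == 3)
  vox <- spec$voxel_size
  r <- diameter / 2
  rng <- vector("list", 3)
  for (ax in 1:3) {
    if (ax %in% spec$active_axes) {
      lo <- max(1L, as.integer(floor((center[ax] - r) / vox)))
      hi <- min(spec$dims[ax], as.integer(ceiling((center[ax] + r) / vox + 1)))
      if (lo > hi) return(matrix(integer(0), ncol = 3,
                                 dimnames = list(NULL, c("i", "j", "k"))))
      rng[[ax]] <- lo:hi
    } else rng[[ax]] <- 1L
  }
  g <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  d2 <- 0
  for (ax in spec$active_axes) {
    cc <- (g[[ax]] - 0.5) * vox
    d2 <- d2 + (cc - center[ax])^2
  }
  # strict inequality on the voxel-centre distance, with a relative epsilon
  # so centres sitting exactly at radius r are excluded despite rounding
  keep <- d2 < r^2 * (1 - 1e-9)
  out <- as.matrix(g[keep, , drop = FALSE])
  dimnames(out) <- list(NULL, c("i", "j", "k"))
  storage.mode(out) <- "integer"
  out
}

#' Generate a porous bone phantom
#'
#' Starting from an all-cortical block, sphere centres are drawn uniformly
#' over the phantom extent and carved to marrow (overlap allowed) until the
#' achieved porosity first reaches the target. Generation is deterministic for
#' a fixed spec and seed, using an RNG stream local to this call.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_volume`: list with `labels` (3D logical array, `TRUE` =
#'   marrow), `achieved_porosity`, `n_spheres_placed` and the `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- array(FALSE, dim = spec$dims)
  total <- prod(spec$dims)
  n_marrow <- 0L
  n_spheres <- 0L
  if (spec$target_porosity > 0) {
    # local RNG stream: restore the caller's state on exit
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    } else on.exit(suppressWarnings(rm(list = ".Random.seed",
                                       envir = globalenv())), add = TRUE)
    set.seed(spec$seed)
    # generous cap: expected count times a wide safety factor
    vol_sphere <- switch(spec$dimensionality,
                         spec$pore_diameter,
                         pi * (spec$pore_diameter / 2)^2,
                         4 / 3 * pi * (spec$pore_diameter / 2)^3)
    vol_total <- prod(spec$extent[spec$active_axes])
    max_iter <- max(1000, ceiling(50 * spec$target_porosity *
                                    vol_total / vol_sphere))
    while (n_marrow / total < spec$target_porosity) {
      if (n_spheres >= max_iter)
        stop(sprintf(paste0("porosity target %.4f unreachable after %d pores",
                            " (achieved %.4f)"),
                     spec$target_porosity, n_spheres, n_marrow / total),
             call. = FALSE)
      center <- runif(3) * spec$extent
      idx <- rasterize_sphere(center, spec$pore_diameter, spec)
      n_spheres <- n_spheres + 1L
      if (nrow(idx) == 0) next
      fresh <- !labels[idx]
      if (any(fresh)) {
        labels[idx[fresh, , drop = FALSE]] <- TRUE
        n_marrow <- n_marrow + sum(fresh)
      }
    }
  }
  achieved <- n_marrow / total
  if (abs(achieved - spec$target_porosity) > spec$porosity_tolerance)
    stop(sprintf(paste0("achieved porosity %.4f misses target %.4f by more ",
                        "than the tolerance %.4f; closest achievable with ",
                        "these pores overshoots by one pore's marginal volume"),
                 achieved, spec$target_porosity, spec$porosity_tolerance),
         call. = FALSE)
  structure(list(labels = labels, achieved_porosity = achieved,
                 n_spheres_placed = n_spheres, spec = spec),
            class = "phantom_volume")
}

#' Marrow volume fraction of a phantom
#'
#' Recomputes the porosity as the marrow-voxel count divided by the total
#' voxel count.
#'
#' @param volume A `phantom_volume`, or a logical array of marrow labels.
#' @return Porosity in `[0, 1]`.
#' @export
measure_porosity <- function(volume) {
  labels <- if (inherits(volume, "phantom_volume")) volume$labels else volume
  if (length(labels) == 0) stop("empty phantom grid", call. = FALSE)
  sum(labels) / length(labels)
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat(sprintf("<phantom_volume> %s voxels, porosity %.4f (target %.4f), %d pores\n",
              paste(dim(x$labels), collapse = "x"), x$achieved_porosity,
              x$spec$target_porosity, x$n_spheres_placed))
  invisible(x)
}

#' Write a phantom to NIfTI with a JSON sidecar
#'
#' The label grid is stored as one byte per voxel (1 = marrow) with the voxel
#' size in the NIfTI header; the full spec, seed, achieved porosity and sphere
#' count go to `<path>.json`.
#'
#' @param volume A `phantom_volume`.
#' @param path Output path; `.nii` is appended if missing.
#' @return The NIfTI path, invisibly.
#' @export
write_phantom <- function(volume, path) {
  stopifnot(inherits(volume, "phantom_volume"))
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii")
  img <- array(as.integer(volume$labels), dim = dim(volume$labels))
  attr(img, "pixdim") <- rep(volume$spec$voxel_size, 3)
  nii <- RNifti::asNifti(img, datatype = "uint8")
  RNifti::writeNifti(nii, path)
  side <- volume$spec[c("pore_diameter", "target_porosity", "extent",
                        "voxel_size", "dimensionality", "seed",
                        "porosity_tolerance")]
  side$achieved_porosity <- volume$achieved_porosity
  side$n_spheres_placed <- volume$n_spheres_placed
  jsonlite::write_json(side, paste0(sub("\\.nii(\\.gz)?$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
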