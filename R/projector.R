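# Analytic attenuated parallel-beam projector with distance-dependent
# Gaussian collimator-detector response (photopeak-only approximation), plus
# count-level scaling and Poisson noise realizations.

#' SPECT acquisition geometry
#'
#' Parallel-beam geometry with a uniform 360-degree orbit.  The detector bin
#' raster matches the phantom voxel raster (bin size = voxel size), so the
#' detector matrix is `nx x nz`.  The collimator-detector response is a
#' Gaussian whose width grows linearly with distance to the detector plane,
#' `sigma(d) = sigma0 + slope * d`; the defaults absorb the photopeak energy
#' window, the intrinsic resolution and the collimator blur of a
#' medium-energy system into a single analytic kernel.
#'
#' @param n_views number of projection views over 360 degrees.
#' @param sigma0_mm Gaussian response width at the detector face (mm).
#' @param sigma_slope response growth per mm of source-detector distance.
#' @param det_radius_mm detector orbit radius (mm, fixed, non-contouring).
#' @param exposure_scale counts recorded per MBq in a view (absorbs
#'   acquisition time and camera sensitivity).
#' @return A `spect_geometry` object.
#' @export
spect_geometry <- function(n_views = 120, sigma0_mm = 2, sigma_slope = 0.02,
                           det_radius_mm = 250, exposure_scale = 20) {
  stopifnot(n_views >= 1, sigma0_mm >= 0, sigma_slope >= 0,
            det_radius_mm > 0, exposure_scale > 0)
  structure(list(n_views = as.integer(n_views),
                 angles = seq(0, 2 * pi, length.out = n_views + 1)[1:n_views],
                 sigma0_mm = sigma0_mm, sigma_slope = sigma_slope,
                 det_radius_mm = det_radius_mm,
                 exposure_scale = exposure_scale),
            class = "spect_geometry")
}

#' @export
print.spect_geometry <- function(x, ...) {
  cat(sprintf(paste0("spect_geometry: %d views / 360 deg, radius %g mm, ",
                     "sigma(d) = %g + %g d mm\n"),
              x$n_views, x$det_radius_mm, x$sigma0_mm, x$sigma_slope))
  invisible(x)
}

new_projection_set <- function(counts, geometry, voxel_mm, exposure_scale,
                               noise_free, seed = NA_integer_,
                               scale_factor = 1) {
  structure(list(counts = counts, angles = geometry$angles,
                 geometry = geometry, voxel_mm = voxel_mm,
                 exposure_scale = exposure_scale, noise_free = noise_free,
                 seed = seed, scale_factor = scale_factor),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("projection_set: %d x %d bins x %d views, %s, total %.4g counts\n",
              d[1], d[2], d[3],
              if (x$noise_free) "noise-free (expected counts)"
              else sprintf("Poisson realization (seed %d)", x$seed),
              sum(x$counts)))
  invisible(x)
}

#' Forward-project a phantom
#'
#' Computes noise-free expected projection counts: for each view the volume
#' is rotated to the detector frame, each slab's activity is attenuated by
#' the accumulated attenuation towards the detector, blurred with the
#' distance-dependent Gaussian response, and summed along the rays.  The
#' operation is linear in the activity grid.
#'
#' @param phantom a [voxel_phantom()].
#' @param geometry a [spect_geometry()].
#' @return A `projection_set` of expected counts
#'   (`nx x nz x n_views`).
#' @export
forward_project <- function(phantom, geometry = spect_geometry()) {
  if (!all(is.finite(phantom$activity)) || !all(is.finite(phantom$mu)))
    stop("phantom grids must be finite")
  act_vox <- phantom$activity * voxel_volume_ml(phantom) # MBq per voxel
  counts <- cpp_forward_project(act_vox, phantom$mu, geometry$angles,
                                phantom$voxel_mm, geometry$sigma0_mm,
                                geometry$sigma_slope, geometry$det_radius_mm)
  counts <- counts * geometry$exposure_scale
  new_projection_set(counts, geometry, phantom$voxel_mm,
                     geometry$exposure_scale, noise_free = TRUE)
}

#' Noise-level specification
#'
#' Describes a target count level, either as a grand total over all bins or
#' as the mean expected count over the detector bins whose rays intersect a
#' reference region (the patient-matching normalization used for the body
#' phantom, with the right kidney as the reference).
#'
#' @param mode `"total_counts"` or `"reference_region"`.
#' @param target positive target (grand total, or mean counts per
#'   contributing bin).
#' @param reference label codes of the reference region (reference mode).
#' @param label short label, e.g. `"eta_max"`.
#' @export
noise_level_spec <- function(mode = c("total_counts", "reference_region"),
                             target, reference = NULL, label = "custom") {
  mode <- match.arg(mode)
  stopifnot(target > 0)
  if (mode == "reference_region" && is.null(reference))
    stop("reference_region mode needs reference label codes")
  structure(list(mode = mode, target = target, reference = reference,
                 label = label), class = "noise_level_spec")
}

# detector bins whose rays intersect the given label codes (logical array
# shaped like the projections); brute force via an unblurred, unattenuated
# projection of the region indicator
region_bin_mask <- function(phantom, geometry, codes) {
  ind <- array(0, dim(phantom$label))
  ind[phantom$label %in% codes] <- 1
  if (sum(ind) == 0) stop("reference region is empty")
  zero_mu <- array(0, dim(phantom$label))
  p <- cpp_forward_project(ind, zero_mu, geometry$angles, phantom$voxel_mm,
                           0, 0, geometry$det_radius_mm)
  p > 1e-9
}

#' Scale projections to a target count level
#'
#' Multiplies a noise-free projection set by a single scalar so that the
#' requested count level is met; the scalar is recorded and the effective
#' exposure scale updated accordingly (so that a matching calibration uses
#' the same effective exposure).
#'
#' @param proj noise-free `projection_set`.
#' @param spec a [noise_level_spec()].
#' @param phantom the phantom the projections came from (needed to locate
#'   the reference region in reference mode).
#' @return The rescaled noise-free `projection_set`.
#' @export
scale_to_count_level <- function(proj, spec, phantom = NULL) {
  stopifnot(inherits(proj, "projection_set"), inherits(spec, "noise_level_spec"))
  if (!proj$noise_free) stop("can only scale noise-free projection sets")
  if (spec$mode == "total_counts") {
    cur <- sum(proj$counts)
  } else {
    if (is.null(phantom)) stop("phantom required for reference_region mode")
    mask <- region_bin_mask(phantom, proj$geometry, spec$reference)
    cur <- mean(proj$counts[mask])
  }
  if (!is.finite(cur) || cur <= 0) stop("projections have no counts; cannot scale")
  s <- spec$target / cur
  out <- proj
  out$counts <- proj$counts * s
  out$exposure_scale <- proj$exposure_scale * s
  out$scale_factor <- proj$scale_factor * s
  out
}

#' Sample Poisson noise realizations
#'
#' Draws `n` independent Poisson realizations of a noise-free projection
#' set.  Realization `i` is seeded `base_seed + i`, so any single
#' realization is reproducible in isolation.
#'
#' @param proj noise-free `projection_set` of expected counts.
#' @param n number of realizations (>= 1).
#' @param base_seed integer base seed.
#' @return List of integer-valued `projection_set` realizations.
#' @export
sample_noise_realizations <- function(proj, n, base_seed = 1) {
  stopifnot(inherits(proj, "projection_set"))
  if (!proj$noise_free) stop("input must be noise-free")
  if (n < 1) stop("n must be >= 1")
  lambda <- as.vector(proj$counts)
  if (!all(is.finite(lambda))) stop("expected counts must be finite")
  lapply(seq_len(n), function(i) {
    set.seed(base_seed + i)
    # double storage: C++ entry points take numeric arrays by reference
    cts <- array(as.double(rpois(length(lambda), lambda)), dim(proj$counts))
    out <- proj
    out$counts <- cts
    out$noise_free <- FALSE
    out$seed <- as.integer(base_seed + i)
    out
  })
}
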