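# External interfaces: NIfTI-1 volumes with JSON sidecars for phantoms and
# reconstructions, raw binary + JSON sidecar for projection sets, JSON/NIfTI
# export for VOIs.

nifti_with_pixdim <- function(arr, voxel_mm) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_mm, 3)
  img
}

#' Write/read a voxel phantom as NIfTI + JSON sidecar
#'
#' Writes `<prefix>_label.nii.gz`, `<prefix>_mu.nii.gz`,
#' `<prefix>_activity.nii.gz` and `<prefix>.json` (organ table, voxel size,
#' units).
#'
#' @param phantom a [voxel_phantom()].
#' @param prefix output path prefix.
#' @return `read_phantom` returns the [voxel_phantom()].
#' @export
write_phantom <- function(phantom, prefix) {
  RNifti::writeNifti(nifti_with_pixdim(phantom$label, phantom$voxel_mm),
                     paste0(prefix, "_label.nii.gz"))
  RNifti::writeNifti(nifti_with_pixdim(phantom$mu, phantom$voxel_mm),
                     paste0(prefix, "_mu.nii.gz"))
  RNifti::writeNifti(nifti_with_pixdim(phantom$activity, phantom$voxel_mm),
                     paste0(prefix, "_activity.nii.gz"))
  side <- list(voxel_mm = phantom$voxel_mm,
               units = list(activity = "MBq/mL", mu = "1/cm"),
               organs = phantom$organs)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  lab <- RNifti::readNifti(paste0(prefix, "_label.nii.gz"))
  voxel_phantom(array(as.integer(lab), dim(lab)),
                array(as.numeric(RNifti::readNifti(paste0(prefix, "_mu.nii.gz"))),
                      dim(lab)),
                array(as.numeric(RNifti::readNifti(
                  paste0(prefix, "_activity.nii.gz"))), dim(lab)),
                side$voxel_mm, as.data.frame(side$organs))
}

#' Write/read a projection set as raw binary + JSON sidecar
#'
#' Bin values go to `<prefix>.bin` (little-endian float64, column-major);
#' shape, angles, geometry, exposure scale, noise flag and seed go to
#' `<prefix>.json`.
#'
#' @param proj a `projection_set`.
#' @param prefix output path prefix.
#' @return `read_projections` returns the `projection_set`.
#' @export
write_projections <- function(proj, prefix) {
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(proj$counts), con, size = 8, endian = "little")
  g <- proj$geometry
  side <- list(dim = dim(proj$counts), angles = proj$angles,
               voxel_mm = proj$voxel_mm,
               geometry = list(n_views = g$n_views, sigma0_mm = g$sigma0_mm,
                               sigma_slope = g$sigma_slope,
                               det_radius_mm = g$det_radius_mm,
                               exposure_scale = g$exposure_scale),
               exposure_scale = proj$exposure_scale,
               noise_free = proj$noise_free, seed = proj$seed,
               scale_factor = proj$scale_factor)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_projections
#' @export
read_projections <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  d <- as.integer(side$dim)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  g <- spect_geometry(n_views = side$geometry$n_views,
                      sigma0_mm = side$geometry$sigma0_mm,
                      sigma_slope = side$geometry$sigma_slope,
                      det_radius_mm = side$geometry$det_radius_mm,
                      exposure_scale = side$geometry$exposure_scale)
  new_projection_set(array(vals, d), g, side$voxel_mm, side$exposure_scale,
                     side$noise_free,
                     if (is.null(side$seed)) NA_integer_ else side$seed,
                     side$scale_factor)
}

#' Write/read a reconstructed volume as NIfTI + JSON sidecar
#'
#' @param recon a `recon_volume`.
#' @param prefix output path prefix.
#' @param seed optional input-realization seed recorded in the sidecar.
#' @return `read_recon` returns the `recon_volume` (without snapshots).
#' @export
write_recon <- function(recon, prefix, seed = NA_integer_) {
  RNifti::writeNifti(nifti_with_pixdim(recon$grid, recon$voxel_mm),
                     paste0(prefix, ".nii.gz"))
  side <- list(voxel_mm = recon$voxel_mm, n_iterations = recon$n_iterations,
               n_subsets = recon$n_subsets, updates = recon$updates,
               seed = seed)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_recon
#' @export
read_recon <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  new_recon_volume(array(as.numeric(img), dim(img)), side$voxel_mm,
                   NULL, side$n_iterations, side$n_subsets)
}

#' Export VOIs as a label NIfTI and a JSON index list
#'
#' @param vois list of [voi()] objects.
#' @param grid_dim grid dimensions the indices refer to.
#' @param voxel_mm voxel size.
#' @param prefix output path prefix.
#' @export
write_vois <- function(vois, grid_dim, voxel_mm, prefix) {
  lab <- array(0L, grid_dim)
  for (i in seq_along(vois)) lab[vois[[i]]$idx] <- i
  RNifti::writeNifti(nifti_with_pixdim(lab, voxel_mm),
                     paste0(prefix, "_vois.nii.gz"))
  side <- lapply(vois, function(v)
    list(name = v$name, volume_ml = v$volume_ml, idx = v$idx))
  jsonlite::write_json(side, paste0(prefix, "_vois.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
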