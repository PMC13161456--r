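# OSEM/MLEM reconstruction with explicit iteration x subset ("updates")
# accounting, built on the projector's forward model and its exact matched
# adjoint (which guarantees monotone Poisson likelihood for 1 subset).

#' Partition views into ordered subsets
#'
#' Views are sorted by angle and dealt round-robin (view j joins subset
#' j mod n_subsets), giving equal-sized subsets with maximal angular spread.
#'
#' @param angles view angles (radians).
#' @param n_subsets number of subsets; must divide the number of views.
#' @return List of integer view-index vectors (1-based, into `angles`).
#' @export
partition_subsets <- function(angles, n_subsets) {
  n <- length(angles)
  if (n_subsets < 1 || n %% n_subsets != 0)
    stop(sprintf("n_subsets (%d) must divide the number of views (%d)",
                 n_subsets, n))
  ord <- order(angles)
  lapply(seq_len(n_subsets), function(k)
    ord[seq(k, n, by = n_subsets)])
}

new_recon_volume <- function(grid, voxel_mm, geometry, n_iterations,
                             n_subsets, snapshots = NULL) {
  structure(list(grid = grid, voxel_mm = voxel_mm, geometry = geometry,
                 n_iterations = n_iterations, n_subsets = n_subsets,
                 updates = n_iterations * n_subsets,
                 snapshots = snapshots),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  cat(sprintf("recon_volume: %s grid, %di%ds (%d updates)\n",
              paste(dim(x$grid), collapse = " x "),
              x$n_iterations, x$n_subsets, x$updates))
  invisible(x)
}

#' OSEM reconstruction
#'
#' Standard multiplicative OSEM update using the package projector as the
#' system model (attenuation and distance-dependent PSF inside the model)
#' and its exact transpose as back projector, with per-subset sensitivity
#' normalization.  Voxels with sensitivity below `sens_eps` are frozen at
#' zero.  With `n_subsets = 1` this is MLEM.
#'
#' @param proj a `projection_set`.
#' @param mu attenuation grid (1/cm) co-registered with the target volume
#'   (usually `phantom$mu`).
#' @param n_iterations full passes over all subsets.
#' @param n_subsets number of ordered subsets.
#' @param init initial volume (positive array) or `NULL` for uniform 1.
#' @param snapshot_iters iterations after which to snapshot the volume.
#' @param sens_eps sensitivity cutoff.
#' @return A `recon_volume`; grid units are counts per voxel (calibrate with
#'   [compute_icf()]).  Snapshots (if any) are stored as a named list of
#'   grids under `$snapshots`, keyed by update number.
#' @export
reconstruct_osem <- function(proj, mu, n_iterations, n_subsets = 1,
                             init = NULL, snapshot_iters = integer(0),
                             sens_eps = 1e-12) {
  stopifnot(inherits(proj, "projection_set"),
            n_iterations >= 1, n_subsets >= 1)
  g <- proj$geometry
  d <- dim(mu)
  if (!identical(dim(proj$counts)[1:2], d[c(1, 3)]))
    stop("projection bins do not match the volume raster")
  if (is.null(init)) init <- array(1, d)
  if (any(init < 0)) stop("init must be non-negative")
  if (sum(proj$counts) == 0) {
    warning("all-zero projections: returning all-zero volume")
    return(new_recon_volume(array(0, d), proj$voxel_mm, g,
                            n_iterations, n_subsets))
  }
  subsets <- partition_subsets(g$angles, n_subsets)
  counts <- proj$counts
  storage.mode(counts) <- "double"  # guard against integer-typed realizations
  storage.mode(mu) <- "double"
  storage.mode(init) <- "double"
  res <- cpp_osem(counts, mu, g$angles,
                  lapply(subsets, function(s) as.integer(s - 1L)),
                  as.integer(n_iterations), init,
                  as.integer(sort(unique(snapshot_iters))),
                  proj$voxel_mm, g$sigma0_mm, g$sigma_slope,
                  g$det_radius_mm, sens_eps)
  snaps <- res$snapshots
  if (length(snaps))
    names(snaps) <- as.character(as.integer(names(snaps)) * n_subsets)
  new_recon_volume(res$final, proj$voxel_mm, g, n_iterations, n_subsets,
                   snapshots = if (length(snaps)) snaps else NULL)
}

#' Reconstruction update sweep
#'
#' Reconstructs one volume per (iterations, subsets) pair.  Pairs sharing
#' the same subset count are served by snapshotting a single OSEM run at the
#' requested iterations, so a sweep like 1i12s..17i12s costs one run.
#'
#' @param proj a `projection_set`.
#' @param mu attenuation grid.
#' @param sweep data frame with columns `iterations` and `subsets`.
#' @return List of `recon_volume`s in sweep order, named by update count
#'   (e.g. `"60"` for 5i12s).
#' @export
update_sweep <- function(proj, mu, sweep) {
  if (NROW(sweep) == 0) return(list())
  stopifnot(all(c("iterations", "subsets") %in% names(sweep)))
  out <- vector("list", nrow(sweep))
  for (s in unique(sweep$subsets)) {
    rows <- which(sweep$subsets == s)
    iters <- sweep$iterations[rows]
    run <- reconstruct_osem(proj, mu, n_iterations = max(iters),
                            n_subsets = s, snapshot_iters = iters)
    for (i in seq_along(rows)) {
      key <- as.character(iters[i] * s)
      out[[rows[i]]] <- new_recon_volume(run$snapshots[[key]], proj$voxel_mm,
                                         proj$geometry, iters[i], s)
    }
  }
  names(out) <- as.character(sweep$iterations * sweep$subsets)
  out
}

#' Poisson log-likelihood of a volume given projections
#'
#' `sum(y log(lambda) - lambda)` over bins with `lambda = forward(x)`;
#' zero-count bins contribute `-lambda`.  Used to verify EM monotonicity.
#'
#' @param grid volume (counts per voxel).
#' @param proj `projection_set` of measured counts.
#' @param mu attenuation grid.
#' @return Scalar log-likelihood (additive constants dropped).
#' @export
poisson_loglik <- function(grid, proj, mu) {
  g <- proj$geometry
  storage.mode(grid) <- "double"
  storage.mode(mu) <- "double"
  lam <- cpp_forward_project(grid, mu, g$angles, proj$voxel_mm,
                             g$sigma0_mm, g$sigma_slope, g$det_radius_mm)
  y <- proj$counts
  pos <- y > 0
  sum(y[pos] * log(pmax(lam[pos], 1e-300))) - sum(lam)
}
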