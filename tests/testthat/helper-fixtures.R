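# Small fixtures shared across tests: tiny grids and few views keep the
# reconstruction tests fast while exercising the full code paths.

tiny_geometry <- function(n_views = 24, ...) {
  spect_geometry(n_views = n_views, ...)
}

# small homogeneous cylinder (32^3, 9 mm voxels)
tiny_cylinder <- function(total = 100) {
  build_calibration_cylinder(c(32, 32, 32), 9, total_activity_MBq = total,
                             radius_mm = 60, height_mm = 120)
}

# small sphere phantom
tiny_lung_spine <- function(...) {
  build_lung_spine_phantom(c(32, 32, 32), 9, sphere_volumes_ml = c(8, 16, 30),
                           ...)
}

# a single hot cubic region at the grid center, everything else cold
point_block_phantom <- function(n = 17, voxel_mm = 8, half = 1,
                                conc = 1) {
  label <- array(0L, c(n, n, n))
  c0 <- (n + 1) / 2
  rng <- (c0 - half):(c0 + half)
  label[rng, rng, rng] <- 2L
  act <- array(0, dim(label)); act[label == 2L] <- conc
  mu <- array(0, dim(label))
  voxvol <- (voxel_mm / 10)^3
  organs <- data.frame(code = 2L, name = "block",
                       volume_ml = sum(label == 2L) * voxvol,
                       conc_MBq_per_ml = conc,
                       activity_MBq = conc * sum(label == 2L) * voxvol)
  voxel_phantom(label, mu, act, voxel_mm, organs)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}
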