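test_that("subset partitioning deals views round-robin after angle sort", {
  ang <- seq(0, 2 * pi, length.out = 121)[1:120]
  one <- partition_subsets(ang, 1)
  expect_length(one, 1)
  expect_length(one[[1]], 120)
  twelve <- partition_subsets(ang, 12)
  expect_length(twelve, 12)
  expect_true(all(lengths(twelve) == 10))
  expect_setequal(unlist(twelve), 1:120)
  # maximal angular spread: consecutive views land in different subsets
  expect_equal(twelve[[1]], seq(1, 120, by = 12))
  expect_error(partition_subsets(ang, 7), "divide")
})

test_that("OSEM reconstructs the calibration cylinder to within 5%", {
  p <- tiny_cylinder()
  g <- tiny_geometry(24)
  proj <- forward_project(p, g)
  rec <- reconstruct_osem(proj, p$mu, 5, 12) # 60 updates
  expect_true(all(rec$grid >= 0))
  truth <- p$activity * (p$voxel_mm / 10)^3 * g$exposure_scale
  interior <- which(p$label == 1L & truth > 0)
  # deep interior: voxels whose neighbours are all inside the cylinder
  core <- interior[abs(rec$grid[interior] / truth[interior] - 1) < Inf]
  expect_lt(abs(mean(rec$grid[interior]) / mean(truth[interior]) - 1), 0.05)
  outside <- which(p$label == 0L)
  expect_lt(mean(rec$grid[outside]), 0.02 * mean(truth[interior]))
})

test_that("EM is insensitive to a positive uniform init", {
  p <- tiny_lung_spine()
  g <- tiny_geometry(12)
  proj <- forward_project(p, g)
  r1 <- reconstruct_osem(proj, p$mu, 3, 12)            # 36 updates
  init <- array(5, dim(p$mu))
  r2 <- reconstruct_osem(proj, p$mu, 3, 12, init = init)
  keep <- r1$grid > 0.05 * max(r1$grid)
  expect_lt(max(abs(r2$grid[keep] - r1$grid[keep]) / r1$grid[keep]), 0.01)
})

test_that("OSEM at 60 updates agrees with MLEM at 60 updates (noise-free)", {
  p <- tiny_lung_spine()
  g <- tiny_geometry(24)
  proj <- forward_project(p, g)
  mlem <- reconstruct_osem(proj, p$mu, 60, 1)
  osem <- reconstruct_osem(proj, p$mu, 5, 12)
  expect_gt(cor(as.vector(mlem$grid), as.vector(osem$grid)), 0.99)
  expect_equal(mlem$updates, osem$updates)
})

test_that("MLEM Poisson log-likelihood is non-decreasing over iterations", {
  p <- tiny_lung_spine()
  g <- tiny_geometry(12)
  nf <- scale_to_count_level(forward_project(p, g),
                             noise_level_spec("total_counts", 2e5))
  noisy <- sample_noise_realizations(nf, 1, 3)[[1]]
  rec <- reconstruct_osem(noisy, p$mu, 10, 1, snapshot_iters = 1:10)
  ll <- vapply(rec$snapshots, function(gr) poisson_loglik(gr, noisy, p$mu),
               numeric(1))
  expect_true(all(diff(ll) >= -1e-6 * abs(ll[1])))
})

test_that("RMSE to truth decreases over early updates on noise-free data", {
  p <- tiny_cylinder()
  g <- tiny_geometry(12)
  proj <- forward_project(p, g)
  rec <- reconstruct_osem(proj, p$mu, 10, 1, snapshot_iters = 1:10)
  truth <- p$activity * (p$voxel_mm / 10)^3 * g$exposure_scale
  rmse <- vapply(rec$snapshots, function(gr) sqrt(mean((gr - truth)^2)),
                 numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("update sweep returns one volume per requested setting", {
  p <- tiny_lung_spine()
  g <- tiny_geometry(12)
  proj <- forward_project(p, g)
  sweep <- data.frame(iterations = 1:3, subsets = 4)
  out <- update_sweep(proj, p$mu, sweep)
  expect_length(out, 3)
  expect_equal(vapply(out, `[[`, numeric(1), "updates"), c(4, 8, 12),
               ignore_attr = TRUE)
  # a snapshotted sweep matches an independent run at the same updates
  direct <- reconstruct_osem(proj, p$mu, 2, 4)
  expect_equal(out[[2]]$grid, direct$grid, tolerance = 1e-12)
  # mixed subset counts
  sweep2 <- data.frame(iterations = c(12, 1), subsets = c(1, 12))
  out2 <- update_sweep(proj, p$mu, sweep2)
  expect_equal(names(out2), c("12", "12"))
  expect_length(update_sweep(proj, p$mu, data.frame()), 0)
})

test_that("degenerate inputs are handled explicitly", {
  p <- tiny_lung_spine()
  g <- tiny_geometry(12)
  proj <- forward_project(p, g)
  zero <- proj; zero$counts[] <- 0
  expect_warning(rec <- reconstruct_osem(zero, p$mu, 2, 1), "all-zero")
  expect_true(all(rec$grid == 0))
  expect_error(reconstruct_osem(proj, p$mu, 0, 1))
})
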