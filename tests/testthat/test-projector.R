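test_that("forward projection of zero activity is zero", {
  p <- point_block_phantom(conc = 0)
  proj <- forward_project(p, tiny_geometry(8))
  expect_true(all(proj$counts == 0))
})

test_that("a centered source with no attenuation/blur projects equal view totals", {
  # a single voxel at the exact rotation centre is invariant under any
  # multiple of 90 degrees (interpolation-exact angles)
  p <- point_block_phantom(n = 17, half = 0)
  g <- spect_geometry(n_views = 4, sigma0_mm = 0, sigma_slope = 0)
  proj <- forward_project(p, g)
  totals <- apply(proj$counts, 3, sum)
  expect_rel_equal(totals, rep(totals[1], 4), 1e-10)
  # a smooth rotationally symmetric source sees equal totals at all angles
  n <- 17; c0 <- (n + 1) / 2
  r2 <- outer(outer((1:n - c0)^2, (1:n - c0)^2, `+`), (1:n - c0)^2, `+`)
  ps <- p; ps$activity <- exp(-r2 / 8); ps$mu[] <- 0
  g12 <- tiny_geometry(12, sigma0_mm = 0, sigma_slope = 0)
  totals12 <- apply(forward_project(ps, g12)$counts, 3, sum)
  expect_rel_equal(totals12, rep(mean(totals12), 12), 1e-3)
})

test_that("projection is linear in activity and conserves counts when mu = 0", {
  p <- tiny_cylinder()
  p$mu[] <- 0
  g <- tiny_geometry(16)
  proj1 <- forward_project(p, g)
  p2 <- p; p2$activity <- 2 * p$activity
  proj2 <- forward_project(p2, g)
  expect_equal(proj2$counts, 2 * proj1$counts, tolerance = 1e-12)
  # conservation oracle: per-view total = grid activity x exposure scale
  expected <- sum(p$activity) * (p$voxel_mm / 10)^3 * g$exposure_scale
  totals <- apply(proj1$counts, 3, sum)
  expect_rel_equal(totals, rep(expected, length(totals)), 0.01)
})

test_that("attenuation can only reduce counts; blur conserves view totals", {
  p <- tiny_cylinder()
  g <- tiny_geometry(8)
  with_mu <- forward_project(p, g)
  p0 <- p; p0$mu[] <- 0
  without_mu <- forward_project(p0, g)
  expect_true(all(with_mu$counts <= without_mu$counts + 1e-12))
  g0 <- tiny_geometry(8, sigma0_mm = 0, sigma_slope = 0)
  sharp <- forward_project(p0, g0)
  t_blur <- apply(without_mu$counts, 3, sum)
  t_sharp <- apply(sharp$counts, 3, sum)
  expect_rel_equal(t_blur, t_sharp, 0.01)
})

test_that("the back projector is the exact adjoint of the forward model", {
  set.seed(7)
  d <- c(14, 14, 6)
  act <- array(runif(prod(d)), d)
  mu <- array(0.1 * runif(prod(d)), d)
  ang <- seq(0, 2 * pi, length.out = 9)[1:8]
  fp <- marrowdose:::cpp_forward_project(act, mu, ang, 6, 2, 0.02, 80)
  y <- array(runif(length(fp)), dim(fp))
  bp <- marrowdose:::cpp_backproject(y, mu, ang, d[1], d[2], 6, 2, 0.02, 80)
  expect_equal(sum(fp * y), sum(act * bp), tolerance = 1e-10)
})

test_that("count-level scaling meets total and reference-region targets", {
  p <- tiny_cylinder()
  g <- tiny_geometry(8)
  proj <- forward_project(p, g)
  # identity and linearity in total_counts mode
  same <- scale_to_count_level(
    proj, noise_level_spec("total_counts", sum(proj$counts)))
  expect_equal(same$counts, proj$counts, tolerance = 1e-12)
  dbl <- scale_to_count_level(
    proj, noise_level_spec("total_counts", 2 * sum(proj$counts)))
  expect_equal(dbl$counts, 2 * proj$counts, tolerance = 1e-12)
  expect_equal(dbl$exposure_scale, 2 * proj$exposure_scale)

  # reference-region oracle: an axis-aligned block source at the center of
  # an odd grid, viewed at multiples of 90 degrees with no blur, projects
  # exactly onto the central 3x3 bins of every view
  pb <- point_block_phantom(n = 17, half = 1)
  gb <- spect_geometry(n_views = 4, sigma0_mm = 0, sigma_slope = 0)
  pj <- forward_project(pb, gb)
  c0 <- 9
  mask <- array(FALSE, dim(pj$counts))
  mask[(c0 - 1):(c0 + 1), (c0 - 1):(c0 + 1), ] <- TRUE
  expect_true(all(pj$counts[!mask] < 1e-9))
  cur_mean <- mean(pj$counts[mask])
  sc <- scale_to_count_level(
    pj, noise_level_spec("reference_region", 50, reference = 2L), pb)
  expect_equal(sc$scale_factor, 50 / cur_mean, tolerance = 1e-9)

  zero <- pj; zero$counts[] <- 0
  expect_error(scale_to_count_level(
    zero, noise_level_spec("total_counts", 10)), "cannot scale")
})

test_that("Poisson realizations are integer, reproducible, with Poisson moments", {
  p <- tiny_cylinder()
  proj <- forward_project(p, tiny_geometry(4))
  z <- proj; z$counts[] <- 0
  r0 <- sample_noise_realizations(z, 2, 1)
  expect_true(all(vapply(r0, function(r) all(r$counts == 0), logical(1))))

  const <- proj; const$counts[] <- 10
  r1 <- sample_noise_realizations(const, 3, 42)
  r2 <- sample_noise_realizations(const, 3, 42)
  expect_identical(r1[[1]]$counts, r2[[1]]$counts)
  expect_true(all(r1[[2]]$counts == round(r1[[2]]$counts)))
  expect_false(r1[[1]]$noise_free)
  expect_equal(r1[[2]]$seed, 44L)

  draws <- sample_noise_realizations(const, 200, 7)
  x <- vapply(draws, function(r) r$counts[1:50], numeric(50))
  m <- rowMeans(x); v <- apply(x, 1, var)
  expect_true(all(abs(mean(m) - 10) < 0.5))
  expect_gt(mean(v) / mean(m), 0.8)
  expect_lt(mean(v) / mean(m), 1.2)
  expect_error(sample_noise_realizations(const, 0, 1), ">= 1")
})
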