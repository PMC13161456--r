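test_that("body phantom honours the uptake specification", {
  zero <- organ_uptake_spec(c(2, 24, 48, 168),
                            matrix(0, 6, 4, dimnames = list(
                              c("background", "kidney", "spleen", "liver",
                                "lung", "marrow"), NULL)))
  p0 <- build_body_phantom(uptake = zero)
  expect_true(all(p0$activity == 0))

  pbm <- build_body_phantom(uptake = marrow_only_uptake())
  nz <- pbm$activity[pbm$activity > 0]
  expect_equal(max(nz) / min(nz), 5)

  p <- build_body_phantom()
  vcodes <- intersect(unique(as.vector(p$label)), 11:20)
  expect_length(vcodes, 10)
})

test_that("organ activity is homogeneous and conserved in the organ table", {
  p <- build_body_phantom()
  voxvol <- (p$voxel_mm / 10)^3
  for (i in seq_len(nrow(p$organs))) {
    vals <- p$activity[p$label == p$organs$code[i]]
    expect_equal(sd(vals), 0)
    expect_equal(p$organs$volume_ml[i], length(vals) * voxvol)
    expect_equal(p$organs$activity_MBq[i], sum(vals) * voxvol)
  }
})

test_that("phantom construction is deterministic", {
  expect_identical(build_body_phantom(), build_body_phantom())
  expect_identical(build_lung_spine_phantom(), build_lung_spine_phantom())
})

test_that("overlapping structures are rejected with the colliding pair", {
  lab <- array(0L, c(8, 8, 8))
  m1 <- array(FALSE, c(8, 8, 8)); m1[3:5, 3:5, 3:5] <- TRUE
  lab <- marrowdose:::paint(lab, m1, 2L, "first")
  m2 <- array(FALSE, c(8, 8, 8)); m2[5:7, 5:7, 5:7] <- TRUE
  expect_error(marrowdose:::paint(lab, m2, 3L, "second"),
               "second.*overlaps.*2")
  # a 4 L "sphere" cannot coexist with the lung inserts
  expect_error(build_lung_spine_phantom(sphere_volumes_ml = 4000),
               "overlaps")
})

test_that("vertebra VOIs are named, ordered cranio-caudally and disjoint", {
  p <- build_body_phantom()
  vois <- vertebra_vois(p)
  expect_named(vois, c("T8", "T9", "T10", "T11", "T12",
                       "L1", "L2", "L3", "L4", "L5"))
  vols <- vapply(vois, `[[`, numeric(1), "volume_ml")
  expect_true(all(vols > 3.5 & vols < 12)) # patient-like 4.6-10.1 mL range
  # cranio-caudal: mean z-slice index decreases from T8 to L5
  nz <- dim(p$label)[3]
  zmean <- vapply(vois, function(v)
    mean((v$idx - 1) %/% (dim(p$label)[1] * dim(p$label)[2])), numeric(1))
  expect_true(all(diff(zmean) < 0))
  all_idx <- unlist(lapply(vois, `[[`, "idx"))
  expect_equal(length(all_idx), length(unique(all_idx)))
})

test_that("lung-spine phantom matches requested contrast", {
  p <- build_lung_spine_phantom(sphere_volumes_ml = c(4, 8, 16), ratio = 2,
                                background_conc = 0.29)
  for (v in sphere_vois(p))
    expect_equal(unique(p$activity[v$idx]), 0.58)
  # identity ratio: activity constant inside the body
  p1 <- build_lung_spine_phantom(ratio = 1)
  inside <- p1$label >= 1L
  expect_equal(length(unique(p1$activity[inside])), 1L)
  # 16 mL sphere radius ~ 15.6 mm: voxelized volume close to nominal
  v16 <- sphere_vois(p)$sphere_16ml
  expect_lt(abs(v16$volume_ml - 16) / 16, 0.2)
  r_expect <- (3 * 16000 / (4 * pi))^(1 / 3)
  expect_equal(r_expect, 15.63, tolerance = 1e-3)
})

test_that("calibration cylinder conserves the requested activity", {
  p <- build_calibration_cylinder(c(32, 32, 32), 9, 100,
                                  radius_mm = 60, height_mm = 120)
  voxvol <- (p$voxel_mm / 10)^3
  expect_equal(sum(p$activity) * voxvol, 100, tolerance = 1e-10)
  expect_equal(p$organs$conc_MBq_per_ml, 100 / p$organs$volume_ml)
  # ~5 L cylinder at 100 MBq -> ~0.02 MBq/mL
  p5 <- build_calibration_cylinder(c(48, 48, 48), 6, 100,
                                   radius_mm = 100, height_mm = 160)
  expect_equal(p5$organs$conc_MBq_per_ml, 0.02, tolerance = 0.03)
  p0 <- build_calibration_cylinder(c(32, 32, 32), 9, 0,
                                   radius_mm = 60, height_mm = 120)
  expect_true(all(p0$activity == 0))
  expect_error(build_calibration_cylinder(c(16, 16, 16), 4, 10,
                                          radius_mm = 100, height_mm = 50),
               "does not fit")
})

test_that("phantom NIfTI round trip preserves grids and organ table", {
  p <- build_lung_spine_phantom(c(24, 24, 24), 6, sphere_volumes_ml = 8)
  prefix <- file.path(tempdir(), "lsp")
  write_phantom(p, prefix)
  q <- read_phantom(prefix)
  expect_equal(q$label, p$label)
  expect_equal(q$mu, p$mu, tolerance = 1e-6)
  expect_equal(q$activity, p$activity, tolerance = 1e-6)
  expect_equal(q$organs$activity_MBq, p$organs$activity_MBq)
})
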