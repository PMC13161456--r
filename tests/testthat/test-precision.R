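test_that("combination enumeration matches closed-form binomials", {
  v7 <- paste0("V", 1:7)
  expect_length(enumerate_combinations(v7, 2)$subsets, 21)
  expect_length(enumerate_combinations(v7, 6)$subsets, 7)
  v10 <- paste0("V", 1:10)
  expect_length(enumerate_combinations(v10, 2)$subsets, 45)
  expect_length(enumerate_combinations(v10, 3)$subsets, 120)
  expect_length(enumerate_combinations(v10, 4)$subsets, 210)
  expect_length(enumerate_combinations(v10, 7 - 7 + 6)$subsets, 210)
  expect_length(enumerate_combinations(paste0("V", 1:5), 5)$subsets, 1)
  expect_error(enumerate_combinations(v7, 7), "capped")
  expect_error(enumerate_combinations(v7, 0), ">= 1")
  expect_warning(out <- enumerate_combinations(paste0("V", 1:3), 5),
                 "exceeds")
  expect_length(out$subsets, 0)
})

test_that("total combination counts equal brute-force enumeration", {
  expect_equal(count_total_combinations(7), 126)
  expect_equal(count_total_combinations(1), 1)
  expect_equal(count_total_combinations(10), 847)
  for (n in 1:12) {
    brute <- sum(vapply(seq_len(min(n, 6)), function(k)
      length(combn(n, k, simplify = FALSE)), numeric(1)))
    expect_equal(count_total_combinations(n), brute)
  }
})

test_that("combination subsets are unique and lexicographically ordered", {
  cs <- enumerate_combinations(paste0("V", 1:6), 3)
  ids <- vapply(cs$subsets, paste, character(1), collapse = "+")
  expect_equal(length(unique(ids)), length(ids))
  expect_equal(cs$subsets[[1]], c("V1", "V2", "V3"))
  expect_true(all(lengths(cs$subsets) == 3))
})

test_that("combination doses average concentrations before fitting", {
  t <- c(2, 24, 48, 168)
  a <- time_activity_series(t, 0.06 * exp(-0.01 * t), "A")
  b <- time_activity_series(t, 0.02 * exp(-0.02 * t), "B")
  sl <- list(A = a, B = b)
  d <- combination_doses(sl, list(c("A", "B")))
  # hand-built oracle: average the two curves, then fit and dose
  avg <- (a$conc + b$conc) / 2
  fit <- fit_biexp(times_h = t, conc = avg)
  ref <- absorbed_dose(time_integrated_concentration(fit))
  expect_equal(d$dose_mGy_per_GBq, ref$dose_mGy_per_GBq, tolerance = 1e-10)
  # permutation invariance
  d2 <- combination_doses(sl, list(c("B", "A")))
  expect_equal(d2$dose_mGy_per_GBq, d$dose_mGy_per_GBq, tolerance = 1e-10)
  # identical members: dose equals the single-vertebra dose for every k
  sl3 <- list(A = a, B = a, C = a)
  combos <- lapply(1:3, function(k)
    enumerate_combinations(c("A", "B", "C"), k))
  d3 <- combination_doses(sl3, combos)
  expect_true(all(abs(d3$dose_mGy_per_GBq - d3$dose_mGy_per_GBq[1]) < 1e-8))
  # mismatched grids rejected
  cbad <- time_activity_series(c(2, 24, 48, 120), 0.02 * exp(-0.01 *
                                                     c(2, 24, 48, 120)), "C")
  expect_error(combination_doses(list(A = a, C = cbad), list(c("A", "C"))),
               "time grid")
})

test_that("precision by group size computes COV per k", {
  doses <- data.frame(k = rep(1:2, each = 3),
                      dose_mGy_per_GBq = c(5, 5, 5, 1, 2, 3))
  tab <- precision_by_group_size(doses)
  expect_equal(tab$cov_percent, c(0, 50))
  expect_equal(tab$mean_dose[1], 5)
  single <- precision_by_group_size(data.frame(k = 1,
                                               dose_mGy_per_GBq = 4))
  expect_true(is.na(single$cov_percent))
})

test_that("COV decreases with group size on exchangeable ensembles", {
  set.seed(31)
  covs <- matrix(NA_real_, 20, 6)
  for (s in 1:20) {
    vals <- exp(rnorm(10, 0, 0.3))
    per_k <- vapply(1:6, function(k) {
      means <- vapply(combn(10, k, simplify = FALSE),
                      function(ix) mean(vals[ix]), numeric(1))
      sd(means) / mean(means) * 100
    }, numeric(1))
    covs[s, ] <- per_k
  }
  avg <- colMeans(covs)
  expect_true(all(diff(avg) < 0))
  expect_lt(avg[6] / avg[1], 0.5) # finite-population shrinkage
})

test_that("region comparison handles shifts, swaps and degeneracy", {
  expect_true(compare_regions(c(1, 2, 3), c(1, 2, 3))$degenerate)
  set.seed(12)
  a <- rnorm(13, 1, 0.1); b <- rnorm(13, 0, 0.1)
  r <- compare_regions(a, b)
  expect_lt(r$p_value, 0.05)
  expect_true(r$significant)
  r2 <- compare_regions(b, a)
  expect_equal(r2$mean_diff, -r$mean_diff)
})

test_that("reconstruction-setting comparison applies Bonferroni correctly", {
  set.seed(5)
  base <- data.frame(k = rep(1:6, each = 8),
                     setting = "5i12s",
                     dose_mGy_per_GBq = rnorm(48, 50, 2))
  same <- base; same$setting <- "60i1s"
  tab <- compare_recon_settings(rbind(base, same))
  expect_true(all(tab$degenerate | tab$p_value > 0))
  expect_equal(tab$mean_delta_ad, rep(0, 6), tolerance = 1e-12)
  expect_false(any(tab$significant))
  # a 10-sigma shift in one group survives Bonferroni
  shift <- same
  shift$dose_mGy_per_GBq[shift$k == 3] <-
    shift$dose_mGy_per_GBq[shift$k == 3] + 20
  tab2 <- compare_recon_settings(rbind(base, shift))
  expect_true(tab2$significant[tab2$k == 3])
  # the flag must match the raw p-value against alpha/m
  expect_equal(tab2$significant, !is.na(tab2$p_value) &
                 tab2$p_value < 0.01 / 6)
})

test_that("ground-truth restoration is a simple percentage", {
  expect_equal(ground_truth_restoration(5, 5), 100)
  expect_equal(ground_truth_restoration(0, 5), 0)
  expect_error(ground_truth_restoration(1, 0), "positive")
})

test_that("synthetic vertebra series are reproducible and exchangeable", {
  s1 <- simulate_vertebra_series(seed = 11)
  s2 <- simulate_vertebra_series(seed = 11)
  expect_equal(s1$V3$conc, s2$V3$conc)
  expect_length(s1, 10)
  expect_true(all(vapply(s1, function(v) all(v$conc >= 0), logical(1))))
  expect_equal(s1$V1$times_h, c(2, 24, 48, 168))
  # washout after the 24 h peak
  m <- rowMeans(vapply(s1, `[[`, numeric(4), "conc"))
  expect_gt(m[2], m[1])
  expect_true(all(diff(m[2:4]) < 0))
})
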