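# Experiment orchestration: the three study designs (patient-like
# combinatorial precision on synthetic series, lung-spine recovery vs noise,
# body-phantom spill-in) plus the subset-sensitivity check, a config-driven
# runner and a bundle reporter.  Every stochastic step derives its seed from
# the experiment base seed with a documented offset (realization i of noise
# level l uses base_seed + (l-1)*n_realizations + i; synthetic-series seed
# for ensemble draw s is base_seed + s).

# ICF per update snapshot, at a given effective exposure (counts/MBq)
calibration_icfs <- function(grid_dim, voxel_mm, geometry, exposure_scale,
                             n_iterations, n_subsets,
                             snapshot_iters = n_iterations,
                             A_cal = 100) {
  cyl <- build_calibration_cylinder(grid_dim, voxel_mm,
                                    total_activity_MBq = A_cal)
  g <- geometry
  g$exposure_scale <- exposure_scale
  proj <- forward_project(cyl, g)
  rec <- reconstruct_osem(proj, cyl$mu, n_iterations, n_subsets,
                          snapshot_iters = snapshot_iters)
  cyl_voi <- label_voi(cyl, 1L, "cylinder")
  snaps <- rec$snapshots
  icfs <- vapply(snaps, function(gr) {
    sum(gr[cyl_voi$idx]) / A_cal
  }, numeric(1))
  stats::setNames(icfs, names(snaps))
}

#' Patient-like combinatorial precision experiment
#'
#' Draws an ensemble of synthetic per-vertebra time-activity sets
#' ([simulate_vertebra_series()]), doses every unique combination of one to
#' `k_max` vertebrae (average-then-fit) and summarizes the COV of the dose
#' per group size, averaged over the ensemble.
#'
#' @param n_vertebrae available (lesion-free) vertebrae per subject.
#' @param n_seeds ensemble size.
#' @param k_max largest group size (capped at 6).
#' @param base_seed base RNG seed; draw `s` uses `base_seed + s`.
#' @param ... passed to [simulate_vertebra_series()].
#' @return List with `per_seed` (data frame: seed, k, mean, COV),
#'   `summary` (mean COV and dose per k), `doses_first_seed`.
#' @export
experiment_combination_precision <- function(n_vertebrae = 10, n_seeds = 25,
                                             k_max = 6, base_seed = 1, ...) {
  combos <- lapply(seq_len(min(k_max, n_vertebrae)), function(k)
    enumerate_combinations(sprintf("V%d", seq_len(n_vertebrae)), k))
  per_seed <- vector("list", n_seeds)
  first_doses <- NULL
  for (s in seq_len(n_seeds)) {
    series <- simulate_vertebra_series(n_vertebrae = n_vertebrae,
                                       seed = base_seed + s, ...)
    doses <- combination_doses(series, combos)
    if (s == 1) first_doses <- doses
    tab <- precision_by_group_size(doses)
    tab$seed <- base_seed + s
    per_seed[[s]] <- tab
  }
  per_seed <- do.call(rbind, per_seed)
  summary <- do.call(rbind, lapply(sort(unique(per_seed$k)), function(k) {
    rows <- per_seed[per_seed$k == k, ]
    data.frame(k = k, n_combinations = rows$n_combinations[1],
               mean_dose = mean(rows$mean_dose),
               mean_cov_percent = mean(rows$cov_percent))
  }))
  list(experiment = "combination_precision", per_seed = per_seed,
       summary = summary, doses_first_seed = first_doses,
       n_seeds = n_seeds, n_vertebrae = n_vertebrae)
}

#' Lung-spine phantom: recovery coefficients versus noise and updates
#'
#' Simulates the sphere-insert phantom, scales the noise-free projections to
#' three total-count budgets (the eta noise levels), draws Poisson
#' realizations, reconstructs each with an OSEM update sweep (fixed subset
#' count), and computes per-realization recovery coefficients for each
#' sphere with a matched, update-specific image calibration factor.
#'
#' @param grid_dim,voxel_mm,n_views phantom raster and orbit sampling.
#' @param sphere_volumes_ml insert volumes.
#' @param noise_totals named vector of total-count budgets (eta levels,
#'   most to least counts).
#' @param n_realizations Poisson realizations per level.
#' @param n_iterations,n_subsets OSEM sweep: snapshots after every iteration
#'   give updates `n_subsets * (1..n_iterations)`.
#' @param base_seed base seed; realization i of level l uses
#'   `base_seed + (l-1)*n_realizations + i`.
#' @return List with `rc` (long data frame: level, realization, sphere,
#'   updates, rc), `rc_noise_free`, `summary` (mean RC and COV per level x
#'   sphere x updates).
#' @export
experiment_lung_spine <- function(grid_dim = c(64, 64, 64), voxel_mm = 4.5,
                                  n_views = 60,
                                  sphere_volumes_ml = c(4, 8, 16),
                                  noise_totals = c(eta_min = 2e6,
                                                   eta_med = 6e5,
                                                   eta_max = 2e5),
                                  n_realizations = 20, n_iterations = 17,
                                  n_subsets = 12, base_seed = 1) {
  phan <- build_lung_spine_phantom(grid_dim, voxel_mm, sphere_volumes_ml)
  geom <- spect_geometry(n_views = n_views)
  nf <- forward_project(phan, geom)
  vois <- sphere_vois(phan)
  a_r <- stats::setNames(phan$organs$activity_MBq[
    match(names(vois), phan$organs$name)], names(vois))
  iters <- seq_len(n_iterations)

  rc_one <- function(rec_snaps, icfs, realization, level) {
    rows <- list()
    for (it in iters) {
      key <- as.character(it * n_subsets)
      gr <- rec_snaps[[as.character(it)]]
      for (v in names(vois)) {
        c_r <- sum(gr[vois[[v]]$idx])
        rows[[length(rows) + 1L]] <- data.frame(
          level = level, realization = realization, sphere = v,
          updates = it * n_subsets,
          rc = c_r / (icfs[[key]] * a_r[[v]]))
      }
    }
    do.call(rbind, rows)
  }

  rc_rows <- list()
  rc_nf <- NULL
  for (li in seq_along(noise_totals)) {
    lev <- names(noise_totals)[li]
    scaled <- scale_to_count_level(
      nf, noise_level_spec("total_counts", noise_totals[[li]], label = lev))
    icfs <- calibration_icfs(grid_dim, voxel_mm, geom,
                             scaled$exposure_scale, n_iterations, n_subsets,
                             snapshot_iters = iters)
    names(icfs) <- as.character(as.integer(names(icfs)))
    icfs <- stats::setNames(as.list(icfs), names(icfs))
    if (li == 1) { # noise-free reference (level-independent up to scaling)
      rec <- reconstruct_osem(scaled, phan$mu, n_iterations, n_subsets,
                              snapshot_iters = iters)
      snaps <- stats::setNames(rec$snapshots,
                               as.integer(names(rec$snapshots)) / n_subsets)
      rc_nf <- rc_one(snaps, icfs, realization = 0, level = "noise_free")
    }
    reals <- sample_noise_realizations(
      scaled, n_realizations,
      base_seed = base_seed + (li - 1) * n_realizations)
    for (ri in seq_along(reals)) {
      rec <- reconstruct_osem(reals[[ri]], phan$mu, n_iterations, n_subsets,
                              snapshot_iters = iters)
      snaps <- stats::setNames(rec$snapshots,
                               as.integer(names(rec$snapshots)) / n_subsets)
      rc_rows[[length(rc_rows) + 1L]] <- rc_one(snaps, icfs, ri, lev)
    }
  }
  rc <- do.call(rbind, rc_rows)
  summary <- do.call(rbind, lapply(split(
    rc, list(rc$level, rc$sphere, rc$updates), drop = TRUE), function(d) {
      g <- cov_stats(d$rc)
      data.frame(level = d$level[1], sphere = d$sphere[1],
                 updates = d$updates[1], mean_rc = g$mean,
                 cov_percent = g$cov_percent, n = g$n)
    }))
  rownames(summary) <- NULL
  list(experiment = "lung_spine", rc = rc, rc_noise_free = rc_nf,
       summary = summary, noise_totals = noise_totals,
       n_realizations = n_realizations)
}

# region means of per-vertebra voxel recovery for a reconstruction
region_recoveries <- function(rec, truth, vois, icf) {
  sapply(vois, function(v) voxel_recovery(rec, truth, v, icf))
}

#' Body phantom spill-in experiment
#'
#' Simulates the body phantom with hot kidneys/spleen/liver adjacent to the
#' lower vertebrae and, separately, with activity only in the marrow
#' (marrow-only map), reconstructs Poisson realizations at a kidney-matched
#' count level, and compares voxel recovery between vertebrae adjacent to
#' high-uptake organs (T12-L2) and remote ones (L3-L5).  Ground-truth
#' absorbed-dose restoration is computed for both regions from noise-free
#' reconstructions at all four time points.
#'
#' @param grid_dim,voxel_mm,n_views raster and orbit sampling.
#' @param n_realizations Poisson realizations per activity map.
#' @param n_iterations,n_subsets reconstruction setting (default 5i12s,
#'   60 updates).
#' @param kidney_target_mean target mean counts per kidney-intersecting bin.
#' @param base_seed base seed (hot map uses `base_seed + i`, marrow-only map
#'   `base_seed + n_realizations + i`).
#' @return List with per-realization region recoveries, t-test report,
#'   marrow-only relative difference, restoration percentages and dose
#'   results.
#' @export
experiment_xcat_spillin <- function(grid_dim = c(64, 64, 64), voxel_mm = 5.5,
                                    n_views = 60, n_realizations = 20,
                                    n_iterations = 5, n_subsets = 12,
                                    kidney_target_mean = 25, base_seed = 1) {
  geom <- spect_geometry(n_views = n_views)
  uptake <- default_uptake()
  updates <- n_iterations * n_subsets
  region_lo <- c("T12", "L1", "L2")   # adjacent to kidneys/liver
  region_hi <- c("L3", "L4", "L5")    # remote

  run_map <- function(up, time_h, n_real, seed0) {
    phan <- build_body_phantom(grid_dim, voxel_mm, up, time_h)
    vois <- vertebra_vois(phan)
    nf <- scale_to_count_level(
      forward_project(phan, geom),
      noise_level_spec("reference_region", kidney_target_mean,
                       reference = 2L, label = "kidney_matched"),
      phan)
    icf <- calibration_icfs(grid_dim, voxel_mm, geom, nf$exposure_scale,
                            n_iterations, n_subsets)[[1]]
    rec_nf <- reconstruct_osem(nf, phan$mu, n_iterations, n_subsets)
    per_real <- NULL
    if (n_real > 0) {
      reals <- sample_noise_realizations(nf, n_real, base_seed = seed0)
      per_real <- lapply(reals, function(r) {
        rec <- reconstruct_osem(r, phan$mu, n_iterations, n_subsets)
        region_recoveries(rec, phan$activity, vois, icf)
      })
    }
    list(phantom = phan, vois = vois, icf = icf, rec_nf = rec_nf,
         recoveries = per_real)
  }

  hot24 <- run_map(uptake, 24, n_realizations, base_seed)
  bm24 <- run_map(marrow_only_uptake(), 24, n_realizations,
                  base_seed + n_realizations)

  reg_mean <- function(recs, region)
    vapply(recs, function(r) mean(r[region]), numeric(1))
  hot_lo <- reg_mean(hot24$recoveries, region_lo)
  hot_hi <- reg_mean(hot24$recoveries, region_hi)
  bm_lo <- reg_mean(bm24$recoveries, region_lo)
  bm_hi <- reg_mean(bm24$recoveries, region_hi)
  spill_test <- compare_regions(hot_hi, hot_lo, paired = FALSE)
  bm_rel_diff <- abs(mean(bm_lo) - mean(bm_hi)) /
    mean(c(mean(bm_lo), mean(bm_hi)))

  # restoration: measured concentration = mean VOI concentration over the
  # region members, per time point, from noise-free reconstructions
  times <- uptake$times_h
  meas <- list(lo = numeric(length(times)), hi = numeric(length(times)))
  truth <- numeric(length(times))
  for (ti in seq_along(times)) {
    m <- if (times[ti] == 24) hot24
         else run_map(uptake, times[ti], 0, base_seed)
    truth[ti] <- uptake$conc["marrow", ti]
    conc_v <- vapply(m$vois, function(v)
      voi_concentration(m$rec_nf, v, m$icf), numeric(1))
    meas$lo[ti] <- mean(conc_v[region_lo])
    meas$hi[ti] <- mean(conc_v[region_hi])
  }
  dose_of <- function(conc) absorbed_dose(
    time_integrated_concentration(fit_biexp(times_h = times, conc = conc)))
  truth_dose <- dose_of(truth)
  dose_lo <- dose_of(meas$lo)
  dose_hi <- dose_of(meas$hi)

  list(experiment = "xcat_spillin",
       recovery_hot = list(T12_L2 = hot_lo, L3_L5 = hot_hi),
       recovery_marrow_only = list(T12_L2 = bm_lo, L3_L5 = bm_hi),
       spill_test = spill_test, marrow_only_rel_diff = bm_rel_diff,
       measured_conc = meas, truth_conc = truth,
       dose = list(truth = truth_dose, L3_L5 = dose_hi, T12_L2 = dose_lo),
       restoration = c(
         L3_L5 = ground_truth_restoration(dose_hi, truth_dose),
         T12_L2 = ground_truth_restoration(dose_lo, truth_dose)),
       updates = updates, n_realizations = n_realizations)
}

#' Subset-sensitivity experiment (60i1s versus 5i12s)
#'
#' Reconstructs noise-free body-phantom projections at all four time points
#' with 60 updates as MLEM (60i1s) and as OSEM (5i12s), derives marrow
#' time-activity curves from the vertebral VOIs with matched calibration
#' factors, and reports the relative absorbed-dose difference dAD.
#'
#' @param grid_dim,voxel_mm,n_views raster and orbit sampling.
#' @param vertebrae vertebra names averaged into the marrow curve.
#' @return List with the two dose results, `delta_ad`, and the per-setting
#'   time-activity concentrations.
#' @export
experiment_subset_sensitivity <- function(grid_dim = c(64, 64, 64),
                                          voxel_mm = 5.5, n_views = 60,
                                          vertebrae = c("L3", "L4", "L5")) {
  geom <- spect_geometry(n_views = n_views)
  uptake <- default_uptake()
  times <- uptake$times_h
  settings <- list(`60i1s` = c(60, 1), `5i12s` = c(5, 12))
  icfs <- lapply(settings, function(s)
    calibration_icfs(grid_dim, voxel_mm, geom, geom$exposure_scale,
                     s[1], s[2])[[1]])
  conc <- lapply(settings, function(s) numeric(length(times)))
  for (ti in seq_along(times)) {
    phan <- build_body_phantom(grid_dim, voxel_mm, uptake, times[ti])
    vois <- vertebra_vois(phan)[vertebrae]
    proj <- forward_project(phan, geom)
    for (nm in names(settings)) {
      s <- settings[[nm]]
      rec <- reconstruct_osem(proj, phan$mu, s[1], s[2])
      conc[[nm]][ti] <- mean(vapply(vois, function(v)
        voi_concentration(rec, v, icfs[[nm]]), numeric(1)))
    }
  }
  dose_of <- function(cv, tag) absorbed_dose(
    time_integrated_concentration(fit_biexp(times_h = times, conc = cv)),
    tag = tag)
  d60 <- dose_of(conc$`60i1s`, "60i1s")
  d512 <- dose_of(conc$`5i12s`, "5i12s")
  list(experiment = "subset_sensitivity", conc = conc,
       dose_60i1s = d60, dose_5i12s = d512,
       delta_ad = delta_ad(d512, d60))
}

#' Run a configured experiment
#'
#' Dispatches on `config$experiment`
#' (`"combination_precision"`, `"lung_spine"`, `"xcat_spillin"`,
#' `"subset_sensitivity"`), passing the remaining entries as arguments.
#' `config` may be a list, or a path to a YAML/JSON file.  If
#' `config$outdir` is set, result tables are written there as CSV/JSON.
#' Identical config + seed reproduces identical outputs.
#'
#' @param config list or path.
#' @return The experiment result bundle (invisibly if written to disk).
#' @export
run_experiment <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package required to read YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$experiment))
  exp_fun <- switch(config$experiment,
    combination_precision = experiment_combination_precision,
    lung_spine = experiment_lung_spine,
    xcat_spillin = experiment_xcat_spillin,
    subset_sensitivity = experiment_subset_sensitivity,
    stop("unknown experiment: ", config$experiment))
  args <- config[setdiff(names(config), c("experiment", "outdir"))]
  # JSON/YAML configs deliver named vectors as lists; flatten numeric ones
  args <- lapply(args, function(a)
    if (is.list(a) && length(a) && all(vapply(a, is.numeric, logical(1))))
      unlist(a) else a)
  fml <- names(formals(exp_fun))
  bad <- setdiff(names(args), fml)
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  bundle <- tryCatch(do.call(exp_fun, args), error = function(e)
    stop(sprintf("experiment '%s' failed: %s", config$experiment,
                 conditionMessage(e)), call. = FALSE))
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(bundle)) {
      x <- bundle[[nm]]
      path <- file.path(config$outdir, nm)
      if (is.data.frame(x)) write.csv(x, paste0(path, ".csv"),
                                      row.names = FALSE)
    }
    jsonlite::write_json(report_bundle(bundle),
                         file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(invisible(bundle))
  }
  bundle
}

#' Summarize an experiment bundle
#'
#' Produces the summary tables for a result bundle: the mean-dose/COV table
#' per group size, the RC-versus-updates curves, or the spill-in report,
#' depending on the experiment.  Errors list any missing components.
#'
#' @param bundle result of [run_experiment()] or an `experiment_*` function.
#' @return Named list of summary tables/values.
#' @export
report_bundle <- function(bundle) {
  if (is.null(bundle$experiment)) stop("bundle is missing: experiment")
  need <- switch(bundle$experiment,
    combination_precision = "summary",
    lung_spine = c("summary", "rc_noise_free"),
    xcat_spillin = c("spill_test", "restoration"),
    subset_sensitivity = c("delta_ad"),
    stop("unknown bundle type: ", bundle$experiment))
  missing <- need[!need %in% names(bundle)]
  if (length(missing))
    stop("bundle is missing: ", paste(missing, collapse = ", "))
  switch(bundle$experiment,
    combination_precision = list(
      experiment = bundle$experiment,
      precision_table = bundle$summary),
    lung_spine = list(
      experiment = bundle$experiment,
      rc_curves = bundle$summary,
      rc_noise_free = bundle$rc_noise_free),
    xcat_spillin = list(
      experiment = bundle$experiment,
      spill_test = bundle$spill_test,
      marrow_only_rel_diff = bundle$marrow_only_rel_diff,
      restoration = as.list(bundle$restoration)),
    subset_sensitivity = list(
      experiment = bundle$experiment,
      delta_ad = bundle$delta_ad,
      dose_60i1s = bundle$dose_60i1s$dose_mGy_per_GBq,
      dose_5i12s = bundle$dose_5i12s$dose_mGy_per_GBq))
}
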