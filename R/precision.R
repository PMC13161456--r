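# Combinatorial precision analysis: enumerate vertebra subsets, dose each
# combination (average concentrations first, then fit), COV per group size,
# region and reconstruction-setting comparisons, ground-truth restoration.

#' Enumerate unique vertebra combinations
#'
#' All unordered subsets of size `k` of the available (lesion-free)
#' vertebrae, in deterministic lexicographic order.  The analysis caps the
#' group size at six.
#'
#' @param vertebrae character vector of available vertebra names.
#' @param k group size, 1..6.
#' @return A `combination_set`: list with `k`, `vertebrae` and `subsets`
#'   (list of character vectors).
#' @export
enumerate_combinations <- function(vertebrae, k) {
  n <- length(vertebrae)
  if (k < 1) stop("k must be >= 1")
  if (k > 6) stop("group size is capped at six vertebrae")
  if (k > n) {
    warning("k exceeds the number of available vertebrae; empty set")
    subsets <- list()
  } else {
    subsets <- combn(vertebrae, k, simplify = FALSE)
  }
  structure(list(vertebrae = vertebrae, k = k, subsets = subsets),
            class = "combination_set")
}

#' @export
print.combination_set <- function(x, ...) {
  cat(sprintf("combination_set: C(%d, %d) = %d subsets\n",
              length(x$vertebrae), x$k, length(x$subsets)))
  invisible(x)
}

#' Total number of unique combinations
#'
#' `sum_{k=1..min(n,6)} C(n, k)`: e.g. 126 for seven available vertebrae.
#'
#' @param n number of available vertebrae.
#' @return Integer count.
#' @export
count_total_combinations <- function(n) {
  stopifnot(n >= 1)
  sum(choose(n, seq_len(min(n, 6))))
}

combo_id <- function(members) paste(members, collapse = "+")

#' Absorbed dose per vertebra combination
#'
#' For each combination the member concentrations are averaged per time
#' point first, then the averaged series is fitted, integrated and
#' converted to dose (average-then-fit).
#'
#' @param series_list named list of [time_activity_series()], one per
#'   vertebra, all on identical time grids.
#' @param combinations a `combination_set` or list of them (or a plain list
#'   of character vectors).
#' @param constants a [dosimetry_constants()].
#' @param tag reconstruction tag propagated to the doses.
#' @return Data frame with columns `id`, `k`, `tiac`, `dose_mGy_per_GBq`,
#'   `fallback`.
#' @export
combination_doses <- function(series_list, combinations,
                              constants = dosimetry_constants(),
                              tag = NA_character_) {
  subsets <- if (inherits(combinations, "combination_set"))
    combinations$subsets
  else if (is.list(combinations) &&
           all(vapply(combinations, inherits, TRUE, "combination_set")))
    do.call(c, lapply(combinations, `[[`, "subsets"))
  else combinations
  t0 <- series_list[[1]]$times_h
  inj <- series_list[[1]]$injected_GBq
  for (s in series_list)
    if (!isTRUE(all.equal(s$times_h, t0)))
      stop("all vertebra series must share the same time grid")
  rows <- lapply(subsets, function(members) {
    if (!all(members %in% names(series_list)))
      stop("combination member missing from series list")
    concs <- vapply(series_list[members], `[[`, numeric(length(t0)), "conc")
    avg <- if (is.matrix(concs)) rowMeans(concs) else concs
    fit <- fit_biexp(times_h = t0, conc = avg)
    tia <- time_integrated_concentration(fit)
    d <- absorbed_dose(tia, constants, inj, tag = tag,
                       id = combo_id(members))
    data.frame(id = d$id, k = length(members), tiac = tia,
               dose_mGy_per_GBq = d$dose_mGy_per_GBq,
               fallback = fit$fallback)
  })
  do.call(rbind, rows)
}

#' Precision by group size
#'
#' Mean dose and COV (Eq. style sigma/mu*100, sample standard deviation)
#' for each vertebra-group size.
#'
#' @param doses data frame from [combination_doses()] (columns `k` and
#'   `dose_mGy_per_GBq`).
#' @return Data frame with one row per `k`: `k`, `n_combinations`,
#'   `mean_dose`, `sd_dose`, `cov_percent` (`NA` flagged when undefined).
#' @export
precision_by_group_size <- function(doses) {
  ks <- sort(unique(doses$k))
  rows <- lapply(ks, function(k) {
    g <- cov_stats(doses$dose_mGy_per_GBq[doses$k == k],
                   label = sprintf("k=%d", k))
    data.frame(k = k, n_combinations = g$n, mean_dose = g$mean,
               sd_dose = g$sd, cov_percent = g$cov_percent)
  })
  do.call(rbind, rows)
}

#' Compare two vertebral regions
#'
#' Paired (default) or two-sample t-test between doses or concentrations
#' computed from two vertebral regions (e.g. L3-L5 versus T12-L2).
#' Zero-variance differences are flagged degenerate rather than crashing.
#'
#' @param a,b numeric vectors (paired: equal length).
#' @param paired paired test?
#' @param alpha significance level.
#' @return List with `mean_diff`, `statistic`, `p_value`, `significant`,
#'   `degenerate`.
#' @export
compare_regions <- function(a, b, paired = TRUE, alpha = 0.05) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (paired) stopifnot(length(a) == length(b))
  md <- mean(a) - mean(b)
  degenerate <- if (paired) var(a - b) == 0 else (var(a) == 0 && var(b) == 0)
  if (degenerate)
    return(list(mean_diff = md, statistic = NA_real_, p_value = NA_real_,
                significant = FALSE, degenerate = TRUE))
  tt <- t.test(a, b, paired = paired)
  list(mean_diff = md, statistic = unname(tt$statistic),
       p_value = tt$p.value, significant = tt$p.value < alpha,
       degenerate = FALSE)
}

#' Compare reconstruction settings per group size
#'
#' Two-sample t-tests between two reconstruction settings within each
#' vertebra-group size, Bonferroni-corrected over the group sizes at family
#' level `alpha`, plus the mean relative dose difference per group
#' ([delta_ad()], first setting as reference).
#'
#' @param doses data frame with columns `k`, `setting`, `dose_mGy_per_GBq`.
#' @param settings length-2 character: reference setting first (the dAD
#'   reference, e.g. "5i12s"), comparison second.
#' @param alpha family-wise level (default 0.01).
#' @return Data frame per `k`: `p_value`, `significant` (Bonferroni),
#'   `mean_delta_ad`.
#' @export
compare_recon_settings <- function(doses, settings = c("5i12s", "60i1s"),
                                   alpha = 0.01) {
  stopifnot(all(c("k", "setting", "dose_mGy_per_GBq") %in% names(doses)),
            length(settings) == 2)
  ks <- sort(unique(doses$k))
  m <- length(ks)
  rows <- lapply(ks, function(k) {
    a <- doses$dose_mGy_per_GBq[doses$k == k & doses$setting == settings[1]]
    b <- doses$dose_mGy_per_GBq[doses$k == k & doses$setting == settings[2]]
    if (length(a) == 0 || length(b) == 0)
      stop(sprintf("missing doses for k = %d", k))
    degenerate <- var(a) == 0 && var(b) == 0
    p <- if (degenerate) NA_real_ else t.test(a, b)$p.value
    dads <- mapply(function(x, y) delta_ad(x, y), a, b)
    data.frame(k = k, p_value = p,
               significant = !is.na(p) && p < alpha / m,
               mean_delta_ad = mean(dads), degenerate = degenerate)
  })
  do.call(rbind, rows)
}

#' Ground-truth restoration
#'
#' Percentage of a ground-truth absorbed dose restored by the measured
#' (image-derived) dose: `100 * recovered / truth`.
#'
#' @param recovered_dose,truth_dose doses (numeric or `dose_result`).
#' @return Percent.
#' @export
ground_truth_restoration <- function(recovered_dose, truth_dose) {
  r <- if (inherits(recovered_dose, "dose_result"))
    recovered_dose$dose_mGy_per_GBq else recovered_dose
  tr <- if (inherits(truth_dose, "dose_result"))
    truth_dose$dose_mGy_per_GBq else truth_dose
  if (tr <= 0) stop("truth dose must be positive")
  100 * r / tr
}

#' Simulate a patient-like set of vertebral time-activity series
#'
#' Generates exchangeable per-vertebra marrow time-activity curves: a
#' common uptake-washout curve `C (exp(-lambda_slow t) - exp(-lambda_fast t))`
#' peaking near 24 h, a lognormal per-vertebra scale factor (biological
#' heterogeneity plus measurement noise at the single-vertebra level), and
#' a small lognormal per-time-point jitter.
#'
#' @param n_vertebrae number of vertebrae (default 10: T8..L5).
#' @param times_h imaging times (default 2, 24, 48, 168 h).
#' @param amplitude curve scale (MBq/mL).
#' @param lambda_slow,lambda_fast washout and uptake rate constants (1/h);
#'   the slow rate includes physical decay.
#' @param sdlog_vertebra lognormal sd of the per-vertebra scale.
#' @param sdlog_time lognormal sd of the per-time-point jitter.
#' @param injected_GBq injected activity.
#' @param seed RNG seed.
#' @return Named list of [time_activity_series()] (`V1`..`Vn`).
#' @export
simulate_vertebra_series <- function(n_vertebrae = 10,
                                     times_h = c(2, 24, 48, 168),
                                     amplitude = 0.043,
                                     lambda_slow = 0.0095,
                                     lambda_fast = 0.25,
                                     sdlog_vertebra = 0.30,
                                     sdlog_time = 0.05,
                                     injected_GBq = 7.4, seed = 1) {
  set.seed(seed)
  base <- amplitude * (exp(-lambda_slow * times_h) -
                       exp(-lambda_fast * times_h))
  out <- lapply(seq_len(n_vertebrae), function(v) {
    g <- exp(rnorm(1, 0, sdlog_vertebra))
    jitter <- exp(rnorm(length(times_h), 0, sdlog_time))
    time_activity_series(times_h, base * g * jitter,
                         source = sprintf("V%d", v),
                         injected_GBq = injected_GBq)
  })
  stats::setNames(out, sprintf("V%d", seq_len(n_vertebrae)))
}
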