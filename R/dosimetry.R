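# Time-activity fitting, time-integrated activity and marrow absorbed dose.
#
# The fitted model is f(t) = A1 exp(-lambda1 t) + A2 exp(-lambda2 t) with
# lambda1, lambda2 > 0; A2 may be negative (uptake phase).  Measured
# concentrations are taken as not decay-corrected, so the fitted rate
# constants include physical decay and no separate decay term is added.

#' Time-activity series
#'
#' Per-region activity concentration versus time after injection.
#'
#' @param times_h strictly increasing times (hours post injection).
#' @param conc concentrations (MBq/mL), non-negative.
#' @param source region identifier (VOI or combination id).
#' @param injected_GBq injected activity (GBq).
#' @return A `time_activity_series` object.
#' @export
time_activity_series <- function(times_h, conc, source = "voi",
                                 injected_GBq = 7.4) {
  stopifnot(length(times_h) == length(conc))
  if (any(diff(times_h) <= 0) || any(times_h < 0))
    stop("times must be non-negative and strictly increasing")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  structure(list(times_h = times_h, conc = conc, source = source,
                 injected_GBq = injected_GBq),
            class = "time_activity_series")
}

#' @export
print.time_activity_series <- function(x, ...) {
  cat(sprintf("time_activity_series '%s' (%.2f GBq injected)\n",
              x$source, x$injected_GBq))
  print(data.frame(time_h = x$times_h, conc_MBq_per_mL = x$conc),
        row.names = FALSE)
  invisible(x)
}

biexp_f <- function(t, p) p[1] * exp(-p[3] * t) + p[2] * exp(-p[4] * t)

# log-linear decay-rate estimate from two (t, c) points; NA if unusable
loglin_rate <- function(t1, c1, t2, c2) {
  if (c1 <= 0 || c2 <= 0 || t2 == t1) return(NA_real_)
  r <- log(c1 / c2) / (t2 - t1)
  if (!is.finite(r) || r <= 0) NA_real_ else r
}

# amplitudes by linear least squares for fixed rate constants
amps_for_rates <- function(t, y, l1, l2) {
  X <- cbind(exp(-l1 * t), exp(-l2 * t))
  a <- tryCatch(qr.solve(X, y), error = function(e) NULL)
  if (is.null(a) || any(!is.finite(a))) a <- c(mean(y), 0)
  a
}

#' Fit a biexponential time-activity curve
#'
#' Nonlinear least squares for
#' `f(t) = A1 exp(-lambda1 t) + A2 exp(-lambda2 t)` via
#' [minpack.lm::nls.lm()] with multi-start initialization: the slow rate is
#' seeded from a log-linear fit to the last two points, the fast rate from
#' the first two points and from fixed multiples of the slow rate, and
#' amplitudes are seeded by linear least squares at each rate pair.  The
#' best start by residual norm wins (ties broken by the smaller fast rate).
#' If no biexponential converges with positive rates and `f >= 0` on
#' `[0, Inf)`, the fit falls back to a monoexponential (`A2 = 0`) and sets
#' the `fallback` flag.
#'
#' @param series a [time_activity_series()] (or numeric times via `times_h`
#'   with `conc` supplied).
#' @param times_h,conc alternative raw-vector interface.
#' @return A `biexp_fit` object with coefficients `A1`, `A2`, `lambda1`,
#'   `lambda2`, residual norm, convergence and fallback flags.
#' @export
fit_biexp <- function(series = NULL, times_h = NULL, conc = NULL) {
  if (!is.null(series)) {
    stopifnot(inherits(series, "time_activity_series"))
    times_h <- series$times_h
    conc <- series$conc
  }
  t <- as.numeric(times_h); y <- as.numeric(conc)
  if (length(t) < 3) stop("need at least 3 time points")
  if (all(y <= 0)) stop("all-zero series cannot be fitted")

  n <- length(t)
  l_slow <- loglin_rate(t[n - 1], y[n - 1], t[n], y[n])
  if (is.na(l_slow)) l_slow <- 0.005
  l_fast0 <- loglin_rate(t[1], y[1], t[2], y[2])
  cand <- unique(c(if (!is.na(l_fast0)) abs(l_fast0),
                   l_slow * c(5, 20, 60)))
  starts <- lapply(cand, function(lf) c(l_slow, max(lf, l_slow * 2)))

  resid_fun <- function(p, t, y) y - (p[1] * exp(-exp(p[3]) * t) +
                                      p[2] * exp(-exp(p[4]) * t))
  best <- NULL
  for (s in starts) {
    a <- amps_for_rates(t, y, s[1], s[2])
    par0 <- c(a[1], a[2], log(s[1]), log(s[2]))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fun, t = t, y = y,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, ptol = 1e-10, maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    p <- c(fit$par[1], fit$par[2], exp(fit$par[3]), exp(fit$par[4]))
    # canonical order: lambda1 = slow component
    if (p[3] > p[4]) p <- p[c(2, 1, 4, 3)]
    ssr <- sum(resid_fun(fit$par, t, y)^2)
    ok <- all(is.finite(p)) && p[3] > 0 && p[4] > 0 &&
      biexp_nonneg(p, max(t))
    if (!ok) next
    if (is.null(best) || ssr < best$ssr - 1e-14 ||
        (abs(ssr - best$ssr) <= 1e-14 && p[4] < best$p[4])) {
      best <- list(p = p, ssr = ssr, converged = fit$info %in% 1:4)
    }
  }

  if (is.null(best)) {
    mono <- fit_monoexp(t, y)
    p <- c(mono$A, 0, mono$lambda, mono$lambda)
    best <- list(p = p, ssr = mono$ssr, converged = mono$converged,
                 fallback = TRUE)
  } else best$fallback <- FALSE

  structure(list(coefficients = stats::setNames(
                   best$p, c("A1", "A2", "lambda1", "lambda2")),
                 times_h = t, conc = y, ssr = best$ssr,
                 converged = best$converged, fallback = best$fallback,
                 source = if (!is.null(series)) series$source else "raw",
                 injected_GBq = if (!is.null(series)) series$injected_GBq
                                else NA_real_),
            class = "biexp_fit")
}

# f(t) >= 0 on [0, Inf): checked on a dense grid out to several times the
# observation window plus the asymptotic (slow) term sign
biexp_nonneg <- function(p, t_max) {
  tt <- c(seq(0, 10 * t_max, length.out = 400), 100 * t_max)
  all(biexp_f(tt, p) >= -1e-9 * max(abs(p[1:2]), 1e-12)) && p[1] >= 0
}

fit_monoexp <- function(t, y) {
  # fallback fits the washout phase only (peak onward): an uptake-phase
  # point would otherwise flatten the fitted rate and inflate the integral
  ipk <- which.max(y)
  if (length(t) - ipk >= 1) { t <- t[ipk:length(t)]; y <- y[ipk:length(y)] }
  pos <- y > 0
  if (sum(pos) >= 2) {
    lf <- lm(log(y[pos]) ~ t[pos])
    lam <- max(-coef(lf)[2], 1e-6)
    A <- exp(coef(lf)[1])
  } else {
    lam <- 0.005; A <- max(y)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(A, log(lam)),
                       fn = function(p, t, y) y - p[1] * exp(-exp(p[2]) * t),
                       t = t, y = y,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-10, ptol = 1e-10, maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    A <- fit$par[1]; lam <- exp(fit$par[2])
    ssr <- sum((y - A * exp(-lam * t))^2)
    list(A = max(A, 0), lambda = lam, ssr = ssr,
         converged = fit$info %in% 1:4)
  } else {
    list(A = A, lambda = lam, ssr = sum((y - A * exp(-lam * t))^2),
         converged = FALSE)
  }
}

#' @export
print.biexp_fit <- function(x, ...) {
  p <- x$coefficients
  cat(sprintf("biexp_fit '%s': f(t) = %.4g e^(-%.4g t) + %.4g e^(-%.4g t)\n",
              x$source, p["A1"], p["lambda1"], p["A2"], p["lambda2"]))
  cat(sprintf("  SSR %.3g, converged %s%s\n", x$ssr, x$converged,
              if (x$fallback) ", monoexponential fallback" else ""))
  invisible(x)
}

#' @export
coef.biexp_fit <- function(object, ...) object$coefficients

#' @export
predict.biexp_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times_h
       else if (is.list(newdata)) newdata$times_h else newdata
  biexp_f(t, object$coefficients)
}

#' @export
fitted.biexp_fit <- function(object, ...) biexp_f(object$times_h,
                                                  object$coefficients)

#' @export
residuals.biexp_fit <- function(object, ...) object$conc - fitted(object)

#' @export
summary.biexp_fit <- function(object, ...) {
  structure(list(fit = object,
                 tia = time_integrated_concentration(object)),
            class = "summary.biexp_fit")
}

#' @export
print.summary.biexp_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  time-integrated concentration: %.4g MBq.h/mL\n", x$tia))
  invisible(x)
}

#' @export
simulate.biexp_fit <- function(object, nsim = 1, seed = NULL, sd_rel = 0.05,
                               ...) {
  if (!is.null(seed)) set.seed(seed)
  f <- fitted(object)
  out <- replicate(nsim, pmax(f * (1 + rnorm(length(f), 0, sd_rel)), 0))
  as.data.frame(out)
}

#' Time-integrated activity concentration
#'
#' Closed-form integral of the fitted curve from zero to infinity:
#' `A1/lambda1 + A2/lambda2` (MBq.h/mL).
#'
#' @param fit a `biexp_fit`.
#' @return Scalar TIA concentration.
#' @export
time_integrated_concentration <- function(fit) {
  p <- coef(fit)
  if (p["lambda1"] <= 0 || p["lambda2"] <= 0)
    stop("rate constants must be positive")
  unname(p["A1"] / p["lambda1"] + p["A2"] / p["lambda2"])
}

#' Red-marrow dosimetry constants
#'
#' The vertebral cavity holds trabecular bone plus red and yellow marrow;
#' `volume_fraction` is the proportion occupied by active red marrow
#' (thoracic/lumbar average over sexes), `absorbed_fraction` the proportion
#' of electron energy emitted in the red marrow that is absorbed there, and
#' `density` the red-marrow mass density.  `mean_electron_energy_J` is the
#' mean electron plus beta energy emitted per Lu-177 decay.
#'
#' @param volume_fraction red-marrow volume fraction, default 0.574.
#' @param absorbed_fraction electron absorbed fraction, default 0.645.
#' @param density_kg_per_ml marrow density, default 1.03e-3 kg/mL.
#' @param mean_electron_energy_J energy per decay, default 2.37e-14 J
#'   (about 148 keV).
#' @export
dosimetry_constants <- function(volume_fraction = 0.574,
                                absorbed_fraction = 0.645,
                                density_kg_per_ml = 1.03e-3,
                                mean_electron_energy_J = 2.37e-14) {
  stopifnot(volume_fraction > 0, volume_fraction <= 1,
            absorbed_fraction > 0, absorbed_fraction <= 1,
            density_kg_per_ml > 0, mean_electron_energy_J > 0)
  structure(list(volume_fraction = volume_fraction,
                 absorbed_fraction = absorbed_fraction,
                 density_kg_per_ml = density_kg_per_ml,
                 mean_electron_energy_J = mean_electron_energy_J),
            class = "dosimetry_constants")
}

#' Marrow absorbed dose from a time-integrated concentration
#'
#' All measured VOI activity is attributed to the red-marrow compartment of
#' volume `VF x V_voi`; the electron energy absorbed there per unit marrow
#' mass gives
#' `D = TIA * 3.6e9 * E_e * AF / (VF * rho)` (Gy), reported in mGy per GBq
#' injected.  Linear in the TIA.
#'
#' @param tiac time-integrated activity concentration (MBq.h/mL), >= 0.
#' @param constants a [dosimetry_constants()].
#' @param injected_GBq injected activity (GBq), > 0.
#' @param tag reconstruction tag (e.g. "60i1s") carried in the result.
#' @param id combination or region identifier.
#' @return A `dose_result` (list with `dose_mGy_per_GBq`, `tiac`, ...).
#' @export
absorbed_dose <- function(tiac, constants = dosimetry_constants(),
                          injected_GBq = 7.4, tag = NA_character_,
                          id = NA_character_) {
  stopifnot(inherits(constants, "dosimetry_constants"))
  if (tiac < 0) stop("TIA concentration must be non-negative")
  if (injected_GBq <= 0) stop("injected activity must be positive")
  decays_per_MBqh <- 3.6e9
  dose_Gy <- tiac * decays_per_MBqh * constants$mean_electron_energy_J *
    constants$absorbed_fraction /
    (constants$volume_fraction * constants$density_kg_per_ml)
  structure(list(id = id, tag = tag, tiac_MBqh_per_ml = tiac,
                 dose_mGy_per_GBq = dose_Gy * 1e3 / injected_GBq),
            class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("dose_result %s%s: %.3f mGy/GBq (TIA %.4g MBq.h/mL)\n",
              ifelse(is.na(x$id), "", x$id),
              ifelse(is.na(x$tag), "", paste0(" [", x$tag, "]")),
              x$dose_mGy_per_GBq, x$tiac_MBqh_per_ml))
  invisible(x)
}

#' Relative absorbed-dose difference between reconstruction settings
#'
#' `dAD = (AD_5i12s - AD_60i1s) / AD_5i12s`.
#'
#' @param ad_5i12s,ad_60i1s absorbed doses (numeric or `dose_result`).
#' @return Signed fraction.
#' @export
delta_ad <- function(ad_5i12s, ad_60i1s) {
  a <- if (inherits(ad_5i12s, "dose_result")) ad_5i12s$dose_mGy_per_GBq
       else ad_5i12s
  b <- if (inherits(ad_60i1s, "dose_result")) ad_60i1s$dose_mGy_per_GBq
       else ad_60i1s
  if (a == 0) stop("reference dose (5i12s) must be non-zero")
  (a - b) / a
}

#' Read/write time-activity series as CSV
#'
#' CSV columns: `source`, `time_h`, `conc_MBq_per_mL`, `injected_GBq`.
#'
#' @param series_list named list of [time_activity_series()].
#' @param path file path.
#' @return `read_tac_csv` returns a named list of series.
#' @export
write_tac_csv <- function(series_list, path) {
  rows <- do.call(rbind, lapply(series_list, function(s)
    data.frame(source = s$source, time_h = s$times_h,
               conc_MBq_per_mL = s$conc, injected_GBq = s$injected_GBq)))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @export
read_tac_csv <- function(path) {
  df <- read.csv(path)
  out <- lapply(split(df, df$source), function(d)
    time_activity_series(d$time_h, d$conc_MBq_per_mL, d$source[1],
                         d$injected_GBq[1]))
  out[unique(df$source)]
}
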