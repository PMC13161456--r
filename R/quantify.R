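# Calibration and VOI quantification: image calibration factor (ICF),
# activity concentration, recovery coefficients, voxelwise recovery, and the
# coefficient of variation.

#' Image calibration factor
#'
#' `ICF = C_cal / A_cal`, where `C_cal` is the total reconstructed count
#' rate in a large cylindrical VOI of a homogeneous calibration phantom and
#' `A_cal` the known activity it holds.  The ICF is camera- and
#' reconstruction-specific: derive it with the same geometry, effective
#' exposure and update number as the data it will calibrate.
#'
#' @param recon `recon_volume` of the calibration cylinder.
#' @param voi cylindrical [voi()] (usually the cylinder label itself).
#' @param A_cal known total activity in the phantom (MBq), > 0.
#' @return A `calibration_factor` object with element `icf` (counts/MBq).
#' @export
compute_icf <- function(recon, voi, A_cal) {
  if (A_cal <= 0) stop("A_cal must be positive")
  c_cal <- sum(recon$grid[voi$idx])
  structure(list(icf = c_cal / A_cal, C_cal = c_cal, A_cal = A_cal),
            class = "calibration_factor")
}

#' @export
print.calibration_factor <- function(x, ...) {
  cat(sprintf("ICF = %.6g counts/MBq (C_cal = %.6g, A_cal = %.6g MBq)\n",
              x$icf, x$C_cal, x$A_cal))
  invisible(x)
}

icf_value <- function(icf) {
  v <- if (inherits(icf, "calibration_factor")) icf$icf else icf
  if (!is.finite(v) || v <= 0) stop("ICF must be positive")
  v
}

#' VOI activity concentration
#'
#' Converts reconstructed voxel values to an activity concentration:
#' `(sum of VOI counts / ICF) / VOI volume` (MBq/mL).  All VOI voxels are
#' used (no thresholding).
#'
#' @param recon `recon_volume`.
#' @param voi a [voi()].
#' @param icf a `calibration_factor` or its numeric value.
#' @return Concentration in MBq/mL.
#' @export
voi_concentration <- function(recon, voi, icf) {
  if (length(voi$idx) == 0) stop("empty VOI")
  sum(recon$grid[voi$idx]) / icf_value(icf) / voi$volume_ml
}

#' Recovery coefficient
#'
#' `RC(v) = C_R(v) / (ICF * A_R(v))` for a region `v` with measured count
#' rate `C_R` and known true activity `A_R`.  RC < 1 indicates spill-out due
#' to partial-volume blurring.
#'
#' @param recon `recon_volume`.
#' @param voi a [voi()].
#' @param icf a `calibration_factor` or numeric value.
#' @param A_R true activity in the region (MBq), > 0.
#' @param updates,noise_label,seed optional provenance stored alongside.
#' @return A `recovery_measurement` (list with `rc`, `C_R`, `A_R`, ...).
#' @export
recovery_coefficient <- function(recon, voi, icf, A_R, updates = recon$updates,
                                 noise_label = NA_character_,
                                 seed = NA_integer_) {
  if (A_R <= 0) stop("A_R must be positive")
  c_r <- sum(recon$grid[voi$idx])
  structure(list(voi = voi$name, rc = c_r / (icf_value(icf) * A_R),
                 C_R = c_r, A_R = A_R, updates = updates,
                 noise_label = noise_label, seed = seed),
            class = "recovery_measurement")
}

#' @export
print.recovery_measurement <- function(x, ...) {
  cat(sprintf("RC(%s) = %.4f at %s updates\n", x$voi, x$rc,
              ifelse(is.na(x$updates), "?", x$updates)))
  invisible(x)
}

#' Voxelwise recovery in a VOI
#'
#' Ratio of the mean calibrated reconstructed concentration to the mean true
#' concentration over a VOI; equals 1 for a perfect reconstruction.
#'
#' @param recon `recon_volume`.
#' @param truth true activity concentration grid (MBq/mL), co-registered.
#' @param voi a [voi()].
#' @param icf a `calibration_factor` or numeric value.
#' @return Scalar recovery ratio.
#' @export
voxel_recovery <- function(recon, truth, voi, icf) {
  if (!identical(dim(recon$grid), dim(truth)))
    stop("reconstruction and truth grids are not co-registered")
  t_mean <- mean(truth[voi$idx])
  if (t_mean <= 0) stop("true activity in VOI is zero")
  voxvol <- (recon$voxel_mm / 10)^3
  conc <- recon$grid[voi$idx] / (icf_value(icf) * voxvol)
  mean(conc) / t_mean
}

#' Coefficient of variation
#'
#' Sample statistics of a group of values: mean, standard deviation (n-1
#' denominator) and `COV = sigma/mu * 100` (percent).  A zero mean leaves
#' the COV undefined (`NA`) with `degenerate = TRUE`.
#'
#' @param values numeric vector (n >= 2 for a standard deviation).
#' @param label optional group label.
#' @return A `group_stats` object (list with `n`, `mean`, `sd`,
#'   `cov_percent`, `degenerate`).
#' @export
cov_stats <- function(values, label = NA_character_) {
  n <- length(values)
  mu <- mean(values)
  sigma <- if (n >= 2) sd(values) else NA_real_
  degenerate <- !is.finite(mu) || mu == 0
  structure(list(label = label, n = n, mean = mu, sd = sigma,
                 cov_percent = if (degenerate) NA_real_
                               else sigma / mu * 100,
                 degenerate = degenerate),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("group %s: n = %d, mean = %.4g, sd = %.4g, COV = %s%%\n",
              ifelse(is.na(x$label), "<unnamed>", x$label), x$n, x$mean,
              x$sd, ifelse(is.na(x$cov_percent), "NA",
                           sprintf("%.3g", x$cov_percent))))
  invisible(x)
}
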