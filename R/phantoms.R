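# Parametric voxel phantoms: body phantom with a T8-L5 vertebral column and
# abdominal organs, elliptical lung-spine phantom with spherical inserts, and
# a homogeneous calibration cylinder.  All anatomy is deterministic; every
# organ carries a single (homogeneous) activity concentration.

# linear attenuation coefficients at 208 keV (1/cm), NIST-derived
MU_208KEV <- c(air = 0, soft = 0.135, lung = 0.040, bone = 0.25)

VERTEBRA_NAMES <- c("T8", "T9", "T10", "T11", "T12",
                    "L1", "L2", "L3", "L4", "L5")
VERTEBRA_CODES <- stats::setNames(11:20, VERTEBRA_NAMES)

#' Voxel phantom constructor
#'
#' Bundles co-registered label, attenuation and activity grids with an organ
#' table into a `voxel_phantom` object, the ground truth consumed by the
#' projector and the quantification routines.
#'
#' @param label integer 3-D array of organ codes (0 = air).
#' @param mu 3-D array of linear attenuation at 208 keV (1/cm).
#' @param activity 3-D array of activity concentration (MBq/mL).
#' @param voxel_mm isotropic voxel size in mm.
#' @param organs data frame with columns `code`, `name`, `volume_ml`,
#'   `conc_MBq_per_ml`, `activity_MBq` (one row per organ code present).
#' @return A `voxel_phantom` object.
#' @export
voxel_phantom <- function(label, mu, activity, voxel_mm, organs) {
  stopifnot(identical(dim(label), dim(mu)),
            identical(dim(label), dim(activity)),
            length(dim(label)) == 3L, voxel_mm > 0)
  if (any(activity < 0)) stop("activity_grid must be non-negative")
  if (any(mu < 0)) stop("mu_grid must be non-negative")
  structure(list(label = label, mu = mu, activity = activity,
                 voxel_mm = voxel_mm, organs = organs),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$label)
  cat(sprintf("voxel_phantom: %d x %d x %d grid, %.2f mm voxels\n",
              d[1], d[2], d[3], x$voxel_mm))
  cat(sprintf("  total activity %.3f MBq in %d labelled regions\n",
              sum(x$organs$activity_MBq), nrow(x$organs)))
  print(x$organs, row.names = FALSE)
  invisible(x)
}

voxel_volume_ml <- function(phantom) (phantom$voxel_mm / 10)^3 # cm^3 == mL

# centered voxel-center coordinates (mm) along one axis
axis_mm <- function(n, voxel_mm) (seq_len(n) - 1 - (n - 1) / 2) * voxel_mm

# coordinate grids for a (nx, ny, nz) volume
coord_grids <- function(grid_dim, voxel_mm) {
  list(x = axis_mm(grid_dim[1], voxel_mm),
       y = axis_mm(grid_dim[2], voxel_mm),
       z = axis_mm(grid_dim[3], voxel_mm))
}

# paint `code` where `mask` is TRUE; error if it collides with an existing
# non-background structure
paint <- function(label, mask, code, name, background = c(0L, 1L)) {
  hit <- mask & !(label %in% background)
  if (any(hit)) {
    other <- setdiff(unique(label[hit]), background)
    stop(sprintf("organ '%s' overlaps existing structure code(s) %s",
                 name, paste(other, collapse = ", ")))
  }
  label[mask] <- code
  label
}

ellipsoid_mask <- function(cc, center, semi) {
  dx <- (cc$x - center[1]) / semi[1]
  dy <- (cc$y - center[2]) / semi[2]
  dz <- (cc$z - center[3]) / semi[3]
  outer(outer(dx^2, dy^2, `+`), dz^2, `+`) <= 1
}

# z-axis aligned cylinder over z in [z0, z1)
cylinder_mask <- function(cc, center_xy, radius, z0, z1) {
  dx <- cc$x - center_xy[1]
  dy <- cc$y - center_xy[2]
  inxy <- outer(dx^2, dy^2, `+`) <= radius^2
  inz <- cc$z >= z0 & cc$z < z1
  outer(inxy, inz, `&`)
}

elliptic_cylinder_mask <- function(cc, center_xy, semi_xy) {
  dx <- (cc$x - center_xy[1]) / semi_xy[1]
  dy <- (cc$y - center_xy[2]) / semi_xy[2]
  inxy <- outer(dx^2, dy^2, `+`) <= 1
  outer(inxy, rep(TRUE, length(cc$z)), `&`)
}

make_organ_table <- function(label, activity, voxvol_ml, code_names) {
  codes <- sort(unique(as.vector(label)))
  codes <- codes[codes != 0]
  rows <- lapply(codes, function(cd) {
    idx <- which(label == cd)
    conc <- activity[idx[1]]
    data.frame(code = cd,
               name = code_names[as.character(cd)],
               volume_ml = length(idx) * voxvol_ml,
               conc_MBq_per_ml = conc,
               activity_MBq = sum(activity[idx]) * voxvol_ml)
  })
  do.call(rbind, rows)
}

#' Per-organ uptake specification
#'
#' Homogeneous activity concentrations (MBq/mL) for each modelled tissue at a
#' set of imaging time points.  The bundled default is a synthetic table
#' shaped like a typical Lu-177 DOTATATE patient (renal excretion dominating,
#' marrow a few times background, marrow peak near 24 h); it is a stand-in,
#' not a published biodistribution, and can be replaced wholesale.
#'
#' @param times_h strictly increasing imaging times, hours post injection.
#' @param conc numeric matrix (organ x time) with rownames
#'   `background`, `kidney`, `spleen`, `liver`, `lung`, `marrow`.
#' @return An `organ_uptake_spec` object.
#' @export
organ_uptake_spec <- function(times_h, conc) {
  stopifnot(is.matrix(conc), ncol(conc) == length(times_h))
  if (any(diff(times_h) <= 0)) stop("time points must be strictly increasing")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  need <- c("background", "kidney", "spleen", "liver", "lung", "marrow")
  if (!all(need %in% rownames(conc)))
    stop("conc must have rows: ", paste(need, collapse = ", "))
  structure(list(times_h = times_h, conc = conc), class = "organ_uptake_spec")
}

#' @rdname organ_uptake_spec
#' @export
default_uptake <- function() {
  times <- c(2, 24, 48, 168)
  conc <- rbind(
    background = c(0.020, 0.015, 0.010, 0.0030),
    kidney     = c(0.400, 0.320, 0.220, 0.0600),
    spleen     = c(0.500, 0.420, 0.300, 0.0900),
    liver      = c(0.150, 0.120, 0.085, 0.0250),
    lung       = c(0.025, 0.018, 0.012, 0.0040),
    marrow     = c(0.045, 0.052, 0.038, 0.0130))
  organ_uptake_spec(times, conc)
}

#' @rdname organ_uptake_spec
#' @param marrow,background concentrations (MBq/mL) for the marrow-only map;
#'   every other tissue gets the background value (default 5:1 contrast).
#' @export
marrow_only_uptake <- function(marrow = 0.05, background = 0.01) {
  times <- c(2, 24, 48, 168)
  conc <- rbind(background = rep(background, 4), kidney = rep(background, 4),
                spleen = rep(background, 4), liver = rep(background, 4),
                lung = rep(background, 4), marrow = rep(marrow, 4))
  organ_uptake_spec(times, conc)
}

# Vertebral column geometry: equal-sized cylindrical vertebral bodies
# stacked contiguously (intervertebral discs are below grid resolution),
# with graded interior marrow VOIs.  The delineable marrow VOI is smaller
# than the vertebral body and grows cranio-caudally, spanning roughly the
# 4.6-10.1 mL range reported for T8-L5 delineations.
vertebra_geometry <- function() {
  list(body_radius = 13.75,        # mm, vertebral body
       body_height = 27.5,         # mm
       voi_radius = 11,            # mm, interior marrow VOI
       voi_target_heights = seq(11, 27.5, length.out = 10)) # T8 -> L5, mm
}

#' Build the parametric body phantom
#'
#' A stylized torso: an elliptical soft-tissue body containing ten stacked
#' cylindrical vertebral bodies (T8 cranially to L5 caudally) of graded
#' volume, two kidneys flanking the T12-L2 levels, a liver right-superior, a
#' spleen left, and two low-density lungs superiorly.  Organ activities are
#' homogeneous and taken from `uptake` at the requested time point.
#'
#' @param grid_dim integer length-3 grid dimensions (x, y, z).
#' @param voxel_mm isotropic voxel size in mm.
#' @param uptake an [organ_uptake_spec()].
#' @param time_point_h one of `uptake$times_h`.
#' @return A [voxel_phantom()] with vertebra labels 11:20 (T8..L5).
#' @export
build_body_phantom <- function(grid_dim = c(64, 64, 64), voxel_mm = 5.5,
                               uptake = default_uptake(), time_point_h = 24) {
  ti <- match(time_point_h, uptake$times_h)
  if (is.na(ti)) stop("time_point_h must be one of the uptake time points")
  conc <- uptake$conc[, ti]
  cc <- coord_grids(grid_dim, voxel_mm)
  label <- array(0L, grid_dim)

  torso <- elliptic_cylinder_mask(cc, c(0, 0), c(150, 100))
  label[torso] <- 1L

  vg <- vertebra_geometry()
  z_top <- 5 * vg$body_height   # column centered on the grid
  vert_z <- matrix(NA_real_, 10, 2,
                   dimnames = list(VERTEBRA_NAMES, c("lo", "hi")))
  z <- z_top
  for (i in 1:10) { # T8 (top) down to L5
    vert_z[i, ] <- c(z - vg$body_height, z)
    z <- z - vg$body_height
  }
  spine_y <- 55
  vois <- vector("list", 10)
  for (i in 1:10) {
    m <- cylinder_mask(cc, c(0, spine_y), vg$body_radius,
                       vert_z[i, "lo"], vert_z[i, "hi"])
    label <- paint(label, m, VERTEBRA_CODES[i], VERTEBRA_NAMES[i])
    # interior marrow VOI: narrower cylinder, central slab of target height
    zc <- mean(vert_z[i, ])
    h <- vg$voi_target_heights[i]
    vois[[i]] <- cylinder_mask(cc, c(0, spine_y), vg$voi_radius,
                               zc - h / 2, zc + h / 2) & m
  }
  names(vois) <- VERTEBRA_NAMES

  kid_c <- (vert_z["L2", "lo"] + vert_z["T12", "hi"]) / 2
  organs <- list(
    kidney_right = list(code = 2L, center = c(-42, 40, kid_c),
                        semi = c(26, 18, 45), tissue = "kidney"),
    kidney_left  = list(code = 3L, center = c(42, 40, kid_c),
                        semi = c(26, 18, 45), tissue = "kidney"),
    liver        = list(code = 4L,
                        center = c(-58, -15, mean(vert_z["T11", ])),
                        semi = c(55, 42, 42), tissue = "liver"),
    spleen       = list(code = 5L,
                        center = c(60, 15, mean(vert_z["T11", ])),
                        semi = c(26, 22, 30), tissue = "spleen"),
    lung_right   = list(code = 6L, center = c(-52, -12, 130),
                        semi = c(38, 45, 42), tissue = "lung"),
    lung_left    = list(code = 7L, center = c(52, -12, 130),
                        semi = c(38, 45, 42), tissue = "lung"))
  for (nm in names(organs)) {
    o <- organs[[nm]]
    m <- ellipsoid_mask(cc, o$center, o$semi) & torso
    label <- paint(label, m, o$code, nm)
  }

  mu <- array(MU_208KEV["air"], grid_dim)
  mu[label >= 1L] <- MU_208KEV["soft"]
  mu[label %in% c(6L, 7L)] <- MU_208KEV["lung"]
  mu[label %in% VERTEBRA_CODES] <- MU_208KEV["bone"]

  activity <- array(0, grid_dim)
  activity[label == 1L] <- conc["background"]
  activity[label %in% c(2L, 3L)] <- conc["kidney"]
  activity[label == 4L] <- conc["liver"]
  activity[label == 5L] <- conc["spleen"]
  activity[label %in% c(6L, 7L)] <- conc["lung"]
  for (v in VERTEBRA_CODES) activity[label == v] <- conc["marrow"]

  code_names <- c("1" = "background", "2" = "kidney_right",
                  "3" = "kidney_left", "4" = "liver", "5" = "spleen",
                  "6" = "lung_right", "7" = "lung_left",
                  stats::setNames(VERTEBRA_NAMES, VERTEBRA_CODES))
  organs_tab <- make_organ_table(label, activity,
                                 (voxel_mm / 10)^3, code_names)
  ph <- voxel_phantom(label, mu, activity, voxel_mm, organs_tab)
  voxvol <- (voxel_mm / 10)^3
  ph$vertebra_vois <- stats::setNames(lapply(VERTEBRA_NAMES, function(nm) {
    idx <- which(vois[[nm]])
    voi(nm, idx, length(idx) * voxvol)
  }), VERTEBRA_NAMES)
  ph
}

#' Build the elliptical lung-spine phantom
#'
#' An elliptical water-equivalent body with two low-density lung regions, a
#' bone-equivalent spinal rod, and spherical inserts of the requested volumes
#' filled at `ratio` times the background concentration.  The rod and lungs
#' differ from the background only in attenuation so that at `ratio = 1` the
#' activity map is uniform inside the body.
#'
#' @param grid_dim,voxel_mm grid dimensions and voxel size (mm).
#' @param sphere_volumes_ml insert volumes in mL.
#' @param ratio sphere-to-background activity concentration ratio.
#' @param background_conc background concentration in MBq/mL (default gives
#'   0.58 MBq/mL in the spheres at ratio 2).
#' @return A [voxel_phantom()]; sphere labels are `10 + seq_along(volumes)`.
#' @export
build_lung_spine_phantom <- function(grid_dim = c(64, 64, 64), voxel_mm = 4.5,
                                     sphere_volumes_ml = c(4, 8, 16),
                                     ratio = 2, background_conc = 0.29) {
  stopifnot(all(sphere_volumes_ml > 0), ratio >= 0, background_conc >= 0)
  cc <- coord_grids(grid_dim, voxel_mm)
  label <- array(0L, grid_dim)
  torso <- elliptic_cylinder_mask(cc, c(0, 0), c(135, 95))
  label[torso] <- 1L

  label <- paint(label, cylinder_mask(cc, c(0, 58), 16, -120, 120) & torso,
                 2L, "spine_rod")
  label <- paint(label, ellipsoid_mask(cc, c(-62, 8, 0), c(36, 48, 110)) & torso,
                 3L, "lung_right")
  label <- paint(label, ellipsoid_mask(cc, c(62, 8, 0), c(36, 48, 110)) & torso,
                 4L, "lung_left")

  n_s <- length(sphere_volumes_ml)
  xs <- if (n_s == 1) 0 else seq(-60, 60, length.out = n_s)
  for (i in seq_len(n_s)) {
    r <- (3 * sphere_volumes_ml[i] * 1000 / (4 * pi))^(1 / 3)
    m <- ellipsoid_mask(cc, c(xs[i], -55, 0), rep(r, 3))
    label <- paint(label, m, 10L + i,
                   sprintf("sphere_%gml", sphere_volumes_ml[i]))
  }

  mu <- array(MU_208KEV["air"], grid_dim)
  mu[label >= 1L] <- MU_208KEV["soft"]
  mu[label %in% c(3L, 4L)] <- MU_208KEV["lung"]
  mu[label == 2L] <- MU_208KEV["bone"]

  activity <- array(0, grid_dim)
  activity[label >= 1L] <- background_conc
  activity[label > 10L] <- ratio * background_conc

  code_names <- c("1" = "background", "2" = "spine_rod", "3" = "lung_right",
                  "4" = "lung_left",
                  stats::setNames(sprintf("sphere_%gml", sphere_volumes_ml),
                                  10L + seq_len(n_s)))
  organs_tab <- make_organ_table(label, activity, (voxel_mm / 10)^3,
                                 code_names)
  voxel_phantom(label, mu, activity, voxel_mm, organs_tab)
}

#' Build the homogeneous calibration cylinder
#'
#' A water-filled cylinder holding a known total activity `A_cal`,
#' distributed uniformly over the voxelized cylinder volume, used to derive
#' the image calibration factor.
#'
#' @param grid_dim,voxel_mm grid dimensions and voxel size (mm).
#' @param total_activity_MBq exact total activity in the cylinder.
#' @param radius_mm,height_mm cylinder dimensions.
#' @return A [voxel_phantom()] whose organ table records `A_cal` exactly.
#' @export
build_calibration_cylinder <- function(grid_dim = c(64, 64, 64),
                                       voxel_mm = 4.5,
                                       total_activity_MBq = 100,
                                       radius_mm = 100, height_mm = 200) {
  stopifnot(total_activity_MBq >= 0)
  cc <- coord_grids(grid_dim, voxel_mm)
  if (radius_mm > min(max(abs(cc$x)), max(abs(cc$y))) ||
      height_mm / 2 > max(abs(cc$z)))
    stop("cylinder does not fit inside the grid")
  label <- array(0L, grid_dim)
  m <- cylinder_mask(cc, c(0, 0), radius_mm, -height_mm / 2, height_mm / 2)
  label[m] <- 1L
  nvox <- sum(m)
  voxvol <- (voxel_mm / 10)^3
  conc <- if (nvox > 0) total_activity_MBq / (nvox * voxvol) else 0
  mu <- array(MU_208KEV["air"], grid_dim)
  mu[m] <- MU_208KEV["soft"]
  activity <- array(0, grid_dim)
  activity[m] <- conc
  organs_tab <- data.frame(code = 1L, name = "cylinder",
                           volume_ml = nvox * voxvol,
                           conc_MBq_per_ml = conc,
                           activity_MBq = total_activity_MBq)
  voxel_phantom(label, mu, activity, voxel_mm, organs_tab)
}

#' Volume of interest
#'
#' @param name VOI name, e.g. "L3".
#' @param idx integer voxel indices (into the flattened grid), non-empty.
#' @param volume_ml VOI volume (voxel count times voxel volume).
#' @export
voi <- function(name, idx, volume_ml) {
  stopifnot(length(idx) > 0, volume_ml > 0)
  structure(list(name = name, idx = as.integer(idx), volume_ml = volume_ml),
            class = "voi")
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("VOI '%s': %d voxels, %.2f mL\n", x$name, length(x$idx),
              x$volume_ml))
  invisible(x)
}

# VOI from a set of label codes
label_voi <- function(phantom, codes, name) {
  idx <- which(phantom$label %in% codes)
  if (length(idx) == 0) stop("no voxels with label code(s) ",
                             paste(codes, collapse = ","))
  voi(name, idx, length(idx) * voxel_volume_ml(phantom))
}

#' Vertebral volumes of interest
#'
#' One marrow VOI per vertebra present in the phantom, named T8..L5 and
#' ordered cranio-caudally.  For the body phantom these are the interior
#' marrow delineations built with the anatomy (graded 4.6-10.1 mL-like
#' volumes inside equal-sized vertebral bodies); for any other phantom with
#' vertebra labels the full labelled regions are used.
#'
#' @param phantom a body [voxel_phantom()] with vertebra labels.
#' @return Named list of [voi()] objects.
#' @export
vertebra_vois <- function(phantom) {
  if (!is.null(phantom$vertebra_vois)) return(phantom$vertebra_vois)
  present <- VERTEBRA_CODES[VERTEBRA_CODES %in% unique(as.vector(phantom$label))]
  if (length(present) == 0) stop("phantom has no vertebra labels")
  out <- lapply(names(present), function(nm)
    label_voi(phantom, present[[nm]], nm))
  stats::setNames(out, names(present))
}

#' Spherical-insert volumes of interest
#'
#' Exact-size VOIs matching each spherical insert of the lung-spine phantom.
#'
#' @param phantom a lung-spine [voxel_phantom()].
#' @return Named list of [voi()] objects (names like `sphere_4ml`).
#' @export
sphere_vois <- function(phantom) {
  tab <- phantom$organs[grepl("^sphere_", phantom$organs$name), ]
  if (nrow(tab) == 0) stop("phantom has no spherical inserts")
  out <- lapply(seq_len(nrow(tab)), function(i)
    label_voi(phantom, tab$code[i], tab$name[i]))
  stats::setNames(out, tab$name)
}
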