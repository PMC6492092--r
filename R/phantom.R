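# Labelled 3D thoraco-cardiac digital phantom and its respiratory motion
# model. Anatomy is laid out in coordinates normalized to the field of view,
# so label volume fractions are stable across grid resolutions; structures
# with an absolute physical size (atrial walls, vessel radii) are configured
# in millimetres.

#' Phantom construction parameters
#'
#' @param grid integer length-3 grid size (SI, RL, AP)
#' @param spacing isotropic voxel size (mm)
#' @param wall_thickness atrial wall thickness (mm)
#' @param myo_thickness ventricular myocardium thickness (mm)
#' @param fat_thickness subcutaneous/epicardial fat layer thickness (mm)
#' @param pv_radius pulmonary-vein tube radius (mm)
#' @param cor_radius coronary vessel tube radius (mm)
#' @return list of class `phantom_config`
#' @export
phantom_config <- function(grid = c(96, 96, 64), spacing = 1.4,
                           wall_thickness = 2.5, myo_thickness = 6,
                           fat_thickness = 5, pv_radius = 5,
                           cor_radius = 3.5) {
  stopifnot(length(grid) == 3, all(grid >= 8), spacing > 0,
            wall_thickness > 0, myo_thickness > 0)
  structure(
    list(grid = as.integer(grid), spacing = spacing,
         wall_thickness = wall_thickness, myo_thickness = myo_thickness,
         fat_thickness = fat_thickness, pv_radius = pv_radius,
         cor_radius = cor_radius),
    class = "phantom_config"
  )
}

# millimetre coordinate arrays for the voxel centres of a grid
coord_arrays <- function(grid, spacing) {
  list(
    x = array(rep((seq_len(grid[1]) - 0.5) * spacing, grid[2] * grid[3]), grid),
    y = array(rep(rep((seq_len(grid[2]) - 0.5) * spacing, each = grid[1]),
                  grid[3]), grid),
    z = array(rep((seq_len(grid[3]) - 0.5) * spacing,
                  each = grid[1] * grid[2]), grid)
  )
}

# internal analytic geometry (normalized centres, mm sizes where absolute)
phantom_geometry <- function(cfg) {
  L <- cfg$grid * cfg$spacing
  minL <- min(L)
  g <- list(L = L)
  g$body_c <- c(0.50, 0.50, 0.50) * L
  g$body_r <- c(0.48, 0.46, 0.44) * L
  g$lung_r <- pmax(g$body_r - cfg$fat_thickness, 0.3 * g$body_r)
  g$liver_c <- c(0.16, 0.45, 0.50) * L
  g$liver_r <- c(0.20, 0.36, 0.38) * L
  g$lv_c <- c(0.38, 0.52, 0.52) * L
  g$lv_r <- 0.130 * minL
  g$la_c <- c(0.58, 0.65, 0.46) * L
  g$la_r <- 0.085 * minL
  g$ra_c <- c(0.58, 0.36, 0.46) * L
  g$ra_r <- 0.080 * minL
  # vessel tubes: list(name, class, p0, p1 (mm), radius mm)
  seg <- function(name, class, q0, q1, r) {
    list(name = name, class = class, p0 = q0 * L, p1 = q1 * L, radius = r)
  }
  la_edge_lo <- (g$la_c[2] - g$la_r - cfg$wall_thickness) / L[2]
  la_edge_hi <- (g$la_c[2] + g$la_r + cfg$wall_thickness) / L[2]
  g$vessels <- list(
    seg("rPV", "venous_blood",
        c(0.58, 0.10, 0.46), c(0.58, la_edge_lo, 0.46), cfg$pv_radius),
    seg("lPV", "venous_blood",
        c(0.58, 0.90, 0.46), c(0.58, la_edge_hi, 0.46), cfg$pv_radius),
    seg("AIV", "venous_blood",
        c(0.16, 0.60, 0.72), c(0.50, 0.60, 0.72), cfg$cor_radius),
    seg("PIV", "venous_blood",
        c(0.16, 0.62, 0.30), c(0.50, 0.62, 0.30), cfg$cor_radius),
    seg("LAD", "arterial_blood",
        c(0.16, 0.40, 0.72), c(0.50, 0.40, 0.72), cfg$cor_radius),
    seg("RCA", "arterial_blood",
        c(0.16, 0.26, 0.46), c(0.50, 0.26, 0.46), cfg$cor_radius)
  )
  g
}

#' Construct the labelled digital phantom
#'
#' Builds a deterministic labelled volume containing a fat body shell, lung
#' background, liver, a blood-filled ventricle with myocardial shell and
#' epicardial fat, two atrial chambers with thin walls, and six straight
#' vessel tubes (two pulmonary veins, two coronary veins, two coronary
#' arteries). Ground-truth vessel centerlines and atrial wall contours (with
#' outward normals and true thickness) are attached as the landmark set.
#'
#' @param cfg a [phantom_config()]
#' @param tissues tissue library from [default_tissue_library()]
#' @return object of class `phantom_volume` with elements `labels` (integer
#'   3D array of tissue class ids), `spacing`, `tissue_table`,
#'   `landmark_set`, `geometry`, `config`
#' @export
make_phantom <- function(cfg = phantom_config(),
                         tissues = default_tissue_library()) {
  if (cfg$wall_thickness < cfg$spacing) {
    warning("atrial wall thickness below voxel size (sub-voxel wall)")
  }
  id <- vapply(tissues, function(t) attr(t, "class_id"), numeric(1))
  g <- phantom_geometry(cfg)
  co <- coord_arrays(cfg$grid, cfg$spacing)
  lab <- array(id[["air"]], cfg$grid)

  in_ellipsoid <- function(c0, r) {
    ((co$x - c0[1]) / r[1])^2 + ((co$y - c0[2]) / r[2])^2 +
      ((co$z - c0[3]) / r[3])^2 <= 1
  }
  dist_to <- function(c0) {
    sqrt((co$x - c0[1])^2 + (co$y - c0[2])^2 + (co$z - c0[3])^2)
  }

  body <- in_ellipsoid(g$body_c, g$body_r)
  lung <- in_ellipsoid(g$body_c, g$lung_r)
  lab[body] <- id[["fat"]]
  lab[lung] <- id[["lung"]]
  liver <- in_ellipsoid(g$liver_c, g$liver_r) & lung
  lab[liver] <- id[["liver"]]

  d_lv <- dist_to(g$lv_c)
  epi <- d_lv <= g$lv_r + cfg$myo_thickness + 3.5
  lab[epi & lung] <- id[["fat"]]
  lab[d_lv <= g$lv_r + cfg$myo_thickness] <- id[["myocardium"]]
  lab[d_lv <= g$lv_r] <- id[["arterial_blood"]]

  d_la <- dist_to(g$la_c)
  lab[d_la <= g$la_r + cfg$wall_thickness] <- id[["myocardium"]]
  lab[d_la <= g$la_r] <- id[["arterial_blood"]]
  d_ra <- dist_to(g$ra_c)
  lab[d_ra <= g$ra_r + cfg$wall_thickness] <- id[["myocardium"]]
  lab[d_ra <= g$ra_r] <- id[["venous_blood"]]

  # vessel tubes, painted last so centerlines stay in their own class
  for (v in g$vessels) {
    p0 <- v$p0; p1 <- v$p1
    u <- p1 - p0; len <- sqrt(sum(u^2)); u <- u / len
    px <- co$x - p0[1]; py <- co$y - p0[2]; pz <- co$z - p0[3]
    tproj <- px * u[1] + py * u[2] + pz * u[3]
    tcl <- pmin(pmax(tproj, 0), len)
    d2 <- (px - tcl * u[1])^2 + (py - tcl * u[2])^2 + (pz - tcl * u[3])^2
    lab[d2 <= v$radius^2] <- id[[v$class]]
  }

  # landmark set: centerlines at 1 mm arclength steps; atrial contours at
  # mid-wall radius in the coronal-like (SI, RL) plane through each atrium
  centerlines <- lapply(g$vessels, function(v) {
    len <- sqrt(sum((v$p1 - v$p0)^2))
    s <- seq(0, len, by = 1)
    pts <- outer(s / len, v$p1 - v$p0) + rep(v$p0, each = length(s))
    list(name = v$name, class = v$class, radius = v$radius, points = pts)
  })
  names(centerlines) <- vapply(centerlines, `[[`, "", "name")
  contour_for <- function(c0, r_lumen, side) {
    ang <- seq(0, 2 * pi, length.out = 37)[-37]
    rmid <- r_lumen + cfg$wall_thickness / 2
    pts <- cbind(c0[1] + rmid * cos(ang), c0[2] + rmid * sin(ang),
                 rep(c0[3], length(ang)))
    nrm <- cbind(cos(ang), sin(ang), rep(0, length(ang)))
    list(side = side, points = pts, normals = nrm,
         thickness = cfg$wall_thickness, lumen_radius = r_lumen)
  }
  landmark_set <- list(
    centerlines = centerlines,
    atria = list(left = contour_for(g$la_c, g$la_r, "left"),
                 right = contour_for(g$ra_c, g$ra_r, "right"))
  )

  structure(
    list(labels = lab, spacing = cfg$spacing, dim = cfg$grid,
         tissue_table = tissues, landmark_set = landmark_set,
         geometry = g, config = cfg),
    class = "phantom_volume"
  )
}

#' Map per-tissue signals onto the phantom grid
#'
#' @param phantom a [make_phantom()] result
#' @param signals data.frame from [tissue_signals()]
#' @param parity `"odd"` or `"even"`
#' @param column which signal column to map (default the signed signal)
#' @return numeric 3D array
#' @export
phantom_signal_volume <- function(phantom, signals, parity = "odd",
                                  column = "signal") {
  s <- signals[signals$parity == parity, ]
  lut <- numeric(max(s$class_id) + 1)
  lut[s$class_id + 1] <- s[[column]]
  array(lut[phantom$labels + 1], phantom$dim)
}

#' Respiratory motion model
#'
#' @param si_amplitude peak superior-inferior displacement (mm)
#' @param rl_coupling ratio of right-left to SI displacement
#' @param nonrigid_gain fraction of the SI displacement converted into a
#'   smooth spatially varying deformation over the heart (0 = rigid)
#' @param period respiratory period (ms)
#' @param drift slow baseline drift (mm per minute)
#' @param noise_sd beat-to-beat Gaussian jitter of the SI value (mm)
#' @return list of class `motion_model`
#' @export
motion_model <- function(si_amplitude = 8, rl_coupling = 0.3,
                         nonrigid_gain = 0.35, period = 3571, drift = 0,
                         noise_sd = 0.3) {
  stopifnot(si_amplitude >= 0, nonrigid_gain >= 0, nonrigid_gain <= 1,
            period > 0, noise_sd >= 0)
  structure(
    list(si_amplitude = si_amplitude, rl_coupling = rl_coupling,
         nonrigid_gain = nonrigid_gain, period = period, drift = drift,
         noise_sd = noise_sd),
    class = "motion_model"
  )
}

#' Smooth unit basis of the non-rigid respiratory deformation
#'
#' Sum of four broad Gaussian bumps around the heart region with fixed
#' directions, tapered to zero at the volume edges and normalized to peak
#' displacement magnitude 1. Deterministic for a given grid.
#'
#' @param grid integer length-3 grid size
#' @param spacing voxel size (mm)
#' @return array `c(grid, 3)`, unit peak magnitude
#' @export
nonrigid_basis <- function(grid, spacing) {
  L <- grid * spacing
  minL <- min(L)
  co <- coord_arrays(grid, spacing)
  centres <- rbind(
    c(0.40, 0.52, 0.52), c(0.58, 0.63, 0.47),
    c(0.58, 0.38, 0.47), c(0.30, 0.50, 0.50)
  )
  dirs <- rbind(
    c(1, 0, 0), c(0.85, 0.45, 0), c(0.85, -0.35, 0.3), c(0.7, 0, -0.4)
  )
  dirs <- dirs / sqrt(rowSums(dirs^2))
  sigma <- 0.14 * minL
  taper <- sin(pi * co$x / L[1])^2 * sin(pi * co$y / L[2])^2 *
           sin(pi * co$z / L[3])^2
  f <- array(0, c(grid, 3))
  for (j in seq_len(nrow(centres))) {
    c0 <- centres[j, ] * L
    bump <- exp(-((co$x - c0[1])^2 + (co$y - c0[2])^2 + (co$z - c0[3])^2) /
                  (2 * sigma^2)) * taper
    for (a in 1:3) f[, , , a] <- f[, , , a] + bump * dirs[j, a]
  }
  mag <- sqrt(f[, , , 1]^2 + f[, , , 2]^2 + f[, , , 3]^2)
  f / max(mag)
}

#' Ground-truth displacement field at a respiratory position
#'
#' The field is a global translation (`si_value` along SI and
#' `rl_coupling * si_value` along RL) plus `nonrigid_gain * si_value` times a
#' fixed smooth unit deformation basis that vanishes at the volume edges.
#'
#' @param model a [motion_model()]
#' @param si_value SI displacement (mm)
#' @param grid integer length-3 grid size
#' @param spacing voxel size (mm)
#' @param basis optional precomputed [nonrigid_basis()] (cached by callers)
#' @param check_invertible assert a positive Jacobian determinant when
#'   `|si_value| <= si_amplitude`
#' @return displacement array `c(grid, 3)` in mm
#' @export
displacement_at <- function(model, si_value, grid, spacing,
                            basis = NULL, check_invertible = FALSE) {
  stopifnot(is.finite(si_value))
  f <- array(0, c(grid, 3))
  f[, , , 1] <- si_value
  f[, , , 2] <- model$rl_coupling * si_value
  if (model$nonrigid_gain > 0 && si_value != 0) {
    if (is.null(basis)) basis <- nonrigid_basis(grid, spacing)
    f <- f + model$nonrigid_gain * si_value * basis
  }
  if (check_invertible && abs(si_value) <= model$si_amplitude) {
    jmin <- jacobian_min(f, spacing)
    if (jmin <= 0) {
      stop("ground-truth deformation is not invertible (min |J| = ",
           signif(jmin, 3), ")", call. = FALSE)
    }
  }
  f
}

#' Regions of interest for SNR/CNR measurements
#'
#' Analytic ROIs derived from the phantom geometry: venous blood (right
#' atrium core), arterial blood (ventricle core), myocardium (mid
#' ventricular shell) and background (lung voxels away from the heart and
#' the body edge).
#'
#' @param phantom a [make_phantom()] result
#' @param margin erosion margin (mm) keeping ROIs away from tissue borders
#' @return named list of logical arrays: `venous`, `arterial`,
#'   `myocardium`, `background`
#' @export
phantom_rois <- function(phantom, margin = 3) {
  g <- phantom$geometry
  cfg <- phantom$config
  co <- coord_arrays(phantom$dim, phantom$spacing)
  dist_to <- function(c0) {
    sqrt((co$x - c0[1])^2 + (co$y - c0[2])^2 + (co$z - c0[3])^2)
  }
  d_lv <- dist_to(g$lv_c); d_ra <- dist_to(g$ra_c); d_la <- dist_to(g$la_c)
  id <- vapply(phantom$tissue_table, function(t) attr(t, "class_id"),
               numeric(1))
  lung <- phantom$labels == id[["lung"]]
  heart_r <- g$lv_r + cfg$myo_thickness
  list(
    venous = d_ra <= pmax(g$ra_r - margin, phantom$spacing),
    arterial = d_lv <= pmax(g$lv_r - margin, phantom$spacing),
    myocardium = d_lv >= g$lv_r + 1 & d_lv <= g$lv_r + cfg$myo_thickness - 1,
    background = lung & d_lv > heart_r + 4 * margin &
      d_ra > g$ra_r + 4 * margin & d_la > g$la_r + 4 * margin
  )
}
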