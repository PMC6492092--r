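# Quantitative endpoints: vessel sharpness and visible length along
# centerlines, SNR/CNR from labelled ROIs, atrial wall thickness from
# profile FWHM on the signed PSIR volume, and paired comparisons with
# Bonferroni correction.

# trilinear lookup of mm-space points in a volume with given voxel size
sample_mm <- function(vol, pts_mm, spacing) {
  co <- pts_mm / spacing + 0.5
  trilinear_sample(vol, co)
}

#' Vessel sharpness and visible length along a centerline
#'
#' At each centerline point two intensity profiles are cast perpendicular to
#' the local tangent (opposite directions, one per vessel edge) with linear
#' interpolation. Per edge, the 20--80% distance `d2080` is the radial
#' distance between the crossings of 20% and 80% of the centre-to-background
#' intensity difference; edge sharpness is `min(100, 100 * voxel /
#' d2080)`, so an edge resolved within one voxel scores 100%. The
#' percentage vessel sharpness is the mean over all defined edges within
#' the first `max_length_cm` of arclength. The visible length is the
#' arclength up to the first point whose centre intensity falls below
#' `background + vis_frac` times the proximal (first centimetre)
#' centre-to-background difference.
#'
#' @param image 3D volume (magnitudes are used)
#' @param centerline matrix `n x 3` of mm coordinates, point spacing at
#'   most one voxel
#' @param background_level background intensity level
#' @param spacing voxel size (mm)
#' @param max_length_cm sharpness evaluation length (cm)
#' @param vis_frac visibility stop fraction of the proximal contrast
#' @param profile_halflength perpendicular profile half-length (mm)
#' @return object of class `vessel_metrics`: `vl_cm`, `vs_pct`, `profile`
#'   (per-point data.frame: arclength_cm, center, sharp_1, sharp_2)
#' @export
vessel_metrics <- function(image, centerline, background_level, spacing,
                           max_length_cm = 4, vis_frac = 0.35,
                           profile_halflength = 8) {
  img <- Mod(image)
  stopifnot(nrow(centerline) >= 2)
  L <- dim(img) * spacing
  inside <- centerline[, 1] >= 0 & centerline[, 1] <= L[1] &
            centerline[, 2] >= 0 & centerline[, 2] <= L[2] &
            centerline[, 3] >= 0 & centerline[, 3] <= L[3]
  if (!all(inside)) {
    warning("centerline exits the image; truncated")
    last <- which(!inside)[1] - 1
    if (last < 2) stop("centerline has < 2 points inside image", call. = FALSE)
    centerline <- centerline[seq_len(last), , drop = FALSE]
  }
  n <- nrow(centerline)
  seglen <- sqrt(rowSums((centerline[-1, , drop = FALSE] -
                          centerline[-n, , drop = FALSE])^2))
  arc <- c(0, cumsum(seglen))            # mm

  step <- 0.2
  tvals <- seq(step, profile_halflength, by = step)
  edge_d2080 <- function(prof, ic) {
    # prof: intensities outward from the centre (excluding the centre)
    v <- c(ic, prof)
    r <- c(0, tvals)
    contrast <- ic - background_level
    if (contrast <= 0) return(NA_real_)
    v80 <- background_level + 0.8 * contrast
    v20 <- background_level + 0.2 * contrast
    cross_down <- function(level) {
      below <- which(v <= level)
      if (!length(below)) return(NA_real_)
      i <- below[1]
      if (i == 1) return(0)
      # linear interpolation between samples i-1 and i
      r[i - 1] + (v[i - 1] - level) / (v[i - 1] - v[i]) * step
    }
    r80 <- cross_down(v80)
    r20 <- cross_down(v20)
    if (is.na(r80) || is.na(r20)) return(NA_real_)
    max(r20 - r80, 0)
  }

  sharp <- matrix(NA_real_, n, 2)
  centres <- numeric(n)
  for (i in seq_len(n)) {
    p <- centerline[i, ]
    i0 <- max(i - 1, 1); i1 <- min(i + 1, n)
    tg <- centerline[i1, ] - centerline[i0, ]
    tg <- tg / sqrt(sum(tg^2))
    # profile normal in the coronal (SI, RL) plane where respiratory
    # motion acts, unless the vessel itself runs anterior-posterior
    ref <- if (abs(tg[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
    u <- c(tg[2] * ref[3] - tg[3] * ref[2],
           tg[3] * ref[1] - tg[1] * ref[3],
           tg[1] * ref[2] - tg[2] * ref[1])
    u <- u / sqrt(sum(u^2))
    centres[i] <- sample_mm(img, matrix(p, 1), spacing)
    for (side in 1:2) {
      dirn <- if (side == 1) u else -u
      pts <- matrix(rep(p, each = length(tvals)), ncol = 3) +
             outer(tvals, dirn)
      prof <- sample_mm(img, pts, spacing)
      d <- edge_d2080(prof, centres[i])
      if (!is.na(d)) {
        sharp[i, side] <- if (d < spacing / 100) 100 else
          min(100, 100 * spacing / d)
      }
    }
  }

  # visible length: stop at the first point losing proximal contrast
  prox <- arc <= 10                      # first centimetre
  prox_contrast <- mean(centres[prox]) - background_level
  if (prox_contrast <= 0) {
    vl_mm <- 0                           # no proximal contrast: not visible
  } else {
    vis_level <- background_level + vis_frac * prox_contrast
    failed <- which(centres < vis_level)
    vl_mm <- if (length(failed)) {
      if (failed[1] == 1) 0 else arc[failed[1] - 1]
    } else arc[n]
  }

  in4 <- arc <= max_length_cm * 10
  vs_vals <- sharp[in4, , drop = FALSE]
  vs_pct <- if (any(!is.na(vs_vals))) mean(vs_vals, na.rm = TRUE) else NA_real_

  structure(
    list(vl_cm = vl_mm / 10, vs_pct = vs_pct,
         profile = data.frame(arclength_cm = arc / 10, center = centres,
                              sharp_1 = sharp[, 1], sharp_2 = sharp[, 2])),
    class = "vessel_metrics"
  )
}

#' Mean background intensity around a vessel centerline
#'
#' Samples a cylindrical annulus between `r_in` and `r_out` around the
#' centerline — the immediate surroundings a reader would take as the
#' vessel's background.
#'
#' @param image 3D volume
#' @param centerline matrix of mm points
#' @param spacing voxel size mm
#' @param r_in,r_out annulus radii (mm)
#' @return scalar mean intensity
#' @export
centerline_background <- function(image, centerline, spacing, r_in, r_out) {
  img <- Mod(image)
  n <- nrow(centerline)
  vals <- c()
  radii <- seq(r_in, r_out, by = spacing / 2)
  for (i in seq_len(n)) {
    p <- centerline[i, ]
    i0 <- max(i - 1, 1); i1 <- min(i + 1, n)
    tg <- centerline[i1, ] - centerline[i0, ]
    tg <- tg / sqrt(sum(tg^2))
    ref <- diag(3)[, which.min(abs(tg))]
    u <- c(tg[2] * ref[3] - tg[3] * ref[2],
           tg[3] * ref[1] - tg[1] * ref[3],
           tg[1] * ref[2] - tg[2] * ref[1])
    u <- u / sqrt(sum(u^2))
    v <- c(tg[2] * u[3] - tg[3] * u[2],
           tg[3] * u[1] - tg[1] * u[3],
           tg[1] * u[2] - tg[2] * u[1])
    for (r in radii) for (ang in seq(0, 2 * pi, length.out = 9)[-9]) {
      q <- p + r * (cos(ang) * u + sin(ang) * v)
      L <- dim(img) * spacing
      if (all(q >= 0) && all(q <= L)) {
        vals <- c(vals, sample_mm(img, matrix(q, 1), spacing))
      }
    }
  }
  mean(vals)
}

#' SNR and CNR from labelled regions of interest
#'
#' `snr_X = mean(|image|) over X / sd(|image|) over background`;
#' `cnr_X = (mean_X - mean_myocardium) / sd(background)`. The background
#' (lung) standard deviation of the magnitude image is used as the noise
#' estimate, as is conventional for these measurements (noise-floor bias of
#' magnitude data is not corrected).
#'
#' @param image 3D volume
#' @param rois named list of disjoint non-empty logical masks: `venous`,
#'   `arterial`, `myocardium`, `background`
#' @return list `(snr_ven, snr_art, cnr_ven, cnr_art)`
#' @export
snr_cnr <- function(image, rois) {
  img <- Mod(image)
  for (nm in c("venous", "arterial", "myocardium", "background")) {
    if (is.null(rois[[nm]]) || !any(rois[[nm]])) {
      stop("missing or empty ROI: ", nm, call. = FALSE)
    }
  }
  sd_bg <- stats::sd(img[rois$background])
  if (sd_bg == 0) stop("zero background standard deviation", call. = FALSE)
  m_ven <- mean(img[rois$venous]); m_art <- mean(img[rois$arterial])
  m_myo <- mean(img[rois$myocardium])
  list(snr_ven = m_ven / sd_bg, snr_art = m_art / sd_bg,
       cnr_ven = (m_ven - m_myo) / sd_bg, cnr_art = (m_art - m_myo) / sd_bg)
}

#' Atrial wall thickness along a contour
#'
#' Along each contour normal (`+/- half_range` mm in `step` mm increments,
#' linear interpolation) the wall appears as a bright band between dark
#' blood and dark lung: thickness is the full width at half maximum of the
#' profile peak above its flanking minima. A point is undefined (NA, not
#' zero) when the peak does not rise to at least twice the flanking level
#' (profiles are shifted by their minimum before the comparison; the
#' flanking level is the mean of the two flanking minima).
#'
#' @param psir_volume a [psir_combine()] result or signed real array
#' @param contour list with `points` (`n x 3` mm) and `normals`
#'   (`n x 3` unit vectors), e.g. one side of the phantom landmark atria
#' @param spacing voxel size (mm)
#' @param half_range profile half-length (mm)
#' @param step profile sampling step (mm)
#' @param invert set `TRUE` if the volume has inverted contrast (wall dark);
#'   profiles are negated before peak finding
#' @param upsample integer sinc (zero-fill) upsampling factor applied to the
#'   volume before profiling; band-limited interpolation avoids the peak
#'   broadening a trilinear kernel introduces at coarse voxel sizes
#' @return object of class `awt_result`: `thickness` (per point, mm, NA
#'   where undefined), `mean`, `sd`, `n_defined`, `side`
#' @export
awt_measure <- function(psir_volume, contour, spacing, half_range = 6,
                        step = 0.2, invert = FALSE, upsample = 2) {
  vol <- if (inherits(psir_volume, "psir_volume")) psir_volume$data
         else psir_volume
  if (upsample > 1) {
    vol <- zero_fill_interpolate(vol, upsample)
    spacing <- spacing / upsample
  }
  pts <- contour$points; nrm <- contour$normals
  L <- dim(vol) * spacing
  if (any(pts < 0) || any(pts > matrix(L, nrow(pts), 3, byrow = TRUE))) {
    stop("contour outside volume", call. = FALSE)
  }
  tvals <- seq(-half_range, half_range, by = step)
  thick <- rep(NA_real_, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    ppts <- matrix(rep(pts[i, ], each = length(tvals)), ncol = 3) +
            outer(tvals, nrm[i, ])
    ok <- ppts[, 1] >= 0 & ppts[, 1] <= L[1] &
          ppts[, 2] >= 0 & ppts[, 2] <= L[2] &
          ppts[, 3] >= 0 & ppts[, 3] <= L[3]
    prof <- rep(NA_real_, length(tvals))
    prof[ok] <- sample_mm(vol, ppts[ok, , drop = FALSE], spacing)
    if (invert) prof <- -prof
    if (anyNA(prof)) next
    ipk <- which.max(prof)
    if (ipk <= 1 || ipk >= length(prof)) next
    fl <- min(prof[1:ipk]); fr <- min(prof[ipk:length(prof)])
    base <- min(prof)
    pk <- prof[ipk] - base
    flank <- mean(c(fl, fr)) - base
    if (pk < 2 * flank || pk == 0) next
    cross <- function(idx_range, level) {
      v <- prof[idx_range]
      below <- which(v <= level)
      if (!length(below)) return(NA_real_)
      i2 <- below[1]
      if (i2 == 1) return(tvals[idx_range[1]])
      t1 <- tvals[idx_range[i2 - 1]]; t2 <- tvals[idx_range[i2]]
      v1 <- v[i2 - 1]; v2 <- v[i2]
      t1 + (v1 - level) / (v1 - v2) * (t2 - t1)
    }
    hl <- (prof[ipk] + fl) / 2
    hr <- (prof[ipk] + fr) / 2
    tl <- cross(seq(ipk, 1), hl)
    tr <- cross(seq(ipk, length(prof)), hr)
    if (!is.na(tl) && !is.na(tr)) thick[i] <- tr - tl
  }
  defined <- !is.na(thick)
  structure(
    list(thickness = thick,
         mean = if (any(defined)) mean(thick[defined]) else NA_real_,
         sd = if (sum(defined) > 1) stats::sd(thick[defined]) else NA_real_,
         n_defined = sum(defined), side = contour$side %||% NA_character_),
    class = "awt_result"
  )
}

#' Paired two-tailed t-test with Bonferroni-corrected significance
#'
#' @param values_a,values_b paired measurements (equal length >= 2)
#' @param n_comparisons number of simultaneous comparisons; the
#'   significance threshold is `0.05 / n_comparisons`
#' @return list `(t_statistic, p_value, threshold, significant)`
#' @export
paired_compare <- function(values_a, values_b, n_comparisons = 1) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t_statistic = 0, p_value = 1,
                  threshold = 0.05 / n_comparisons, significant = FALSE))
    }
    stop("zero-variance non-zero differences: t undefined", call. = FALSE)
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE)
  thr <- 0.05 / n_comparisons
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       threshold = thr, significant = tt$p.value < thr)
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_comparisons number of comparisons
#' @param alpha family-wise error rate
#' @param digits if given, truncate (not round) to this many decimals, the
#'   convention used when quoting the threshold
#' @return the corrected threshold
#' @export
bonferroni_threshold <- function(n_comparisons, alpha = 0.05, digits = NULL) {
  thr <- alpha / n_comparisons
  if (!is.null(digits)) thr <- floor(thr * 10^digits) / 10^digits
  thr
}
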