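# Beat-to-beat translational motion estimation from 2D iNAVs, respiratory
# outlier rejection, and equally populated respiratory binning.

#' Estimate 2D translation between an iNAV and the reference iNAV
#'
#' Template matching by normalized cross-correlation over integer pixel
#' shifts within `max_shift_mm`, refined to sub-pixel precision by a 1D
#' parabolic fit through the correlation peak along each axis. The sign
#' convention is positive when the object in `inav` has moved toward the
#' positive axis relative to `ref_inav`.
#'
#' @param inav,ref_inav 2D images (complex allowed; magnitudes are used)
#' @param roi integer list/vector `(si_min, si_max, rl_min, rl_max)` (pixel
#'   indices into the reference image) covering the heart — whole heart
#'   along RL, base-to-mid along SI
#' @param spacing in-plane pixel size (mm)
#' @param max_shift_mm search range per axis (mm)
#' @return list `(d_si, d_rl, score)` with displacements in mm and the peak
#'   normalized cross-correlation in `[-1, 1]`
#' @export
estimate_translation <- function(inav, ref_inav, roi, spacing = 1.4,
                                 max_shift_mm = 20) {
  a <- Mod(inav); r <- Mod(ref_inav)
  stopifnot(all(dim(a) == dim(r)), length(roi) == 4)
  tmpl <- r[roi[1]:roi[2], roi[3]:roi[4]]
  if (stats::sd(tmpl) == 0) {
    stop("flat (zero-variance) template: correlation undefined",
         call. = FALSE)
  }
  m <- floor(max_shift_mm / spacing)
  # clip the search so the shifted window stays inside the image
  lo1 <- max(1 - roi[1], -m); hi1 <- min(dim(a)[1] - roi[2], m)
  lo2 <- max(1 - roi[3], -m); hi2 <- min(dim(a)[2] - roi[4], m)
  s1 <- lo1:hi1; s2 <- lo2:hi2
  cc <- matrix(NA_real_, length(s1), length(s2))
  t0 <- tmpl - mean(tmpl)
  tn <- sqrt(sum(t0^2))
  for (i in seq_along(s1)) {
    for (j in seq_along(s2)) {
      w <- a[(roi[1] + s1[i]):(roi[2] + s1[i]),
             (roi[3] + s2[j]):(roi[4] + s2[j])]
      w0 <- w - mean(w)
      den <- sqrt(sum(w0^2)) * tn
      cc[i, j] <- if (den > 0) sum(w0 * t0) / den else 0
    }
  }
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  refine <- function(vals, idx, shifts) {
    if (idx <= 1 || idx >= length(shifts)) return(shifts[idx])
    y1 <- vals[idx - 1]; y2 <- vals[idx]; y3 <- vals[idx + 1]
    if (1 - y2 < 1e-12) return(shifts[idx])   # exact match: no refinement
    den <- y1 - 2 * y2 + y3
    delta <- if (abs(den) > .Machine$double.eps) 0.5 * (y1 - y3) / den else 0
    shifts[idx] + max(min(delta, 0.5), -0.5)
  }
  d1 <- refine(cc[, pk[2]], pk[1], s1)
  d2 <- refine(cc[pk[1], ], pk[2], s2)
  list(d_si = d1 * spacing, d_rl = d2 * spacing, score = max(cc))
}

#' Select the end-expiratory reference beat
#'
#' The reference iNAV is the beat whose SI value is closest to the modal
#' (most frequent) SI level on a 1 mm histogram — the end-expiratory plateau
#' — rather than an extreme value, which could be an outlier.
#'
#' @param si per-beat SI values (mm)
#' @return index of the reference beat
#' @export
select_reference_beat <- function(si) {
  cnt <- table(round(si))   # 1 mm histogram
  mode_si <- as.numeric(names(cnt)[which.max(cnt)])
  which.min(abs(si - mode_si))
}

#' Track all beats against the reference iNAV
#'
#' @param inavs complex array `c(Nx, Ny, n_beats)` of per-beat iNAVs
#' @param roi heart ROI passed to [estimate_translation()]
#' @param spacing in-plane pixel size (mm)
#' @param ref_beat reference beat index; default selected on a first
#'   tracking pass via [select_reference_beat()]
#' @return data.frame `(beat, d_si, d_rl, score)` of class
#'   `translation_series`, with the reference beat index as attribute
#' @export
track_inavs <- function(inavs, roi, spacing = 1.4, ref_beat = NULL) {
  n <- dim(inavs)[3]
  run <- function(ref_idx) {
    ref <- inavs[, , ref_idx]
    out <- lapply(seq_len(n), function(b) {
      est <- estimate_translation(inavs[, , b], ref, roi, spacing)
      data.frame(beat = b, d_si = est$d_si, d_rl = est$d_rl,
                 score = est$score)
    })
    do.call(rbind, out)
  }
  if (is.null(ref_beat)) {
    first <- run(1)
    ref_beat <- select_reference_beat(first$d_si)
  }
  out <- run(ref_beat)
  attr(out, "ref_beat") <- ref_beat
  class(out) <- c("translation_series", "data.frame")
  out
}

#' Respiratory outlier rejection (mean +/- 2 SD rule)
#'
#' A beat is kept iff its SI value lies within the mean plus or minus twice
#' the sample standard deviation (n-1 denominator) of the full series.
#'
#' @param si_series per-beat SI values (mm), length >= 3
#' @return logical keep mask
#' @export
reject_outliers <- function(si_series) {
  stopifnot(length(si_series) >= 3)
  mu <- mean(si_series)
  s <- stats::sd(si_series)
  if (s == 0) return(rep(TRUE, length(si_series)))
  si_series >= mu - 2 * s & si_series <= mu + 2 * s
}

#' Assign kept beats to equally populated respiratory bins
#'
#' The number of bins is the smallest `n` in `[n_min, n_max]` for which
#' quantile-based equal-count bins all have width at most `max_width`; if no
#' such `n` exists, `n_max` bins are used and the cap violation is recorded
#' (attribute `cap_violated`, plus a message). Ties are broken by beat
#' order. The most end-expiratory bin (smallest centre, i.e. closest to the
#' end-expiratory level at 0) is flagged as the reference bin.
#'
#' @param si_kept SI values of the kept beats (mm)
#' @param max_width maximum allowed bin width (mm)
#' @param n_min,n_max allowed range for the number of bins
#' @return list of class `bin_assignment`: `bin_label` (per kept beat),
#'   `n_bins`, `bin_center` (mean SI per bin), `bin_edges`, `reference_bin`,
#'   `cap_violated`
#' @export
assign_bins <- function(si_kept, max_width = 3.5, n_min = 4, n_max = 6) {
  n <- length(si_kept)
  if (n < n_min) stop("fewer kept beats than n_min", call. = FALSE)
  ord <- order(si_kept, seq_len(n))   # ties broken by beat order
  labels_for <- function(nb) {
    lab <- integer(n)
    # equal counts: first (n mod nb) bins get one extra beat
    sizes <- rep(n %/% nb, nb)
    if (n %% nb > 0) sizes[seq_len(n %% nb)] <- sizes[seq_len(n %% nb)] + 1
    lab[ord] <- rep(seq_len(nb), times = sizes)
    lab
  }
  widths_for <- function(lab, nb) {
    vapply(seq_len(nb), function(b) {
      v <- si_kept[lab == b]
      if (length(v)) diff(range(v)) else 0
    }, numeric(1))
  }
  chosen <- NULL
  for (nb in n_min:n_max) {
    lab <- labels_for(nb)
    if (all(widths_for(lab, nb) <= max_width)) { chosen <- nb; break }
  }
  cap_violated <- is.null(chosen)
  if (cap_violated) {
    chosen <- n_max
    message("respiratory bin width cap (", max_width,
            " mm) not achievable with <= ", n_max, " bins")
  }
  lab <- labels_for(chosen)
  centers <- vapply(seq_len(chosen), function(b) mean(si_kept[lab == b]),
                    numeric(1))
  edges <- vapply(seq_len(chosen), function(b) max(si_kept[lab == b]),
                  numeric(1))
  edges <- c(min(si_kept), edges)
  structure(
    list(bin_label = lab, n_bins = chosen, bin_center = centers,
         bin_edges = edges, reference_bin = which.min(centers),
         cap_violated = cap_violated),
    class = "bin_assignment"
  )
}

#' Export the translation series and bin assignment as one CSV table
#'
#' @param translations a [track_inavs()] result
#' @param keep logical keep mask from [reject_outliers()]
#' @param bins a [assign_bins()] result on the kept beats
#' @param path output CSV path
#' @export
write_motion_csv <- function(translations, keep, bins, path) {
  df <- as.data.frame(translations)
  df$keep <- keep
  df$bin <- NA_integer_
  df$bin[keep] <- bins$bin_label
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
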