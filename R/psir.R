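# Phase-sensitive inversion-recovery (PSIR) combination of the two
# co-registered bright-blood volumes into a signed black-blood volume, and
# zero-filling (sinc) interpolation.

#' Phase-sensitive combination of the inversion-prepared volume
#'
#' The background phase is taken from the non-inverted (even-beat) volume:
#' its complex values are smoothed with a Gaussian kernel, the phase is
#' extracted, and the inversion-prepared volume is rotated by the negative
#' of that phase; the real part is the signed PSIR image. Where the
#' reference magnitude falls below `eps` times its maximum the smoothed
#' phase is unreliable and the voxel's own (unsmoothed) phase of the
#' inversion-prepared volume is used instead, which there reduces to its
#' magnitude (sign convention 0, i.e. non-negative output in unreliable
#' voxels).
#'
#' @param ir_volume complex inversion-prepared volume
#' @param ref_volume complex phase-reference volume (same shape, not all
#'   zero)
#' @param phase_smooth_sigma Gaussian smoothing of the reference phase
#'   (voxels)
#' @param eps relative magnitude floor for phase reliability
#' @return object of class `psir_volume`: `data` (signed real array),
#'   `phase_smooth_sigma`, `eps`, `n_unreliable`
#' @export
psir_combine <- function(ir_volume, ref_volume, phase_smooth_sigma = 2,
                         eps = 0.05) {
  if (!all(dim(ir_volume) == dim(ref_volume))) {
    stop("ir_volume and ref_volume shapes differ", call. = FALSE)
  }
  mx <- max(Mod(ref_volume))
  if (mx == 0) stop("ref_volume is identically zero", call. = FALSE)
  sm <- if (phase_smooth_sigma > 0) {
    gaussian_smooth(ref_volume, phase_smooth_sigma)
  } else ref_volume
  phi <- Arg(sm)
  out <- Re(ir_volume * exp(-1i * phi))
  unreliable <- Mod(ref_volume) < eps * mx
  if (any(unreliable)) {
    out[unreliable] <- Mod(ir_volume[unreliable])
  }
  structure(
    list(data = out, phase_smooth_sigma = phase_smooth_sigma, eps = eps,
         n_unreliable = sum(unreliable)),
    class = "psir_volume"
  )
}

# split-Nyquist symmetric zero padding of one unshifted spectrum axis
pad_axis <- function(karr, axis, factor) {
  if (factor == 1) return(karr)
  d <- dim(karr)
  n <- d[axis]
  n_new <- n * factor
  dn <- d; dn[axis] <- n_new
  out <- array(0i, dn)
  idx_src <- vector("list", 3); idx_dst <- vector("list", 3)
  for (a in 1:3) { idx_src[[a]] <- seq_len(d[a]); idx_dst[[a]] <- seq_len(d[a]) }
  half <- n %/% 2
  pos <- seq_len(half)                 # frequencies 0 .. n/2-1 -> same slots
  neg <- (half + 2):n                  # frequencies -(n/2-1) .. -1
  sel <- function(i) { s <- idx_src; s[[axis]] <- i; s }
  asg <- function(arr, i, val) {
    s <- sel(i); do.call(`[<-`, c(list(arr), s, list(val)))
  }
  get <- function(arr, i) { s <- sel(i); do.call(`[`, c(list(arr), s, list(drop = FALSE))) }
  out <- asg(out, pos, get(karr, pos))
  if (length(neg)) out <- asg(out, neg + n_new - n, get(karr, neg))
  if (n %% 2 == 0 && n >= 2) {
    nyq <- get(karr, half + 1)         # Nyquist bin, split symmetrically
    out <- asg(out, half + 1, nyq / 2)
    out <- asg(out, n_new - half + 1, nyq / 2)
  }
  out
}

#' Zero-fill (sinc) interpolation of a volume
#'
#' Fourier transforms the volume, symmetrically zero-pads k-space by integer
#' factors per axis (splitting the Nyquist bin so real inputs stay real),
#' and transforms back with amplitude-preserving scaling: original grid
#' points are reproduced exactly and a delta keeps its peak value.
#'
#' @param volume 3D array (numeric or complex)
#' @param factor integer upsampling factor(s) per axis (length 1 or 3)
#' @return interpolated volume, dimensions `dim(volume) * factor`; real if
#'   the input was real (up to numerical precision, which is enforced)
#' @export
zero_fill_interpolate <- function(volume, factor) {
  factor <- rep(as.integer(factor), length.out = 3)
  stopifnot(all(factor >= 1))
  if (all(factor == 1)) return(volume)
  was_real <- !is.complex(volume)
  k <- stats::fft(volume)
  for (ax in 1:3) k <- pad_axis(k, ax, factor[ax])
  out <- stats::fft(k, inverse = TRUE) / length(volume)
  if (was_real) Re(out) else out
}
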