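# Unitary n-dimensional Fourier transforms. All k-space arrays in this
# package use R's native fft() layout (DC component at index [1,1,...]).

#' Unitary forward Fourier transform of an array
#' @param x numeric or complex array
#' @return complex array, same dimensions
#' @keywords internal
ft <- function(x) stats::fft(x) / sqrt(length(x))

#' Unitary inverse Fourier transform of an array
#' @param x complex array
#' @return complex array, same dimensions
#' @keywords internal
ift <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

#' Integer frequency indices for one axis in fft() layout
#'
#' Position `i` (1-based) of an unshifted spectrum of length `n` holds
#' integer frequency `kfreq(n)[i]`, running 0, 1, ..., n/2-1, -n/2, ..., -1.
#' @param n axis length
#' @keywords internal
kfreq <- function(n) {
  k <- 0:(n - 1)
  k - n * (k >= ceiling(n / 2))
}

#' k-space coordinates (cycles/mm) for scheduled grid indices
#'
#' @param idx integer grid frequencies (fft layout: 0, 1, ..., n/2-1,
#'   -n/2, ..., -1)
#' @param n axis length
#' @param spacing voxel size (mm)
#' @return frequencies in cycles/mm
#' @export
kcycles <- function(idx, n, spacing) idx / (n * spacing)

#' Gaussian smoothing of a 3D array by Fourier multiplication
#'
#' Circular boundary handling; adequate here because volumes are padded by
#' near-zero background at the edges. Works for real or complex input.
#' @param x 3D array
#' @param sigma standard deviation in voxels, scalar or length-3
#' @return array of the same type and dimensions
#' @keywords internal
gaussian_smooth <- function(x, sigma) {
  d <- dim(x)
  stopifnot(length(d) == 3)
  sigma <- rep(sigma, length.out = 3)
  if (all(sigma <= 0)) return(x)
  # transfer function of a sampled Gaussian: exp(-2 pi^2 sigma^2 f^2)
  tf <- function(n, s) exp(-2 * pi^2 * s^2 * (kfreq(n) / n)^2)
  h <- outer(outer(tf(d[1], sigma[1]), tf(d[2], sigma[2])), tf(d[3], sigma[3]))
  out <- stats::fft(stats::fft(x) * h, inverse = TRUE) / length(x)
  if (is.complex(x)) out else Re(out)
}

#' Root-mean-square error normalized by the reference norm
#'
#' NRMSE between magnitude images, optionally restricted to a mask.
#' @param x test volume (numeric or complex)
#' @param ref reference volume
#' @param mask optional logical array selecting voxels
#' @return scalar `||  |x| - |ref|  || / || |ref| ||`
#' @export
nrmse <- function(x, ref, mask = NULL) {
  a <- Mod(x); b <- Mod(ref)
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
}
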