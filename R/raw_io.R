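# Raw-acquisition container: a documented, language-neutral directory
# format so externally converted k-space (e.g. from ISMRMRD) can be fed to
# the same reconstruction pipeline.
#
# Layout (version 1):
#   manifest.json   shapes, spacing, seeds, noise level, container version
#   schedule.csv    beat, parity, line, ky, kz (integer grid frequencies)
#   trace.csv       beat, time_ms, si, rl (ground-truth trace if synthetic)
#   samples.bin     complex array c(Nx, n_entries, n_coils)
#   inavs.bin       complex array c(Nx, Ny, n_beats)
#   coils.bin       complex array c(grid, n_coils)
# Binary files are little-endian float64: all real parts (column-major),
# then all imaginary parts.

write_complex_bin <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.double(c(Re(x), Im(x))), con, size = 8, endian = "little")
}

read_complex_bin <- function(path, dims, what) {
  n <- prod(dims)
  if (!file.exists(path)) {
    stop("raw container schema error: missing dataset ", what, call. = FALSE)
  }
  v <- readBin(path, "double", n = 2 * n, size = 8, endian = "little")
  if (length(v) != 2 * n) {
    stop("raw container schema error: dataset ", what, " truncated (",
         length(v), " of ", 2 * n, " values)", call. = FALSE)
  }
  array(complex(real = v[seq_len(n)], imaginary = v[n + seq_len(n)]), dims)
}

#' Write a raw acquisition to a directory container
#'
#' @param raw a [synthesize_raw()] result
#' @param path directory to create/overwrite
#' @return `path`, invisibly
#' @export
write_raw <- function(raw, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    container_version = 1L,
    grid = raw$grid, spacing = raw$spacing,
    dim_samples = dim(raw$samples), dim_inavs = dim(raw$inavs),
    dim_coils = dim(raw$coils),
    noise_sd = raw$noise_sd, seed = raw$seed, inav_lines = raw$inav_lines,
    golden_angle = attr(raw$schedule, "golden_angle")
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(raw$schedule),
                   file.path(path, "schedule.csv"), row.names = FALSE)
  utils::write.csv(raw$trace_truth, file.path(path, "trace.csv"),
                   row.names = FALSE)
  write_complex_bin(raw$samples, file.path(path, "samples.bin"))
  write_complex_bin(raw$inavs, file.path(path, "inavs.bin"))
  write_complex_bin(raw$coils, file.path(path, "coils.bin"))
  invisible(path)
}

#' Read a raw acquisition from a directory container
#'
#' @param path container directory written by [write_raw()] (or converted
#'   from external raw data following the documented layout)
#' @return a `raw_acquisition` object
#' @export
read_raw <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) {
    stop("raw container schema error: missing dataset manifest.json",
         call. = FALSE)
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(manifest$container_version) ||
      manifest$container_version != 1L) {
    stop("unsupported raw container version", call. = FALSE)
  }
  sf <- file.path(path, "schedule.csv")
  if (!file.exists(sf)) {
    stop("raw container schema error: missing dataset schedule.csv",
         call. = FALSE)
  }
  schedule <- utils::read.csv(sf, stringsAsFactors = FALSE)
  attr(schedule, "grid") <- c(Nky = manifest$grid[2], Nkz = manifest$grid[3])
  attr(schedule, "golden_angle") <- manifest$golden_angle
  class(schedule) <- c("sampling_schedule", "data.frame")
  tf <- file.path(path, "trace.csv")
  trace <- if (file.exists(tf)) {
    tr <- utils::read.csv(tf)
    class(tr) <- c("resp_trace", "data.frame")
    tr
  } else NULL
  structure(
    list(
      samples = read_complex_bin(file.path(path, "samples.bin"),
                                 manifest$dim_samples, "samples.bin"),
      inavs = read_complex_bin(file.path(path, "inavs.bin"),
                               manifest$dim_inavs, "inavs.bin"),
      schedule = schedule, trace_truth = trace,
      coils = read_complex_bin(file.path(path, "coils.bin"),
                               manifest$dim_coils, "coils.bin"),
      spacing = manifest$spacing, grid = manifest$grid,
      noise_sd = manifest$noise_sd, seed = manifest$seed,
      inav_lines = manifest$inav_lines
    ),
    class = "raw_acquisition"
  )
}

#' Write a volume as NIfTI
#'
#' Requires the suggested RNifti package; magnitude and phase are written
#' for complex input.
#' @param vol 3D array
#' @param path output path (`.nii.gz`)
#' @param spacing voxel size (mm)
#' @return written path(s), invisibly; `NULL` with a message if RNifti is
#'   unavailable
#' @export
write_volume_nifti <- function(vol, path, spacing) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    message("RNifti not available; skipping NIfTI export")
    return(invisible(NULL))
  }
  wr <- function(v, p) {
    img <- RNifti::asNifti(v, reference = NULL)
    RNifti::pixdim(img) <- rep(spacing, 3)
    RNifti::writeNifti(img, p)
    p
  }
  if (is.complex(vol)) {
    base <- sub("\\.nii(\\.gz)?$", "", path)
    out <- c(wr(Mod(vol), paste0(base, "_mag.nii.gz")),
             wr(Arg(vol), paste0(base, "_phase.nii.gz")))
    invisible(out)
  } else {
    invisible(wr(vol, path))
  }
}

#' Write the phantom landmark set as JSON (mm coordinates)
#' @param phantom a [make_phantom()] result
#' @param path output JSON path
#' @export
write_landmarks_json <- function(phantom, path) {
  ls <- phantom$landmark_set
  out <- list(
    spacing = phantom$spacing,
    centerlines = lapply(ls$centerlines, function(cl) {
      list(name = cl$name, class = cl$class, radius = cl$radius,
           points_mm = cl$points)
    }),
    atria = lapply(ls$atria, function(a) {
      list(side = a$side, thickness_mm = a$thickness,
           points_mm = a$points, normals = a$normals)
    })
  )
  jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}
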