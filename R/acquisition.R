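# ECG-segmented golden-angle spiral-profile-order Cartesian sampling of the
# moving phantom: sampling schedule, respiratory trace, synthetic coil
# sensitivities, multi-coil k-space synthesis and per-beat iNAVs.
#
# The readout axis (SI) is fully encoded; phase encoding runs over the
# (RL, AP) = (ky, kz) plane. One schedule entry is one full readout line.

#' Golden-angle spiral-profile-order Cartesian sampling schedule
#'
#' Each spiral interleaf is an Archimedean arm in the (ky, kz) phase-encode
#' plane, rotated by the golden angle between consecutive interleaves and
#' snapped to the nearest integer grid positions (duplicates within an arm
#' are replaced by the nearest unsampled grid point, deterministic
#' distance-then-row-major tie-break). The centre line (0,0) opens every
#' beat (centric ordering). Odd and even heartbeats of an interleaved pair
#' share the same arm, so the two contrast volumes are sampled on identical
#' (ky, kz) positions and are geometrically co-registered by construction;
#' the interleaf rotation of arm `i` (0-based pair index) is
#' `i * golden_angle` degrees.
#'
#' @param Nky,Nkz phase-encode grid size (RL, AP), >= 8
#' @param lines_per_beat lines acquired per heartbeat
#' @param n_beats total number of heartbeats (both parities)
#' @param golden_angle interleaf rotation increment (degrees)
#' @param n_turns spiral turns per arm
#' @return data.frame of class `sampling_schedule` with columns `beat`,
#'   `parity`, `line`, `ky`, `kz` (integer grid frequencies)
#' @export
build_schedule <- function(Nky, Nkz, lines_per_beat, n_beats,
                           golden_angle = 137.508, n_turns = 1) {
  stopifnot(Nky >= 8, Nkz >= 8, lines_per_beat >= 1, n_beats >= 1)
  if (lines_per_beat > Nky * Nkz) {
    stop("lines_per_beat exceeds the number of phase-encode grid points",
         call. = FALSE)
  }
  ky_lo <- -floor(Nky / 2); ky_hi <- ceiling(Nky / 2) - 1
  kz_lo <- -floor(Nkz / 2); kz_hi <- ceiling(Nkz / 2) - 1

  # candidate substitution offsets, sorted by distance then row-major
  R <- 8L
  off <- expand.grid(dky = -R:R, dkz = -R:R)
  off <- off[order(off$dky^2 + off$dkz^2, off$dkz, off$dky), ]

  L <- lines_per_beat
  frac <- if (L > 1) (seq_len(L) - 1) / (L - 1) else 0
  arms <- unique(floor((seq_len(n_beats) - 1) / 2))
  arm_lines <- lapply(arms, function(a) {
    th <- a * golden_angle * pi / 180
    phi <- th + n_turns * 2 * pi * frac
    ky <- round(frac * (Nky / 2 - 0.5) * cos(phi))
    kz <- round(frac * (Nkz / 2 - 0.5) * sin(phi))
    ky <- pmin(pmax(ky, ky_lo), ky_hi)
    kz <- pmin(pmax(kz, kz_lo), kz_hi)
    ky[1] <- 0; kz[1] <- 0
    taken <- matrix(FALSE, Nky, Nkz)
    for (j in seq_len(L)) {
      iy <- ky[j] - ky_lo + 1; iz <- kz[j] - kz_lo + 1
      if (!taken[iy, iz]) { taken[iy, iz] <- TRUE; next }
      found <- FALSE
      for (o in seq_len(nrow(off))) {
        ny <- ky[j] + off$dky[o]; nz <- kz[j] + off$dkz[o]
        if (ny < ky_lo || ny > ky_hi || nz < kz_lo || nz > kz_hi) next
        if (!taken[ny - ky_lo + 1, nz - kz_lo + 1]) {
          ky[j] <- ny; kz[j] <- nz
          taken[ny - ky_lo + 1, nz - kz_lo + 1] <- TRUE
          found <- TRUE
          break
        }
      }
      if (!found) { # dense arm: fall back to first free grid point
        free <- which(!taken, arr.ind = TRUE)[1, ]
        ky[j] <- free[1] + ky_lo - 1; kz[j] <- free[2] + kz_lo - 1
        taken[free[1], free[2]] <- TRUE
      }
    }
    cbind(ky, kz)
  })
  names(arm_lines) <- as.character(arms)

  out <- do.call(rbind, lapply(seq_len(n_beats), function(b) {
    kk <- arm_lines[[as.character((b - 1) %/% 2)]]
    data.frame(beat = b, parity = if (b %% 2 == 1) "odd" else "even",
               line = seq_len(L), ky = kk[, 1], kz = kk[, 2])
  }))
  attr(out, "grid") <- c(Nky = Nky, Nkz = Nkz)
  attr(out, "golden_angle") <- golden_angle
  class(out) <- c("sampling_schedule", "data.frame")
  out
}

#' Simulate a per-beat respiratory trace
#'
#' Asymmetric breathing waveform (end-expiratory plateau at 0 mm,
#' inspiratory peaks at `si_amplitude`) sampled at the beat times, with
#' optional slow drift and Gaussian beat-to-beat jitter. The RL trace is a
#' fixed fraction of the SI trace.
#'
#' @param model a [motion_model()]
#' @param n_beats number of heartbeats
#' @param rr_ms R-R interval (ms)
#' @param seed RNG seed (trace is reproducible for a fixed seed)
#' @return data.frame of class `resp_trace`: columns `beat`, `time_ms`,
#'   `si`, `rl` (mm)
#' @export
simulate_trace <- function(model, n_beats, rr_ms = 1000, seed = 1) {
  stopifnot(n_beats >= 1)
  t_ms <- (seq_len(n_beats) - 1) * rr_ms
  si <- model$si_amplitude * cos(pi * t_ms / model$period)^4 +
        model$drift * t_ms / 60000
  noise <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    stats::rnorm(n_beats, 0, model$noise_sd)
  })
  si <- si + noise
  out <- data.frame(beat = seq_len(n_beats), time_ms = t_ms, si = si,
                    rl = model$rl_coupling * si)
  class(out) <- c("resp_trace", "data.frame")
  out
}

#' Synthetic birdcage-like coil sensitivity maps
#'
#' Smooth complex sensitivities centred on points around the body, with a
#' gentle linear phase per coil, normalized to unit sum-of-squares magnitude
#' at every voxel (so no voxel has zero total sensitivity).
#'
#' @param grid length-3 grid size
#' @param spacing voxel size mm
#' @param n_coils number of coils
#' @return complex array `c(grid, n_coils)`
#' @export
make_coil_maps <- function(grid, spacing, n_coils = 8) {
  L <- grid * spacing
  co <- coord_arrays(grid, spacing)
  ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils
  maps <- array(0i, c(grid, n_coils))
  sigma <- 0.55 * min(L)
  for (cidx in seq_len(n_coils)) {
    c0 <- c(0.5 * L[1] + 0.15 * L[1] * cos(3 * ang[cidx]),
            0.5 * L[2] + 0.55 * L[2] * cos(ang[cidx]),
            0.5 * L[3] + 0.55 * L[3] * sin(ang[cidx]))
    mag <- exp(-((co$x - c0[1])^2 + (co$y - c0[2])^2 + (co$z - c0[3])^2) /
                 (2 * sigma^2))
    ph <- 0.8 * ang[cidx] +
      0.3 * pi * (cos(ang[cidx]) * co$y / L[2] + sin(ang[cidx]) * co$z / L[3])
    maps[, , , cidx] <- mag * exp(1i * ph)
  }
  sos <- sqrt(apply(Mod(maps)^2, 1:3, sum))
  for (cidx in seq_len(n_coils)) {
    maps[, , , cidx] <- maps[, , , cidx] / sos
  }
  maps
}

# direct trilinear gather (no operator matrix); coords in voxel units
trilinear_sample <- function(vol, coords) {
  d <- dim(vol)
  cx <- pmin(pmax(coords[, 1], 1), d[1])
  cy <- pmin(pmax(coords[, 2], 1), d[2])
  cz <- pmin(pmax(coords[, 3], 1), d[3])
  x0 <- pmin(floor(cx), d[1] - 1L); fx <- cx - x0
  y0 <- pmin(floor(cy), d[2] - 1L); fy <- cy - y0
  z0 <- pmin(floor(cz), d[3] - 1L); fz <- cz - z0
  out <- if (is.complex(vol)) complex(length(fx)) else numeric(length(fx))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    idx <- (x0 + dx) + d[1] * (y0 + dy - 1) + d[1] * d[2] * (z0 + dz - 1)
    out <- out + w * vol[idx]
  }
  out
}

# trilinear gather with periodic (wrapped) boundaries: the sampled field of
# view is periodic by construction of the DFT, so the acquisition warp wraps
trilinear_sample_wrap <- function(vol, coords) {
  d <- dim(vol)
  out <- if (is.complex(vol)) complex(nrow(coords)) else numeric(nrow(coords))
  x0 <- floor(coords[, 1]); fx <- coords[, 1] - x0
  y0 <- floor(coords[, 2]); fy <- coords[, 2] - y0
  z0 <- floor(coords[, 3]); fz <- coords[, 3] - z0
  wrap <- function(i, n) ((i - 1) %% n) + 1
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    idx <- wrap(x0 + dx, d[1]) + d[1] * (wrap(y0 + dy, d[2]) - 1) +
           d[1] * d[2] * (wrap(z0 + dz, d[3]) - 1)
    out <- out + w * vol[idx]
  }
  out
}

# warp a volume to respiratory position si: anatomy displaced by +u means
# the observed image samples the rest volume at p - u(p)
warp_to_position <- function(vol, model, si, spacing, basis) {
  if (si == 0) return(vol)
  grid <- dim(vol)
  u <- displacement_at(model, si, grid, spacing, basis = basis)
  g <- voxel_grid(grid)
  g[, 1] <- g[, 1] - as.vector(u[, , , 1]) / spacing
  g[, 2] <- g[, 2] - as.vector(u[, , , 2]) / spacing
  g[, 3] <- g[, 3] - as.vector(u[, , , 3]) / spacing
  array(trilinear_sample_wrap(vol, g), grid)
}

# 2D coronal iNAV: AP projection of the warped contrast-weighted volume,
# low-pass filtered along RL to n_lines phase-encode lines
project_inav <- function(vol, n_lines) {
  img2 <- apply(vol, c(1, 2), sum)
  k2 <- stats::fft(img2)
  keep <- abs(kfreq(ncol(img2))) <= (n_lines / 2)
  k2[, !keep] <- 0
  stats::fft(k2, inverse = TRUE) / length(img2)
}

#' Synthesize multi-coil raw k-space and per-beat iNAVs
#'
#' For each heartbeat the contrast-weighted phantom (per the beat's parity)
#' is warped to the beat's respiratory position, multiplied by each coil
#' sensitivity, Fourier transformed, and the scheduled phase-encode lines
#' are recorded with additive complex Gaussian noise. The per-beat iNAV is
#' the coronal (SI, RL) projection of the same warped, contrast-weighted
#' object, low-pass filtered along RL to the ramp-up resolution and stored
#' before any interpolation.
#'
#' @param phantom a [make_phantom()] result
#' @param model a [motion_model()]
#' @param schedule a [build_schedule()] result (grid must match the phantom
#'   RL/AP dimensions)
#' @param trace a [simulate_trace()] result (one row per scheduled beat)
#' @param coils complex coil array from [make_coil_maps()]
#' @param signals per-tissue signals from [tissue_signals()]
#' @param noise_sd complex-noise standard deviation per real/imaginary
#'   channel, in units of the (unitary-FFT) k-space signal
#' @param seed RNG seed for the noise
#' @param inav_lines RL phase-encode lines retained in the iNAV
#' @return object of class `raw_acquisition`: `samples` (complex array
#'   `c(Nx, n_entries, n_coils)`), `inavs` (complex array
#'   `c(Nx, Ny, n_beats)`), `schedule`, `trace_truth`, `coils`, `spacing`,
#'   `noise_sd`, `seed`
#' @export
synthesize_raw <- function(phantom, model, schedule, trace, coils, signals,
                           noise_sd = 0, seed = 1, inav_lines = 14) {
  grid <- phantom$dim
  gk <- attr(schedule, "grid")
  if (gk[["Nky"]] != grid[2] || gk[["Nkz"]] != grid[3]) {
    stop("schedule phase-encode grid does not match the phantom grid",
         call. = FALSE)
  }
  n_beats <- max(schedule$beat)
  stopifnot(nrow(trace) >= n_beats)
  n_coils <- dim(coils)[4]
  vols <- list(
    odd = phantom_signal_volume(phantom, signals, "odd") + 0i,
    even = phantom_signal_volume(phantom, signals, "even") + 0i
  )
  basis <- if (model$nonrigid_gain > 0) {
    nonrigid_basis(grid, phantom$spacing)
  } else NULL

  entries_by_beat <- split(seq_len(nrow(schedule)), schedule$beat)
  samples <- array(0i, c(grid[1], nrow(schedule), n_coils))
  inavs <- array(0i, c(grid[1], grid[2], n_beats))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  for (b in seq_len(n_beats)) {
    par <- if (b %% 2 == 1) "odd" else "even"
    wv <- warp_to_position(vols[[par]], model, trace$si[b], phantom$spacing,
                           basis)
    rows <- entries_by_beat[[as.character(b)]]
    iy <- ((schedule$ky[rows] %% grid[2])) + 1
    iz <- ((schedule$kz[rows] %% grid[3])) + 1
    lin <- iy + (iz - 1) * grid[2]   # linear index into the (ky, kz) plane
    for (cidx in seq_len(n_coils)) {
      ks <- ft(wv * coils[, , , cidx])
      dim(ks) <- c(grid[1], grid[2] * grid[3])
      samples[, rows, cidx] <- ks[, lin]
    }
    inavs[, , b] <- project_inav(wv, inav_lines)
  }
  if (noise_sd > 0) {
    n <- length(samples)
    samples <- samples +
      complex(real = stats::rnorm(n, 0, noise_sd),
              imaginary = stats::rnorm(n, 0, noise_sd))
  }
  structure(
    list(samples = samples, inavs = inavs, schedule = schedule,
         trace_truth = trace[seq_len(n_beats), ], coils = coils,
         spacing = phantom$spacing, grid = grid, noise_sd = noise_sd,
         seed = seed, inav_lines = inav_lines),
    class = "raw_acquisition"
  )
}
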