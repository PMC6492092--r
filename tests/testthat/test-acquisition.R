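test_that("sampling schedule is centric, paired and golden-angle rotated", {
  s <- build_schedule(32, 32, 32, 64)
  # centre line opens every beat
  first <- s[s$line == 1, ]
  expect_true(all(first$ky == 0 & first$kz == 0))
  # lines_per_beat = 1 samples only the centre line
  s1 <- build_schedule(16, 16, 1, 6)
  expect_true(all(s1$ky == 0 & s1$kz == 0))
  # odd/even beats of a pair share identical (ky, kz) positions
  for (b in c(1, 11, 31)) {
    a <- s[s$beat == b, c("ky", "kz")]
    bb <- s[s$beat == b + 1, c("ky", "kz")]
    expect_true(all(a$ky == bb$ky) && all(a$kz == bb$kz))
  }
  # parity alternates with beat index
  expect_true(all(s$parity[s$beat %% 2 == 1] == "odd"))
  expect_true(all(s$parity[s$beat %% 2 == 0] == "even"))
  # no duplicates within a beat; all points inside the grid
  for (b in unique(s$beat)) {
    kk <- s[s$beat == b, ]
    expect_false(any(duplicated(kk[, c("ky", "kz")])))
  }
  expect_true(all(s$ky >= -16 & s$ky <= 15 & s$kz >= -16 & s$kz <= 15))
  # coverage: >= half the grid visited at least once
  cover <- nrow(unique(s[, c("ky", "kz")])) / (32 * 32)
  expect_gte(cover, 0.5)
  expect_error(build_schedule(8, 8, 100, 4), "exceeds")
})

test_that("respiratory trace is reproducible with the stated envelope", {
  m <- motion_model(si_amplitude = 8, noise_sd = 0.5, drift = 0)
  tr1 <- simulate_trace(m, 400, 1000, seed = 5)
  tr2 <- simulate_trace(m, 400, 1000, seed = 5)
  expect_identical(tr1, tr2)
  ptp <- diff(range(tr1$si))
  expect_gte(ptp, 8)
  expect_lte(ptp, 8 + 6 * 0.5)
  expect_equal(tr1$rl, m$rl_coupling * tr1$si)
  m0 <- motion_model(si_amplitude = 0, noise_sd = 0, drift = 0)
  expect_true(all(simulate_trace(m0, 20, 1000, 1)$si == 0))
})

test_that("coil maps are normalized and nowhere zero", {
  grid <- c(24, 24, 12)
  cm <- make_coil_maps(grid, 2.8, 6)
  sos <- apply(Mod(cm)^2, 1:3, sum)
  expect_true(all(abs(sos - 1) < 1e-6))
  expect_true(all(apply(Mod(cm), 1:3, max) > 0))
})

test_that("noiseless full sampling inverts to the weighted phantom", {
  ph <- small_phantom()
  grid <- ph$dim
  sch <- full_schedule(grid)
  m0 <- motion_model(si_amplitude = 0, noise_sd = 0, drift = 0,
                     nonrigid_gain = 0)
  raw <- synthesize_raw(ph, m0, sch, static_trace(), uniform_coil(grid),
                        default_signals(), noise_sd = 0, seed = 1)
  kk <- array(0i, grid)
  lin <- wholeheart:::schedule_lin_index(sch$ky, sch$kz, grid)
  dim(kk) <- c(grid[1], grid[2] * grid[3])
  kk[, lin] <- raw$samples[, , 1]
  dim(kk) <- grid
  rec <- wholeheart:::ift(kk)
  truth <- phantom_signal_volume(ph, default_signals(), "odd")
  expect_lt(max(Mod(rec - truth)) / max(abs(truth)), 1e-6)
  # Parseval: energy identical between image and assembled k-space
  expect_equal(sum(Mod(kk)^2), sum(Mod(truth)^2), tolerance = 1e-6)
})

test_that("a purely translated beat obeys the Fourier shift theorem", {
  ph <- small_phantom()
  grid <- ph$dim
  sch <- full_schedule(grid)
  coil <- uniform_coil(grid)
  m0 <- motion_model(si_amplitude = 0, noise_sd = 0, nonrigid_gain = 0)
  raw0 <- synthesize_raw(ph, m0, sch, static_trace(), coil,
                         default_signals(), noise_sd = 0, seed = 1)
  # integer-voxel translation: si = 2 voxels, rl = 1 voxel (coupling 0.5)
  mt <- motion_model(si_amplitude = 10, rl_coupling = 0.5,
                     nonrigid_gain = 0, noise_sd = 0)
  d <- c(2 * ph$spacing, 1 * ph$spacing)
  rawd <- synthesize_raw(ph, mt, sch, static_trace(si = d[1], rl = d[2]),
                         coil, default_signals(), noise_sd = 0, seed = 1)
  k_si <- kcycles(wholeheart:::kfreq(grid[1]), grid[1], ph$spacing)
  k_rl <- kcycles(sch$ky, grid[2], ph$spacing)
  pred <- kspace_translate(raw0$samples[, , 1], k_si, k_rl, d)
  expect_lt(max(Mod(rawd$samples[, , 1] - pred)) / max(Mod(pred)), 1e-8)
})

test_that("added complex noise has the configured standard deviation", {
  ph <- small_phantom()
  grid <- ph$dim
  sch <- full_schedule(grid)
  m0 <- motion_model(si_amplitude = 0, noise_sd = 0, nonrigid_gain = 0)
  clean <- synthesize_raw(ph, m0, sch, static_trace(), uniform_coil(grid),
                          default_signals(), noise_sd = 0, seed = 9)
  noisy <- synthesize_raw(ph, m0, sch, static_trace(), uniform_coil(grid),
                          default_signals(), noise_sd = 0.02, seed = 9)
  dvec <- as.vector(noisy$samples - clean$samples)
  expect_gt(length(dvec), 1e4)
  # complex sd = sqrt(2) * per-channel sd
  expect_equal(stats::sd(Mod(dvec)) * 0 + sqrt(mean(Mod(dvec)^2)),
               sqrt(2) * 0.02, tolerance = 0.05 * sqrt(2) * 0.02)
  # determinism of the noise for a fixed seed
  noisy2 <- synthesize_raw(ph, m0, sch, static_trace(), uniform_coil(grid),
                           default_signals(), noise_sd = 0.02, seed = 9)
  expect_identical(noisy$samples, noisy2$samples)
})

test_that("iNAVs are coronal projections at ramp-up RL resolution", {
  ph <- small_phantom()
  grid <- ph$dim
  sch <- full_schedule(grid)
  m0 <- motion_model(si_amplitude = 0, noise_sd = 0, nonrigid_gain = 0)
  raw <- synthesize_raw(ph, m0, sch, static_trace(), uniform_coil(grid),
                        default_signals(), noise_sd = 0, seed = 1,
                        inav_lines = 14)
  expect_equal(dim(raw$inavs), c(grid[1], grid[2], 1))
  # RL spectrum truncated beyond 14 central lines
  k2 <- stats::fft(raw$inavs[, , 1])
  hi <- abs(wholeheart:::kfreq(grid[2])) > 7
  expect_lt(max(Mod(k2[, hi])), 1e-8 * max(Mod(k2)))
})
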