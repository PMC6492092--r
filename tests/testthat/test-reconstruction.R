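test_that("k-space translation is a unitary phase ramp", {
  set.seed(13)
  grid <- c(16, 16, 8)
  img <- smooth_test_image(grid)
  k <- wholeheart:::ft(img)
  dim(k) <- c(16, 16 * 8)
  k_si <- kcycles(wholeheart:::kfreq(16), 16, 1.4)
  k_rl <- rep(kcycles(wholeheart:::kfreq(16), 16, 1.4), 8)
  # identity
  expect_identical(kspace_translate(k, k_si, k_rl, c(0, 0)), k)
  # round trip
  kt <- kspace_translate(k, k_si, k_rl, c(3.1, -2.2))
  back <- kspace_translate(kt, k_si, k_rl, c(-3.1, 2.2))
  expect_lt(max(Mod(back - k)) / max(Mod(k)), 1e-12)
  # integer-voxel shift equals a circular shift of the image
  kt2 <- kspace_translate(k, k_si, k_rl, c(2 * 1.4, 0))
  dim(kt2) <- grid
  shifted <- Re(wholeheart:::ift(kt2))
  expect_lt(max(abs(shifted - img[c(15, 16, 1:14), , ])) / max(abs(img)),
            1e-9)
})

test_that("soft-gating weights follow the exponential decay law", {
  expect_equal(soft_weights(5, 5, 1.75), 1)
  expect_equal(soft_weights(5 + 1.75, 5, 1.75), exp(-1))
  si <- seq(0, 10, by = 0.5)
  w <- soft_weights(si, 4, 1.75)
  expect_true(all(diff(w[si >= 4]) < 0))
  expect_true(all(w > 0 & w <= 1))
  expect_error(soft_weights(1, 0, 0), "soft_sigma")
})

test_that("It-SENSE equals the inverse FFT for full single-coil sampling", {
  grid <- c(16, 16, 8)
  obj <- smooth_test_image(grid, seed = 17)
  kk <- wholeheart:::ft(obj)
  dim(kk) <- c(grid[1], grid[2] * grid[3])
  full <- expand.grid(ky = wholeheart:::kfreq(16),
                      kz = wholeheart:::kfreq(8))
  lin <- wholeheart:::schedule_lin_index(full$ky, full$kz, grid)
  y <- array(kk[, lin], c(grid[1], nrow(full), 1))
  res <- itsense(y, full$ky, full$kz, rep(1, nrow(full)),
                 uniform_coil(grid))
  expect_lt(nrmse(res$image, obj), 1e-6)
  expect_true(all(diff(res$objective) <= 1e-9))
  # zero data -> zero image
  res0 <- itsense(y * 0, full$ky, full$kz, rep(1, nrow(full)),
                  uniform_coil(grid))
  expect_true(all(res0$image == 0))
  expect_error(itsense(y, full$ky, full$kz, rep(0, nrow(full)),
                       uniform_coil(grid)), "weights")
})

test_that("It-SENSE matches a direct least-squares oracle on a crop", {
  # 16 x 16 x 8 crop, 4 coils, 2x undersampling along RL
  grid <- c(16, 16, 8)
  coils <- make_coil_maps(grid, 2.8, 4)
  obj <- smooth_test_image(grid, seed = 23) + 0i
  kys <- wholeheart:::kfreq(16)[seq(1, 16, by = 2)]
  full <- expand.grid(ky = kys, kz = wholeheart:::kfreq(8))
  lin <- wholeheart:::schedule_lin_index(full$ky, full$kz, grid)
  nvox <- prod(grid)
  # forward model per coil: sample ft(S_c x) at lin
  fwd <- function(x) {
    out <- vector("list", 4)
    for (cc in 1:4) {
      k <- wholeheart:::ft(coils[, , , cc] * x)
      dim(k) <- c(grid[1], grid[2] * grid[3])
      out[[cc]] <- k[, lin]
    }
    out
  }
  y <- fwd(obj)
  ysamp <- array(0i, c(grid[1], nrow(full), 4))
  for (cc in 1:4) ysamp[, , cc] <- y[[cc]]
  res <- itsense(ysamp, full$ky, full$kz, rep(1, nrow(full)), coils,
                 recon_config(n_iter_itsense = 5))

  # independent oracle: explicit normal-equation solve (A^H A) x = A^H y
  # built column-by-column from unit vectors, then a dense solve
  adj <- function(ylist) {
    acc <- array(0i, grid)
    for (cc in 1:4) {
      km <- matrix(0i, grid[1], grid[2] * grid[3])
      km[, lin] <- ylist[[cc]]
      dim(km) <- grid
      acc <- acc + Conj(coils[, , , cc]) * wholeheart:::ift(km)
    }
    acc
  }
  N <- matrix(0i, nvox, nvox)
  for (j in seq_len(nvox)) {
    e <- array(0i, grid); e[j] <- 1
    N[, j] <- as.vector(adj(fwd(e)))
  }
  rhs <- as.vector(adj(y))
  x_direct <- array(solve(N, rhs), grid)
  expect_lt(nrmse(x_direct, obj), 1e-8)          # oracle solves the model
  expect_lt(nrmse(res$image, x_direct), 0.05)    # CG agrees with the oracle
})

test_that("It-SENSE reconstructs a 2x-undersampled 8-coil phantom", {
  ph <- suppressWarnings(make_phantom(
    phantom_config(grid = c(64, 64, 16), spacing = 2.8), tissue_lib()))
  grid <- ph$dim
  coils <- make_coil_maps(grid, 2.8, 8)
  obj <- phantom_signal_volume(ph, default_signals(), "even") + 0i
  kys <- wholeheart:::kfreq(64)[seq(1, 64, by = 2)]
  full <- expand.grid(ky = kys, kz = wholeheart:::kfreq(16))
  lin <- wholeheart:::schedule_lin_index(full$ky, full$kz, grid)
  ysamp <- array(0i, c(grid[1], nrow(full), 8))
  for (cc in 1:8) {
    k <- wholeheart:::ft(coils[, , , cc] * obj)
    dim(k) <- c(grid[1], grid[2] * grid[3])
    ysamp[, , cc] <- k[, lin]
  }
  res <- itsense(ysamp, full$ky, full$kz, rep(1, nrow(full)), coils,
                 recon_config(n_iter_itsense = 5))
  body <- ph$labels > 0
  expect_lt(nrmse(res$image, obj, body), 0.05)
})

test_that("the GMD encoding operator passes the adjoint dot-product test", {
  set.seed(29)
  grid <- c(16, 16, 8)
  sp <- 2.8
  coils <- make_coil_maps(grid, sp, 3)
  full <- expand.grid(ky = wholeheart:::kfreq(16),
                      kz = wholeheart:::kfreq(8))
  sub <- full[seq(1, nrow(full), by = 3), ]
  lin <- wholeheart:::schedule_lin_index(sub$ky, sub$kz, grid)
  w <- runif(nrow(sub), 0.2, 1)
  field <- array(stats::rnorm(prod(grid) * 3, 0, 1.5), c(grid, 3))
  M <- wholeheart:::warp_matrix(field, sp)
  E <- function(x) {
    xb <- array(wholeheart:::apply_complex(M, as.vector(x)), grid)
    out <- array(0i, c(grid[1], nrow(sub), 3))
    for (cc in 1:3) {
      k <- wholeheart:::ft(coils[, , , cc] * xb)
      dim(k) <- c(grid[1], grid[2] * grid[3])
      out[, , cc] <- sweep(k[, lin], 2, w, `*`)
    }
    out
  }
  EH <- function(y) {
    acc <- array(0i, grid)
    for (cc in 1:3) {
      km <- matrix(0i, grid[1], grid[2] * grid[3])
      km[, lin] <- sweep(y[, , cc], 2, w, `*`)
      dim(km) <- grid
      acc <- acc + Conj(coils[, , , cc]) * wholeheart:::ift(km)
    }
    array(wholeheart:::apply_complex(Matrix::t(M), as.vector(acc)), grid)
  }
  x <- array(complex(real = rnorm(prod(grid)), imaginary = rnorm(prod(grid))),
             grid)
  y <- array(complex(real = rnorm(16 * nrow(sub) * 3),
                     imaginary = rnorm(16 * nrow(sub) * 3)),
             c(grid[1], nrow(sub), 3))
  lhs <- sum(Conj(E(x)) * y)
  rhs <- sum(Conj(x) * EH(y))
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-8)
})

test_that("single-bin GMD with identity field equals It-SENSE bit-for-bit", {
  grid <- c(16, 16, 8)
  coils <- make_coil_maps(grid, 2.8, 4)
  obj <- smooth_test_image(grid, seed = 37) + 0i
  full <- expand.grid(ky = wholeheart:::kfreq(16),
                      kz = wholeheart:::kfreq(8))
  sub <- full[seq(1, nrow(full), by = 2), ]
  lin <- wholeheart:::schedule_lin_index(sub$ky, sub$kz, grid)
  ysamp <- array(0i, c(grid[1], nrow(sub), 4))
  for (cc in 1:4) {
    k <- wholeheart:::ft(coils[, , , cc] * obj)
    dim(k) <- c(grid[1], grid[2] * grid[3])
    ysamp[, , cc] <- k[, lin]
  }
  w <- soft_weights(seq(0, 2, length.out = nrow(sub)), 1)
  a <- itsense(ysamp, sub$ky, sub$kz, w, coils)
  b <- gmd_reconstruct(list(list(samples = ysamp, ky = sub$ky, kz = sub$kz,
                                 weights = w)),
                       list(NULL), coils, 2.8)
  expect_identical(a$image, b$image)
  expect_error(gmd_reconstruct(list(list(samples = ysamp, ky = sub$ky,
                                         kz = sub$kz, weights = w)),
                               list(), coils, 2.8), "field")
})
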