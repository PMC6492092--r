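# shared synthetic iNAV: a smooth blob image with reproducible texture
make_inav <- function(n = 48, seed = 21) {
  set.seed(seed)
  img <- matrix(0, n, n)
  img[16:32, 18:34] <- 1
  img <- img + matrix(stats::rnorm(n * n, 0, 0.05), n, n)
  k <- stats::fft(img)
  f <- exp(-2 * pi^2 * 1.2^2 * (wholeheart:::kfreq(n) / n)^2)
  Re(stats::fft(k * outer(f, f), inverse = TRUE)) / length(img)
}

shift_int <- function(im, dx, dy) {
  n <- nrow(im); m <- ncol(im)
  im[((seq_len(n) - 1 - dx) %% n) + 1, ((seq_len(m) - 1 - dy) %% m) + 1]
}

test_that("translation estimation recovers known shifts", {
  img <- make_inav()
  roi <- c(12, 36, 14, 38)
  # identical images: exact zero and perfect score
  e0 <- estimate_translation(img, img, roi, spacing = 1.4)
  expect_identical(c(e0$d_si, e0$d_rl), c(0, 0))
  expect_equal(e0$score, 1, tolerance = 1e-12)
  # integer-pixel shift (+2.8, -1.4) mm recovered
  e <- estimate_translation(shift_int(img, 2, -1), img, roi, spacing = 1.4)
  expect_equal(e$d_si, 2.8, tolerance = 0.05)
  expect_equal(e$d_rl, -1.4, tolerance = 0.05)
  expect_gt(e$score, 0.99)
  # sub-pixel 0.7 mm shift applied via Fourier phase, within 0.5 mm
  k <- stats::fft(img)
  ph <- exp(-2i * pi * wholeheart:::kfreq(48) * 0.5 / 48)
  sub <- Re(stats::fft(k * ph, inverse = TRUE) / length(k))
  es <- estimate_translation(sub, img, roi, spacing = 1.4)
  expect_lt(abs(es$d_si - 0.7), 0.5)
  # flat template errors out
  expect_error(estimate_translation(img, matrix(1, 48, 48), roi),
               "flat")
})

test_that("translation estimation is antisymmetric", {
  img <- make_inav()
  roi <- c(12, 36, 14, 38)
  mv <- shift_int(img, 3, 2)
  ab <- estimate_translation(mv, img, roi, spacing = 1.4)
  ba <- estimate_translation(img, mv, roi, spacing = 1.4)
  expect_lt(abs(ab$d_si + ba$d_si), 0.5)
  expect_lt(abs(ab$d_rl + ba$d_rl), 0.5)
})

test_that("mean +/- 2 SD outlier rejection matches the arithmetic oracle", {
  expect_true(all(reject_outliers(rep(3, 10))))
  # brute-force oracle: mean 8.33, sample sd 20.42, upper bound 49.2
  x <- c(0, 1, 0, -1, 0, 50)
  expect_identical(reject_outliers(x),
                   x >= mean(x) - 2 * sd(x) & x <= mean(x) + 2 * sd(x))
  expect_identical(which(!reject_outliers(x)), 6L)
  # Gaussian series: retained fraction near the normal-theory 95.4%
  set.seed(31)
  keep <- reject_outliers(stats::rnorm(100000))
  expect_equal(mean(keep), 0.954, tolerance = 0.01)
  expect_error(reject_outliers(c(1, 2)), "3")
})

test_that("equally populated bins respect the width cap when feasible", {
  # evenly spread SI over [0, 13] mm: 4 bins suffice (13/4 <= 3.5)
  si <- seq(0, 13, length.out = 200)
  b <- assign_bins(si)
  expect_equal(b$n_bins, 4)
  counts <- table(b$bin_label)
  expect_lte(max(counts) - min(counts), 1)
  widths <- vapply(1:4, function(k) diff(range(si[b$bin_label == k])),
                   numeric(1))
  expect_true(all(widths <= 3.5))
  expect_equal(b$reference_bin, which.min(b$bin_center))

  # [0, 35] mm cannot satisfy the cap with <= 6 bins
  si2 <- seq(0, 35, length.out = 120)
  expect_message(b2 <- assign_bins(si2), "cap")
  expect_equal(b2$n_bins, 6)
  expect_true(b2$cap_violated)

  # degenerate constant series still splits evenly
  b3 <- assign_bins(rep(2, 21))
  expect_equal(b3$n_bins, 4)
  expect_lte(max(table(b3$bin_label)) - min(table(b3$bin_label)), 1)

  expect_error(assign_bins(c(1, 2, 3)), "n_min")
})

test_that("bin centres are invariant to beat order", {
  set.seed(7)
  si <- stats::runif(97, 0, 12)
  b1 <- assign_bins(si)
  perm <- sample(length(si))
  b2 <- assign_bins(si[perm])
  expect_equal(sort(b1$bin_center), sort(b2$bin_center), tolerance = 1e-12)
})

test_that("the reference beat sits at the modal end-expiratory level", {
  si <- c(rep(0.2, 50) + stats::rnorm(50, 0, 0.05), seq(1, 8, length.out = 20))
  expect_lt(abs(si[select_reference_beat(si)]), 0.5)
})
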