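# Bin-to-bin non-rigid registration: cubic B-spline free-form deformation
# driven by normalized cross-correlation with bending-energy regularization,
# optimized coarse-to-fine over an image pyramid. The control lattice is
# defined in scanner millimetres over the full field of view, so the same
# coefficients parameterize every pyramid level.

# cubic B-spline weights for fractional position s in [0,1)
bspline3_w <- function(s) {
  cbind((1 - s)^3 / 6,
        (3 * s^3 - 6 * s^2 + 4) / 6,
        (-3 * s^3 + 3 * s^2 + 3 * s + 1) / 6,
        s^3 / 6)
}

# sparse (n_vox x n_ctrl) cubic B-spline evaluation matrix for one axis;
# control node j sits at position (j - 2) * h mm
bspline_axis_matrix <- function(n_vox, spacing, h, n_ctrl) {
  u <- (seq_len(n_vox) - 0.5) * spacing
  t <- u / h + 2
  i0 <- floor(t)
  w <- bspline3_w(t - i0)
  jj <- as.vector(outer(i0, -1:2, `+`))
  ii <- rep(seq_len(n_vox), 4)
  xx <- as.vector(w)
  ok <- jj >= 1 & jj <= n_ctrl
  Matrix::sparseMatrix(i = ii[ok], j = jj[ok], x = xx[ok],
                       dims = c(n_vox, n_ctrl))
}

# multiply a 3D array along one mode by a (new_n x old_n) sparse matrix
tmult <- function(arr, M, mode) {
  d <- dim(arr)
  perm <- switch(mode, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- as.matrix(M %*% matrix(a, da[1], da[2] * da[3]))
  out <- array(m, c(nrow(M), da[2], da[3]))
  aperm(out, order(perm))
}

# block-average downsampling by 2 along every axis (odd trailing slices
# are dropped)
downsample2 <- function(vol) {
  d <- dim(vol) %/% 2
  v <- vol[seq_len(2 * d[1]), seq_len(2 * d[2]), seq_len(2 * d[3])]
  i1 <- seq(1, 2 * d[1], by = 2); i2 <- seq(1, 2 * d[2], by = 2)
  i3 <- seq(1, 2 * d[3], by = 2)
  (v[i1, i2, i3] + v[i1 + 1, i2, i3] + v[i1, i2 + 1, i3] +
   v[i1, i2, i3 + 1] + v[i1 + 1, i2 + 1, i3] + v[i1 + 1, i2, i3 + 1] +
   v[i1, i2 + 1, i3 + 1] + v[i1 + 1, i2 + 1, i3 + 1]) / 8
}

# central-difference spatial gradient (per mm)
spatial_gradient <- function(vol, spacing) {
  d <- dim(vol)
  g <- array(0, c(d, 3))
  for (ax in 1:3) {
    n <- d[ax]
    ip <- c(2:n, n); im <- c(1, 1:(n - 1))
    vp <- switch(ax, vol[ip, , ], vol[, ip, ], vol[, , ip])
    vm <- switch(ax, vol[im, , ], vol[, im, ], vol[, , im])
    g[, , , ax] <- (vp - vm) / (2 * spacing)
  }
  g
}

# bending energy of the control lattice and its gradient (second
# differences along each lattice direction, summed over components)
bending_energy <- function(C) {
  d2 <- function(a, ax) {
    n <- dim(a)[ax]
    if (n < 3) return(array(0, dim(a)))
    ip <- c(2:n, n); im <- c(1, 1:(n - 1))
    switch(ax, a[ip, , ] + a[im, , ] - 2 * a,
               a[, ip, ] + a[, im, ] - 2 * a,
               a[, , ip] + a[, , im] - 2 * a)
  }
  e <- 0
  g <- array(0, dim(C))
  for (comp in 1:3) {
    for (ax in 1:3) {
      s <- d2(C[, , , comp], ax)
      e <- e + sum(s^2)
      g[, , , comp] <- g[, , , comp] + 2 * d2(s, ax)
    }
  }
  list(energy = e, grad = g)
}

#' Non-rigid registration of one respiratory bin to the reference bin
#'
#' Estimates a dense deformation field `d` such that
#' `moving(p + d(p)) ~ fixed(p)`: cubic B-spline free-form deformation,
#' normalized-cross-correlation similarity on magnitude images,
#' bending-energy regularization, multiresolution gradient ascent. The
#' optimizer starts at zero deformation, so identical inputs return a
#' (near-)zero field.
#'
#' @param moving,fixed 3D volumes (complex allowed; magnitudes are used)
#' @param spacing voxel size (mm)
#' @param config a [recon_config()] (fields `ffd_grid`, `ffd_levels`,
#'   `bending_weight`, `ffd_iter`)
#' @param init_translation optional length-3 mm translation initializing
#'   the deformation (e.g. the known offset between respiratory bin
#'   centres); the optimizer refines the non-rigid residual from there
#' @param presmooth Gaussian smoothing (voxels) applied to both magnitude
#'   images before matching; damps incoherent undersampling artefacts in
#'   bin images
#' @return object of class `deformation_field`: `field` (mm,
#'   `c(dim(fixed), 3)`), `jacobian_min`, `ncc` (final similarity)
#' @export
register_nonrigid <- function(moving, fixed, spacing,
                              config = recon_config(),
                              init_translation = c(0, 0, 0),
                              presmooth = 0) {
  mv <- Mod(moving); fx <- Mod(fixed)
  stopifnot(all(dim(mv) == dim(fx)))
  if (any(!is.finite(mv)) || any(!is.finite(fx))) {
    stop("non-finite voxels in registration input", call. = FALSE)
  }
  if (presmooth > 0) {
    mv <- gaussian_smooth(mv, presmooth)
    fx <- gaussian_smooth(fx, presmooth)
  }
  norm01 <- function(v) (v - mean(v)) / max(stats::sd(v), 1e-12)
  mv <- norm01(mv); fx <- norm01(fx)

  d0 <- dim(fx)
  L <- d0 * spacing
  h <- config$ffd_grid
  nc <- floor(L / h) + 4
  C <- array(0, c(nc, 3))                       # control coefficients (mm)
  for (a in 1:3) C[, , , a] <- init_translation[a]

  n_lev <- config$ffd_levels
  pyramid <- vector("list", n_lev)
  pyramid[[1]] <- list(mv = mv, fx = fx, spacing = spacing)
  for (l in seq_len(n_lev - 1)) {
    p <- pyramid[[l]]
    pyramid[[l + 1]] <- list(mv = downsample2(p$mv), fx = downsample2(p$fx),
                             spacing = p$spacing * 2)
  }

  ncc_final <- NA_real_
  for (lev in rev(seq_len(n_lev))) {
    p <- pyramid[[lev]]
    dl <- dim(p$fx)
    Tx <- bspline_axis_matrix(dl[1], p$spacing, h, nc[1])
    Ty <- bspline_axis_matrix(dl[2], p$spacing, h, nc[2])
    Tz <- bspline_axis_matrix(dl[3], p$spacing, h, nc[3])
    base <- voxel_grid(dl)
    f0 <- as.vector(p$fx)
    f0 <- f0 - mean(f0)
    nf <- sqrt(sum(f0^2))
    mgrad <- spatial_gradient(p$mv, p$spacing)

    dense_field <- function(C) {
      f <- array(0, c(dl, 3))
      for (a in 1:3) {
        f[, , , a] <- tmult(tmult(tmult(C[, , , a], Tx, 1), Ty, 2), Tz, 3)
      }
      f
    }
    eval_cost <- function(C) {
      fl <- dense_field(C)
      co <- base
      co[, 1] <- co[, 1] + as.vector(fl[, , , 1]) / p$spacing
      co[, 2] <- co[, 2] + as.vector(fl[, , , 2]) / p$spacing
      co[, 3] <- co[, 3] + as.vector(fl[, , , 3]) / p$spacing
      m <- trilinear_sample(p$mv, co)
      m0 <- m - mean(m)
      nm <- sqrt(sum(m0^2))
      ncc <- if (nm > 0) sum(f0 * m0) / (nf * nm) else 0
      be <- bending_energy(C)
      list(cost = ncc - config$bending_weight * be$energy, ncc = ncc,
           co = co, m0 = m0, nm = nm, be = be)
    }
    ctrl_grad <- function(ev) {
      if (ev$nm == 0) return(array(0, dim(C)))
      dncc_dm <- as.vector(f0) / (nf * ev$nm) -
        ev$ncc * ev$m0 / ev$nm^2
      g <- array(0, dim(C))
      for (a in 1:3) {
        gm <- array(trilinear_sample(mgrad[, , , a], ev$co), dl)
        gv <- array(dncc_dm, dl) * gm
        g[, , , a] <- tmult(tmult(tmult(gv, Matrix::t(Tx), 1),
                                  Matrix::t(Ty), 2), Matrix::t(Tz), 3)
      }
      g - config$bending_weight * ev$be$grad
    }

    step <- 0.5 * p$spacing
    ev <- eval_cost(C)
    for (it in seq_len(config$ffd_iter)) {
      g <- ctrl_grad(ev)
      gmax <- max(abs(g))
      if (gmax < 1e-12) break
      accepted <- FALSE
      for (try in 1:8) {
        Cn <- C + (step / gmax) * g
        evn <- eval_cost(Cn)
        if (evn$cost > ev$cost + 1e-12) {
          C <- Cn; ev <- evn; step <- step * 1.2; accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) break
    }
    ncc_final <- ev$ncc
  }

  Tx <- bspline_axis_matrix(d0[1], spacing, h, nc[1])
  Ty <- bspline_axis_matrix(d0[2], spacing, h, nc[2])
  Tz <- bspline_axis_matrix(d0[3], spacing, h, nc[3])
  field <- array(0, c(d0, 3))
  for (a in 1:3) {
    field[, , , a] <- tmult(tmult(tmult(C[, , , a], Tx, 1), Ty, 2), Tz, 3)
  }
  structure(
    list(field = field, jacobian_min = jacobian_min(field, spacing),
         ncc = ncc_final),
    class = "deformation_field"
  )
}
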