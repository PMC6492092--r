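# End-to-end pipeline: simulate -> track -> bin -> reconstruct (uncorrected,
# translational, non-rigid) -> PSIR -> metrics, with reproducible seeding
# and a run manifest.

#' Default pipeline configuration
#'
#' The shipped reference configuration simulates the study conditions at a
#' desk-scale grid; every block can be overridden. All sub-seeds are derived
#' from the single master seed.
#'
#' @param grid phantom/acquisition grid (SI, RL, AP)
#' @param spacing voxel size (mm)
#' @param n_beats total heartbeats (both parities)
#' @param lines_per_beat k-space lines per heartbeat
#' @param noise_sd complex-noise sd per channel (k-space units)
#' @param n_coils synthetic coils
#' @param seed master seed
#' @param odd_scheme,even_scheme preparation schemes of the two parities
#' @return nested configuration list of class `pipeline_config`
#' @export
default_config <- function(grid = c(64, 64, 32), spacing = 2.1,
                           n_beats = 400, lines_per_beat = 30,
                           noise_sd = 0.01, n_coils = 8, seed = 1,
                           odd_scheme = "MTC_IR", even_scheme = "MTC_FS") {
  structure(list(
    phantom = list(grid = grid, spacing = spacing, wall_thickness = 2.5,
                   myo_thickness = 6, fat_thickness = 5, pv_radius = 5,
                   cor_radius = 3.5),
    motion = list(si_amplitude = 8, rl_coupling = 0.3, nonrigid_gain = 0.35,
                  period = 3571, drift = 0, noise_sd = 0.3),
    sequence = list(odd_scheme = odd_scheme, even_scheme = even_scheme,
                    RR = 1000, lines_per_beat = lines_per_beat),
    schedule = list(n_beats = n_beats, golden_angle = 137.508),
    acquisition = list(noise_sd = noise_sd, n_coils = n_coils,
                       inav_lines = 14),
    binning = list(max_width = 3.5, n_min = 4, n_max = 6),
    recon = list(n_iter_itsense = 5, soft_sigma = 1.75, cg_tol = 1e-6,
                 ffd_grid = 16, ffd_metric = 5, ffd_levels = 3,
                 bending_weight = 1e-3, ffd_iter = 40),
    seed = seed
  ), class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a [default_config()]-style list
#' @param path YAML file path
#' @return the path / the configuration
#' @export
write_config <- function(config, path) {
  writeLines(yaml::as.yaml(unclass(config), precision = 15), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "pipeline_config")
}

# deterministic sub-seed derivation (kept below 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 127 + k * 9973) %% 2147483647)
}

# md5 of a serialized object (base tools only)
hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 3)
  close(con)
  unname(tools::md5sum(f))
}

# heart-covering iNAV ROI (whole heart along RL, base-to-mid along SI)
inav_roi <- function(phantom) {
  g <- phantom$geometry
  sp <- phantom$spacing
  si_lo <- g$lv_c[1] - g$lv_r - 4
  si_hi <- max(g$la_c[1] + g$la_r, g$lv_c[1] + g$lv_r) + 4
  rl_lo <- g$ra_c[2] - g$ra_r - 8
  rl_hi <- g$la_c[2] + g$la_r + 8
  px <- function(v, n) min(max(round(v / sp), 1), n)
  c(px(si_lo, phantom$dim[1]), px(si_hi, phantom$dim[1]),
    px(rl_lo, phantom$dim[2]), px(rl_hi, phantom$dim[2]))
}

# split schedule rows for one parity restricted to given beats
parity_rows <- function(schedule, parity, beats) {
  which(schedule$parity == parity & schedule$beat %in% beats)
}

#' Run the full simulation + reconstruction + metrics pipeline
#'
#' Executes: phantom and signal simulation, golden-angle sampling of the
#' moving phantom, iNAV translation tracking, outlier rejection,
#' respiratory binning, then per contrast parity the requested
#' reconstruction variants (`uncorrected`: all data, no correction;
#' `translational`: beat-wise k-space phase correction to the
#' end-expiratory reference; `nonrigid`: beat-to-bin correction, soft-gated
#' It-SENSE bins, bin-to-bin registration and motion-compensated GMD
#' conjugate-gradient reconstruction), PSIR combination of the two
#' non-rigid volumes, and the quantitative endpoints.
#'
#' @param config a [default_config()]-style configuration
#' @param seed optional master-seed override
#' @param variants subset of `c("uncorrected", "translational", "nonrigid")`
#' @param use_true_fields use ground-truth deformation fields in the GMD
#'   step instead of registering bin images (validation mode)
#' @param out_dir optional output directory (NIfTI volumes, CSV/JSON
#'   metrics, run manifest, raw container)
#' @param tissue_file optional tissue library YAML override
#' @param verbose print stage progress
#' @return list with all intermediate products, per-variant
#'   reconstructions, `psir`, `metrics` and `manifest`
#' @export
run_pipeline <- function(config = default_config(), seed = NULL,
                         variants = c("uncorrected", "translational",
                                      "nonrigid"),
                         use_true_fields = FALSE, out_dir = NULL,
                         tissue_file = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message("[wholeheart] ", ...)
  if (!is.null(seed)) config$seed <- seed
  seed <- config$seed
  variants <- match.arg(variants, several.ok = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("signal model")
  tissues <- stage("signal_model", default_tissue_library(tissue_file))
  seq_odd <- stage("signal_model", seq_params(
    config$sequence$odd_scheme, RR = config$sequence$RR,
    lines_per_beat = config$sequence$lines_per_beat))
  seq_even <- stage("signal_model", seq_params(
    config$sequence$even_scheme, RR = config$sequence$RR,
    lines_per_beat = config$sequence$lines_per_beat))
  mt <- mt_params()
  signals <- stage("signal_model",
                   tissue_signals(tissues, seq_odd, seq_even, mt))

  say("phantom")
  pcfg <- do.call(phantom_config, config$phantom)
  phantom <- stage("phantom", make_phantom(pcfg, tissues))
  model <- do.call(motion_model, config$motion)

  say("acquisition")
  schedule <- stage("acquisition", build_schedule(
    Nky = pcfg$grid[2], Nkz = pcfg$grid[3],
    lines_per_beat = config$sequence$lines_per_beat,
    n_beats = config$schedule$n_beats,
    golden_angle = config$schedule$golden_angle))
  trace <- stage("acquisition", simulate_trace(
    model, config$schedule$n_beats, config$sequence$RR,
    seed = derive_seed(seed, 1)))
  coils <- stage("acquisition", make_coil_maps(
    pcfg$grid, pcfg$spacing, config$acquisition$n_coils))
  raw <- stage("acquisition", synthesize_raw(
    phantom, model, schedule, trace, coils, signals,
    noise_sd = config$acquisition$noise_sd, seed = derive_seed(seed, 2),
    inav_lines = config$acquisition$inav_lines))

  say("motion estimation")
  # the two contrast data sets are tracked, outlier-filtered and binned
  # independently (their iNAV contrast differs, so a cross-parity reference
  # would bias the estimates)
  roi <- inav_roi(phantom)
  n_beats <- max(raw$schedule$beat)
  mo <- list()
  for (par in c("odd", "even")) {
    idx <- which((seq_len(n_beats) %% 2 == 1) == (par == "odd"))
    tr_par <- stage("motion_estimation",
                    track_inavs(raw$inavs[, , idx, drop = FALSE], roi,
                                spacing = pcfg$spacing))
    tr_par$beat <- idx[tr_par$beat]
    keep_par <- stage("motion_estimation", reject_outliers(tr_par$d_si))
    bins_par <- stage("motion_estimation", assign_bins(
      tr_par$d_si[keep_par], max_width = config$binning$max_width,
      n_min = config$binning$n_min, n_max = config$binning$n_max))
    kept_beats <- tr_par$beat[keep_par]
    mo[[par]] <- list(
      translations = tr_par, keep = keep_par, bins = bins_par,
      bin_of_beat = stats::setNames(bins_par$bin_label, kept_beats),
      d_si_of = stats::setNames(tr_par$d_si, tr_par$beat),
      d_rl_of = stats::setNames(tr_par$d_rl, tr_par$beat),
      rl_center = vapply(seq_len(bins_par$n_bins), function(b) {
        mean(tr_par$d_rl[keep_par][bins_par$bin_label == b])
      }, numeric(1))
    )
  }
  translations <- rbind(mo$odd$translations, mo$even$translations)
  translations <- translations[order(translations$beat), ]
  keep_all <- logical(n_beats)
  keep_all[mo$odd$translations$beat] <- mo$odd$keep
  keep_all[mo$even$translations$beat] <- mo$even$keep

  rc <- do.call(recon_config, config$recon)
  grid <- pcfg$grid
  k_si <- kcycles(kfreq(grid[1]), grid[1], pcfg$spacing)

  recon_one <- function(parity, variant) {
    bins <- mo[[parity]]$bins
    bin_of_beat <- mo[[parity]]$bin_of_beat
    d_si_of <- mo[[parity]]$d_si_of
    d_rl_of <- mo[[parity]]$d_rl_of
    rl_center <- mo[[parity]]$rl_center
    kept_beats <- as.integer(names(bin_of_beat))
    if (variant == "uncorrected") {
      rows <- which(raw$schedule$parity == parity)
      res <- itsense(raw$samples[, rows, , drop = FALSE],
                     raw$schedule$ky[rows], raw$schedule$kz[rows],
                     rep(1, length(rows)), coils, rc)
      return(res$image)
    }
    if (variant == "translational") {
      rows <- parity_rows(raw$schedule, parity, kept_beats)
      y <- raw$samples[, rows, , drop = FALSE]
      k_rl <- kcycles(raw$schedule$ky[rows], grid[2], pcfg$spacing)
      bt <- as.character(raw$schedule$beat[rows])
      # per-entry correction toward the end-expiratory reference (0,0)
      for (b in unique(bt)) {
        sel <- bt == b
        d <- c(d_si_of[[b]], d_rl_of[[b]])
        y[, sel, ] <- kspace_translate(y[, sel, , drop = FALSE],
                                       k_si, k_rl[sel], -d)
      }
      res <- itsense(y, raw$schedule$ky[rows], raw$schedule$kz[rows],
                     rep(1, length(rows)), coils, rc)
      return(res$image)
    }
    # non-rigid: translational correction to bin centres, soft-gated
    # It-SENSE per bin, registration to the end-expiratory bin, GMD.
    # With zero estimated respiratory spread the data describe a single
    # respiratory state: the formal equal-count bins are degenerate and the
    # reconstruction collapses to one bin with no deformation to estimate.
    kept_chr <- as.character(kept_beats)
    if (diff(range(d_si_of[kept_chr])) < 1e-9 &&
        diff(range(d_rl_of[kept_chr])) < 1e-9) {
      rows <- parity_rows(raw$schedule, parity, kept_beats)
      res <- gmd_reconstruct(
        list(list(samples = raw$samples[, rows, , drop = FALSE],
                  ky = raw$schedule$ky[rows], kz = raw$schedule$kz[rows],
                  weights = rep(1, length(rows)))),
        list(NULL), coils, pcfg$spacing, rc)
      return(res$image)
    }
    bin_imgs <- vector("list", bins$n_bins)
    bin_dat <- vector("list", bins$n_bins)
    for (b in seq_len(bins$n_bins)) {
      beats_b <- as.integer(names(bin_of_beat))[bin_of_beat == b]
      rows <- parity_rows(raw$schedule, parity, beats_b)
      y <- raw$samples[, rows, , drop = FALSE]
      k_rl <- kcycles(raw$schedule$ky[rows], grid[2], pcfg$spacing)
      bt <- as.character(raw$schedule$beat[rows])
      for (bb in unique(bt)) {
        sel <- bt == bb
        d <- c(d_si_of[[bb]] - bins$bin_center[b],
               d_rl_of[[bb]] - rl_center[b])
        y[, sel, ] <- kspace_translate(y[, sel, , drop = FALSE],
                                       k_si, k_rl[sel], -d)
      }
      w <- soft_weights(d_si_of[bt], bins$bin_center[b], rc$soft_sigma)
      bin_dat[[b]] <- list(samples = y, ky = raw$schedule$ky[rows],
                           kz = raw$schedule$kz[rows], weights = w)
      bin_imgs[[b]] <- itsense(y, raw$schedule$ky[rows],
                               raw$schedule$kz[rows], w, coils, rc)
    }
    ref <- bins$reference_bin
    fields <- vector("list", bins$n_bins)
    basis <- if (model$nonrigid_gain > 0) {
      nonrigid_basis(grid, pcfg$spacing)
    } else NULL
    for (b in seq_len(bins$n_bins)) {
      if (b == ref) next
      if (use_true_fields) {
        # ground truth: beats are corrected to their own bin centre, so the
        # bin-to-reference deformation is the full displacement difference
        # (translation between bin centres plus the differential non-rigid
        # component)
        beats_b <- as.integer(names(bin_of_beat))[bin_of_beat == b]
        beats_r <- as.integer(names(bin_of_beat))[bin_of_beat == ref]
        si_b <- mean(trace$si[beats_b]); si_r <- mean(trace$si[beats_r])
        f <- array(0, c(grid, 3))
        f[, , , 1] <- -(si_b - si_r)
        f[, , , 2] <- -model$rl_coupling * (si_b - si_r)
        if (!is.null(basis)) {
          f <- f - model$nonrigid_gain * (si_b - si_r) * basis
        }
        fields[[b]] <- f
      } else {
        # initialize with the estimated inter-bin translation; the
        # optimizer refines the non-rigid residual
        init <- c(-(bins$bin_center[b] - bins$bin_center[ref]),
                  -(rl_center[b] - rl_center[ref]), 0)
        fields[[b]] <- register_nonrigid(bin_imgs[[ref]]$image,
                                         bin_imgs[[b]]$image,
                                         pcfg$spacing, rc,
                                         init_translation = init,
                                         presmooth = 1)
      }
    }
    res <- gmd_reconstruct(bin_dat, fields, coils, pcfg$spacing, rc)
    attr(res$image, "bin_images") <- bin_imgs
    res$image
  }

  recons <- list()
  for (par in c("odd", "even")) {
    for (v in variants) {
      say("recon ", par, " / ", v)
      recons[[par]][[v]] <- stage(paste0("reconstruction:", v),
                                  recon_one(par, v))
    }
  }

  say("psir")
  psir_variant <- if ("nonrigid" %in% variants) "nonrigid" else variants[1]
  psir <- stage("psir", psir_combine(recons$odd[[psir_variant]],
                                     recons$even[[psir_variant]]))

  say("metrics")
  # ground truth per parity, in that parity's end-expiratory reference frame
  basis_t <- if (model$nonrigid_gain > 0) {
    nonrigid_basis(grid, pcfg$spacing)
  } else NULL
  vols_truth <- lapply(c(odd = "odd", even = "even"), function(par) {
    m <- mo[[par]]
    ref_beats <- as.integer(names(m$bin_of_beat))[m$bin_of_beat ==
                                                    m$bins$reference_bin]
    si_ref <- mean(trace$si[ref_beats])
    warp_to_position(phantom_signal_volume(phantom, signals, par) + 0i,
                     model, si_ref, pcfg$spacing, basis_t)
  })
  body <- phantom$labels > 0
  nrmse_tab <- do.call(rbind, lapply(names(recons), function(par) {
    do.call(rbind, lapply(names(recons[[par]]), function(v) {
      data.frame(parity = par, variant = v,
                 nrmse = nrmse(recons[[par]][[v]], vols_truth[[par]], body))
    }))
  }))

  rois <- phantom_rois(phantom)
  snr <- lapply(recons$odd, snr_cnr, rois = rois)

  vess <- list()
  for (v in names(recons$odd)) {
    img <- Mod(recons$odd[[v]])
    vess[[v]] <- lapply(phantom$landmark_set$centerlines, function(cl) {
      bg <- centerline_background(img, cl$points, pcfg$spacing,
                                  cl$radius + 4, cl$radius + 9)
      vessel_metrics(img, cl$points, bg, pcfg$spacing)
    })
  }

  awt <- lapply(phantom$landmark_set$atria, function(ct) {
    awt_measure(psir, ct, pcfg$spacing)
  })

  metrics <- list(
    retention = mean(keep_all), n_bins = mo$odd$bins$n_bins,
    nrmse = nrmse_tab,
    snr = snr,
    vs_pct = sapply(vess, function(vv) {
      mean(vapply(vv, function(m) m$vs_pct, numeric(1)), na.rm = TRUE)
    }),
    vl_cm = sapply(vess, function(vv) {
      mean(vapply(vv, function(m) m$vl_cm, numeric(1)), na.rm = TRUE)
    }),
    vessels = vess, awt = awt
  )

  manifest <- list(
    config_hash = hash_obj(unclass(config)), seed = seed,
    n_beats = config$schedule$n_beats, retention = mean(keep_all),
    n_bins = mo$odd$bins$n_bins,
    reference_bin = mo$odd$bins$reference_bin,
    nrmse = nrmse_tab,
    volume_hashes = lapply(recons, function(p) lapply(p, hash_obj)),
    psir_hash = hash_obj(psir$data)
  )

  out <- list(config = config, phantom = phantom, signals = signals,
              schedule = schedule, trace = trace, raw = raw,
              translations = translations, keep = keep_all,
              bins = list(odd = mo$odd$bins, even = mo$even$bins),
              recons = recons, psir = psir, truth = vols_truth,
              metrics = metrics, manifest = manifest)

  if (!is.null(out_dir)) {
    say("writing outputs")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_raw(raw, file.path(out_dir, "raw"))
    for (par in c("odd", "even")) {
      write_motion_csv(mo[[par]]$translations, mo[[par]]$keep,
                       mo[[par]]$bins,
                       file.path(out_dir, paste0("motion_", par, ".csv")))
    }
    write_signals_csv(signals, file.path(out_dir, "signals.csv"))
    write_landmarks_json(phantom, file.path(out_dir, "landmarks.json"))
    for (par in names(recons)) {
      for (v in names(recons[[par]])) {
        write_volume_nifti(recons[[par]][[v]],
                           file.path(out_dir, paste0(par, "_", v, ".nii.gz")),
                           pcfg$spacing)
      }
    }
    write_volume_nifti(psir$data, file.path(out_dir, "psir.nii.gz"),
                       pcfg$spacing)
    jsonlite::write_json(
      list(manifest = manifest[c("config_hash", "seed", "n_beats",
                                 "retention", "n_bins", "reference_bin")],
           nrmse = nrmse_tab, snr = snr,
           vs_pct = as.list(metrics$vs_pct), vl_cm = as.list(metrics$vl_cm),
           awt = lapply(awt, function(a) {
             list(side = a$side, mean = a$mean, sd = a$sd,
                  n_defined = a$n_defined)
           })),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  out
}
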