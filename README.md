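# wholeheart

Simulation and motion-corrected reconstruction of interleaved bright- and
black-blood whole-heart MRI, exercised end to end on a synthetic digital
thorax phantom.

Free-breathing whole-heart imaging for the planning of atrial-fibrillation
ablation needs two things at once: a bright-blood volume that depicts the
pulmonary veins and the cardiac venous system, and a co-registered
black-blood volume from which atrial wall thickness (AWT) can be measured.
An interleaved acquisition alternates two differently
magnetization-prepared bright-blood volumes — magnetization-transfer (MT)
preparation with a short-TI inversion in odd heartbeats, MT preparation
with spectral fat saturation in even heartbeats — and combines them by
phase-sensitive inversion recovery (PSIR) into a complementary black-blood
volume. A low-resolution 2D image navigator (iNAV) acquired every heartbeat
drives beat-to-beat translational correction, respiratory binning,
bin-to-bin non-rigid registration, and a motion-compensated reconstruction,
giving 100% scan efficiency with no respiratory gating.

This package implements the full chain as testable components:

- **Signal model** — two-pool MT saturation of a Gaussian pulse train
  (15 pulses, 800°, 20.48 ms, BWTP 1.92, 3000 Hz offset), preparation
  schemes (`MTC_IR`, `MTC_FS`, `T2PREP_IR`, `T2PREP`, `IR_BLOODNULL`,
  `REF_LOWFA`), and the driven steady state of the interleaved bSSFP
  readout (TR 3.5 ms, TE 1.4 ms, flip 90°, TI 140 ms for the inverted
  beats).
- **Phantom** — labelled 3D thorax (lung, fat, liver, ventricle with
  myocardial shell, two thin-walled atria, six vessel tubes) with
  ground-truth centerlines, wall contours and an invertible respiratory
  deformation model (SI/RL translation plus a smooth non-rigid component).
- **Acquisition** — ECG-segmented Cartesian sampling with golden-angle
  spiral profile order, multi-coil k-space synthesis of the moving
  phantom, complex Gaussian noise, per-beat coronal iNAVs at ramp-up
  resolution.
- **Motion estimation** — normalized-cross-correlation iNAV tracking with
  sub-pixel refinement, mean ± 2 SD outlier rejection, equally populated
  respiratory bins (4–6 bins, 3.5 mm width cap), end-expiratory reference.
- **Reconstruction** — k-space phase-ramp translation, exponential
  soft-gating weights, density-compensated iterative SENSE (5 CG
  iterations), cubic B-spline free-form bin-to-bin registration, and the
  generalized-matrix-description (GMD) conjugate-gradient reconstruction
  `min_x Σ_b ||W_b (A_b F S U_b x − y_b)||²` with the interpolation
  transpose as the adjoint of each warp `U_b`.
- **PSIR** — phase-sensitive combination using the even-beat volume as
  phase reference; zero-fill (sinc) interpolation.
- **Metrics** — percentage vessel sharpness (%VS, 20–80% edge distance)
  and visible vessel length (VL), SNR/CNR from labelled ROIs, AWT by FWHM
  profiling of the signed PSIR volume, paired t-tests with Bonferroni
  correction (0.05/3 → 0.016).

## Worked example

```r
library(wholeheart)

cfg <- default_config()        # 64 x 64 x 32 at 2.1 mm, 400 beats
res <- run_pipeline(cfg, seed = 1)

res$metrics$nrmse
#>   parity       variant     nrmse
#> 1    odd   uncorrected 0.523
#> 2    odd translational 0.240
#> 3    odd      nonrigid 0.177
#> ...

res$metrics$retention          # fraction of beats kept by the +/-2 SD rule
#> [1] 1
res$bins$odd$n_bins            # equally populated respiratory bins
#> [1] 5
res$metrics$awt$left$mean      # atrial wall thickness on the PSIR volume, mm
```

The NRMSE rows compare each reconstruction of the inversion-prepared
(odd-beat) volume against the ground-truth phantom in the end-expiratory
frame: motion corrupts the uncorrected image (≈0.52), beat-to-beat
translational correction recovers most of it (≈0.24), and the non-rigid
GMD reconstruction recovers the rest (≈0.18). `res$psir` holds the signed
black-blood volume (blood strongly negative, wall slightly positive);
`res$metrics$vessels` the per-vessel %VS/VL tables.

A thin command-line wrapper is installed at
`system.file("cli", "wholeheart.R", package = "wholeheart")`
(`simulate` and `full` subcommands, `--config/--seed/--out/--variant`).

## Raw-data container

`write_raw()` / `read_raw()` persist an acquisition as a directory:
`manifest.json` (shapes, spacing, seeds, container version),
`schedule.csv` (beat, parity, line, ky, kz), `trace.csv`, and
`samples.bin` / `inavs.bin` / `coils.bin` — little-endian float64, all real
parts (column-major) then all imaginary parts. Externally converted
k-space (e.g. from ISMRMRD) mapped onto this layout enters the same
reconstruction pipeline.

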