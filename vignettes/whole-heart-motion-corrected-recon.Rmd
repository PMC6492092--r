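---
title: "Interleaved bright/black-blood whole-heart MRI: the simulation and reconstruction model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interleaved bright/black-blood whole-heart MRI: the simulation and reconstruction model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wholeheart)
```

This vignette is the package's account of its science: what is modelled,
which knobs matter, what the synthetic data do and do not emulate, and
where genuinely open design choices were resolved.

## The imaging problem

Planning of atrial-fibrillation ablation benefits from two co-registered
whole-heart volumes: a bright-blood volume depicting the pulmonary veins
and the coronary venous system, and a black-blood volume on which atrial
wall thickness (AWT) can be quantified. The interleaved sequence modelled
here acquires two differently prepared bright-blood volumes — an MT
(magnetization-transfer) train followed by a short-TI inversion in odd
heartbeats, the MT train with spectral fat saturation in even heartbeats —
and combines them in a phase-sensitive inversion-recovery (PSIR)
reconstruction into a third, black-blood volume. MT preparation, unlike a
T2 preparation, attenuates the bound-pool-rich myocardium while sparing
both arterial and venous blood; this is what preserves venous depiction
and gives the wall its intermediate intensity in the PSIR image.

## Signal model

`mt_saturation_factor()` propagates a two-pool (free/bound) longitudinal
system through the pulse train. Each Gaussian pulse (defaults: 15 pulses,
flip 800°, duration 20.48 ms, bandwidth–time product 1.92, offset
3000 Hz, 1.5 ms gaps) is discretized into piecewise-constant amplitude
steps; the bound pool absorbs through a Gaussian lineshape evaluated at
the offset, the free pool through a Lorentzian lineshape (direct
saturation at 3000 Hz is a ~1% effect for long-T2 tissue and is retained
rather than neglected), and saturation transfers by exchange
(`k_exch * f_bound` free→bound, `k_exch * (1 - f_bound)` bound→free).
Longitudinal relaxation over the ~330 ms train is not modelled, so the
factor is a pure multiplicative attenuation in `[0, 1]` — the form the
cycle simulator consumes. The two-pool parameters are not measurable from
the data the simulator mimics; the shipped library
(`inst/extdata/tissues.yaml`) carries literature-informed defaults chosen
once — a strongly attenuated wall (`f_bound` 0.20, factor ≈ 0.34 under the
default train), weakly attenuated blood (≈ 0.9), near-transparent fat and
lung — and is fully overridable.

`simulate_prep_cycle()` iterates one R-R interval to its fixed point: free
T1 recovery, the preparation for the beat's parity, the prep-to-readout
delay (TI 140 ms for the inverted beats, measured from the instantaneous
inversion to the k-space-centre line), then a centric bSSFP readout
approximated by its k-space-centre signal `Mz * sin(flip/2)` followed by
exponential approach to the bSSFP steady state at the standard apparent
rate `cos²(flip/2)/T1 + sin²(flip/2)/T2`. A per-TR Bloch train is
deliberately not simulated: contrast at the k-space centre dominates image
contrast, and the fixed-point iteration keeps the simulator instantaneous.
Flowing blood is marked `inflow: true` and modelled as fully replenished
each heartbeat (single preparation pass from equilibrium); without this,
repeated 90° readouts would saturate the blood pool that in vivo is
continuously replaced, and the bright-blood contrast the sequence is built
on would not form. Inversion efficiency is ideal by default and
configurable, as is whether a `T2PREP` of zero duration reduces exactly to
no preparation (it does, bit-exactly — a regression-tested identity).

The resulting defaults put the wall slightly past its zero crossing at
TI = 140 ms (Mz ≈ +0.02), blood deeply negative (≈ −0.74), and fat near
its null — so the signed PSIR volume shows dark blood, a wall band
brighter than both blood and lung, and suppressed fat, the contrast the
black-blood volume is designed for.

## Phantom and motion

`make_phantom()` lays out the anatomy in coordinates normalized to the
field of view (label volume fractions are therefore stable across grid
resolutions) while absolute-size structures — atrial walls (default
2.5 mm), vessel radii — are configured in millimetres. Six straight tubes
emulate the rPV, lPV, AIV, PIV, LAD and RCA; the pulmonary-vein tubes
carry the venous (short-T2) tissue class because that is how pulmonary
veins behave under T2 preparation in this imaging context, oxygenation
notwithstanding. Ground truth ships with the object: centerlines at 1 mm
steps, atrial wall contours with outward normals and true thickness.

Respiratory motion is a global SI translation with a fixed RL coupling
(default 0.3) plus a smooth non-rigid component: four broad Gaussian bumps
over the heart, edge-tapered, normalized to unit peak, scaled by
`nonrigid_gain * si` (default gain 0.35). The waveform is `cos⁴` (period
3571 ms, incommensurate with the 1000 ms R-R), which spends most of its
time on the end-expiratory plateau — the feature that makes an
end-expiratory reference meaningful — plus Gaussian beat-to-beat jitter
(0.3 mm) and optional drift. Invertibility of the deformation is asserted
through the finite-difference Jacobian. What the model does *not* emulate:
hysteresis between inspiration and expiration, cardiac contractile motion
(acquisition is assumed mid-diastolic), arrhythmic R-R variability, and
through-plane iNAV effects. Passing tests therefore demonstrate correct
mechanics of the estimation/correction chain, not robustness to every
physiological confounder.

## Acquisition

Sampling is Cartesian with spiral profile order: each interleaf is an
Archimedean arm in the (RL, AP) phase-encode plane, rotated by the golden
angle (137.508°) between interleaves, snapped to grid points with a
deterministic nearest-free-point substitution for duplicates, and opened
by the centre line every beat (centric order). The radial pacing and
snapping rule are not dictated by the sequence description; the
Archimedean-plus-nearest-neighbour choice is this package's documented
convention. Odd and even beats of a pair share one arm, so the two
contrast volumes sample identical (ky, kz) positions and are co-registered
by construction. The iNAV is the coronal projection of the same warped,
contrast-weighted object, low-pass filtered along RL to 14 phase-encode
lines (the ramp-up resolution) and stored before interpolation. Eight
birdcage-like synthetic coils (unit sum-of-squares everywhere) stand in
for the physical arrays; complex Gaussian noise is added per real/imaginary
channel with a fixed seed.

## Motion estimation and binning

Template matching maximizes normalized cross-correlation over integer
shifts within ±20 mm and refines to sub-pixel precision by a parabolic fit
(cheap and sufficient at the iNAV pitch; Fourier upsampling would buy
nothing at 1.4 mm). The reference iNAV is the beat at the modal 1-mm SI
level — the end-expiratory plateau — rather than an extreme, which could
be an outlier. Outliers are rejected by the mean ± 2·SD rule with the
sample (n−1) standard deviation; on Gaussian breathing this retains
≈ 95.4% of beats. Kept beats fall into the smallest number of equally
populated bins (4–6) whose widths all respect the 3.5 mm cap; when no
count does, six bins are used and the violation is logged. Ties are broken
by beat order; bin centres are permutation-invariant.

## Reconstruction

Beat-level translational correction is an exact k-space phase ramp
(`exp(−2iπ k·d)`), applied toward the bin centre in the binned pipeline
and toward the end-expiratory reference in the translational-only variant.
Soft gating weights each line by `exp(−|si − centre| / σ)` with σ = 1.75 mm
(half the bin-width cap; the decay form is fixed, the constant is this
package's choice).

Both solvers run conjugate gradient on the weighted normal equations for a
fixed five iterations (the empirically optimized count of the modelled
protocol), starting from the adjoint estimate, with a relative-residual
safety stop at 1e-6; the quadratic objective is non-increasing by
construction. One numerical choice deserves emphasis: the spiral profile
order revisits the centre of k-space every interleaf, so the accumulated
per-point weights span two orders of magnitude, and five CG iterations
cannot equilibrate that spectrum. Per-grid-point weights are therefore
capped at one — duplicate measurements enter as their soft-weighted
average — the standard density-compensated CG-SENSE formulation. Soft
gating still arbitrates between duplicates, which is the only place the
weights carry information under a consistent sampling model.

The motion-compensated reconstruction solves
`min_x Σ_b ||W_b (A_b F S U_b x − y_b)||²`, where `U_b` warps the
end-expiratory reference volume into bin `b` by trilinear interpolation
along the bin's deformation field. The adjoint of `U_b` is the transpose
of the interpolation operator (implemented literally as a sparse-matrix
transpose), *not* the inverse warp — substituting the inverse warp breaks
the symmetry CG relies on, which is why the operator pair is regression
tested with a dot-product identity. The single-bin, identity-field case
degenerates bit-for-bit to iterative SENSE because both run the same code
path.

Bin-to-bin registration is a cubic B-spline free-form deformation with
control points every 16 mm (defined in scanner millimetres, so one
coefficient set parameterizes every pyramid level), volume-wide
normalized-cross-correlation similarity, bending-energy regularization
(weight 1e-3), three multiresolution levels and adaptive-step gradient
ascent. The sequence description delegates its registration to cited
software and states no metric; volume-wide NCC was chosen over a windowed
local variant because the two inputs share contrast by construction — the
`ffd_metric` window field is accepted and reserved. Because each bin holds
roughly a fifth of the data, bin images are aliased; registration is
therefore initialized with the estimated inter-bin translation (a quantity
the binning already provides) and runs on 1-voxel-presmoothed magnitudes.
On a known 6 mm smooth deformation the registration recovers the field to
≈ 0.4 mm mean endpoint error in the heart.

## PSIR and measurements

The even-beat (non-inverted) volume supplies the background phase: its
complex values are smoothed with a 2-voxel Gaussian (the reference method
smooths but names no kernel), the inversion-prepared volume is rotated by
the negative phase, and the real part is the signed black-blood image.
Voxels whose reference magnitude falls below 5% of its maximum take their
own magnitude (sign convention 0), and the count of such voxels is
reported. Surface-coil intensity normalization is unnecessary here because
the synthetic coils are normalized; a flag documents the omission.

%VS caps at 100 when the 20–80% edge distance resolves within one voxel —
a convention that supports only relative comparisons. Profiles are cast in
the coronal (SI, RL) plane, where respiratory motion acts; a normal chosen
blindly per axis alignment would run anterior–posterior for most vessels
and see no motion blur at all. The visible-length criterion stops at the
first point whose centre intensity drops below background plus 35% of the
proximal (first-centimetre) contrast — a documented default, as the cited
tool's exact rule is unpublished. AWT is the full width at half maximum of
the wall peak above its flanking minima along each contour normal (±6 mm,
0.2 mm steps); the volume is sinc-upsampled (zero-fill ×2) before
profiling because trilinear sampling at coarse voxels broadens the peak by
a measurable ~0.3 mm; points whose peak does not reach twice the mean
flanking level (after shifting by the profile minimum) are flagged
undefined rather than zero. SNR/CNR use the magnitude-image lung standard
deviation as the noise estimate, as conventional for such reports; the
Rician noise-floor bias of that convention is documented, not corrected.

## Reference study conditions and problem sizes

The shipped reference simulation (`default_config()`) runs at
64 × 64 × 32 voxels, 2.1 mm isotropic (full-size anatomy on a coarser
grid than the protocol's native 1.4 mm), 400 heartbeats at R-R 1000 ms,
30 lines per beat, 8 coils, k-space noise 0.01 — sizes chosen so the
complete pipeline runs in about three minutes on one core. Unit tests use
smaller grids still (16³–48³). Absolute in-vivo SNR values are expressly
not a target; the noise level is set so that thermal noise is visible
without dominating the motion-correction comparisons.

Two findings from these conditions are worth stating plainly. First, the
expected quality ordering non-rigid < translational < uncorrected holds
for NRMSE against the ground-truth phantom (≈ 0.18 / 0.24 / 0.52 for the
inversion-prepared volume). Second, the %VS sharpness metric separates the
uncorrected volume (≈ 72–82%) from both corrected ones but cannot rank
translational against non-rigid here: with an end-expiration-dominated
breathing waveform the translationally corrected point-spread function
keeps a dominant sharp peak, both corrected variants sit at the 100% cap
(≈ 99.5%), and their difference is within the metric's saturation. This
was verified at two grid resolutions and across regularization settings;
it is a property of the capped sharpness convention under these study
conditions, not of the reconstruction chain.

## Known limitations

Single-contrast steady-state per parity (the interleaving's cross-parity
magnetization history is folded into the free-recovery interval rather
than simulated jointly); no off-resonance banding, eddy currents or
gradient delays; translational-only iNAV tracking (no rotation); straight
vessel tubes, so visible length saturates at the tube length; the raw
container is a documented directory format rather than HDF5, because no
R HDF5 binding is available in the supported dependency set.
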