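---
title: "Sparse-view OPT reconstruction and vessel segmentation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-view OPT reconstruction and vessel segmentation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Optical projection tomography (OPT) images transparent mesoscopic specimens
— classically a zebrafish embryo with fluorescently labelled vasculature —
by recording wide-field projections over a full rotation and reconstructing
the 3-D distribution tomographically. Acquisition time, and therefore
photodamage and motion artefact, scales with the number of rotation angles.
This package implements and evaluates the strategy of acquiring *sparse*
angular samplings and compensating with total-variation (TV) regularised
iterative reconstruction, followed by automated segmentation of the
vascular network.

# The forward model

A transaxial slice `X` observed at angles `theta_1 ... theta_K` yields a
sinogram

```
Y = R X + n,
```

where `R` is the parallel-beam Radon transform and `n` is measurement
noise. The parallel-beam model is appropriate for OPT at small effective
numerical aperture (the shallow-depth-of-field, telecentric-like regime);
cone-beam and defocus effects are out of scope. Conventions:

* angle 0 sends rays along image rows; angles increase counter-clockwise
  and span the full 360° (the redundancy of opposing views averages noise);
* the rotation centre defaults to the detector midpoint
  `(n_detector - 1) / 2` (bins are 0-based, as in acquisition manifests);
* slices are indexed along the rotation axis: camera row = slice.

`radon_forward()` is a ray-driven discretisation: each (angle, bin) ray
samples the image bilinearly at unit steps and sums, scaled by the detector
pitch. We realise the operator as a cached sparse matrix; `back_project()`
applies its exact transpose, so the adjoint identity
`<Rx, y> = <x, R^T y>` holds to machine precision rather than only
approximately. A ray-driven (rather than pixel-splatting) discretisation
was chosen because splatting aliases at angles near 45°; the chord-length
oracle in the test suite (central chord of an antialiased disk equal to
`2r` within 2%) holds for the ray-driven operator.

Transmission (bright-field) data measure attenuation, not emission;
`transmission_to_lineintegrals()` applies the Beer–Lambert conversion
`-log(I / I_0)` (intensities floored at `1e-6` of the bright reference) so
both channels fit the same linear model. Whether a given real dataset needs
the conversion is a pipeline flag: the simulator already produces
line-integral-domain stacks for both channels.

# Filtered back projection

`fbp_reconstruct()` is the analytic baseline: each sinogram row is filtered
in the detector frequency coordinate and back-projected, scaled by
`pi / K` so that full-rotation data average rather than double. The filter
is the band-limited Ram–Lak kernel evaluated via FFT with zero-padding to
`pad_factor ×` the next power of two, with its DC bin forced to exactly
zero (a constant row maps to numerical zero); Shepp–Logan and Hamming
windows are available. The default is the plain ramp: the dense FBP
reference tolerates noise, and an unwindowed ramp keeps the reference
sharp.

# TV-regularised reconstruction (TwIST)

Sparse-view reconstruction solves

```
minimise_X  0.5 * ||Y - R X||^2 + tau * TV(X),
```

with the isotropic TV functional `sum_i sqrt((D_i^H)^2 + (D_i^V)^2)`
(forward differences, replicate boundary). The solver is the two-step
iterative shrinkage/thresholding (TwIST) scheme

```
X_1     = G(X_0)
X_{t+1} = (1 - alpha) X_{t-1} + (alpha - beta) X_t + beta * G(X_t),
G(X)    = Psi_tau(X + R^T (Y - R X)),
```

where `Psi_tau` is TV denoising computed by Chambolle's dual
projected-gradient iteration (dual step 1/8, the 2-D operator-norm bound),
run for a fixed number of inner iterations `tv_iters` with no inner
tolerance — the iteration count is deliberately exposed as a quality/speed
knob.

Numerical choices:

* **Operator normalisation and the meaning of `tau`.** `R` is divided by a
  power-iteration estimate of its largest singular value, and `tau` is
  *dimensionless*: the working weight is `tau` times the data's intensity
  scale (the peak of the back-projected data on the normalised operator).
  Two considerations force this. First, the two-step weights assume a
  unit-bounded operator. Second, an absolute `tau` would tie the useful
  range of regularisation weights to the recording scale of the data — on
  intensity-100 data the conventional grid `tau ∈ {0.002, 0.006, 0.01}`
  would act orders of magnitude too weakly to matter. A corollary, tested
  as a property: scaling `Y` by `c` scales the reconstruction by `c` at
  fixed `tau`.
* **Two-step weights.** With eigenvalue-ratio assumption `xi = 1e-4`:
  `rho = (1 - sqrt(xi)) / (1 + sqrt(xi))`,
  `alpha = 2 / (1 + sqrt(1 - rho^2))` ≈ 1.669, and
  `beta = 2 alpha / (1 + xi)` ≈ 3.339. Note `beta > alpha` — this is the
  reference TwIST default rule, not a typo; stability requires
  `0 < alpha < 2` and `beta > 0`, which the constructor enforces.
* **Monotone safeguard.** A candidate step that would increase the
  objective is replaced by the plain one-step (IST) update, and if that
  also fails to descend, iteration stops. The objective trace is therefore
  non-increasing in every run — useful because the Chambolle prox is only
  approximate at small `tv_iters`.
* **Initialisation and stopping.** `X_0 = R^T Y` (scaled back projection)
  by default, with `zero` and `fbp` selectable; at most 100 outer
  iterations or a relative objective change below `1e-4`. A non-negativity
  clamp exists but is off by default (the objective above contains none).

# Vesselness segmentation

Vessels are enhanced with the multiscale Hessian eigenvalue filter. At
scale `sigma`, the Hessian is computed by separable correlation with
sampled Gaussian-derivative kernels (reflective boundary) and multiplied by
`sigma^2` (gamma-normalisation). The kernels are moment-corrected so that
responses to constants, ramps and quadratics are exact — a constant volume
yields an exactly zero Hessian and `x^2` yields exactly `2 sigma^2` — which
makes the filter's closed-form limits testable rather than approximate.

With eigenvalues ordered `|l1| <= |l2| <= |l3|`, bright tubular structures
have `l1 ≈ 0`, `l2 ≈ l3 < 0`, and the vesselness is zero when `l2 > 0` or
`l3 > 0`, otherwise

```
V = (1 - exp(-Ra^2 / 2a^2)) * exp(-Rb^2 / 2b^2) * (1 - exp(-S^2 / 2c^2)),
Ra = |l2| / |l3|,   Rb = |l1| / sqrt(|l2 l3|),   S = sqrt(l1^2 + l2^2 + l3^2),
```

with defaults `a = b = 0.5`, `c = 500`. Useful closed forms (all tested):
an ideal bright tube `(0, -L, -L)` with `S >> c` scores `1 - e^-2 ≈ 0.865`;
an ideal sphere `(-L, -L, -L)` scores `(1 - e^-2) e^-2 ≈ 0.117`; a plate
`(0, 0, -L)` scores 0. Per-voxel eigenvalues use a vectorised analytic
symmetric-3×3 solver (verified against the characteristic polynomial and
`eigen()` on random matrices). The multiscale map is the voxelwise maximum
over `n_scales` log-uniformly spaced scales; defaults `sigma in [1, 6]`
voxels, 5 scales, covering tube radii from the resolution floor
(~1.5 voxels, emulating the ~20 µm limit of real acquisitions at
6.5 µm/voxel-scale sampling) up to major trunks. A tube of radius `r`
responds maximally near `sigma = r / sqrt(2)`.

**Mask threshold.** The binary mask uses either a fixed threshold or, by
default, Otsu's method computed on the *logarithm* of the vesselness values
above `1e-3` of the map peak. Vesselness spans several decades; in the
linear domain the bright-centerline tail drags the Otsu cut into the middle
of the vessel value range (halving recall on a single-tube phantom), while
the log domain without a support floor admits the large-`sigma` halo around
thin tubes. Log-domain Otsu over the supported values separates the modes
cleanly; the threshold used is recorded on the mask.

# Quality metrics

`ssim_global()` implements the *single-window* structural similarity index
— means, population variances and covariance over all voxels at once, with
`c1 = (k1 L)^2`, `c2 = (k2 L)^2`, `k1 = 0.01`, `k2 = 0.03` and `L` the
joint dynamic range by default. No sliding window is involved; SSIM is 1
exactly for identical volumes. `dice()` is the Dice similarity index
`2|A ∩ B| / (|A| + |B|)`, with the 0/0 convention (two empty masks score 1,
with a message). Conventional interpretation labels (SSIM ≥ 0.9 "highly
similar"; DSI ≥ 0.7 "excellent", 0.6–0.7 "substantial") are attached to
metric records but never used as gates. `mip_render()` provides
maximum-intensity projections for visual reporting, and
`subset_uncertainty()` estimates sampling variability by reconstructing
repeatedly from random angular subsets, reporting each metric's mean and
maximum absolute deviation (the error-bar convention of down-sampling
studies).

# The synthetic specimen

`make_vessel_phantom()` and `make_anatomy_phantom()` generate the seeded
digital stand-in for a vascularised specimen:

* **Fluorescence channel** — `vessel_count` smooth tubes with
  piecewise-linear random centerlines; radii drawn from `radius_range`
  (floor 1.5 voxels — a sub-resolution tube is rejected); rendered by
  distance-to-centerline with a 1-voxel partial-volume soft edge (hard
  edges would corrupt the Hessian eigenvalue oracles). The first tube is
  always straight and aligned with the rotation axis, giving the
  vesselness tests an analytically placed target. Optionally each tube's
  intensity is scaled by a factor drawn from `intensity_range`, emulating
  varying fluorophore concentration; the default `c(1, 1)` keeps every
  tube at `vessel_intensity`.
* **Transmission channel** — soft-edged ellipsoids (two high-contrast
  "eyes" at attenuation 1.0 and a mid-contrast organ) over a smooth body
  envelope at `background_intensity = 0.1`, so the anatomy peak is ≥ 5×
  the body level — the high-contrast condition that makes transmission
  reconstructions robust to under-sampling.
* **Acquisition** — every slice is forward-projected at evenly spaced
  angles and i.i.d. zero-mean Gaussian noise is added. Gaussian additive
  noise is a standard sCMOS read-noise approximation; the level is a free
  parameter (a Poisson term could be added later without changing the
  interface). The two channels record different physical quantities at
  different scales, so their noise levels are set independently — in
  studies, each channel's noise sd is 2% of its own noiseless projection
  peak (noise is a detector property and scales with the recorded dynamic
  range; transmission, being light-rich, then ends up with much higher SNR
  than fluorescence, as in real instruments).

What the generator does *not* emulate: anatomically faithful vasculature
topology, refraction and scattering, depth-of-field blur (the tail-blur
artefact of real acquisitions), photobleaching, or rotation-axis
miscalibration. Passing tests on these phantoms therefore demonstrate
correctness of the algorithms and the direction of the sampling trade-offs,
not instrument-level performance on real data.

# Study design and problem sizes

`run_full_study()` orchestrates the full experiment: simulate the dense
two-channel acquisition → dense FBP reference (the "gold standard" is
itself a noisy reconstruction, exactly as in real studies — it caps
attainable SSIM) → sweep the TwIST grid
`tau ∈ {0.002, 0.006, 0.01} × tv_iters ∈ {5, 20, 40}` over evenly spaced
subsets → reconstruct every subset with FBP and with the per-subset optimal
TwIST cell in both channels → segment the fluorescence reconstructions →
score SSIM/Dice → optional random-subset uncertainty → write volumes,
masks, tables, MIPs, a config snapshot and a manifest.

Default study conditions, chosen once: a 64 × 64 × 16 phantom with 24
vessels of radius 1.5–3 voxels and per-tube intensity factors in
[0.4, 1]; dense acquisition of 160 angles; subsets {64, 50, 40, 32, 20};
vesselness scales narrowed to [1, 4] voxels to match those radii. The
richer network and varying intensities matter: a uniform-intensity
piecewise-constant phantom is so TV-compressible that 20 projections
already reconstruct it nearly perfectly, leaving a down-sampling study with
nothing to measure. Desk-scale grids (16³–64³) keep the whole suite in
minutes; the pipeline is size-agnostic and accepts acquisition-layout TIFF
stacks (one page per angle plus a CSV angle manifest) for real data.

# Known limitations

* The projector is 2-D parallel-beam per slice; no inter-slice (3-D) TV
  coupling, fan/cone geometry, detector PSF or centre-of-rotation
  auto-calibration.
* Numeric parity with any particular instrument's reconstructions is not
  claimed: published figures depend on unreported filter windows, TwIST
  defaults, vesselness scale ranges and mask thresholds. The package's
  claims are the exact identities, adjoint/closed-form oracles, and the
  qualitative orderings its tests verify on seeded phantoms.
* The global (single-window) SSIM is insensitive to where in the volume a
  discrepancy occurs; a sliding-window variant is deliberately out of
  scope because the global form is what the metric records report.
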