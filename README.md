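# optomo

Sparse-view optical projection tomography (OPT) reconstruction and vessel
segmentation in R.

OPT acquires wide-field projection images of a transparent specimen —
typically a zebrafish embryo with fluorescently labelled vasculature —
over a full rotation and reconstructs the 3-D intensity (fluorescence) or
attenuation (transmission) distribution. Dense angular sampling makes
acquisitions slow; this package implements the alternative: acquire few
angles and reconstruct with total-variation (TV) regularised iteration,
then segment the vasculature and quantify what sparse sampling costs.

For imaging scientists and computational biologists, it provides:

* a seeded digital vascular specimen (fluorescent tube network +
  high-contrast anatomy) so the whole pipeline runs without any data
  download;
* the parallel-beam forward model `Y = RX + n` with an exact-adjoint
  ray-driven Radon operator;
* filtered back projection (FBP; Ram-Lak/Shepp-Logan/Hamming);
* TV-regularised reconstruction `min_X 0.5 ||Y − RX||² + τ Φ_TV(X)` solved
  by the two-step iterative shrinkage/thresholding algorithm (TwIST) with
  a Chambolle dual-projection TV denoiser and a monotone safeguard;
* multiscale Hessian vesselness `V = max_σ V(σ)` built from the ordered
  eigenvalues `|λ1| ≤ |λ2| ≤ |λ3|` (ratios `R_A = |λ2|/|λ3|`,
  `R_B = |λ1|/√|λ2λ3|`, `S = ‖λ‖`; defaults a = b = 0.5, c = 500) with
  Otsu-based mask extraction;
* quality scoring with the single-window structural similarity index
  (SSIM) and the Dice similarity index (DSI), maximum-intensity
  projections, and random-subset error bars;
* an end-to-end study driver (`run_full_study()`) and a thin CLI
  (`inst/cli/optomo-cli`).

## Worked example

Simulate a 64×64×16 vascular phantom, acquire 160 noisy projections,
down-sample to 32 angles (20% of the data), reconstruct both ways, and
score against the dense FBP reference:

```r
library(optomo)

spec  <- phantom_spec(shape = c(64, 64, 16), vessel_count = 24,
                      radius_range = c(1.5, 3), intensity_range = c(0.4, 1),
                      seed = 42)
fluor <- make_vessel_phantom(spec)
anat  <- make_anatomy_phantom(spec)
geom  <- projection_geometry(evenly_spaced_angles(160), n_detector = 64)

clean <- simulate_dataset(fluor, anat, geom, noise_sd = 0, seed = 42)
sim   <- simulate_dataset(fluor, anat, geom,
                          noise_sd = 0.02 * max(clean$fluorescence$values),
                          seed = 42)

ref <- fbp_volume(sim$fluorescence)                  # dense reference
sub <- subset_angles(sim$fluorescence, downsample_angles(160, 32))

tw  <- twist_volume(sub, twist_params(tau = 0.01, tv_iters = 40))
fb  <- fbp_volume(sub)
cat(sprintf("SSIM twist %.3f  fbp %.3f\n",
            ssim_global(tw, ref), ssim_global(fb, ref)))

vp   <- vesselness_params(sigma_max = 4, n_scales = 4)
mask <- segment_mask(vesselness_multiscale(tw, vp), vp)
refm <- segment_mask(vesselness_multiscale(ref, vp), vp)
cat(sprintf("DSI %.3f\n", dice(mask, refm)))
```

```
SSIM twist 0.953  fbp 0.854
DSI 0.934
```

From 32 of 160 angles, the TV-regularised reconstruction stays close to
the dense reference (SSIM 0.95, "highly similar") while FBP drops to 0.85
with visible streaking, and the vessel segmentation still overlaps the
reference segmentation at DSI 0.93 ("excellent", ≥ 0.7). The full
experiment — parameter sweep over τ ∈ {0.002, 0.006, 0.01} and
TV_it ∈ {5, 20, 40}, both channels, every subset size, with all artefacts
on disk — is one call:

```r
res <- run_full_study(experiment_config(seed = 42))
res$sweep$best        # optimal (tau, TV_it) per subset size
```

## Layout

```
R/                  phantoms, projection, fbp, twist, vesselness, metrics,
                    pipeline, io
scripts/acceptance.R
inst/cli/optomo-cli simulate | reconstruct | segment | evaluate | sweep |
                    full-study
vignettes/          methods: models, parameters, design choices
tests/testthat/     unit, property and acceptance tests
```
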