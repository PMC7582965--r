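---
title: "Simulating time-gated multiphoton skin imaging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating time-gated multiphoton skin imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science inside `skinflim`: the forward models,
every tunable parameter that matters, the synthetic-data generator and what
it does and does not emulate, the numerical choices, and the design
decisions that were genuinely open.

## 1. Pulse train, arrival-time bins and wrapped decays

An 80 MHz excitation laser yields a period `T = 12.5` ns, divided into 16
equal arrival-time bins of `T/16 = 0.78125` ns (~780 ps). Fluorescence from
earlier pulses folds into the current period, so the steady-state arrival
density of a mono-exponential decay with lifetime `tau` is the wrapped
exponential

$$ p(t) = \frac{e^{-t/\tau}}{\tau\,(1 - e^{-T/\tau})}, \qquad t \in [0, T). $$

Multi-exponential decays are fraction-weighted mixtures; second harmonic
generation (collagen) is a prompt emitter, a point mass at `t = 0` spread
only by the instrument response.

**Bin/pulse alignment.** The instrument's documented gate windows are
[−0.4, 1.2] ns (red) and [0.4, 12] ns (green). Nothing ties the bin grid to
the excitation pulse a priori; we place bin 1's leading edge at −0.4 ns so
both documented windows land exactly on bin edges: red = bins {1, 2}, green =
bins {2, ..., 16}, sharing bin 2. This is the only alignment under which
the documented windows are realizable by whole bins while reproducing the
documented overlap of the two channels, and it is flagged as a
reconstruction, not a measured property. Negative arrival times are late
photons of the previous pulse, handled by the periodic wrap.

**Window snapping.** A bin belongs to a window iff its *center* lies inside
the window. Integer-bin snapping mirrors what counting hardware can do; no
fractional-bin weighting exists.

**Instrument response.** A Gaussian IRF with
`sigma = 0.57 / (2 sqrt(2 log 2)) ≈ 0.242` ns, reading the 570 ps detector
rise time as an effective FWHM. The system is sampling-limited (bin width
780 ps), so any sub-bin IRF model is adequate; a Gaussian keeps the
arithmetic closed-form. `sigma = 0` selects an ideal prompt response.

**Numerics.** Bin masses use the closed-form wrapped-exponential CDF; the
IRF convolution is a Gauss–Legendre quadrature over the jitter (±8σ, 512
nodes — the integrand varies on the lifetime scale, so nodes are generous;
the error is < 1e-6 for τ ≥ 0.1 ns, validated against a 10⁶-sample
Monte-Carlo arrival-time sampler in the test suite). The probability vector
is renormalized at the end; only the < 2e-9 truncated Gaussian tail is
redistributed. Phase shifts by whole bins permute the vector exactly, by
construction.

**Lifetime defaults** (literature-informed, fully overridable): melanin
0.2 ns mono-exponential; NAD(P)H 0.4/2.5 ns bi-exponential (0.75/0.25);
keratin 1.4 ns; elastin 1.7 ns; FAD 2.3 ns; collagen prompt (SHG).

## 2. The corrected-red melanin channel

Integrating counts over the red and green windows and subtracting,

$$ \mathrm{CR} = \max(R - G,\, 0), $$

isolates short-lifetime emitters: for melanin the red-window mass (0.997)
exceeds the green-window mass (0.149), while every longer-lived fluorophore
contributes more green than red and is clipped away. Clipping happens after
channel integration, per image — not per bin — and no scaling factor is
applied before the subtraction (pure photon counts).

**3D virtual staining.** The stain thresholds pooled corrected-red counts
of a z-stack. Otsu's threshold on the pooled nonzero histogram is the
default, but Otsu is meaningless on a unimodal histogram (it bisects it),
so the threshold policy accepts Otsu only when its lower class is a genuine
background mode — below-class mean under the shot-noise floor
`2 sqrt(mean(R + G))`, the scale of clipping-induced false positives.
Otherwise (an all-melanin field, or a melanin-free one) the noise floor
itself is the threshold. A fixed-quantile policy is available as an
explicit alternative.

**Scoring.** ROC AUC uses the continuous corrected-red counts against the
phantom's voxel truth; Dice uses the thresholded stain. In the bundled
benchmark the imaged planes sit at voxel centers of the phantom grid so
each optical section is dominated by exactly the truth slice it is scored
against; planes straddling voxel boundaries would mix two truth slices and
understate the discrimination that is actually achieved.

## 3. The skin phantom

The generator emulates the features label-free multiphoton imaging sees in
human skin, on a voxel grid (default 0.9 µm lateral, 2.5–5 µm axial pitch):

* a keratin-rich stratum corneum (default 0–10 µm) with corneocyte-scale
  multiplicative texture;
* viable-epidermis keratinocytes (10–45 µm): NAD(P)H-bright cytoplasm
  ellipsoids (~11 µm spacing, anisotropic Poisson-disc packing) around
  dark elliptical nuclei (5–10 µm diameter), FAD co-localized at 35%;
* perinuclear melanin caps on a configurable fraction of cells (default
  0.6), painted as a shell on the superficial side of the nucleus;
* melanocytic dendrites: ~1 µm thick branched random walks rooted at the
  basal layer, carrying melanin, with the melanocyte soma;
* below the dermo-epidermal junction (52 µm): collagen as oriented
  band-pass noise (a prompt SHG emitter) and elastin fibers as random
  walks.

Ground truth is exact: `melanin_truth` is the set of voxels with positive
melanin concentration; `dendrite_truth` marks dendrite voxels. The
`melanin_fraction` parameter scales cap probability and melanocyte density
jointly; every pigmented structure draws its randomness from its own
derived seed, so raising the fraction only adds structures (melanin voxel
counts are monotone in it) and regeneration under a fixed seed is
bit-identical.

**What the phantom does not emulate:** hairs, sweat glands, skin folds,
refractive-index heterogeneity, depth-dependent aberrations, and any
optical wave propagation. Passing tests on this phantom demonstrate the
pipeline's statistical behaviour under controlled truth, not performance
on real tissue.

**Optical sectioning.** Sections weight the concentration axially with a
Gaussian of FWHM 3.3 µm and blur laterally with FWHM 0.5 µm (the documented
axial/lateral resolutions; the PSF model itself is not documented — a Gaussian
is chosen for separability). Sections are attenuation-free by contract;
depth attenuation `exp(-depth / 100 µm)` is applied by the photon
simulator, where it belongs.

## 4. Photon budget and its calibration

Per-frame pixel dwell is `0.122 µs` (4 kHz resonant scanner, bidirectional,
1024 lines × 1024 pixels); accumulation multiplies it: 7 → ~1 µs, 15 →
~2 µs, 70 → ~9 µs. Resonant-velocity nonuniformity and duty cycle are
ignored (uniform dwell): the instrument's own dwell arithmetic is
consistent with the uniform model.

Fluorophore brightnesses (photons/µs/unit concentration) set the photon
budget. They were calibrated **once** so that raw 15-accumulation epidermal
sections score a mean SSIM in the 0.3–0.5 band against 70-accumulation
ground truth — the reference low-SNR operating point — and then frozen:
melanin 2.4 (the brightest, as in pigmented skin), keratin 0.48, NAD(P)H
0.40, elastin 0.40, FAD 0.24, collagen/SHG 0.8. Under this budget a typical
epidermal pixel detects ~1.3 photons at 15 accumulations: restoration
operates in a genuinely photon-starved regime.

## 5. Mosaic geometry

* **Strips**: `ceil(width / 0.75 mm)` strips; strip length bounded by the
  13 mm stage travel (exceeding it is an error naming the limit).
  Serpentine offsets one strip width apart, direction alternating.
  Stitching is abutment at planned offsets — registration fidelity is the
  scanner synchronization's job, and stage repeatability error is exposed
  as a Gaussian jitter parameter of the simulator instead. A 10 × 12 mm
  area takes 16 strips.
* **Tiles**: `ceil(area / (0.9 mm × (1 − overlap)))` per axis; zero-overlap
  tiles abut, positive overlap is blended with separable linear feathering
  whose weights are normalized to sum to one. 4.5 × 4.5 mm → 5 × 5 tiles
  (25 MPx nominal), 6.3 × 6.3 mm → 7 × 7 (49 MPx).
* **Z-stacks**: planes at `k · step`, `k = 1..round(range/step)` — the
  convention that yields 30 planes for 150 µm at 5 µm (inclusivity at the
  boundaries is otherwise unstated).
* **Aspect rebinning**: separable Catmull–Rom (bicubic) resampling of the
  coarser-pitch axis up to the finer pitch, pixel-center aligned so the
  physical extent is preserved within half a pixel and constants are
  preserved exactly. The 64 → 80 MPx example fixes the along/across pitch
  ratio at 1.25 — the only ratio consistent with the documented megapixel
  pair; the acquired raster dimensions themselves are not documented, and an
  8000 × 8000 raster is the documented assumption.
* **Flat-field**: the across-tile mean image is fit with a full tensor
  polynomial basis of order 2 per axis (9 terms), normalized to unit mean,
  and divided out; estimation is invariant to global intensity scale. A
  radial quadratic vignette is inside the basis, hence recovered exactly up
  to noise.

## 6. The restorer

A deliberately small two-scale convolutional encoder–decoder: two 3×3
convolutions at full resolution (8 features), 2×2 mean-pool, four 3×3
convolutions at half resolution (16 features), nearest-neighbour
upsampling, skip concatenation, one 3×3 + one 1×1 convolution back to a
single channel. ~19k parameters, receptive-field radius ≈ 14 px. It is
trained with MSE loss and Adam (benchmark lr 2e-3, per-epoch decay 0.97) on
percentile-normalized (0.1/99.9) patch pairs, both input accumulation
levels pooled into one model, with random flip/transpose augmentation.
No deep-learning framework for R is involved: convolutions are evaluated
as im2col gathers plus BLAS GEMMs, and gradients are exact (verified
against numerical differentiation in the tests).

Three design choices deserve their rationale:

* **Direct prediction, no residual head.** With a residual head the network
  passes input shot noise through unless it learns to cancel it; direct
  prediction forces it to synthesize the restored image and scored
  consistently higher structural similarity in our experiments.
* **Multi-scale input channels.** The input patch is presented together
  with Gaussian-blurred copies (σ = 1, 2, 4 px) as extra channels. At ~1
  detected photon per pixel these are pre-aggregated photon counts at
  several scales — information a deeper network would have to spend
  capacity recovering.
* **Validation-SSIM model selection.** The ground truth is itself an
  acquisition (70 accumulations), not a noise-free image. Prolonged MSE
  training keeps lowering validation MSE while the output drifts toward
  reproducing the ground truth's noise texture, *degrading* SSIM. Training
  therefore keeps the weights of the epoch with the best validation SSIM.
  Crucially, validation patches are split from training patches at the
  section level (`val_by = "image"`), because patches cut on an overlapping
  grid share pixels and a patch-level split would leak and inflate late
  epochs. The protocol's patch-level 10% split remains available
  (`val_by = "patch"`) and is the bookkeeping the protocol numbers (35,200
  → 3,520/31,680) refer to.

**Tiled inference** trims a 16 px margin (beyond the receptive field) from
interior tile edges and normalizes overlapping contributions, so tiled and
whole-image inference agree to floating-point precision and blending
weights sum to one everywhere.

**Ground truth is a noisy draw.** The 70-accumulation ground truth is an
independent Poisson realization, matching the acquired-ground-truth
protocol; a perfect restorer therefore cannot reach SSIM 1 against it —
on the calibrated budget the noise-free expected field itself scores only
~0.70. Reported SSIM bands must be read against that ceiling.

## 7. Desk-scale study conditions

The bundled benchmark (`restoration_benchmark()`) uses 12 phantoms × 4
epidermal depths = 48 sections of 256 × 256 px at 0.9 µm pitch; 20 randomly
held-out sections are never seen in training; ~2,000 64-px patch pairs
(both accumulation levels pooled) train for 30 epochs × 30 steps at batch
8. The full acquisition-scale configuration (128-px patches, 35,200 patches, 100
epochs) remains expressible through `restoration_config()`; the desk-scale
sizes were chosen once as the smallest experiment in which the input-SSIM
band, the restoration gain, and the melanin AUC are all stably measurable,
and are documented here as the package's study conditions. The melanin
benchmark uses one default phantom (40 × 256 × 256 voxels, 5 µm axial
pitch) imaged at 7 voxel-center planes through the viable epidermis at 15
accumulations.

## 8. Degenerate inputs and edge behaviour

* `decay_bin_probs` rejects non-positive lifetimes and unnormalized
  fractions; `tau >> T` converges to the uniform histogram.
* Windows outside the aligned period are configuration errors, not
  warnings.
* A constant image cannot be percentile-normalized: the identity transform
  is returned with a warning.
* Zero-jitter strip simulation takes an exact-indexing fast path, making
  the stitch round trip bit-exact rather than merely close.
* An all-zero tile set is rejected by the flat-field estimator; gains are
  clamped strictly positive.
* Training failure (non-finite validation loss) raises an explicit error.

## 9. Known limitations

* The phantom's dermis is decorrelated across axial slices (per-slice
  textures); fine for per-section statistics, wrong for 3D dermal texture
  studies.
* No detector afterpulsing, pile-up/dead-time, saturation or
  photobleaching; at ≤ few counts/pixel/frame these are secondary.
* The corrected-red subtraction is unscaled; if an instrument applied a
  gain factor before subtraction, the stain threshold policy would need
  recalibration.
* Channel/mosaic images are written as plain multi-page TIFF with a JSON
  sidecar (scale, pixel size, channel order); no OME-XML is embedded.
* The restorer is CPU-sized (~19k parameters); it demonstrates the paired
  low/high-SNR protocol and its evaluation, not state-of-the-art
  restoration capacity.
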