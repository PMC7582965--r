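# skinflim

Simulation and analysis toolkit for **time-gated multiphoton microscopy of
human skin**: it reproduces, end to end and without any hardware, the
computational pipeline of a fast clinical multiphoton exoscope — arrival-time
binned single-photon counting, virtual red/green lifetime gating with
corrected-red melanin discrimination, strip/tile mosaic scan geometry, and
paired low/high-SNR convolutional image restoration — driven by a
physics-based synthetic skin phantom and a Poisson photon-counting
simulator.

It is aimed at microscopy methods developers who want a fully controlled,
ground-truthed testbed for time-gated detection schemes and
restoration-assisted fast scanning.

## The model

**Time-gated detection.** An 80 MHz pulsed laser gives a 12.5 ns period,
divided into 16 arrival-time bins of ~780 ps. A fluorophore with lifetime
mixture {(τ_i, f_i)} produces the steady-state wrapped decay

    p(t) = Σ_i f_i · e^(−t/τ_i) / (τ_i (1 − e^(−T/τ_i))),   t ∈ [0, T),

integrated over each bin and convolved with a Gaussian instrument response
(σ ≈ 0.24 ns from the 570 ps detector rise time). Two virtual channels
integrate bins: red [−0.4, 1.2] ns and green [0.4, 12] ns. Because the
windows deliberately share a bin, melanin — the shortest-lived endogenous
fluorophore (τ ≈ 0.2 ns) — is isolated by the **corrected red** channel

    CR = max(R − G, 0),

which is positive for short-lifetime emitters and vanishes for long-lived
ones. Thresholding CR across a z-stack yields a 3D virtual melanin stain,
scored here against the phantom's voxel ground truth by ROC AUC and Dice.

**Photon counting.** Each pixel-bin of a frame is an independent Poisson
draw with mean set by the phantom's optical section, the per-frame pixel
dwell (0.122 µs at 4 kHz resonant scanning, 1024×1024), depth attenuation,
and the fluorophore's decay histogram; accumulating n frames multiplies the
mean (70 accumulations ≈ 9 µs effective dwell).

**Restoration.** Pairs of pixel-registered acquisitions at low (7/15) and
high (70) accumulation train a small two-scale convolutional
encoder–decoder (MSE loss, Adam, validation-SSIM model selection) that
restores low-SNR images; quality is reported as MSE/MAE/SSIM against the
high-SNR ground truth on held-out sections.

**Mosaics.** Planners reproduce the instrument's scan geometry — 0.75 mm
strips under a 13 mm stage travel limit, 0.9 mm tiles, 5 µm z-steps — and
the package simulates, stitches, bicubic-rebins (anisotropic 64 MPx rasters
to isotropic 80 MPx) and flat-field-corrects the results.

## Worked example

```r
library(skinflim)

ph <- generate_phantom(seed = 1, shape = c(24, 256, 256),
                       pitch = c(2.5, 0.9, 0.9))
ph
#> Skin phantom: 24 x 256 x 256 voxels (z,y,x), pitch 2.5/0.9/0.9 um
#>   depth 60 um; fluorophores: melanin, nadh, fad, keratin, elastin, collagen
#>   melanin-positive voxels: 60268 (3.83%); dendrite voxels: 1025

# one gated acquisition at 15 accumulated frames
ci <- simulate_channel_image(ph, depth = 25, n_accum = 15, seed = 1)
ci
#> Channel image 256 x 256 px: mean red 0.423, green 0.226, corrected red 0.248, shg 0

# scan geometry
plan_strip_scan(12, 10)
#> Strip scan: 16 strips of 10 x 0.75 mm (covers 10 x 12 mm)
plan_tile_scan(4.5, 4.5)
#> Tile scan: 5 x 5 tiles of 0.9 mm (0% overlap), 25 MPx nominal
plan_zstack(150, 5)
#> Z-stack: 30 planes, 5 to 150 um every 5 um

# melanin discrimination on a default phantom (ROC AUC vs ground truth)
mb <- melanin_benchmark(seed = 1)
round(c(auc = mb$auc, dice = mb$dice), 3)
#>   auc  dice
#> 0.926 0.623
```

The AUC is the probability that a melanin-bearing pixel scores a higher
corrected-red count than a melanin-free one; 0.93 at only 15 accumulated
frames (~2 µs dwell) is what makes near-instantaneous 3D virtual melanin
staining practical.

The paired-restoration experiment (several CPU-minutes) is run by
`restoration_benchmark(seed = 1)`; it simulates 48 phantom sections, trains
the restorer on ~2,000 patch pairs and reports held-out SSIM for raw and
restored 15-accumulation images.

## Command line

A thin CLI over the package functions is installed at
`inst/cli/skinflim`:

```sh
Rscript inst/cli/skinflim phantom  --seed 1 --out out/
Rscript inst/cli/skinflim simulate --seed 1 --out out/ --phantom out/phantom
Rscript inst/cli/skinflim gate     --seed 1 --out out/ --frame out/frame.tif
```

Every subcommand freezes its resolved configuration (JSON) next to its
artifacts, so any run can be reproduced bit for bit.
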