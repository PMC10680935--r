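---
title: "Neural bias field correction: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural bias field correction: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(biasnet)
```

## The model

T1-weighted MR volumes are corrupted by a smooth, strictly positive,
low-spatial-frequency multiplicative modulation — the bias field — caused by
magnetic-field and coil-sensitivity inhomogeneity:

$$a(r) = u(r)\, b(r),$$

where $a$ is the acquired image, $u$ the underlying (corrected) image, $b$
the field, and $r$ the voxel.  Taking logs makes the field additive and
sign-free, $\log u = \log a - \log b$, so the estimation problem becomes a
voxelwise regression: a 3D U-Net $f$ maps the normalized acquired volume to
the predicted log field, $\log b'(r) = f(a(r))$.  Correction divides by the
exponentiated (optionally smoothed) prediction.

Training minimizes $\mathcal{L} = \mathcal{L}_a + \mathcal{L}_b$ with

$$\mathcal{L}_a = \tfrac1N \sum_{r \in M} \bigl(e^{\log b'(r)} - b(r)\bigr)^2,
\qquad
\mathcal{L}_b = \tfrac1N \sum_{r \in M} \bigl(e^{\log a(r) - \log b'(r)} - u(r)\bigr)^2,$$

where $M$ is the brain mask and $N$ its voxel count.  Both terms compare in
linear intensity space; masking avoids the zero background dominating the
sums.  A log-space variant of the field term is available
(`train_config(loss_space = "log")`) but is not the default.

## The preprocessing chain and its inversion

Inputs of any voxel size are resampled to 2 mm isotropic (trilinear;
nearest-neighbour for masks), padded or cropped to a fixed 128³ grid
(content centered, excess split floor/ceil), and normalized by the volume's
99th intensity percentile with clipping to $[0,1]$.  Every step is written
to a `prep_record`, so a field predicted on the fixed grid can be mapped
back through the inverse pad/crop and a trilinear resample onto the native
grid (`restore_to_native()`); the field's smoothness is what justifies
linear interpolation on the way back.  Two conventions worth stating
because they change numbers:

* the normalization percentile is computed over **all** voxels, not only
  the brain, since normalization precedes masking in the chain;
* correction can be delivered on the preprocessed grid or at native
  resolution (`correct_volume(deliver =)`); both are exposed because the
  reference pipeline's convention is not fixed.

The brain mask is a two-stage histogram threshold (a first Otsu pass splits
dark from bright; a second pass below that cut separates true background
from the darkest tissue class), followed by the largest 6-connected
component and hole filling.  A single Otsu pass is the textbook choice but
lands *between* tissue classes on a trimodal T1 histogram and would exclude
CSF; the two-stage scheme finds the background/tissue boundary instead.
This mask gates losses and metrics only — it is not skull stripping of
clinical quality.

## The network

`build_unet()` constructs a standard encoder–decoder: per resolution level
two 3×3×3 convolutions, each followed by instance normalization and leaky
ReLU (slope 0.01); 2×2×2 pooling between levels; transpose-convolution
upsampling mirrored with channel-concatenating skips; and a final 1×1×1
linear convolution with **no** output nonlinearity, because a log field is
signed and clipping it would bias corrections.  Depth, width, epochs and
batch size are deliberately configurable (`unet_config()`,
`train_config()`): the corpus-scale design (levels = 4, base = 32 channels,
128³ inputs) and the desk-scale variants used in the tests (levels = 2–3,
base = 4–8, 16³–48³ inputs) are the same code.

Design choices where the block design was genuinely open:

* **Downsampling is 2×2×2 max pooling by default** — the common U-Net
  choice.  Average pooling, which preserves the smooth local mean intensity
  instead of the maximum, is exposed as `pool = "avg"`; in the package's
  desk-scale experiments the two were indistinguishable, so the
  conventional default stands.
* **Zero-initialized output layer.**  The untrained network then predicts
  exactly $\log b' \equiv 0$, i.e. the identity field — a sensible prior
  that also makes "initial loss" a well-defined baseline.  Hidden layers
  use He initialization.
* **"Instance batch normalization" is read as instance normalization**
  (per-volume, per-channel), the standard reading for batch size 1.
* The compiled core computes in single precision (the conventional
  deep-learning precision) with double-precision loss accumulation;
  backpropagation is verified against central finite differences in the
  test suite.

## Smoothing the predicted field

Three post-processing variants of the exponentiated prediction:

* **NS** — no smoothing (the raw field);
* **G** — separable convolution with a truncated, renormalized Gaussian,
  σ = 3 voxels, 19³ kernel, reflective boundaries (reflection avoids edge
  attenuation of a multiplicative field);
* **B** — slicewise multilevel cubic B-spline approximation, five levels:
  level 1 fits a single-span uniform mesh by least squares, each further
  level doubles the mesh and fits the residual, mirroring the coarse-to-fine
  scheme of B-spline field fitting in iterative correction.  The fit is
  dense (every slice pixel enters the least squares); scattered-point
  subsampling is out of scope, which is a known deviation from pipelines
  that fit on random point subsets.  The slicewise axis defaults to the
  third (axial) and is configurable; B-spline output is clamped at a small
  positive epsilon because approximation can undershoot.

Smoothing sits **outside** the training loss by default; the predicted raw
field enters $\mathcal{L}$.  `train_config(smoothing_in_loss = TRUE)` moves
Gaussian smoothing into the loss path differentiably — the backward pass
applies the exact adjoint of the reflect-boundary convolution.  The
B-spline variant is linear too, but its adjoint bookkeeping is not worth
the complexity for a non-default path, so it is not offered in-loop.

## The synthetic phantom engine

Training and validation need paired $(a, u, b, \text{mask})$ volumes.  The
generator emulates exactly the statistical structure the model assumes:

* `generate_phantom()`: three nested ellipsoidal tissue shells (CSF, grey,
  white at intensities 0.15 / 0.45 / 0.75 on $[0,1]$, strictly increasing)
  inside an ellipsoidal head support on a zero background, with
  within-tissue Gaussian jitter (sd 0.02) so tissue is near-constant, not
  constant.
* `generate_bias_field()`: $b = e^g$ with $g$ drawn from one of three
  smooth families — Gaussian-filtered white noise, random low-order
  polynomials, or a random coarse B-spline mesh — then rescaled so
  $\max|g|$ equals `log_amplitude` exactly.  The default amplitude 0.3
  (field range ≈ 0.74–1.35) is in the regime bias correction targets:
  clearly visible, not contrast-destroying.  The random-field correlation
  length defaults to a quarter of the smallest volume side (12 voxels at
  48³), i.e. modulation over a few centimetres at 2 mm spacing.
* `generate_sample()`: $a = u\,b + \varepsilon$ with additive Gaussian
  noise (sd 0.01 by default).  Rician noise, partial-volume effects and
  anatomical realism are deliberately out of scope.

Everything is driven by explicit seeds; a dataset's manifest records the
per-sample seeds so `regenerate_from_manifest()` reproduces it
bit-identically.  Because the phantom is piecewise-near-constant and the
fields come from known families, passing tests demonstrate that the
estimator recovers *smooth multiplicative structure from tissue-modulated
images* — they do not demonstrate performance on real anatomy, scanner
artifacts, or fields outside the generated families.

## Training protocol

Adam with the standard moments (β₁ = 0.9, β₂ = 0.999), batch size 1,
best-on-validation selection by total loss, full per-epoch history, and
end-to-end seeded reproducibility on one CPU thread; checkpoints store
weights, optimizer state and RNG state, so a resumed run continues the
exact trajectory of an uninterrupted one.  The corpus-scale learning rate
(1e-4, the published protocol) is the `train_config()` default.  Runs of a
few hundred optimizer steps sit in a different regime: with Adam's
per-parameter step capped near the learning rate, 1e-4 cannot move the
weights far enough to fit anything in ~300–600 steps, so the desk-scale
experiments in this package (the tests, the acceptance script, the CLI
default) use 1e-3.  Learning-rate schedules, augmentation and mixed
precision are non-goals.

Desk-scale problem sizes used by the test suite and acceptance script,
chosen so the full suite runs on a laptop-class single CPU: unit tests at
16³–32³ with levels 2; the field-recovery experiment trains levels 3 /
base 8 on 64 samples of 48³ for 10 epochs (640 optimizer steps), with 8
validation samples for model selection and 16 held-out samples for
scoring.

## Evaluation

Division-based correction leaves a global intensity offset (the predicted
field's overall scale is arbitrary to one multiplicative constant), so the
protocol applies `mean_shift_to_reference()` — matching masked means —
before fidelity is measured; the same adjustment is standard when comparing
correction methods against a gold standard.  `psnr()` is
$10\log_{10}(R^2/\mathrm{MSE})$ with the MSE over **masked**
voxels and $R$ the masked maximum of the reference.  The masked convention
is documented prominently because including the zero background would
inflate both terms and change absolute dB values; identical inputs report
`Inf`.  `compare_methods()` aligns per-case scores, reports per-method
medians, and for each method pair a two-sided Wilcoxon signed-rank p
(exact via the signed-rank distribution for n ≤ 25 without ties; exhaustive
sign-pattern enumeration when magnitudes tie and n ≤ 14 — the tied case has
no standard exact path; normal approximation with continuity and tie
corrections otherwise), Bonferroni adjustment with the number of pairs as
multiplier, and Cohen's d for paired data (mean over SD of differences; 0
when all differences vanish, an infinite sentinel for a nonzero constant
shift).  `percentile_cases()` picks representative cases nearest the 90th,
50th and 10th linear-interpolation percentiles with smaller-id tie-breaks,
and `intensity_profile()` extracts in-slice lines for the classic
profile-flattening picture.

## Numerical conventions

* Division and logs clamp at ε = 1e-6 on the normalized scale — far below
  tissue intensity, preventing infinities at background zeros.
* Resampling output shapes use round-half-away-from-zero on physical
  extent; the record keeps the exact shapes so inversion never re-rounds.
* The multilevel B-spline least squares adds a 1e-10 ridge to the normal
  equations, harmless at the fit's accuracy and protective when a basis
  function covers no sample point.
* Percentiles are linear-interpolation (type 7) percentiles everywhere.

## Known limitations

The phantom is geometric, not anatomical; noise is Gaussian, not Rician;
the B-spline smoother fits slices densely rather than on scattered points;
the desk-scale network (85k parameters, 640 optimizer steps) recovers the dominant
smooth component of the field but cannot be expected to match a
corpus-trained model's fidelity; and correction quality on real scanner
data is untested by construction — the package's evidence is limited to
what the synthetic engine generates.
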