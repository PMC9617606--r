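---
title: "Self-supervised missing-wedge restoration: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised missing-wedge restoration: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomowedge)
```

## The problem

Single-axis electron tomography tilts the specimen about one axis
(conventionally Y) over a limited range, typically −60° to +60°.  By the
central-slice theorem each projection samples one central plane of the 3D
Fourier transform, so the union of all tilts is a fan of planes and the two
complementary wedge-shaped regions around the beam axis (kz) are never
measured.  In real space this *missing wedge* elongates every feature along
Z, turns spherical gold beads into "X" shapes, and makes membranes normal to
the beam vanish.

`tomowedge` restores the missing information with a self-supervised scheme
that needs nothing but the tomograms themselves.  The key observation: a
subtomogram rotated by a cube symmetry carries its own missing wedge into a
*new* orientation.  Imposing the standard wedge on the rotated copy produces
a volume that is missing information in *two* wedge orientations, while the
rotated copy itself is missing only one.  A volumetric network trained to map
the doubly-corrupted input to the singly-corrupted target learns to fill a
wedge from surrounding context, and that ability transfers to the original
orientation.

## Wedge geometry

A Fourier voxel with integer frequencies $(k_x, k_y, k_z)$ is *sampled* iff
the angle of $(k_x, k_z)$ from the $k_x$ axis, folded to $(-90°, 90°]$, lies
within the tilt range; $k_y$ is unconstrained.  The binary wedge filter is 1
on sampled voxels and 0 elsewhere.  Conventions fixed once here:

* the DC voxel is always sampled (the volume mean is measured data);
* voxels exactly on the wedge boundary count as sampled (deterministic
  tie-break);
* asymmetric ranges (e.g. −48°…+66°) test the signed folded angle against
  `[tilt_min, tilt_max]`; because a direction and its antipode fold to the
  same angle, the filter is automatically Hermitian-symmetric and filtered
  real volumes stay real;
* the filter edge is left sharp.  A binary filter keeps the conservation
  guarantee below exact; smoothing the edge would trade a little ringing
  against leaking modified values into measured frequencies.

Of the 24 proper rotations of the cube, four (the identity and the three
180° axis rotations) map the wedge support onto itself and would produce
training pairs whose input equals the target; they are excluded, leaving 20
useful orientations per subtomogram.  The exclusion is computed from the
filter geometry rather than hard-coded, so it adapts to asymmetric ranges.
Training-pair rotation uses exact axis permutations (no interpolation, no
information loss); interpolating rotation exists only in the synthetic
benchmark where arbitrary poses are required.

## CTF deconvolution

Reconstructed tomograms acquired without a phase plate carry the microscope's
oscillatory contrast transfer function.  A Wiener filter

$$ W(f) \;=\; \frac{\mathrm{CTF}(f)}{\mathrm{CTF}(f)^2 + 1/\mathrm{SSNR}(f)} $$

is applied as a radially symmetric 3D filter with the empirical
spectral-SNR model

$$ \mathrm{SSNR}(f) \;=\; e^{-f \cdot 100 F} \cdot 10^{S} \cdot H(f), $$

where $f$ is in cycles/pixel, $F$ (`snrfalloff`) sets how fast the assumed
SNR decays with frequency, $S$ (`deconvstrength`) sets its plateau, and $H$
is a high-pass.  Larger $F$ damps high frequencies harder (more contrast,
less detail); $S$ shifts the balance between inverse filtering and
suppression.  Published analyses of comparable data used $F$ around 0.7–1.0
and $S = 1$.

Choices the model itself does not dictate:

* $H$ is a cosine ramp, zero at DC and one beyond `highpass_freq`
  (default 0.02 cycles/pixel) — smooth, and it prevents the huge DC-adjacent
  SSNR from turning the filter into a pure (noise-amplifying) inverse there;
* the DC coefficient passes unchanged, otherwise $H(0)=0$ would zero the
  volume mean;
* one defocus per tomogram, no depth gradient: the input is an already
  reconstructed volume, and per-voxel defocus correction belongs to
  reconstruction, not restoration;
* CTF sign convention: underfocus positive, negative contrast at low
  frequency, amplitude contrast 0.07 by default.

## Masking and extraction

Subtomograms should come from regions with structure, not vacuum, carbon or
pure ice.  Two statistical masks are intersected: a *density* mask (Gaussian
smoothing, σ = 2 voxels, then a 5³ sliding maximum on the contrast-inverted
volume; keep the top `density_percentage` percent) and a *local standard
deviation* mask (5³ window; keep the top `std_percentage` percent).  Ties at
the percentile threshold are resolved by keeping strictly-above values, so a
constant volume yields an empty mask with a warning rather than an arbitrary
half.  `z_crop` removes that fraction of slices from each of the top and
bottom of the volume, where reconstructions are usually empty.

Extracted cubes are contrast-inverted (density becomes white, the polarity
the network trains on) and normalized per cube so that the 5th percentile
maps to 0 and the 95th to 1 — 90% of voxel values inside $(0,1)$.  The paper
behind this design states only the 90% bracket; the symmetric (5, 95) pair
is our choice and is configurable.  Normalization is per-subtomogram: cubes
from differently exposed tomograms then share one intensity frame.  The
affine transform is recorded so predictions can be mapped back.

## The noise model and schedule

Optionally the network can denoise while it fills the wedge, using a
noisier-input strategy: extra synthetic noise is added to the *input* of each
training pair while the target stays clean.  Because tomographic noise is
not white — each projection's noise is smeared along the beam by
backprojection — the noise volumes are built exactly that way: one iid
Gaussian image per tilt angle (default −60°…+60° in 2° steps), optionally
filtered along the tilt-perpendicular axis (`ramp` = weighted
backprojection, `hamming` = Hamming-rolled ramp, `none` = SIRT-like), then
smeared along the tilted beam direction and accumulated.  The resulting
noise has essentially no power inside the missing wedge — as real
reconstruction noise does not.

The *denoise level* is the ratio of added-noise standard deviation to
subtomogram standard deviation.  The default schedule trains 10 iterations
at level 0, then raises the level by 0.05 every 5 iterations, capped at 0.2
(so iterations 11–15 run at 0.05 and iteration 30 reaches 0.2).  Noise is
drawn fresh each iteration from seeds derived from the master seed.

## Network and training

The restoration model is a volumetric U-net: blocks of three 3×3×3
convolutions with ReLU, a stride-2 convolution after each of the three
encoder blocks (kernel count doubling each time), a three-convolution
bottleneck, and a mirrored decoder using transposed convolutions with skip
concatenations at equal resolution.  The final 3×3×3 convolution is linear
with one channel.  Dropout (rate 0.5) is applied once per block after its
last convolution, during training only.  Where the original description
leaves details open we chose: base width 32 (configurable; small test models
use 8), same-size padding so skips concatenate without cropping, no
normalization layers, and a deliberately small-variance initialisation of
the output convolution so that an untrained model predicts near zero and the
first merge leaves the originals essentially untouched.

Training minimises mean absolute error with Adam at learning rate 4×10⁻⁴,
10 epochs per refinement iteration, batches of 8 by default.  The optimizer
state is reset at each refinement iteration; the weights carry over.
Convolutions are implemented as patch-unfolding plus BLAS matrix products
(the standard im2col construction, here written for 3D), with analytic
backward passes verified against finite differences.  One caveat worth
recording: with zero-initialised biases an untrained network produces
pre-activations that are *exactly* zero wherever a receptive field is fully
ReLU-inactive; at such points the ReLU subgradient is ambiguous and finite
differences straddle the kink, so gradient checks are run with non-zero
biases.

## Refinement and the conservation guarantee

Each refinement iteration: (1) build all 20-rotation training pairs from the
*corrected* cubes of the previous iteration, cropping both members centrally
(cube 96³ → crop 64³ by default) *after* wedge filtering so edge artefacts
are trimmed; (2) add scheduled noise to inputs; (3) train; (4) predict on
the *original* cubes and keep only the predictions' missing-wedge Fourier
content, added onto the originals:

$$ \text{corrected} \;=\; \text{original} \;+\;
   \mathcal{F}^{-1}\!\big[ M_\text{inv} \cdot \mathcal{F}[\text{predicted}] \big] $$

with $M_\text{inv}$ the inverse wedge filter (1 inside the wedge, 0
elsewhere, 0 at DC).  Two consequences: measured frequencies are *never*
modified, at any iteration (the package tests this to 10⁻⁴ relative); and
because prediction always starts from the originals, errors cannot compound
across iterations — each iteration's wedge content is one network
application, not a tower of them.

All per-iteration randomness (pair shuffling, noise draws, dropout masks)
derives from one master seed, so an interrupted run resumed from a
checkpoint reproduces an uninterrupted one exactly.  Corrected cubes and
states are checkpointed per iteration, keeping the latest two by default.
Convergence is reported, not auto-acted-on: the per-epoch MAE and the mean
squared change of corrected cubes between iterations are both recorded, and
the iteration count is fixed (10–15 without denoising, ~30–35 with, in
typical use).

## Whole-tomogram prediction

Full tomograms rarely fit a training-sized input, so prediction uses an
overlap-tile montage: disjoint core regions exactly tile the volume, each
core is predicted from a window extended by `margin` voxels of real context
on every side (default `crop_size/4`), and only the core is written back —
every output voxel written exactly once.  Boundary windows read from a
reflect-padded copy.  A single tomogram-level percentile transform (not
per-tile) provides one intensity frame so tiles cannot disagree about
contrast.  The montage is the raw network output (de-normalized); merging
with the original spectrum at whole-tomogram scale is available as an option
but is not the default.  Note that stride-2 layers are only equivariant to
even shifts, so tiles whose windows sit at odd offsets can differ from a
hypothetical whole-volume pass by a small amount near core borders; the
margin absorbs this, and the identity-model montage is exact by
construction.

## Validation

Resolution claims use Fourier shell correlation between two reconstructions
produced by *independently trained* halves of the subtomogram set
(gold-standard protocol; `extract(..., split = TRUE)` records the halves).
Beyond the global FSC, `conical_fsc()` restricts correlation to a double
cone (default half-angle 20°, one-voxel shells) about a chosen axis, and
`gold_standard_3dfsc()` crops matched cubes from the two half-volumes,
computes per-direction curves over a hemisphere of cone axes, averages over
cubes, and reads out per-direction resolutions at the 0.5 and 0.143
cutoffs.  Narrow cones contain no voxels in the lowest shells; those shells
are reported `NA` rather than invented.  Resolution readout interpolates the
first downward crossing linearly; curves that never cross report the Nyquist
resolution ($2 \times$ pixel size) and curves below the cutoff from the first
shell report the lowest shell, flagged.

## The synthetic benchmark

Because real benchmark data cannot ship with a package, ground truth comes
from procedural phantoms: hollow sphere-shells (whose caps vanish under the
wedge), random tubes, Gaussian assemblies and sphere lattices, each
band-limited to a stated fraction of Nyquist (default 0.6) with a
raised-cosine edge and seeded for exact reproducibility.  A benchmark run
rotates the phantom into $n$ random orientations (trilinear interpolation,
mirror padding — the one interpolating rotation in the package) and imposes
the wedge on each copy, retaining the clean rotated copies for scoring.
`recovery_score()` reports the real-space Pearson correlation plus
normalized spectral correlations over the wedge and non-wedge supports
separately: a merely wedge-filtered volume scores ≈ (high, 0, 1), a restored
one should raise the middle number.  An optional hook accepts any
user-supplied MRC map as ground truth in place of a phantom.

What the phantoms do *not* emulate: CTF corruption, realistic molecular
crowding, detector statistics, or alignment errors.  Passing the synthetic
suite shows the machinery restores wedge information it has never seen under
the stated noise model; it does not certify biological fidelity on real
specimens, which is what the gold-standard FSC tooling is for.

## Problem sizes used by the test-suite

Tests run the full pipeline at deliberately small scale, chosen as the
smallest sizes at which each property is meaningful: 16³ cubes with an
8³ crop and a depth-1, base-2 model for orchestration properties;
a 32³ tube phantom, 10 orientations, a depth-2/base-8/two-convolution
model with 16³ crops, two epochs per iteration and 5 iterations for the
recovery benchmark (three seeds, majority criterion); 200³ volumes for the
overlap-tile montage.  Two epochs per iteration matter here: with the
optimizer reset at each iteration, a single epoch leaves early iterations
under-converged enough to wobble the recovery trajectory.  Dropout is disabled in the scaled recovery runs —
halving an 8-channel model's activations mostly adds variance at this size —
and enabled in the tests that specifically exercise it.

## Known limitations

* Single-axis geometry only; dual-axis ("missing pyramid") sampling is out
  of scope.
* One defocus per tomogram in deconvolution; no depth-dependent CTF.
* The training loop is CPU-bound R/BLAS; it is sized for method validation
  and small studies, not for production-scale 96³ × 300-cube refinements,
  which belong on GPU implementations of the same algorithm.
* No per-tilt dose weighting of the wedge filter; every sampled direction is
  weighted 1.
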