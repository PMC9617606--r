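# tomowedge

Self-supervised missing-wedge compensation and denoising for cryo-electron
tomograms, in R.

Single-axis cryo-ET tilts the specimen about the Y axis over a limited range
(typically ±60°), so two wedge-shaped regions of 3D Fourier space around the
beam axis are never measured. The resulting *missing wedge* elongates every
feature along Z and erases membranes normal to the beam. `tomowedge` fills
that wedge by training a volumetric U-net **on the tomograms themselves** —
no ground truth, no external training data:

1. **Extract** subtomogram cubes from the tomogram (optionally after Wiener
   CTF deconvolution and statistical masking of empty regions).
2. **Refine**, iteratively: rotate each cube by the 20 cube-group rotations
   that move its wedge to a new orientation, impose the standard wedge on
   the rotated copy, and train the network to map the doubly-corrupted input
   back to the singly-corrupted target (mean absolute error, Adam, lr
   4·10⁻⁴). After training, predict on the *original* cubes and keep only
   the predictions' wedge-region Fourier content:

   `corrected = original + F⁻¹[ M_inv · F(predicted) ]`

   where `M_inv` is 1 inside the wedge and 0 elsewhere. Measured
   frequencies are never modified and errors cannot accumulate across
   iterations. An optional noisier-input schedule (level 0 for 10
   iterations, then +0.05 every 5 up to 0.2) adds
   reconstruction-consistent noise — 2D Gaussian images backprojected
   through the tilt range — to the inputs so the same network also
   denoises.
3. **Predict** whole tomograms with an overlap-tile montage (disjoint cores,
   margin of real context, every voxel written once).
4. **Validate** with gold-standard FSC between halves processed by
   independently trained networks, including conical/3D FSC and resolution
   readout at the 0.5 and 0.143 cutoffs.

The CTF deconvolution uses the Wiener filter `W = CTF/(CTF² + 1/SSNR)` with
the empirical model `SSNR(f) = e^(−f·100F) · 10^S · H(f)` (`F` =
`snrfalloff`, `S` = `deconvstrength`, `H` a cosine-ramp high-pass).

Everything is plain R plus a small amount of RcppArmadillo (the 3D
convolution kernels are im2col + BLAS, with hand-derived backward passes);
volumes travel as MRC2014 files and metadata as RELION-dialect STAR tables.

## Worked example

Simulate the classic benchmark — a band-limited phantom rotated into ten
random orientations, each wedge-corrupted — then refine for three iterations
with a small model and score the recovery:

```r
library(tomowedge)

phantom <- make_phantom(32, "tube", rng_seed = 7)
bench   <- simulate_benchmark(phantom, n_orientations = 10,
                              wedge_spec(-60, 60), rng_seed = 1)

recovery_score(bench$corrupted$cubes[[1]], bench$truth[[1]], wedge_spec())
#>     real_r    wedge_r nonwedge_r
#>      0.745      0.015      1.000

state <- refine(bench$corrupted, iterations = 3,
                cfg = refine_config(crop_size = 16, keep_iterations = 0),
                train_cfg = train_config(epochs_per_iteration = 1, batch_size = 8),
                model_cfg = unet_config(depth = 2, convs_per_block = 2,
                                        base_channels = 8, dropout_rate = 0),
                master_seed = 1)

recovery_score(state$corrected$cubes[[1]], bench$truth[[1]], wedge_spec())
#>     real_r    wedge_r nonwedge_r
#>      0.842      0.686      1.000
```

The three numbers are Pearson correlations with the ground truth: overall
real-space, Fourier *wedge region only*, and Fourier non-wedge region. The
corrupted input starts with essentially zero wedge correlation (0.015);
three refinement iterations raise it to 0.69 while the non-wedge (measured)
content stays at 1.000 — the conservation guarantee at work. The per-
iteration mean-squared change of the corrected cubes
(`state$mse_history`: 0.0386, 0.0267, 0.0020) tracks convergence.

A command-line wrapper mirroring the workflow
(`prepare_star`, `deconv`, `make_mask`, `extract`, `refine`, `predict`,
`simulate`, `fsc3d`) is installed at
`system.file("scripts", "tomowedge", package = "tomowedge")`; every run
writes a JSON manifest of its resolved parameters, and `--print_only` echoes
the command without executing it.

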