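---
title: "Self-supervised equivariant restoration of cryo-electron tomograms: models and methods"
author: "equitomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised equivariant restoration of cryo-electron tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

A cryo-electron tomogram is reconstructed from a tilt series: projection
images of a frozen specimen acquired while the stage tilts about one
axis, typically from -60 to +60 degrees. Two corruptions dominate the
result. First, the electron dose per tilt must stay minuscule, so the
data are extremely noisy (signal-to-noise ratios well below one are
normal). Second, the stage cannot tilt to +/-90 degrees, so a
wedge-shaped region of 3D Fourier space is never measured; filtered
backprojection (FBP) fills it with zeros, which appear in real space as
anisotropic smearing and streaking -- the *missing wedge*.

`equitomo` restores tomograms from **pairs of independently noisy FBP
reconstructions** of the same specimen, with no clean reference, by
combining two self-supervision signals:

1. **Noise2Noise data fidelity.** Two reconstructions `y0`, `y1` whose
   noise is independent (from splitting detector frames or tilt angles)
   are mutual targets: a network `f` minimising
   `E || f(y0) - y1 ||^2` converges, in expectation, to the estimator it
   would learn against the clean signal, because the independent noise
   contributes only an additive constant to the risk. The package's test
   suite verifies this decomposition by Monte Carlo.
2. **Rotation-equivariance.** The data-fidelity term constrains `f` only
   inside the observed region of Fourier space. The wedge is constrained
   by a symmetry argument: the distribution of subtomograms is (to a
   useful approximation) invariant under rotations, while the wedge
   operator is not. Let `A` be the orthogonal projector that zeroes the
   wedge, `G` the 40-element group of interpolation-free rotations and
   flips of a cubic grid, and `R_g` the action of `g` on volumes. With
   plug-in estimates `x0 = f(y0)` and `x1 = f(y1)` the equivariance
   residual for a sampled `g` is

   `r_g = A_g ( f( A( R_g x0 ) ) - R_g x1 )`,

   where `A_g = R_g A R_g^-1` and the outer masking by `A_g` (the
   original wedge transported by the rotation) restricts the comparison
   to frequencies where the rotated plug-in target carries measured
   content; it can be disabled (`mask_original_wedge = FALSE`), which
   reduces the term to the plain equivariant-imaging residual. Because
   the rotation moves *observed* content into the *missing* orientation,
   the network receives genuine supervision for wedge filling. The
   second application of `f` inside the residual is essential; gradients
   flow through both applications (a `detach_plugin` ablation switch
   exists).

The total objective is `L = L_N2N + lambda * L_equi` with
`lambda = 2` by default. At inference the trained network is applied
**twice**: the first pass denoises each half-tomogram (the two denoised
halves are averaged), the second pass, run on the averaged output,
improves the wedge fill -- mirroring how the equivariance term sees
denoised volumes during training.

## The rotation group

The group contains the 24 proper rotations of the cube minus the
identity and the three axis-aligned 180-degree rotations (20 elements;
edge-axis 180-degree rotations are kept -- this is the only counting
consistent with a 40-element group after adding flips), each also
composed with a fixed mirror (reversal of the x axis), for 20 improper
elements. All act on voxel grids as signed permutations about the patch
centre: pure index rearrangement, no interpolation, so voxel values are
preserved bitwise. In frequency space the same elements act by index
permutation with modular negation, which is how the rotated projectors
`A_g` are built directly from the wedge mask; the conjugation identity
`A_g = R_g A R_g^-1` is verified exhaustively in the tests.

## Operators and conventions

* **Coordinates.** 1-based indices with inclusive crop ranges and axis
  order (x, y, z), matching R's native array indexing. The tilt axis is
  y; the beam at zero tilt runs along z.
* **Wedge mask.** A frequency voxel is observed iff the line through its
  (kx, kz) coordinates lies within `[theta_min, theta_max]` of the kx
  axis. The mask is binary (a hard-edged orthogonal projector), constant
  along ky, Hermitian-symmetric by explicit sign symmetrization (on even
  grids the Nyquist row is its own negation partner, which a naive angle
  test misses), and has the zero frequency observed. Gaps between
  discrete tilt angles are treated as observed: the discrete radial
  sampling is the simulator's business, not the projector's. A cosine
  `rolloff` (degrees) is available but off by default.
* **Projection and FBP.** Implemented in Fourier space via the central
  slice theorem, with the rotation centre at the phase origin. The
  (x, z) plane is oversampled twofold and oblique slices are sampled
  with a width-6 Kaiser-Bessel kernel plus deapodization -- plain
  bilinear interpolation of the oscillating complex spectrum is not
  accurate enough to meet the package's own round-trip accuracy target
  (`fbp(project(v))` NRMSE below 5% on a smooth phantom). The FBP
  scatters unit-spaced slice samples with a width-4 kernel, normalises
  every frequency voxel by its accumulated weight, decimates back to the
  target grid (so never-touched wedge voxels stay exactly zero), and
  divides out the kernel's discrete transform. Wedge-interior energy
  measurements exclude a 2-voxel boundary shell, the region a gridding
  kernel inevitably touches.
* **Precision.** Network convolutions run in single precision by default
  (`mixed_precision`, the CPU counterpart of reduced-precision training
  on GPUs; a double-precision mode exists and is used by the gradient
  checks). All FFT-based operators always run in double precision.

## The network

The restoration claims are architecture-agnostic, so the network is a
pluggable component behind `network_spec()`: a residual 3D U-Net with
3x3x3 convolutions, leaky-ReLU activations, average-pool downsampling,
nearest-neighbour upsampling, additive skips and a 1x1x1 output head.
Forward and backward passes are hand-derived and verified against
central finite differences at double precision, both for the network in
isolation and through the full combined objective (wedge projector and
grid rotations included). The
package default is depth 3 with 16 base channels. The desk-scale
protocol used by the tests and the acceptance script is depth 2 with 4
base channels (~4k parameters): on a single CPU this trains in minutes
while still showing all the qualitative behaviour of the method --
strong denoising and a clear increase of wedge-region spectral
correlation with the ground truth. Much larger networks are appropriate
on GPU-scale hardware but are not exercised here.

## Training

`train()` minimises the combined objective with Adam (default learning
rate 4e-4; the short desk-scale runs use 3e-3, appropriate for the tiny
network and 300-500-iteration schedules). Per batch example it samples a
source tomogram, a patch centre inside the interest mask, one group
element uniformly from the 40, and a random assignment of the two
observations to source/target roles (the losses themselves expose fully
symmetrised variants; the training loop uses the cheaper random-swap
form). Protocol defaults mirror the intended production scale: patch 72,
batch 8, 50000 iterations, `lambda = 2`, fine-tuning budget 5000. A
moving-average plateau rule (`plateau = list(window, tol)`) is available
but off by default; training otherwise runs its fixed budget.
Everything is deterministic given the seeds; two runs with one seed
yield identical loss histories.

Normalisation is per tomogram pair (joint mean/sd over both halves, so
the pair stays on one intensity scale), with the statistics retained for
inverse mapping at inference.

## The simulator and what it does (not) show

`generate_phantom()` builds additive scenes of spherical shells
(membranes), straight rods (filaments) and gaussian blobs (globular
particles) at random poses with a minimum mutual separation, on a
constant background. `generate_paired_dataset()` projects each phantom
through the tilt scheme, corrupts two copies with independent noise, and
reconstructs both by FBP -- exactly the observation model the losses
assume. Default desk-scale conditions: 48^3 volumes, a -60..+60 degree
scheme at 3-degree steps, and gaussian noise with standard deviation
twice the clean projections' standard deviation, which lands the FBP
volumes at a signal-to-noise ratio near 0.2, typical of cryo-ET.

The simulator deliberately omits CTF, detector MTF, beam-induced motion
and alignment error. Passing tests therefore demonstrate the
self-supervision mechanics (noise cancellation, wedge filling,
equivariance) under the stated acquisition model -- not performance on
real micrographs, which additionally depends on those unmodelled
effects.

## Numerical choices and degenerate inputs

* Projector identities are asserted at 1e-5 relative tolerance.
* Patch sizes must be divisible by `2^(depth-1)`; inference pads
  volumes reflectively instead of erroring, and crops back.
* Stitching uses raised-cosine windows tapered only on overlapped,
  non-border margins and renormalised voxelwise: an exact partition of
  unity, so an identity network reproduces its input bitwise up to
  floating-point addition order.
* Zero-variance tomograms, empty interest masks, out-of-bounds crops,
  overlapping split assignments, non-finite losses and malformed MRC
  headers all raise immediate, named errors.
* The wedge-interior metrics (`wedge_energy_ratio`,
  `wedge_correlation`) erode the missing region by 2 frequency voxels
  in (kx, kz) so that gridding-kernel leakage at the wedge boundary is
  not mistaken for restored signal.

## Design choices that were genuinely open

* **Flips.** "Rotations plus flips" is realised as composition with one
  fixed mirror, which is the only choice that gives exactly 20 improper
  elements (all eight sign patterns would give more).
* **Masking placement.** The wedge mask `A_g` is applied to the
  equivariance *residual*; the recorrupted input uses the unrotated
  projector `A` on the rotated plug-in estimate. With masking disabled
  the term reduces (verified by a unit test) to the plain
  equivariant-imaging form.
* **Averaging point at inference.** With two half-tomograms the two
  denoised first-pass outputs are averaged *between* the passes, so the
  second (wedge-refining) pass sees the highest-SNR input available.
  A `passes = 1` variant exists; on wedge-corrupted data it produces a
  measurably different (worse-constrained) result.
* **Angle-split parity.** Even-indexed tilts to split 0, odd to split 1:
  deterministic, balanced, and interleaved so both halves span the full
  angular range.
* **Checkpoints** are self-describing R serialisations (spec +
  parameters + iteration); loading validates structural compatibility
  and names mismatched fields.

## Problem sizes used by the test suite

The suite exercises the full pipeline at sizes a laptop CPU handles
comfortably: operator tests at 8^3-64^3; smoke training at 48^3 with
patch 48, batch 4, 300 iterations, three seeds; the warm-start
comparison at 32^3 with patch 16, batch 2, one 500-iteration
pretraining on a blob-only phantom family and five paired 500-iteration
runs on a held-out membrane-and-filament family. These sizes are the
package's chosen desk-scale study conditions; the qualitative
conclusions (loss descent, PSNR gain, wedge-correlation gain, warm-start
advantage) are the same ones expected at production scale, with the
caveats of the simulator section above.

## Known limitations

* The interest-mask builder (central slab + local-variance quantile) is
  a lightweight stand-in for dedicated lamella-detection tools; users
  with curated masks should pass them through the `mask` argument or the
  `prepare` CLI.
* The rotation group is the finite interpolation-free subgroup, not
  continuous SO(3); content whose symmetry axis is far from every group
  element's is constrained more weakly.
* Fourier-domain projection assumes the specimen is fully inside the
  reconstruction box; wrap-around from content at the volume border is
  suppressed by the twofold oversampling but not eliminated.
* The FBP simulator is not bit-compatible with any external package;
  real tomograms reconstructed elsewhere are accepted as inputs and do
  not need to match it.
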