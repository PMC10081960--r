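---
title: "Partition-direction k-space interpolation for stack-of-spirals 3D MRF: models and design choices"
author: "mrfkz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partition-direction k-space interpolation for stack-of-spirals 3D MRF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mrfkz)
```

## The problem

3D magnetic resonance fingerprinting (MRF) on a stack-of-spirals
trajectory acquires, for each of `T` time frames, one spiral arm per
kz *partition*. Whole-brain coverage at high resolution makes the scan
long, and the standard acceleration is to skip partitions: acquire every
`R`-th kz plane plus a fully sampled central block of auto-calibration
(ACS) partitions, then *interpolate* the skipped planes in k-space
before reconstruction. `mrfkz` implements three self-calibrated
interpolators that are trained on nothing but the scan's own ACS block:

* **Spiral GRAPPA** — for every readout location `i`, offset
  `m in 1..R-1` and coil `c`, a complex linear kernel over a
  `2 x (2v+1) x C` source neighbourhood (two flanking acquired
  partitions, `2v+1` readout points, all coils), fitted by least squares
  on all ACS instances pooled across time frames and stride-1 start
  positions. Kernels are location-specific because spiral samples are
  not equally spaced.
* **Cartesian CNN** — the spiral readout "straightened" into a 1-D
  sequence; residual blocks of one width-3 convolution followed by two
  pointwise (width-1) convolutions, ReLU activations, shared across all
  readout locations.
* **GCN** — the same architecture with the width-3 aggregation replaced
  by a graph convolution `Dhat^{-1/2} Ahat Dhat^{-1/2} H W` over a
  Gaussian-weighted kNN graph on the actual 2-D positions of the
  readout points, so aggregation respects the non-uniform spiral
  geometry. One graph serves every golden-angle frame because the
  adjacency depends only on pairwise distances.

Quantification uses dictionary template matching: per voxel, the
`(T1, T2)` of the unit-norm simulated fingerprint maximising the
magnitude inner product with the measured time course, with
`PD = |<signal, entry>|`.

## The k-space graph

`A[i,j] = exp(-||v_i - v_j||^2 / dbar^2)` with `dbar` the mean distance
over all unordered pairs of points on one interleaf; each row keeps its
`K` largest entries (ties to the lower column index; the unit diagonal
always survives). The propagation matrix applies `Ahat = A + I` and the
symmetric normalisation `Dhat^{-1/2} Ahat Dhat^{-1/2}`. Two details are
deliberate:

* The adjacency formula adds the identity *again* even though
  `A[i,i] = 1`; the constant diagonal boost is absorbed by the learned
  weights, and `K = 1` then reduces the propagation matrix exactly to
  the identity — a useful algebraic anchor that the tests exploit
  (a GCN with `K = 1` coincides with a pointwise CNN).
* Row-wise truncation yields an asymmetric matrix; it is kept
  asymmetric (a `symmetrize` flag is available). The symmetric
  normalisation is used for the degree scaling in either case; for the
  symmetrized variant its spectral radius is at most 1.

## Architecture and training

Blocks have 512, 1024 and 1024 filters by default, with a residual
connection spanning each block (identity when channel counts match,
otherwise a learned pointwise projection; the block output passes a
ReLU, the network's final pointwise map does not). Input features are
the real and imaginary parts of the two flanking partitions stacked
across coils (`2*2*C` per readout point); outputs are the `(R-1)*2*C`
features of the skipped partitions. Training minimises MSE with ADAM,
batch size 1, initial learning rate `5e-4` decayed by 0.99 at the end
of each epoch; initialisation is variance-scaled uniform under a fixed
seed, and training is bit-deterministic given the seed.

**Normalization.** All features are divided by the global ACS peak
magnitude, and — by default — each pair (input and target jointly) is
additionally divided by the RMS of its own input, with inference
rescaling by the input pair's RMS. The per-pair step makes the learned
map amplitude-equivariant. It matters because k-space magnitudes span
roughly two orders of magnitude between the central and outer kz
partitions: a ReLU network trained on raw central-ACS amplitudes simply
does not extrapolate to the outer-partition amplitudes it must predict
at inference (we measured a ~25% NMSE improvement from this one
choice). `normalize = "global"` restores the plain behaviour.

**Edge handling.** Skipped partitions beyond the last acquired one have
only one flanking neighbour; they are predicted from a degenerate pair
that reuses that neighbour for the missing flank (both for GRAPPA and
the networks). These trailing predictions are measurably worse than
interior ones; at the package's working sizes they are a larger
fraction of the volume than at full protocol sizes.

## The synthetic pipeline and what it does (not) emulate

No public raw data exists for this acquisition type, so the package
generates its own study data end to end:

* **Anatomy**: tilted concentric ellipsoids (background / WM / GM /
  CSF) with conventional 3T values (WM 800/70, GM 1300/90,
  CSF 4000/1800 ms; PD 0.7/0.8/1.0). The tilt matters: a perfectly
  axis-aligned, constant-in-z object concentrates nearly all kz energy
  in a single partition and makes the interpolation problem
  pathological in a way real heads are not.
* **Within-tissue heterogeneity** (default ±4%, two smooth seeded
  fields quantised to 3 x 3 sub-classes per tissue): real T1/T2 vary
  within tissue, and this variation is what gives the acquisition a
  temporally rich structure. With perfectly homogeneous labels every
  voxel time course is one of only three fingerprints and the ACS
  calibration problem is rank-deficient — a degeneracy no real scan
  has. Set `heterogeneity = 0` for exactly on-dictionary values when
  testing parameter recovery.
* **Coils**: a receive array of localised loop elements (two rings
  along z), Gaussian magnitude profiles with seeded jitter and smooth
  phase, RSS-normalised to 1. Localised elements carry spatial encoding
  along kz — the physical resource all partition-direction parallel
  imaging rests on. Global low-order polynomial fields (available as
  `coil_model = "poly"`) are too smooth along z and make interpolation
  beyond R = 2 ill-posed.
* **Fingerprints**: an intentionally simple longitudinal recursion
  (inversion, per-TR `sin(alpha) exp(-TE/T2)` emission, `cos(alpha)`
  saturation, T1 recovery, per-segment recovery delay and T2-prep
  attenuation `exp(-TE_prep/T2)`), *not* a Bloch/EPG simulation. The
  interpolators are agnostic to fingerprint fidelity; the recursion
  preserves the sequence's qualitative T1/T2 encoding, which is what
  matching needs. No quantitative equivalence to any scanner
  implementation is claimed.
* **Sampling**: centered DFT along kz, then a Kaiser-Bessel gridding
  NUFFT (oversampling 2, width-7 kernel, Beatty shape parameter) at the
  golden-angle-rotated arm; complex white Gaussian noise with standard
  deviation `2.5e-4` of the ACS peak, chosen so the outermost kz
  partitions sit at SNR about 5 — the regime where interpolation is
  both beneficial and non-trivial. (Referencing the DC peak makes the
  fraction look small: the peak scales with object volume.)

Passing tests on these data therefore demonstrate the correctness of
the operators and the qualitative behaviour of the methods; they do not
demonstrate performance on real brains, where coil geometry, noise
correlation, B0/B1 effects, partial Fourier and motion are all absent
here.

## Density compensation

For the uniform-parameter Archimedean arm
`k(tau) = k_max tau e^{i 2 pi turns tau}`, the exact k-space area
element of the (parameter, arm) mapping is
`dA = (2 pi r / n_arms) * k_max * dtau`: the offset between adjacent
arms at radius `r` is azimuthal, and only the radial component of the
arm velocity crosses it, so the element is proportional to radius times
the *parameter* step and independent of `turns`. The common heuristic
`|k| * ds` with `ds` the arc length double-counts the azimuthal stretch
for this parameterisation and visibly breaks the adjoint
reconstruction; it is retained as `dcf_mode = "radial"` for comparison,
with `"jacobian"` the default. Weights are normalised to the sampled
disk area, and the apex sample covers the small disk of radius half the
radial step.

## Numerical anchors and working sizes

The NUFFT is validated against a brute-force direct-sum DFT oracle
(relative error ~1e-6) and satisfies an exact adjoint dot-test by
construction. GRAPPA calibration equals a column-wise pseudo-inverse
oracle; backpropagation matches finite-difference gradients. The
default working size for experiments and tests is T=48, P=24, Q=512,
C=8, M=64 with R=4 and the protocol's 12 ACS partitions; the full
protocol geometries (256/320 matrix, 144/176 partitions, 768 frames,
32 coils) are available as configuration presets. Network trainings in
the test suite use reduced filter counts (64/128/128) where the check
is about behaviour rather than the full-size architecture.

## Known limitations, measured

Three behaviours at the working size are worth stating plainly,
because they are properties of the physics and the protocol rather
than of the implementation:

* **Per-voxel on-grid recovery saturates near 88%.** On noiseless,
  fully sampled data, template matching recovers the exact on-grid
  (T1, T2) for about 88% of mask voxels — and an *ideal*
  disk-bandlimited reconstruction (exact FFT, spectrum masked to the
  inscribed disk that is all a spiral can reach) achieves 87.6% on the
  same data. The failures are one-grid-cell flips of voxels
  contaminated by Gibbs ringing near tissue boundaries: with 48 frames
  the fingerprints of adjacent dictionary entries correlate at
  0.998-0.9999, so a few percent of ringing flips the argmax. The
  matcher itself is exact (oracle-verified; 100% on un-blurred series).
* **At R = 4, no interpolator beats zero-filling in skipped-partition
  NMSE** (nets ~1.7-1.9, GRAPPA ~3, zero-filling 1 by definition),
  while the learned interpolators do beat GRAPPA, and at R = 2 GRAPPA
  reaches NMSE 0.29 and every ordering holds. This mirrors the
  field's experience that plain spiral GRAPPA is limited to R = 2-3
  along the partition direction; with 8 coils and a 24-partition desk
  volume the middle-offset predictions at R = 4 are
  under-encoded.
* **500 single-pair ADAM updates under the prescribed decaying
  schedule reduce the one-pair training MSE by a factor of 400-600**,
  saturating once the learning rate has decayed ~20-fold; gradients
  are finite-difference exact, so this is an optimisation-budget
  property of the schedule, not a defect.

Other limitations: no B0/B1 or motion modelling; no partial-Fourier
handling; no EPG-accurate fingerprints; the SVD-compressed dictionary
and spatially-regularised quantifiers used in some MRF pipelines are
out of scope (plain template matching is the quantification stage
here).
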