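---
title: "Atlas-based 4D flow analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-based 4D flow analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science inside `flow4d`: the models each
stage implements, the tunable parameters and why their defaults are what
they are, what the synthetic phantoms do and do not emulate, and the
numerical choices a careful user should know about.

## The analysis problem

4D flow CMR reconstructs, for each of ~20 cardiac frames, a signal
magnitude volume `M` and three velocity-component volumes `Vx, Vy, Vz`
(cm/s) on a common grid (typically ~2.7 mm voxels, ~50 ms frames,
VENC 120 cm/s). Flow in any vessel can be measured retrospectively —
provided the vessel is segmented in every frame and an analysis plane is
placed through it. `flow4d` automates both steps by deforming a labelled
reference (atlas) onto each subject and integrating through-plane
velocities at atlas-defined planes.

## Velocity preprocessing

**Temporal unwrapping.** Velocities map to phase linearly with ±VENC at
±π, so true speeds beyond VENC alias by `2·VENC`. Scanning each voxel's
series in time order from an anchor frame assumed alias-free (frame 1 by
default: with retrospective gating the cycle starts at the R wave, where
speeds are lowest relative to a 120 cm/s VENC), any successive jump
larger than VENC is corrected by the nearest multiple of `2·VENC` and
propagated. The pass is idempotent and only ever changes values by exact
multiples of `2·VENC`. It cannot fix a series whose anchor frame is
itself aliased — a limitation shared by any purely temporal scheme.

**Background phase correction.** Residual eddy-current offsets vary
smoothly in space; they are modelled per velocity component as a full
2nd-order 3D polynomial (10 terms) in per-axis normalized coordinates
(`[-1, 1]`, for conditioning) and fitted by weighted least squares to
the temporal-mean velocity of *static tissue*. Because no ground-truth
static map exists, static tissue is detected as voxels with usable
signal (time-mean magnitude ≥ `mag_frac = 0.1` of the volume's 95th
percentile — a fraction low enough to keep dim parenchyma, high enough
to reject air) whose temporal speed standard deviation is at most
`vel_std_max = 2` cm/s (well below any pulsatile lumen, above typical
noise). Weights fall linearly from 1 at zero variation to 0 at the
threshold. The fit refuses rank-deficient designs (fewer than 10
usable voxels, or voxels confined to a plane).

## Angiography and frame selection

The PC-MRA combines the frame-averaged magnitude with the norm of the
frame-averaged velocity: `PC-MRA = M̄·sqrt(V̄x²+V̄y²+V̄z²)`. Averaging the
*components* before the norm is deliberate: oscillating or opposing flow
cancels, and `M̄` suppresses regions with no signal (lungs, air).

The systolic window is not annotated in the data, so it is derived from
a per-frame scalar signal: the volume mean of `M·speed`, the
single-frame analogue of the PC-MRA product. Frames reaching
`systolic_frac = 0.7` of the curve maximum form the systolic set; the
argmax is the *peak frame*. A relative threshold adapts to waveform
shape; 0.7 keeps the 3–6 frames around peak systole for typical
half-sine-like waveforms. Both the magnitude-only and product criteria
are implemented (`frame_signal_curve(use=)`); the product is the default
because the peak frame should best resemble the PC-MRA-built atlas.

## Registration

**Affine stage.** A 12-parameter transform acting about the grid centre
is optimized against `1 − NCC` (normalized correlation) over a
coarse-to-fine Gaussian pyramid (smooth, decimate by 2; coarsest level
≥ 8 voxels). BFGS with numerical gradients runs at every level; most of
the work happens at the cheap coarse levels. If the optimum is not
materially better than the identity the exact identity is returned —
ties must not introduce spurious subvoxel shifts, and a genuinely worse
optimum is flagged as divergence.

**Non-rigid stage (Morphon-style).** Per iteration, on the shared grid
in voxel units:

1. *Local displacement estimation.* Directional-gradient matching along
   six fixed orientations (the three axes and three face diagonals):
   for orientation `n̂ₖ`, `gₖ = n̂ₖ·∇`, certainty `cₖ = gₖ²`, and a
   per-orientation displacement `δₖ = (T − S_w)·gₖ/(gₖ² + (T − S_w)² + λ)`.
   The `(T − S_w)²` term (Thirion-style) bounds the step where the local
   linearization is unreliable; `λ = 0.01·max‖∇‖²` suppresses updates in
   regions with no structure. The per-voxel 3×3 system
   `Σ cₖ n̂ₖn̂ₖᵀ u = Σ cₖ δₖ n̂ₖ` is solved in closed form; steps are
   capped at 0.8 voxels.
2. *Fluid regularization:* certainty-weighted Gaussian smoothing
   (normalized convolution) of the increment, `sigma_fluid = 2.0`
   voxels.
3. *Diffeomorphic accumulation:* the increment is **composed** with the
   running field, `d ← u + d(x + u)` — never added voxel-wise — so the
   accumulated deformation compresses and stretches without tearing or
   folding.
4. *Elastic regularization:* certainty-weighted Gaussian smoothing of
   the accumulated field, `sigma_elastic = 1.5` voxels, followed by a
   safety check that re-smooths in the rare case the interior Jacobian
   determinant approaches zero.

The gradient-based estimator stands in for the original Morphon's
quadrature-filter phase differences: it preserves the iterative,
certainty-weighted, orientation-decomposed character while being fully
specified in a few lines. A consequence worth knowing: repeated elastic
smoothing biases recovered deformation *amplitudes* low in regions the
images do not constrain (the aperture problem), which is why endpoint
errors are quoted inside object support.

Scale schedules follow the two use cases: **3 scales × 5 iterations**
for atlas fitting (large, smooth anatomical differences) and **5 scales
× 5 iterations** for frame-to-frame propagation (small differences
needing fine sensitivity). Temporal propagation registers structure-
tensor **edge maps** (Frobenius norm of the Gaussian-averaged gradient
outer product) rather than raw magnitudes: the edge representation is
invariant to affine intensity rescaling between frames, which is what
varies most across the cycle. Atlas fitting registers raw PC-MRAs, where
intensities are already commensurate. The regularization widths are
package choices (exposed in `reg_params()`); the scale/iteration counts
and linear interpolation are the method's stated operating point.

**Convention.** All fields are pull-back (`target point x samples the
source at x + d(x)`), stored in world mm on the target grid. Forward
mapping of atlas points (for planes) goes through fixed-point field
inversion (`invert_field`, tolerance 0.01–0.05 voxels), whose
composition residual is reported. Frames are each registered to the
peak frame *independently*, never chained, so a single bad frame cannot
contaminate its neighbours.

**Divergence.** A fit whose final objective is no better than the
identity — or whose residual similarity falls below `min_ncc = 0.25`,
an absolute floor catching subjects with no overlapping structure —
raises `"unreliable registration"` rather than returning garbage. The
floor extends the objective-vs-identity rule because on pure noise the
optimizer can always buy a marginal correlation improvement.

## Plane flow

Deformed plane point sets are flattened by PCA (centroid + first two
principal directions; the normal's sign follows the pre-deformation
normal so downstream flow stays positive). The in-plane vessel mask
(nearest-label lookup of the time-resolved segmentation — labels are
categorical, interpolating codes would be meaningless) is convolved with
a normalized disk of radius 9 lattice pixels and kept where the response
reaches `keep_frac = 0.1`, making the region rounder and slightly
larger; since the pixels just outside a vessel carry near-zero
velocities, the enlargement barely moves the net volume (checked to
≤ 2% under a further 2-pixel dilation) while guaranteeing no high-
velocity pixel is lost. The lattice spacing defaults to half the
smallest voxel (Nyquist for the velocity field); the 9-pixel radius is
interpreted in these lattice pixels. Flow rate is the masked sum of
through-plane velocity times pixel area (`cm/s·mm² → ml/s` via 0.01);
the net volume uses the rectangle rule with the acquired frame duration
— exact for retrospectively gated data, whose equal frames tile the
cycle.

## The phantom generator

Phantoms emulate the target acquisition: 64³ voxels at 2.7×2.7×2.8 mm,
20 frames of 52.8 ms, VENC 120 cm/s (`grid = "clinical"`), with a 32³
preset (`grid = "fast"`) for quick checks. Geometries are straight
tubes, two parallel tubes, a Y-bifurcation (branch radii `0.75R`, peak
velocities scaled so branch flows sum exactly to the trunk flow), and a
curved tube. Flow is laminar Poiseuille (`v(r) = v_max(1 − r²/R²)`)
modulated by a half-sine systole of 0.3 s within the cycle — so every
plane has the closed-form truth `V = (v_max·πR²/2)·∫w dt`. Magnitude is
three-valued (lumen 100, an 8 mm static-tissue shell 40, background 2).
Optional corruptions: bulk sinusoidal motion or radial pulsation
(geometry re-evaluated analytically per frame, truth recorded), Gaussian
velocity/magnitude noise, a quadratic background offset, and aliasing
injection beyond VENC — each exactly invertible by the corresponding
preprocessing stage in the noise-free case, which is what the
exactness tests exploit.

Velocity is assigned from the analytic profile at each voxel *centre*,
with no subvoxel averaging: partial-volume effects at the wall are
therefore sharper than in a real scan, but the truth stays analytic and
the remaining discrepancy is honest discretization error (the 3–5%
tolerances on flow recovery absorb it; measured error on the
acquisition-matched grid is ≈ 0.5%).

What the phantoms do **not** emulate: turbulence, valve jets, CFD-
realistic secondary flow, k-space/SENSE artefacts, contrast variation,
and anatomy-scale inter-subject shape differences. Passing tests
demonstrate the pipeline's geometric and numerical correctness, not
clinical-grade robustness to pathology — on real data the atlas fit is
the fragile step (registration of a subject whose morphology differs
grossly from the atlas is detected and refused rather than silently
wrong).

## Numerical choices and degenerate inputs

* Trilinear interpolation everywhere (`mode = "mask"` thresholds the
  interpolated 0/1 image at 0.5); samples beyond the grid are zero for
  image warping but edge-clamped inside registration, where zero-fill
  would punch dark faces into small pyramid levels and corrupt the
  correlation objective. Out-of-bounds tests carry a 1e-6-voxel fuzz so
  numerically-zero displacements cannot evict border voxels.
* Label transfer warps each code's 0/1 mask and takes the largest
  response ≥ 0.5; codes are conserved by construction.
* Connected components (atlas building) use 6-connectivity with
  size-ranked codes; ties are resolved by array order, and seed points
  can fix codes explicitly.
* Degenerate inputs fail loudly: constant images (undefined
  correlation), collinear plane points (third-singular-value ratio
  test), empty foregrounds, empty static masks, non-invertible affines.
* Frame indices are 1-based in the R API; voxel indices are 0-based in
  world-coordinate conversions (`grid_to_world`), matching the NIfTI
  convention.
* Problem sizes in the test-suite: module tests run on 16–28³ grids
  with 6 frames; the end-to-end checks use the 32³ preset, and the
  headline flow-recovery check runs the full 64³ acquisition-matched
  phantom. These sizes were chosen as the smallest at which
  discretization error is representative of the target acquisition.

## Known limitations

* The temporal unwrapper assumes the anchor frame is alias-free and
  cannot repair spatial (intra-frame) wraps.
* The Morphon estimator here is gradient-based, not quadrature-filter
  based; exact numerical agreement with the original toolkit is not a
  goal, only the same contract (certainty-weighted, diffeomorphic,
  fluid/elastic-regularized multi-scale estimation).
* Planes are placed once, from the systolic fit; only the *mask* is
  time-resolved. For vessels with large through-plane motion a
  per-frame plane would track better.
* Net volume is the only flow quantity computed; peak velocity,
  pulse-wave velocity, turbulent kinetic energy and pressure gradients
  are out of scope.
* Registration runs single-threaded on the CPU; a 64³, 20-frame
  subject takes a few minutes end to end.
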