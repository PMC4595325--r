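# flow4d

Fully automatic segmentation of the great thoracic vessels and net flow
volume quantification in **4D flow cardiovascular MR** (time-resolved 3D
phase-contrast CMR with three-directional velocity encoding).

4D flow CMR delivers a magnitude volume and three velocity-component
volumes for every cardiac frame. It contains, in a single free-breathing
scan, everything needed to measure flow in all the great vessels — but
only after someone delineates each vessel and places analysis planes,
which is the time-consuming, operator-dependent step. `flow4d` removes
that step: a pre-labelled atlas is deformed onto each new dataset, carried
through the cardiac cycle, and the flow is integrated automatically at
atlas-defined planes. The package is aimed at researchers processing 4D
flow studies who want hands-off, reproducible volumetric flow
measurements, and it ships a synthetic phantom generator so the entire
pipeline is testable against analytic ground truth without any scan data.

## Method

1. **Angiography.** A phase-contrast MR angiogram is computed over the
   systolic frames,

   `PC-MRA(x) = M̄(x) · sqrt( V̄x² + V̄y² + V̄z² )`,

   where the bars average magnitude and velocity components over systole;
   the magnitude factor suppresses noise in low-signal regions and the
   component averaging keeps stationary spins dark. Optional
   preprocessing first applies temporal phase unwrapping (aliasing beyond
   ±VENC is corrected by multiples of 2·VENC along each voxel's time
   series) and background phase correction (a weighted 2nd-order 3D
   polynomial fitted to automatically detected static tissue).
2. **Atlas fitting.** The atlas PC-MRA is registered to the subject
   PC-MRA by affine registration followed by Morphon-style multi-scale
   non-rigid registration (3 scales × 5 iterations, linear
   interpolation), with fluid regularization of each displacement
   increment, elastic regularization of the accumulated field, and
   diffeomorphic field accumulation by composition — the deformation can
   compress and stretch but never tears or folds (interior Jacobian
   determinant stays positive). Vessel labels and analysis planes are
   transferred through the fitted transform.
3. **4D propagation.** The systolic frame with the highest angiographic
   signal is registered to every other frame independently (5 scales × 5
   iterations, on structure-tensor edge maps), yielding a time-resolved
   segmentation that follows the vessels through the cycle.
4. **Flow quantification.** Each deformed plane is flattened by PCA, the
   in-plane mask is rounded and slightly enlarged with a 9-pixel-radius
   circular averaging filter (the added rim carries near-zero
   velocities), velocities are linearly interpolated on the plane
   lattice, and the net flow volume is `V = Σ_t Q(t)·Δt` with
   `Q(t) = Σ (v·n̂) · pixel area` in ml/s.

## Worked example

A pulsatile Poiseuille tube phantom on the default acquisition grid
(64³ voxels at 2.7×2.7×2.8 mm, 20 frames of 52.8 ms, VENC 120 cm/s),
with radius 10 mm, peak velocity 100 cm/s and a half-sine systole of
0.3 s. Its analytic net volume is
`(v_max·πR²/2)·(2·0.3/π)·0.01 ≈ 30.0 ml` per cycle.

```r
library(flow4d)

ph  <- make_phantom(phantom_spec(grid = "clinical"))
at  <- build_atlas(ph$flow, threshold_frac = 0.3, planes = ph$planes)
res <- run_pipeline(list(flow_data = ph$flow, atlas_obj = at,
                         flow = list(spacing = 0.5)))
round(res$net_volumes, 2)
#> tube_a tube_b
#>  29.87  29.87
ph$truth$plane_truth
#> tube_a tube_b
#>     30     30
```

The pipeline (threshold-built atlas → affine + non-rigid fit → temporal
propagation → plane flow at 0.5 mm spacing) recovers the analytic
30.0 ml within 0.5%, and the two planes along the tube agree with each
other — the same consistency checks (conservation at a bifurcation,
equality of two circulations, plane-position robustness) that validate
the method on real vessels.

A thin CLI covering the same pipeline is installed at
`inst/cli/flow4d` (`phantom`, `angio`, `run` verbs).

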