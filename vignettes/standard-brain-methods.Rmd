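---
title: "Methods: standard-brain construction, neuron tracing and registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standard-brain construction, neuron tracing and registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mothatlas` implements a complete desk-scale pipeline for insect standard-brain
work: averaging individual confocal brain volumes into a reference shape,
tracing single-neuron morphologies out of image stacks, registering both
volumes and SWC morphologies into the reference frame with landmark-driven
transforms, and quantifying every step. This vignette records the models,
the numerical choices, and what the test suite does and does not establish.

## Coordinate conventions

All physical quantities are micrometres. An `image_stack` stores voxels in
`(z, y, x)` slice order with explicit `spacing = (dz, dy, dx)` and origin;
the physical position of voxel `(k, j, i)` is `origin + (index - 1) * spacing`.
Spacing is never read from TIFF metadata: microscope exports are unreliable,
so it is an explicit argument or a JSON sidecar written by `write_stack()`.
The default `(2, 1, 1)` matches 2 um optical sectioning with ~1 um in-plane
pixels, the regime the averaging scheme was designed for. SWC morphologies
and landmarks live directly in physical coordinates, which is what allows
stacks of different magnification to meet in one registration.

## Landmark transforms

Three families cover the pipeline:

* **Rigid** (`fit_rigid`): orthogonal Procrustes by SVD with the reflection
  branch excluded, so `det(R) = +1` always. Averaging individuals into a
  standard shape must not rescale them — size and shape differences between
  individuals are the signal, not noise — and a silent mirror would corrupt
  hemispheres, so mirroring is only available as the explicit `mirror()`
  operation (which also swaps leading `R`/`L` in landmark names so a mirrored
  left hemisphere pairs correctly with a right-hemisphere reference).
* **Affine** (`fit_affine`): least-squares 12-parameter fit, exact on
  affine-consistent data.
* **Thin-plate spline** (`fit_tps`): the 3D kernel is `U(r) = r`, the
  biharmonic Green's function in three dimensions (`r^2 log r` is the 2D
  kernel and would be wrong here). The bordered linear system is solved per
  output coordinate with one step of iterative refinement; kernel values at
  evaluation time are computed by direct coordinate differencing because the
  expanded inner-product formula cancels catastrophically exactly at the
  landmarks, where interpolation is asserted to 1e-6 um. At least four
  non-coplanar landmark pairs are required; `lambda = 0` (exact
  interpolation) is the default since the evaluation protocol treats
  landmarks as exact anchors, with `lambda > 0` available for smoothing.

Image warping always uses inverse-direction lookup with trilinear
interpolation; out-of-field voxels are zero. A TPS has no analytic inverse,
so `invert_transform()` refits with source and destination landmarks
exchanged — exact at the landmarks, approximate elsewhere, the standard
device inherited from landmark-registration practice. TPS warping here is
full-3D, not slicewise; a slicewise implementation could differ slightly
near strong through-plane gradients.

`apply_morphology()` moves SWC coordinates and never touches topology.
Radii are untouched by default (`radius_policy = "fixed"`, registration
transforms geometry only); `"local_scale"` multiplies each radius by
`|det J|^(1/3)` of the central-difference Jacobian for workflows that want
diameters to follow volumetric distortion.

## Atlas construction

`build_standard_brain()` runs the averaging scheme: left-hemisphere inputs
are mirrored about the sagittal midplane (both hemispheres of each
individual enter as independent samples under a bilateral-symmetry
assumption), each stack is rigidly aligned to a designated reference stack
through shared named landmarks (the original five-point scheme: central-body
centre, both mushroom-body calyx centres, both antennal-lobe centres),
aligned stacks are averaged voxelwise, and the average is binarized and
surfaced. The per-stack landmark residual RMS is carried in the provenance
so alignment quality is always visible.

Binarization is Otsu's global threshold by default (a reproducible stand-in
for "separating light and dark areas"; a fixed threshold is available),
followed by keeping the largest 26-connected component and filling interior
cavities — the standard outline is one solid shape. No per-stack intensity
normalization is applied before averaging by default; the inputs the scheme
was designed for share staining and acquisition protocols, and a
normalization flag would be the first thing to add if they do not.

Surface extraction emits the boundary faces between foreground and
background voxels (quads split into outward-wound triangles). No R
marching-cubes implementation is available in the supported dependency set,
and the boundary-face mesh has two properties worth having anyway: it is
watertight by construction and its enclosed volume equals the voxel count
times the voxel volume *exactly*, which makes volume assertions sharp. The
cost is a blocky appearance at voxel scale rather than a smoothed
isosurface; downstream volume and overlap numbers are unaffected.

## The phantom world

`phantom_spec()` pins the synthetic benchmark: cylinder-tree neurons
rendered into 3D stacks with exact SWC ground truth under four conditions —
clean, biased background (a large bright object covering the neuron),
additive white noise, and an overlapping bright cylinder. The defaults are
a 256 x 256 x 256 um field (128 sections of 2 um, 1 um in-plane), 8-bit
intensities with foreground 200 on background 20, 2-4 binary branching
generations (always at least 3 bifurcations), 20-60 um segments at 20-70
degree branch angles, root radius 2 um tapering 0.8 per generation, noise
sigma 30, bias amplitude 100, distractor radius 8 um. None of these values
are prescribed by a source; they were chosen once as a realistic desk-scale
confocal regime that produces the intended qualitative difficulty of each
condition, and they are all exposed in the spec object. Rendering uses
tapered frusta between consecutive SWC nodes (matching SWC semantics), so
segment ends are rounded; the analytic volume checks account for the caps.

What the phantoms do **not** emulate: depth-dependent attenuation,
anisotropic PSFs, multi-neuron scenes, or real background texture. A green
benchmark therefore establishes that the pipeline recovers tubular trees
under these stated corruptions — not performance on arbitrary real stacks.

## Tracing

`trace_neurites()` is a deterministic embodiment of region-growing
centerline extraction: flood-fill from the seed voxel over the thresholded
mask; Euclidean distance transform (exact separable parabola method,
anisotropic); shortest-path tree from the seed with edge weights
`step_length / (1 + EDT)` so paths hug tube centres; union of paths to
geodesic local maxima; spur pruning below 3 um; a rounding correction that
trims terminal nodes whose arc distance to the tip is at most the local EDT
(the skeleton otherwise overshoots each process end by one radius, to the
apex of the rendered end cap); resampling at 1 um with EDT-derived radii
floored at 0.25 um. Ties in the shortest-path tree break on the smaller
linear voxel index, making traces bit-reproducible. The published tracer's
exact growing criterion is not recoverable from its description; this
formulation was chosen as a reproducible, testable equivalent, and that is
a fidelity caveat, not a claim of algorithmic identity.

Otsu is the default threshold and works for high-contrast stacks where the
neuron is a visible fraction of the histogram. When the neuron occupies a
vanishing fraction of the volume under heavy noise, Otsu splits the
background distribution instead — the benchmark therefore binarizes at the
phantom's known midpoint intensity `(fg + bg) / 2`, standing in for the
display-calibrated threshold an annotator sets interactively. The
biased-background condition additionally enables per-slice coarse-grid
median background subtraction, the option provided for exactly that regime.

The **semiautomatic** path (`trace_semiauto`) reproduces the human
correction loop deterministically: delete traced terminal branches without
reference support within 2 um (iterating inward), then add every reference
branch missing from the trace as an `add_path` edit anchored at the nearest
traced node. Corrections only improve the matched-structure score, so
semiautomatic consistency dominates automatic consistency phantom by
phantom. The fully manual mode of the original software corresponds to
applying an edit script to an empty trace; the GUI itself is out of scope.

## Metrics

**Consistency** is the mean of two length-weighted fractions computed on
0.5 um arc-length resamplings: the fraction of reference cable length with
a traced point within `tau` (missing-branch side) and the fraction of traced
cable length with a reference point within `tau` (false-branch side). The
reference the published benchmark cites is not reproduced in the paper
itself, so this tolerance-explicit bidirectional definition is adopted and
documented; length-weighting (rather than branch-counting) is used because
it does not reward fragmenting long branches. `tau` defaults to 2 um, about
one z-step. An empty extraction scores 0, not 0.5 — a null answer earns no
credit from the false-branch side. Diameter discrepancy is the
length-weighted mean relative diameter error over matched reference points.

**Landmark error** reports per-landmark Euclidean distances of each sample
to a base set; the grand mean is minimized when the base is the per-name
centroid, which is the formal version of "the average brain is the best
reference". **Registration error** follows the held-out protocol: fitting
landmarks drive the transform, named distinct points measure before/after
distances; points far outside the landmark hull can remain poorly
registered, which is a property of TPS extrapolation and is asserted
qualitatively in the tests.

## Passive cable validation

Reconstructions that look right can still be electrically wrong, so traced
morphologies are compared under a passive membrane model. Each SWC edge
becomes a frustum compartment (lateral area `pi (r0 + r1) slant`, axial
resistance `Ra L / (pi r0 r1)`); node voltages solve the sparse SPD system
`(L_axial + diag(g_m)) v = i` for steady current injection at the root.
Parameters default to the textbook conventions Rm = 10000 Ohm cm^2,
Ra = 100 Ohm cm, Cm = 1 uF/cm^2, E_rest = -65 mV — stated conventions, not
measured moth values. The discretization is validated against the sealed
uniform cable closed form `V(L)/V(0) = 1/cosh(L/lambda)`,
`lambda = sqrt(Rm a / 2 Ra)`, to 1% at 1 um compartments.

The error functional compares steady-state tip deflections (tips matched by
nearest-Euclidean pairing) relative to the reference deflection, with the
relative input-resistance error reported alongside. The original benchmark
does not state its error functional; this one was chosen as the minimal
deterministic option and is isolated behind `response_error()` so it can be
swapped. Transient responses add only time constants under a purely passive
model, so the steady state carries the same morphological information.

## Overlap connectivity

`overlap_volume()` rasterizes two registered arbors as frusta on a shared
isotropic grid and reports intersection volume and Jaccard index. Voxel
rasterization was chosen over analytic frustum intersection for robustness;
the grid (default 1 um) is configurable and halving it moves smooth-fixture
overlaps by under 5%. `dilation` grows every radius isotropically, turning
strict intersection into a proximity measure (~2 um approximates a
putative-synapse reach). How overlap maps to synaptic weight is unspecified
in the source material; the toolkit reports geometry only.

## Numerical notes and limitations

* The EDT uses a large finite sentinel (1e15) instead of infinity: infinite
  parabola intersections are undefined when a scan line starts on foreground.
* Dijkstra tie-breaks, scan-order component labelling and seeded RNG make
  every pipeline stage bit-reproducible for fixed inputs.
* `resample_image` tolerates 1e-6 voxel of floating-point jitter at the
  volume border so identity transforms are exact.
* SWC files are written with 17 significant digits so read-write round
  trips are bit-exact.
* Single-seed tracing deliberately ignores mask components disconnected
  from the seed (reported as a coverage warning); fragmented fills are
  reconnected with `edit_connect`, not silently bridged.
* The tracer's accuracy bars (cylinder length +/- 2 um, radius +/- 0.5 um)
  hold at ~1 um grids; markedly coarser grids degrade radius estimates
  first.
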