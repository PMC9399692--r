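---
title: "Reconstructing muscle volumes from attachment areas: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing muscle volumes from attachment areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myovol)
```

## The model

`myovol` reconstructs a muscle as a watertight triangle mesh generated
from three inputs: a bone surface, an *origin* attachment patch, and an
*insertion* attachment patch (face subsets of bone meshes, the headless
equivalent of painting attachment areas on the bone). The pipeline is

1. attachment areas and area-weighted centroids;
2. a centerline from origin centroid to insertion centroid, optionally
   bent by displacing interior control points;
3. a sweep of the origin boundary cross-section along the centerline,
   blending into the insertion boundary;
4. Boolean removal of muscle–bone and muscle–muscle overlap;
5. metrics export, including frustum/PCSA/force comparison statistics.

The frustum comparison uses
$V_f = \tfrac{l}{3}\,(A_{or} + A_{ins} + \sqrt{A_{or} A_{ins}})$
with the *linear* (centroid-to-centroid) length $l$, PCSA $= V/l$ with
the matching length for each variant (linear for the frustum, curved for
the 3D volume), and force $= \mathrm{PCSA} \times \sigma$ with isometric
muscle stress $\sigma = 0.3\ \mathrm{N\,mm^{-2}}$ by default. PCSA and
force assume a parallel-fibred muscle whose fibre length equals muscle
length; pennation is deliberately not a parameter — the point of these
outputs is the *relative* difference between the frustum and volumetric
estimates, which is invariant to a constant architectural correction.
The CSV header records this assumption.

## Key parameters

| parameter | default | units | role |
|---|---|---|---|
| `n_samples` | 32 | – | centerline polyline samples; muscle length is measured on this polyline |
| `ring_vertex_count` | 64 | – | vertices per cross-section ring |
| `blend` | `linear_blend` | – | ring shape interpolation origin→insertion (`origin_only` keeps the bare bevel) |
| `resolution` | 96 | cells | Boolean lattice cells along the longest scene axis |
| `stress` | 0.3 | N mm⁻² | isometric muscle stress |

Coordinates are millimetres throughout; meshes carry no unit metadata.

## Numerical design choices

**Boundary alignment.** The origin boundary loop is aligned to a plane by
principal-component analysis: the two largest-variance directions span
the plane, the smallest is the normal. Sign and rotation ambiguities are
resolved deterministically: the first axis is oriented so the loop's
first point has non-negative first coordinate, and the frame is flipped
so the projected loop winds counter-clockwise. When the in-plane
variances are equal to within $10^{-6}$ relative (circular boundaries)
the principal directions themselves are arbitrary, so the first axis is
instead anchored to the loop's first vertex; this makes the construction
exactly invariant under rigid motion of the scene, which the test suite
asserts at $10^{-6}$ relative on volumes for the circular fixture.
Elongated boundaries keep true PCA axes (an ellipse maps with its major
axis along the first plane axis).

**Bevel orientation.** How the projected origin shape is oriented
relative to the curve is not prescribed by the workflow this package
automates; we carry the boundary plane's normal onto the initial curve
tangent by the minimal rotation, then transport frames along the curve
by the double-reflection rotation-minimizing method (no twist
accumulation; Frenet frames would flip at inflections). Ring
correspondence between origin and insertion outlines uses the cyclic
seam shift minimizing summed squared distance — deterministic and free
of twist artifacts.

**End closure.** Each terminal ring is the (resampled) attachment
boundary; ends are closed by a triangle fan to the attachment centroid.
An alternative would weld copies of the attachment patch triangles onto
the tube; the fan cap is used unconditionally because it is provably
watertight for arbitrary patch triangulations, and the two differ only
by the volume between the patch surface and its boundary plane (zero for
planar attachments, small for gently curved ones). This choice is why
every generated muscle passes the watertightness invariant by
construction.

**Boolean engine.** No exact mesh-Boolean library is available in the
target environment, so Booleans are evaluated on a regular lattice:
signed distances to each watertight input are sampled (exact distances in
a narrow band, ray-parity signs), combined with pointwise min/max
($A \setminus B \equiv \min(f_A, -f_B)$), and contoured by marching
tetrahedra (six positively oriented tetrahedra per cell, shared-face
diagonals consistent across cells), which yields closed, consistently
oriented meshes for any sign pattern. Consequences:

* Volumes of lattice-Boolean outputs carry an $O(h^2)$ discretization
  error concentrated at sharp edges. At the default `resolution = 96`
  the conservation identity
  $V(\mathrm{target}) = V(\mathrm{target}\setminus\mathrm{cutter}) +
  V(\mathrm{target}\cap\mathrm{cutter})$ holds to better than $10^{-3}$
  relative for plane-bounded solids and to about $2\times10^{-3}$ for
  the cylindrical muscle fixtures; the acceptance suite checks the
  $10^{-3}$ bound on the cube pair at the default lattice and on the
  muscle pair at `resolution = 192`.
* `resolve_overlaps()` performs all cuts on one scene-fixed lattice and
  tracks each muscle as a field, so after resolution no lattice point is
  inside two solids: the residual overlap *measured on that lattice* is
  exactly zero, and a second pass is a no-op. Measured on an independent
  lattice the residual is of order $h^2 \times$ area ($\approx 10^{-3}$
  relative), which is the honest resolution limit of a remeshing
  Boolean; an exact-arithmetic residual of $10^{-6}$ relative would
  require an exact kernel this environment does not provide.
* A cutter disjoint from the target returns the target unchanged (no
  remeshing); a cutter wholly inside leaves a cavity, which is retained
  (negatively oriented component nested in the solid). If a subtraction
  severs a muscle into several solids, the largest is kept with a
  warning — the interpretation we adopt for a case the workflow leaves
  unspecified.
* Exactly coplanar inputs are dodged structurally: the lattice origin
  carries a small irrational offset and ray origins a fixed jitter, so
  grazing configurations have measure zero rather than being retried.

**Degenerate inputs.** Zero-area faces contribute nothing to areas or
centroids; an all-degenerate patch is an error. Painted areas that are
not edge-connected warn and sweep from the largest component while
reporting the *total* painted area (matching painted-area semantics).
Boundaries with holes warn and use the longest loop for the sweep shape.
Coincident attachment centroids (zero-length muscle) and offsets applied
to endpoint control points are errors.

## The synthetic fixtures

Real specimen meshes are not redistributable, so the geometric layer is
validated entirely against analytic scenes, generated deterministically
(seeds are recorded but nothing is random):

* `make_parallel_plates(radius = 3, gap = 20)` — a straight cylindrical
  muscle between two plates; patch area $\pi r^2$, volume $\pi r^2 g$
  (2% tolerance; the cross-section is a 64-gon, an 0.16% area deficit).
* `make_curved_channel(20, 2)` — a quarter-circle centerline; curved
  length $\pi R/2$ vs linear $R\sqrt2$ (the ~11% divergence that makes
  curved muscles interesting), volume by Pappus (3%).
* `make_overlap_pair(offset = 2)` — congruent parallel cylinders whose
  intersection is a circular-segment lens times length (2%).

The defaults are desk-scale values chosen once: radii of a few mm and
lengths of a few cm match the jaw-muscle scale of the motivating data,
and tolerances state what the default mesh resolutions achieve with a
margin. What a green fixture test establishes is that the geometric
operators converge on smooth analytic shapes; it does not establish
anything about segmentation quality, attachment identification, or
biological realism of a reconstruction — those remain the user's
responsibility, as in any reconstruction workflow.

The numeric layer (frustum/PCSA/force/percent differences) is instead
validated against the four printed jaw-adductor rows shipped in
`inst/extdata/frustum_inputs_table1.csv`: every derived cell is
recomputed from the printed inputs. Magnitude cells agree to 1%
relative. Percent-difference cells are compared with an absolute budget
of 0.15 percentage points because the source printed those columns from
unrounded intermediates: rounding the *inputs* to their printed
precision moves the length percent-difference by up to ~0.13 points, so
agreement beyond that is unattainable from printed data by any
implementation.

## Known limitations

* The Boolean kernel remeshes: output triangulations are lattice-scale,
  not minimal, and sub-lattice features are lost. Raise `resolution` for
  finer work (cost grows cubically).
* Curve adjustment is parametric (control-point offsets), not
  interactive sculpting; there is no automatic wrapping of the
  centerline around bone.
* PCSA/force outputs assume parallel fibres with fibre length equal to
  muscle length; they are comparison statistics, not absolute force
  predictions.
* The sweep assumes the attachment boundary projects to a simple polygon
  and that the centerline's radius of curvature exceeds the
  cross-section radius; violations are detected and reported, not
  repaired.
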