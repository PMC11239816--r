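---
title: "Tri-planar free-form deformation: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tri-planar free-form deformation: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffdseg)
```

## The model

`ffdseg` deforms a labelled template volume onto a target image with
free-form deformation driven by three independent, plane-constrained
control lattices. Each lattice is a regular grid of control points with
spacing *h* (identical on all axes) whose displacement field is the
tensor-product uniform cubic B-spline interpolant of the control
displacements. The three lattices are tied to the anatomical viewing
planes, and each may displace its points only within its own plane:
the axial lattice carries (x, y) displacements, the sagittal lattice
(y, z), the coronal lattice (x, z). The out-of-plane component is not
clamped at evaluation time — it is structurally absent: the lattice
cannot store one, so the constraint holds exactly at every control
point and, by linearity of the interpolant, at every sample.

The basis is the uniform cubic B-spline, not the Bernstein polynomials
of the original FFD formulation. Cubic B-splines have local (4×4×4)
support, so a single dragged control point affects only its 4*h*
neighbourhood — the behaviour an interactive fitting workflow needs —
and they reproduce translations exactly (partition of unity), which
gives a sharp correctness oracle: displacing *all* control points of
one lattice by a constant must produce that constant field to
round-off (< 1e-9 mm is asserted; observed error is ~1e-15).

### Composition, not addition

The whole deformation field is the *product* of the three planar
fields, with the shape-application order fixed: coronal first, then
sagittal, then axial. Two readings of "product" are possible —
pointwise addition of displacements, or function composition. This
package composes. Sequential application of deformations to a shape is
function composition by definition, and only composition makes the
order matter, which is an explicit property of the method (the order is
fixed precisely because permuting it changes the result). Addition is
commutative and was rejected on those grounds; the choice is asserted
by a test constructing non-commuting fields whose two orderings differ
measurably.

All fields are stored as backward (pull) maps: output point `x`
samples template content at `x + d(x)`. Backward warping is single-pass
and hole-free for label resampling. With that convention the fixed
forward order (coronal applied to the shape first, axial last) becomes

```
B(x) = B_coronal( B_sagittal( B_axial(x) ) )
```

with the axial factor innermost. Inner-field lookups during
composition use trilinear interpolation with edge clamping (the nearest
edge displacement extrapolates better than an abrupt zero); constant
fields therefore compose additively to within 1e-6 mm, which is the
tolerance the composition tests use. The innermost factor is read
directly off its grid, exactly.

### Lattice coverage and the margin

A lattice covers the target extent plus one control point beyond each
face, and enough points past the far face that every voxel has a full
4-point support per axis (`dims = floor(u_max) + 3` in lattice units).
Evaluating a geometry outside the support is an error rather than an
extrapolation. The spacing ladder defaults to 80 → 40 → 20 mm: coarse
global placement first, with 20 mm as the finest practical grid —
coarse relative to single muscles, which is what makes whole-template
fitting robust for non-expert operators.

### Refinement bakes; it does not subdivide

`refine()` composes the current triple (in the canonical order) with
any existing base field, stores the result as the new dense base, and
returns fresh all-zero lattices at half the spacing. The alternative —
exact dyadic B-spline subdivision of the control mesh — was rejected:
baking matches the workflow notion of "use the current result as the
initial value", keeps the fresh lattices exactly zero, and guarantees
the applied warp is bit-identical across the refinement boundary
(all-zero triples short-circuit to the exact zero field, so no
interpolation jitter enters; resampling the base through a zero field
would otherwise perturb values at ~1e-16 and break bit-identity).

### Topology checking

Deformations are not constrained to be diffeomorphic; instead
`jacobian_min()` reports the minimum central-finite-difference Jacobian
determinant of `x ↦ x + d(x)` over interior voxels, with the attaining
voxel. Identity and translations give exactly 1; the linear field
`d = (0.1 x, 0, 0)` gives exactly 1.1 (central differences are exact on
affine fields), which the tests use as a closed-form oracle. As a rule
of thumb — encoded in the phantom generator's default — in-plane
displacements bounded by 0.4 × lattice spacing keep the composed field's
determinant positive; the tests verify this for 20 random deformations.

### Alignment

Initial placement is a similarity transform (translation, z-y-x Euler
rotation about the template's world centre, isotropic scale) — the
smallest family that supports "roughly place the whole template". It
composes as the innermost, template-side factor: align first, then
deform. Whether rotation and scale are strictly needed is open; the
family errs on the permissive side while remaining rigid-shape-safe.
When the alignment is the identity it is skipped entirely, so identity
sessions are bit-reproducible.

### Conventions

* Canonical axes: x left–right, y anterior–posterior, z
  superior–inferior; NIfTI inputs are reoriented (RAS) on load, so
  "axial" always means the plane ⊥ z. World coordinates are mm at
  voxel centres.
* Indices (voxels and control points) are **1-based** throughout the R
  API, matching R arrays and the R imaging ecosystem; a 0-based
  convention in an R package would invite off-by-one errors at every
  call site. World-coordinate math is unaffected.
* Nearest-neighbour ties at half-integer coordinates round toward
  negative infinity, fixed across platforms.
* Sample points outside a source volume return background (0): FFD
  near an edge must not invent anatomy.
* Label data are unsigned 16-bit integers at most; label tables ride
  along as `id,name,r,g,b` sidecar CSVs.

## The phantom generator

`generate_phantom()` emulates a limb cross-section: a central bone
(label 1) whose radius varies smoothly along z, an annulus of
`n_muscles` angular-sector muscles (labels 2..n+1) under a bright fat
rim, and dark background. Defaults are fixed at 96 × 96 × 120 voxels at
1.0 × 1.0 × 1.5 mm — the anisotropic MR acquisition grid, so resampling
between the isotropic 1 mm template convention and the anisotropic
target grid is exercised — with 8 muscles, bone radius 10 mm, limb
radius 38 mm, 4 mm rim, class intensity means background/bone/muscle/
fat = 10/40/110/200 and noise sd 10 (class separation well above the
2-sd floor that keeps segmentation difficulty controlled). Generation
is fully deterministic per seed.

Ground-truth "participants" come from `generate_deformation()` (smooth
random in-plane displacements on a coarse 40 mm lattice, each component
bounded by 0.4 × spacing, band-limited by construction) and
`make_target()`, which warps labels and image through the *identical*
composed field. Because `make_target()` and `apply_session()` share one
warp implementation, replaying the generating triple in a session
recovers the ground truth bit-exactly — the closed loop the end-to-end
tests assert (Dice exactly 1 on every label), with any perturbation of
the replay strictly degrading mean Dice.

What the phantom does *not* emulate: real anatomy (muscle
cross-sections are sectors, not fascicle-shaped compartments), MR
physics (no bias field, no Dixon phases), inter-subject topology
changes, or operator behaviour. Passing the closed loop therefore
demonstrates the deformation/warp/metric machinery is self-consistent
and invertible under known conditions — not that non-expert fitting of
real MR images reaches any particular accuracy.

## Evaluation machinery

* **Dice** of two empty masks is defined as 1 with a `both_empty`
  attribute — benchmark-style per-element averaging must not propagate
  NaN when an element is absent from both volumes.
* **Volume error** is the absolute difference of element volumes in
  cm³ (voxel count × voxel volume / 1000); signedness conventions vary
  across reports, and the absolute reading is the conservative one.
* **Wilcoxon signed-rank**: zero differences dropped, midranks for
  ties, Z from the tie-corrected normal approximation with 0.5
  continuity correction; p by exact enumeration of all 2^n sign
  assignments when n ≤ 12 (doubling convention, capped at 1), normal
  approximation otherwise. Fewer than 5 nonzero differences warns
  rather than errors (the exact path remains well-defined there).
  `stats::wilcox.test` is used in the tests as an external
  cross-check of the normal path, never as the implementation — it does
  not report the Z statistic this protocol quotes.
* **Bonferroni** with m = 3 mirrors the three pairwise classifier
  contrasts of the benchmark protocol.
* **k-fold grouping** is a seeded shuffle dealt round-robin (fold sizes
  differ by ≤ 1; folds are numbered 1..k, R-style); per-fold training
  sets are the evaluation ids outside the held-out fold plus any extra
  cohort, reproducing the 16/83-train, 4-held-out bookkeeping.
* Report CSVs are written in binary mode with fixed 6-decimal
  formatting, so identical inputs give byte-identical files.

## Problem sizes

The unit tests run phantoms at 48 × 48 × 32 and composition grids of
20–30 voxels per axis; the end-to-end acceptance checks use a
64 × 64 × 48 phantom at the 1.0 × 1.0 × 1.5 mm spacing and 20 random
topology draws on a 30 × 30 × 24 grid. These sizes were chosen so the
whole suite runs in well under a minute on one core while every code
path — anisotropic resampling, composition, baking, closed-loop
recovery — is exercised at realistic voxel counts; the defaults users
see remain the full 96 × 96 × 120 grid.

## Known limitations

* Only axis-aligned NRRD/NIfTI geometries are accepted; oblique
  acquisition matrices are rejected on load rather than resampled.
* Invertibility is detected (`jacobian_min`), not enforced; a user (or
  script) can fold the template if displacements are extreme.
* The similarity alignment is global; there is no per-region rigid
  initialisation.
* `.seg.nrrd` layered segmentations are out of scope; labels must be a
  single integer volume.
* Composition accumulates trilinear interpolation error at each
  refinement level (bounded by the field's second derivative times the
  voxel size squared); at the default ladder depth (two bakes) this is
  far below voxel resolution.
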