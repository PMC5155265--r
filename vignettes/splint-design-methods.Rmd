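---
title: "Methods: ruled-surface splint bases, distance-field Booleans and swept-silhouette undercut removal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ruled-surface splint bases, distance-field Booleans and swept-silhouette undercut removal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splintforge)
```

`splintforge` designs occlusal surgical splints from triangle meshes of the
maxilla and mandible. This vignette explains the geometry behind each stage,
the tunable parameters and their defaults, the numerical choices that keep
the pipeline deterministic and watertight, and what the bundled synthetic
phantoms do and do not demonstrate about clinical data.

All coordinates are millimetres, and STL files are read and written as mm —
the natural unit for dental geometry. The package's universal carrier is the
`triangle_mesh`: an indexed triangle surface that is *watertight* when every
undirected edge is shared by exactly two faces with opposite traversal.
Watertightness is not cosmetic here: the Boolean stage and the slicing stage
both need a well-defined inside.

## The initial splint base

A splint plan consists of two ordered lists of *landmark lines*, one per
jaw. A line models one picked point on the dentition: an anchor point
$\mathbf a$, a unit axis $\hat{\mathbf d}$, and inner/outside extents
$\ell_{\mathrm{in}}, \ell_{\mathrm{out}} \ge 0$ (their sum positive), with
derived endpoints $\mathbf a - \ell_{\mathrm{in}}\hat{\mathbf d}$ and
$\mathbf a + \ell_{\mathrm{out}}\hat{\mathbf d}$. In the auto-generated arch
plans the axis runs bucco-lingually (radially across the arch), so the
inner endpoints trace a lingual curve and the outside endpoints a buccal
curve; the plan format keeps the axis explicit, so vertically oriented
lines are equally expressible. `adjust_line()` rebuilds a line with any
field replaced, re-normalizing the axis and re-checking the invariants.

The four endpoint sequences (up-inner, up-outer, down-inner, down-outer)
are interpolated with chord-length-parameterized Catmull–Rom splines and
resampled on a shared per-span grid, $(k-1)\,s + 1$ samples for $k$ lines
and `samples_per_span` $= s$ (default 10 — on a 30 mm arch with 6–8 lines
this keeps chordal deviation well under 0.1 mm while the base stays below a
thousand faces). Catmull–Rom is used because it *interpolates*: the
surgeon-picked endpoints are reproduced exactly. Two numerical details
matter:

* **Chord-length parameterization.** Uniform parameterization overshoots on
  unevenly spaced picks; chordal parameterization is the standard fix and
  makes the resampling invariant under reversal of the line order.
* **End conditions.** The spline needs one ghost point beyond each end. A
  point-reflection ghost ($2P_1 - P_2$) forces the end tangent onto the
  first chord and visibly flattens circular arches (up to ~0.4 mm on an
  8-point, 30 mm-radius arc). The package instead extrapolates the
  parabola through the first/last three points, which brings end spans to
  interior accuracy; the test suite checks a 0.25 mm bound on that arch.

A *ruled strip* joins two aligned sample rows $A_i$, $B_i$ with straight
rungs, splitting each quad along a fixed diagonal (low index to high index
in parameter space) for determinism: exactly $2(n-1)$ triangles whose
boundary is the two polylines plus the end rungs. One property of chordal
strips is worth knowing: for twisted rulings the strip's area converges (as
the $u$-sampling refines) to
$\tfrac12\int (|A' \times r| + |B' \times r|)\,du$ with rung
$r(u) = B(u) - A(u)$, which strictly exceeds the area of the smooth
bilinear patch — a triangle-inequality effect of chordal interpolation
across the rung, not a defect; the tests pin the strip against exactly this
limit integral.

The closed base assembles six sheets — top (up-inner to up-outer), bottom,
inner wall, outer wall, and two planar end caps — sharing their boundary
vertices, so there are no T-junctions by construction; global orientation
is fixed by the sign of the enclosed volume. The closure scheme is a design
choice: ruled sheets alone bound no solid, and the Boolean stage needs a
watertight operand. Degenerate inputs are rejected early: coincident
consecutive anchors (zero chord), anchor sequences that backtrack along the
arch, and self-intersecting bases (triangle–triangle scan) raise errors
that point back at the offending lines.

## The mesh Boolean

`mesh_boolean()` computes difference, union and intersection of watertight
meshes in three steps.

**Splitting.** Candidate face pairs are culled with a uniform grid over
face bounding boxes, intersection segments come from interval-overlap
triangle–triangle tests, and each intersected face is re-triangulated so
the segments become mesh edges. The per-face triangulation is a constrained
Delaunay triangulation: points are inserted with Lawson edge-flip
legalization and constraint segments by cavity re-triangulation. Delaunay
legalization is not an optimization nicety — without it, faces crossed by
hundreds of seam segments (a flat base face against a dense dentition mesh)
accumulate slivers that derail the cavity walk. Splitting only
re-triangulates: surface areas are conserved to round-off, which the tests
assert.

**Classification.** Every split cell is classified by the signed distance
of its *centroid* to the other solid — unsigned distance from an AABB tree,
sign from the generalized winding number with threshold 0.5. Centroids are
used because seam vertices sit at distance zero by construction; centroids
of split cells are strictly off the seam. The boundary tolerance is
$10^{-6}$ of the joint bounding-box diagonal.

**Assembly.** Difference keeps A-cells at nonnegative distance from B plus
B-cells at nonpositive distance from A with reversed orientation (so the
cavity walls face outward); union keeps the mutually-outside cells;
intersection the mutually-inside ones. Seam vertices are welded within
$\varepsilon_{\mathrm{seam}} = 10^{-7}$ of the bounding-box diagonal
(union-find over a spatial grid, so pairs straddling a grid cell still
merge). If the weld leaves residual T-junctions, a repair pass splits edges
at vertices lying on them and re-fans the affected faces about their
centroid.

**Coplanar contacts.** Distance-sign classification is undefined on
exactly coplanar overlapping faces (CAD fixtures abound with them, and
A − A is the extreme case). Perturbing one operand does not help at any
useful scale: a perturbation small enough to preserve volumes collapses
below the seam-welding tolerance and leaves non-manifold fins. The package
therefore handles coplanarity exactly: coplanar overlapping faces are split
along each other's edges, and a covered cell is classified by *normal
agreement* with the covering face — difference keeps opposite-normal
A-cells, union and intersection keep same-normal A-cells, and covered
B-cells always drop (the A-side copy represents the shared boundary). This
makes A − A exactly empty, cube-on-cube differences exact to the last bit,
and all results watertight. A deterministic, seeded $10^{-9}$-scale
translation retry remains as a last-resort fallback when assembly fails the
watertightness check.

An empty result (disjoint difference operands, say) is returned as an empty
mesh, which is vacuously watertight, rather than as an error.

## Undercut elimination

A splint moulded over teeth that widen away from the insertion path cannot
seat or unseat along a straight removal direction $\hat{\mathbf r}$. The
forbidden region is the swept silhouette
$\bigcup_{t \ge 0} (\text{teeth} - t\,\hat{\mathbf r})$: a splint point
collides during extraction exactly when it lies in that set.
`sweep_model()` reconstructs it in five steps:

1. **Slice** (`slice_contours()`): cutting planes orthogonal to
   $\hat{\mathbf r}$ at `slice_spacing` (default 0.5 mm), placed half a
   spacing inside the extent so no plane grazes a cap; planes that would
   graze a vertex are nudged by $10^{-7}$ of the extent. Closed
   intersection loops are chained from edge crossings and oriented by
   nesting parity: outer boundaries counter-clockwise, holes clockwise.
2. **Accumulate** (`accumulate_sweep()`): slices are ordered from the far
   end along $\hat{\mathbf r}$; marching toward the near end, each slice
   receives the union of all slices before it. The union is realized by
   *appending* the oriented contours and filling with the nonzero winding
   rule — overlapping same-orientation loops then fill as a true union,
   and a hole survives only where no earlier slice covers it.
3. **Rasterize** (`rasterize_stack()`): scanline fill at voxel centres
   (`voxel_spacing`, default 0.25 mm, isotropic), boundary-inclusive within
   a relative epsilon so a polygon edge on a voxel centre counts as
   occupied; the volume gets a one-voxel zero pad on all six faces and a
   memory guard refuses grids beyond $512^3$ voxels. Voxel layers map to
   the nearest slice plane. An `extension` (default: the model's extent
   along $-\hat{\mathbf r}$) prolongs the final accumulated slice so the
   swept solid clears the splint from below.
4. **Close** (`close_volume()`): morphological closing — dilation then
   erosion with the 6-connected structuring element, `closing_iterations`
   times (default 1) — heals rasterization gaps; the pad is restored if a
   dilation reaches the boundary.
5. **Extract** (`marching_cubes()`): the 0.5-isosurface via a fixed
   tetrahedral decomposition of each cell (six tetrahedra about a shared
   main diagonal, face-consistent across neighbours). Every tetrahedral
   case is unambiguous and complementary-safe, so the extracted surface is
   watertight by construction and the pipeline fully deterministic; the
   price is that some vertices sit on cell diagonals rather than only on
   axis-aligned cell edges, and triangle counts run higher than a
   hexahedral case table would give.

`eliminate_interference()` subtracts the temporary model from the splint.
It first dilates the occupancy grid by `clearance_voxels` (default 1,
26-connected): the voxelized silhouette can dip up to about one voxel
inside the true swept set, and a sub-voxel sliver left on the splint would
still catch on a crown. The dilation acts as a seating clearance — the
same role a cement-gap offset plays in restorative dental CAD — and makes
the removability property robust: translating the result by any positive
multiple of $\hat{\mathbf r}$ yields zero intersection volume with the
dentition, which the tests check at 0.5, 1, 2 and 5 mm. `sweep_model()`
itself applies no clearance, so accuracy measurements against the analytic
silhouette are unbiased.

Two properties orient expectations about accuracy. First, the reconstructed
silhouette of a frustum converges, as voxels refine, to the cylinder at the
*first-contour* radius — the first cutting plane sits half a slice spacing
inside the extent, so that radius is marginally below the frustum's top
radius; convergence checks therefore compare against that limiting
cylinder, while the headline validation bound is taken against the
idealized top-radius cylinder and holds with a wide margin. Second, with
0.5 mm slices and 0.25 mm voxels the mean symmetric surface distance
between the reconstruction and the standard model on the bundled frustum
phantom is computed by `scripts/acceptance.R` at run time; the test suite
asserts it stays within the clinically motivated 0.365 mm budget.

## Distance metrics

`signed_distance()` pairs an AABB-tree nearest-distance query with the
generalized winding number (threshold 0.5) for the sign; winding numbers
degrade gracefully near edges and vertices where single-ray parity tests
flip erratically. `mean_surface_distance()` is the *symmetric* mean: the
average unsigned distance from area-uniform samples on A to surface B,
averaged with the same from B to A, 20,000 samples per surface by default,
deterministic for a fixed seed (the caller's RNG stream is saved and
restored). The symmetric form is used because one-sided means are blind to
protrusions of the unsampled surface; where a single directed figure is
reported, the symmetric value is the conservative choice.

## The phantoms, and what the tests do and do not show

No patient data ships with the package. The phantoms are chosen so that
ground truth is analytic:

* `make_cone_frustum()` — the canonical undercut shape; its swept
  silhouette is a cylinder, and `make_standard_swept()` builds exactly that
  comparator.
* `make_icosphere()` — near-uniform faceted spheres for volume and
  distance validation.
* `make_arch_phantom()` — two jaws, each the Boolean union of a curved
  ridge block and frustum teeth (crown radius 3 mm over base radius 2 mm,
  so every tooth is undercut), facing across a 10 mm occlusal gap along a
  semicircular arch; `make_plan_for_arch()` places one landmark line per
  tooth with the end lines swung past the last teeth so the end caps clear
  the crowns. Output is byte-identical for identical specifications.

Frustum teeth give exact analytic expectations but are kind inputs: convex,
smooth, generously spaced. Clinical dentition meshes bring interproximal
slivers, fissured occlusal surfaces, scan noise and orders of magnitude
more triangles. Passing tests demonstrate the algorithms' correctness
contracts (watertightness, conservation, removability, convergence) — they
do not demonstrate clinical fit, which requires patient data and a printed
splint. The test suite runs the arch pipeline at reduced size (4 teeth,
22 mm arch, 16-segment teeth, 0.5 mm voxels) and the Boolean stress battery
on 20 seeded random solid pairs of a few millimetres at a 15 µm
column-oracle grid; these sizes were chosen to probe the same code paths as
clinical-scale inputs while keeping the whole suite around a minute.

## Known limitations

* The Boolean engine targets closed, non-self-intersecting operands; there
  is no exact-arithmetic kernel, and pathological inputs (near-degenerate
  faces at the seam tolerance scale) fall back to a perturbation retry
  rather than a guarantee.
* No mesh repair beyond vertex welding: open scans must be closed upstream.
* The removal direction is user input; the package does not search for an
  optimal insertion axis.
* The temporary model is not decimated; at 0.25 mm voxels it can carry
  hundreds of thousands of faces, which is the main cost of
  `eliminate_interference()`.
* Splint edges are left sharp; filleting for soft-tissue comfort is out of
  scope.
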