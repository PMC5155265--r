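# splintforge

Scriptable computer-aided design of occlusal surgical splints for
orthognathic (corrective jaw) surgery, from triangle meshes to a printable
STL.

In orthognathic surgery a dental splint is a custom wafer that locks the
maxilla and mandible into their planned relative position. Designing one in
a general CAD package is slow and manual. `splintforge` implements the
splint-specific pipeline as a library plus command-line tool:

1. **Initial splint base from landmark lines.** The surgeon's picked points
   become *landmark lines* — an anchor **a**, a unit axis **d̂**, and two
   extents, giving endpoints **a** − ℓ_in **d̂** and **a** + ℓ_out **d̂**.
   Ordered up (maxilla) and down (mandible) line lists are resampled with
   chord-length-parameterized interpolating Catmull–Rom splines, and the
   dense samples are joined into ruled surfaces
   S(u,v) = (1−v) A(u) + v B(u). Four ruled sheets plus two planar end caps
   close into a watertight solid (`build_initial_splint()`).

2. **Mesh Boolean on signed distance fields.** The dentition is imprinted by
   subtracting the maxilla–mandibular model from the base. Both meshes are
   split along their intersection curve (triangle–triangle intersection
   segments embedded by constrained Delaunay retriangulation), and cells are
   classified by the signed distance d(x) to the other solid — negative
   inside, positive outside, the inside test by generalized winding number.
   The difference A − B keeps the cells of A with d_B ≥ 0 together with the
   cells of B with d_A ≤ 0, orientation-reversed (`mesh_boolean()`). Because
   the original facets are reused, the occlusal imprint keeps full input
   accuracy. Exactly coplanar contacts are handled exactly, so A − A is
   empty and shared-face solids subtract cleanly.

3. **Undercut (interference) elimination.** A tooth that is wider away from
   the insertion path than near it ("big-end-up") traps the splint. The
   dentition is sliced into planar contours orthogonal to the removal
   direction **r̂**; marching opposite to **r̂**, each slice accumulates the
   union of all slices before it, reconstructing the swept silhouette
   ⋃_{t≥0} (teeth − t **r̂**). The accumulated stack is voxelized
   (nonzero-winding scanline fill), morphologically closed, isosurfaced into
   the watertight *temporary model* (`sweep_model()`), and subtracted from
   the splint (`eliminate_interference()`), after which the splint seats and
   unseats along **r̂** without collision.

Supporting modules: binary/ASCII STL I/O (auto-detected read, byte-stable
write), watertightness/volume/Euler diagnostics, signed-distance queries,
symmetric mean-surface-distance validation, and deterministic synthetic
phantoms (cone frusta, the analytic swept "standard model", and a toy
dental arch with undercut teeth plus an auto-generated plan) that stand in
for patient CT meshes.

## Worked example

```r
library(splintforge)

# jaws and landmark plan for a synthetic dental arch
spec <- arch_phantom_spec(n_teeth = 6, arch_radius = 30)
jaws <- make_arch_phantom(spec)
plan <- make_plan_for_arch(spec)

# 1. ruled-surface splint base from the landmark lines
base <- build_initial_splint(plan)
#> triangle_mesh: 204 vertices, 404 faces, watertight

# 2. imprint the dentition with the signed-distance-field Boolean
splint <- mesh_boolean(base, jaws$maxilla, "difference")
splint <- mesh_boolean(splint, jaws$mandible, "difference")
#> triangle_mesh: 1674 vertices, 3344 faces, watertight

# 3. remove undercuts along the vertical removal direction
freed <- eliminate_interference(splint, jaws$mandible, c(0, 0, 1),
                                voxel_spacing = 0.5)
cat(sprintf("volume: base %.0f -> splint %.0f -> de-undercut %.0f mm^3\n",
            mesh_volume(base), mesh_volume(splint), mesh_volume(freed)))
#> volume: base 9415 -> splint 8823 -> de-undercut 8543 mm^3

# verify removability: lift the splint off along +z, test for collision
lifted <- translate_mesh(freed, c(0, 0, 1))
mesh_volume(mesh_boolean(lifted, jaws$mandible, "intersection"))
#> [1] 0

write_stl(freed, "splint.stl")
```

The volumes tell the story: subtracting the jaws removes the occlusal
imprint (9415 → 8823 mm³), and the sweep pass shaves the additional
material that would catch on the crowns (→ 8543 mm³); afterwards the lifted
splint no longer intersects the teeth.

The same pipeline is scriptable from a shell via the bundled CLI
(`inst/cli/splintforge.R`) with subcommands `phantom`, `base`, `boolean`,
`sweep`, `deundercut`, `measure` and `design`:

```sh
Rscript inst/cli/splintforge.R phantom arch -o maxilla.stl mandible.stl plan.json
Rscript inst/cli/splintforge.R design --maxilla maxilla.stl \
    --mandible mandible.stl --plan plan.json -o splint.stl --report report.json
```

`design` writes a JSON run report with per-stage timings and cell/point
counts, and identical inputs give byte-identical STL output.

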