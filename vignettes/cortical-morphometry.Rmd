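---
title: "Surface-based cortical morphometry: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based cortical morphometry: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the measures it
computes, the assumptions and tunable parameters behind each one, the
numerical choices that make the results reproducible, what the synthetic
phantoms do and do not emulate, and the known limitations. Everything
quantitative stated here is computed by the test suite or the
`analysis/` scripts; nothing is quoted from elsewhere.

## The pipeline at a glance

A subject is a closed, oriented pial/white triangle-mesh pair in mm.
`run_subject()` conditions the meshes, computes per-vertex principal
curvatures and the shape index on the pial surface, classifies every vertex
into nine minor and three major shape classes, measures bidirectional
cortical thickness against the white surface, builds the alpha (exposed)
surface and measures sulcal depth against it, smooths all local measures,
and reduces them to one morphometry record: total and exposed areas,
gyrification index (GI), enclosed volume, mean thickness, folding amplitude
(mean depth), convex/concave thickness ratio, and per-shape tables.
`run_cohort()` adds species summaries, pooled shape contrasts, aging
trends, and allometric fits. Everything is deterministic given the inputs
and configuration; the only random numbers in the package live in the
phantom generators and are controlled by explicit seeds.

## Mesh conditioning

Vertex density — the square root of area per vertex — is the mesh's
sampling spacing; all spatial defaults derive from it. Resampling to a
target density is interpreted as reaching a target triangle count by
midpoint subdivision and/or shortest-edge collapse (with the manifold link
condition, a normal-flip guard, and volume-preserving vertex placement:
plain midpoint collapses systematically shrink convex surfaces, which the
normal-offset correction removes to below 1%). Coordinates are never
rescaled; the point of normalization is equal element size, not unit
change.

Two smoothers are provided with the conventional defaults (exposed in
`conditioning_config()`): Taubin lambda/mu smoothing (lambda = 0.5,
mu = -0.53, 10 iterations), which denoises while preserving shape — the
inflate-back magnitude must exceed the shrink magnitude, which the
constructor enforces — and Laplacian smoothing (factor 0.5, 5 iterations),
which shrinks and is therefore applied sparingly. On a subdivision-4 sphere
the default Taubin pass changes measured mean curvature by about 1%, the
same-length Laplacian pass by about 3%; the test suite asserts this
ordering.

Local measures (thickness, depth, shape index) are smoothed by two
iterations of one-ring weighted averaging. The weights are uniform over the
vertex and its ring by default — the reproducible choice when no weighting
scheme is otherwise fixed — with inverse-edge-length weights available.
Floored thickness zeros (the medial-wall mask) keep their value and are
excluded from every neighbourhood average, so the mask cannot bleed into
its surroundings.

## Curvature and shape

Curvatures come from a per-vertex quadric fit: the two-ring neighbourhood
is projected into the tangent frame of the area-weighted vertex normal and
`w = p u + q v + a u^2 + b u v + c v^2` is fitted by least squares; the
principal curvatures are the eigenvalues of the Weingarten map assembled
from the first and second fundamental forms of the fit, with the sign
convention that closed convex surfaces with outward normals have positive
curvature. The window grows to three rings if the fit is rank-deficient
(fewer than six well-spread samples). On open meshes, boundary vertices are
flagged invalid and excluded from statistics. Validation is two-route: the
discrete estimator against the closed-form implicit-surface oracle
(`analytic_oracle()`, computed from gradients and Hessians of the defining
functions of a sphere, ellipsoid, and torus), agreeing within 5% at over
95% of vertices at the default density.

The shape index is `(2/pi) atan((k1+k2)/(k1-k2))`. Two orientations exist
in the literature and both are offered: `"koenderink"` (cap = +1) and the
default `"paper"` (its negation), under which the quantitative
classification operates: convex shapes in (-1, -0.375), saddles in
(-0.375, 0.375), concave in (0.375, 1), and nine minor bands with edges at
±1/8, ±3/8, ±5/8, ±7/8, so the three-way boundary is also a nine-way edge.
Band edges belong to the band closer to zero (ties toward saddle).
Umbilic points map to ±1; flat points (both curvatures below 1e-8 mm^-1)
carry shape index 0, a flat flag, and classify as saddle — a deterministic
rule for a measure-zero case. The index is scale-free, and the test suite
checks that classification is bit-identical under uniform rescaling.

## Thickness and the floor rule

Thickness at a pial vertex is the bidirectional closest-point distance:
`d1` from the pial vertex to the white surface (point-to-triangle, through
a uniform spatial grid over the triangles), `d2` from that foot point back
to the pial surface, thickness `(d1+d2)/2`. Anchoring at the pial vertex
matches reporting all measures on the pial surface; on the concentric-shell
fixture, swapping the roles of the surfaces changes the mean by under 2%.
Values below the 0.5 mm floor are set to exactly zero before measure
smoothing, and zeros are excluded from smoothing neighbourhoods and every
downstream statistic including the thickness ratio: in real reconstructions
those zeros encode the masked medial wall, not tissue. The floor is global
and configurable (`thickness_config()`); whether it should shrink for very
small cortices is left to the user, since the phantoms never approach it.

## The alpha surface

The exposed surface is built as the boundary of the morphological closing
of the pial solid with a ball of radius `alpha`: dilation then erosion,
evaluated on a voxel grid. No 3-D Delaunay machinery is involved; the
closing is computed from two distance fields. Near the surface (within 2.5
voxels) the signed distance to the pial triangles is exact, so wherever the
wrap touches the cortex — gyral crowns, the regions that dominate the
exposed area — it is sub-voxel accurate; far from the surface a Euclidean
distance transform of the rasterized surface shell stands in, accurate to
about one voxel, which only the sulcus-bridging parts of the wrap ever
see. The zero level of `min(signed_distance, alpha - erosion_distance)` is
extracted with marching tetrahedra (a consistent 6-tetrahedron cube split,
so the wrap is watertight by construction), the largest component kept,
lightly Taubin-smoothed, and its near-contact vertices snapped back onto
the pial surface (smoothing otherwise draws them slightly inside). Residual
protrusions of pial vertices beyond the wrap are pushed out until all lie
within the 0.1 mm containment tolerance. The node-based erosion transform
overestimates distances to the continuous region boundary by half a voxel
on average; that bias is subtracted, which brings the wrap area of an
analytic sphere within a fraction of a percent of truth at every tested
resolution. The default voxel size is 0.75 of the vertex density, widening
to `alpha/15` for very large wraps, with the grid capped at 6 million
nodes.

Automatic selection returns the smallest `alpha` whose wrap has reached
the exposed-area plateau: below it the wrap still descends into sulci and
its area falls as `alpha` grows; above it all sulci are bridged and the
area is stable. The sweep is geometric (factor 1.3) from the vertex density
to a third of the bounding-box diagonal, all evaluated on one fixed coarse
grid so resolution-induced area jitter cancels, with a final bisection to
5% relative tolerance. The stability threshold is 2%, chosen above the
measured ~1% jitter of the coarse grids and far below the 5–15% area drops
that bridging produces. On a sphere the plateau holds from the start and
the lower bound is returned; the selected value scales exactly with the
geometry. A closing-based wrap is always closed and always contains the
input, so closedness/containment cannot serve as the selection criterion
here — area stabilization is what "tightly wraps" means for this
construction.

Sulcal depth is the closest distance from each pial vertex to the wrap
triangles, then measure-smoothed like everything else. One geometric fact
deserves note: a ball of radius `alpha` bridging a fold mouth of width `w`
dips below the crowns by the sagitta `alpha - sqrt(alpha^2 - (w/2)^2)`, so
depth at the fundus is recovered in full only when `alpha` is much larger
than the fold width and the mouth is narrow; over wide, soft-shouldered
basins part of the nominal depth is genuinely invisible to any closing.
The depth-recovery test therefore uses a narrow-mouth pit phantom with
`alpha` far above the fold width, where the pipeline recovers the nominal
depth within 15% even after smoothing.

## Global metrics and statistics

GI is total over exposed area; folding amplitude the unweighted vertex
mean of depth; the thickness ratio the mean over convex vertices divided
by the mean over concave vertices, floored zeros excluded. Means are
vertex-level, not area-weighted — the unweighted average is what "averaged
over all points" implies, and on approximately uniform conditioned meshes
the two differ negligibly. Whole-cortex metrics pool both hemispheres
(concatenate with `combine_meshes()` before reduction); per-hemisphere
analysis is just running each separately. A perfectly smooth subject has no
concave vertices, so `summarize_subject()` reports the lissencephalic limit
of 1 for the ratio (missing class falls back to the overall mean), while
the strict `thickness_ratio()` raises an error — the distinction is
deliberate and documented in both places.

Group contrasts use Welch's t with Cohen's d on the pooled standard
deviation, on vertex samples pooled across subjects — consistent with the
extreme significance such contrasts reach at vertex-level n. Kernel density
profiles use a Gaussian kernel with Scott's-rule bandwidth
(`sd * n^(-1/5)`), overridable. Allometric fits are ordinary least squares
of `log10 y` on `log10 x` (semilog for the dimensionless GI), one point
per species (species means when N > 1), with the 95% CI of the slope from
the t distribution; `isometry_check()` reports whether the
geometric-similarity exponent (1/2 for lengths, 1 for areas, 3/2 for
volume) lies inside the CI, with a 1e-8 guard for the zero-width CIs of
numerically perfect fits. No multiple-testing correction is applied
anywhere, by design; users combining many contrasts should correct
downstream. `age_trend()` is a plain linear fit of a measure on age.

## Synthetic phantoms: what they emulate and what they do not

`make_sphere_pair()` is the analytic control: concentric icospheres with
exact thickness, curvature, GI = 1, and zero depth.

`make_bumpy_pair()` emulates a folded cortex. A random spherical-harmonic
field of a single degree (the fold wavelength control) is rank-uniformized
and passed through an offset sigmoid, and the result carves inward grooves
into a sphere: gyral crowns form a near-uniform envelope at radius `R`,
sulcal fundi plateau near `R - 2a`, and steep walls connect them, with
`groove_fraction` of the area in the grooves. This shaping is the one
place the generator departs from the simplest "sphere plus radial harmonic
bumps" construction, for a geometric reason: with plain bumps the crest
heights vary so widely that no ball radius bridges the folds flush — the
closing tracks mid-level terrain, the exposed area stays near the total
area, and fundus depth is unrecoverable. Folds in real cortex are grooves
cut into a smooth envelope, and every wrap-related property (GI above 1,
bridging, depth recovery) depends on exactly that structure. The white
surface is offset inward along the pial normal by
`t = base_thickness + (coupling/2) g`, where `g` is the normalized radial
deviation (+1 on crowns, -1 in fundi); `g` saturates at twice the
geometric sigmoid gain so that the injected thickness plateaus extend past
the class boundaries — otherwise the two measure-smoothing iterations mix
wall values into the class means and systematically shrink the injected
convex-concave gap. The generator rejects self-intersecting constructions
(negative white volume, or white poking through pial).

Defaults — the package's standard study conditions, chosen once from
geometric feasibility and realism and then left alone: `R = 30` mm (a
small-primate-scale hemisphere), fold half-depth 4 mm, degree 8 (fold
wavelength ~24 mm), groove fraction 0.35, sigmoid gain 2.5, base thickness
1.6 mm, coupling 0.4 mm, icosphere subdivision 4 (2562 vertices, ~1.5 mm
density). Feasibility means the inward offset stays below the crest
curvature radius (no cusps in the white surface), the three major classes
are all well populated, and measured thickness agrees with truth to a few
percent RMS. A 2.7 mm cortex, for instance, needs the same folding pattern
at 1.5 times the scale, which is what the corresponding test uses.

What the phantoms do not emulate: multi-scale folding spectra (one
harmonic degree only), hemispheric asymmetry or a medial wall, scanner
noise and segmentation artifacts, regional thickness patterns beyond the
single shape coupling, and mechanical buckling dynamics. Passing tests
therefore demonstrate that the estimators recover known geometry and
injected effects at realistic scales and resolutions — not that real
reconstructions are free of segmentation-driven bias.

`make_isometric_family()` rescales a base phantom's coordinates, giving
exact power laws (areas s^2, volume s^3, lengths s) for exponent-recovery
tests; `make_allometric_cohort()` builds cross-species cohorts whose
thickness and fold amplitude follow prescribed exponents of realized area
with optional lognormal noise. Volume is not independently prescribable
for a quasi-spherical solid, so the exponent map covers thickness and
amplitude.

## Numerical choices and limitations

Vertex indices are 1-based in memory (the R convention) and 0-based in
every on-disk format, converted at the I/O boundary; CSV vertex fields
carry an explicit 0-based `vertex` column. Units are always mm; no unit
inference from headers. Format auto-detection reads magic bytes before any
parsing. All generators and the pipeline are seed-deterministic; rerunning
a subject writes byte-identical CSVs.

Absolute length constants — the 0.5 mm thickness floor and the 0.1 mm wrap
containment tolerance — do not scale with the geometry, so depth is
scale-equivariant only up to them: on the isometric family the folding
amplitude exponent comes out 0.494 rather than exactly 0.5, while
thickness, volume, and exposed-area exponents are exact to discretization.
The wrap is grid-based: bridging geometry is resolved to about one voxel,
and depth in wide-mouthed folds is bounded by the sagitta argument above.
Curvature near flat or near-umbilic regions has a scale-free index but a
noisy direction; classification there is stabilized by the two smoothing
iterations applied to the shape index before binning. Test problem sizes
(subdivision 3–4 meshes, subdivision 5 where sub-millimetre sampling is
the point, five-scale families) are chosen so that the entire suite
exercises every stage end-to-end in well under an hour on one core while
keeping every tolerance meaningful.
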