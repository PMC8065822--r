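---
title: "Geostatistical biogeography with endemapr: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geostatistical biogeography with endemapr: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endemapr)
```

endemapr implements a landscape-scale analysis chain for species occurrence
records: cleaning, density and richness surfaces, the corrected Habitat
Specificity index over ecoregion-like patches, climatic association tests
(raster correlation, bioclim-profile clustering, SVM niche-overlap
detection), and Geographical Interpolation of Endemism (GIE). This vignette
is the package's account of the methods: the models and their assumptions,
the parameters that matter, the numerical conventions, and what the
synthetic validation does and does not demonstrate.

## Coordinates, projection, and grids

Occurrences are stored lon-first in decimal degrees. All densities and
endemism surfaces are computed on a planar grid in kilometres under the
world cylindrical equal-area projection on a sphere of radius 6371 km
(`x = R·lon_rad`, `y = R·sin lat`). The projection choice is a genuine
design decision: GIS toolchains used for this kind of analysis often leave
the projection at a dataset default, but a density in points/km² is only
meaningful if every cell has the same true area, which the cylindrical
equal-area projection guarantees exactly (its planar cell area equals the
spherical area, which the test suite asserts). The inverse is closed-form,
so round trips are exact to floating-point noise. Distortion of *shape*
grows toward the poles; for the subtropical latitudes the synthetic
landscapes emulate it is modest, and no statistic in the package depends on
shape. Distances that enter scientific definitions — the GIE
area-of-influence radius and kernel distances — use great-circle kilometres
on the sphere, not planar distance.

Grids use half-open cells `[edge, edge + cell)` with row 1 at the minimum
y, and the column/row counts always round *up* so the grid covers the
requested extent. Both conventions are fixed so results are bit-exact
reproducible.

## Record cleaning

Cleaning drops, in order: records missing species or coordinates; records
with out-of-range coordinates; records whose stated coordinate uncertainty
exceeds `max_uncertainty_m` (default 10 000 m — a deliberate,
logged configuration knob, since no community-wide threshold exists;
records with *no* stated precision are retained); and exact duplicates on
(species, lon, lat) at full float precision, keeping the first. Exactness
makes the duplicate rule deterministic; an optional `round_digits` knob
coarsens it when a dataset mixes precisions. "Doubtful" records — an
expert-judgement category in curated datasets — are out of scope for
automation. The report's counts always reconcile
(`n_input = n_retained + sum(dropped)`), and cleaning is idempotent.

## Density and richness surfaces

Point density counts points within `radius_km` of each cell centre and
divides by the neighbourhood area `pi·radius²`. Kernel density uses the
quartic (biweight) kernel `K(d) = 3/(pi h²)(1 − d²/h²)²` for `d < h` — the
kernel classically used by GIS density tools — so the surface integrates to
the summed weights for interior points. No edge correction is applied,
matching planar GIS practice: mass conservation is asserted only one
bandwidth away from the grid edge, and the analysis scripts report the edge
deficit rather than hiding it. The bandwidth has no universally correct
value; the package requires it explicitly, and the workflow uses 100 km on
continental extents (50 km default in the function signature) — wide enough
to bridge sampling gaps at museum-record densities, narrow enough to keep
regional structure.

Species richness uses a square tessellation (100 km in the workflow):
distinct species per cell, zero cells omitted. Squares rather than hexagons
keep cell membership a half-open floor operation, hence exactly testable.
The continuous richness surface is the quartic kernel applied to cell
centres weighted by richness — identical by construction to
`kernel_density(..., weights = richness)`, and tested as such.

## Corrected Habitat Specificity

With `n_i` the number of patches species `i` occupies and `m_j` the number
of species in patch `j`, the corrected index is

$$S_j = \sum_{i \,\in\, \text{patch } j} \frac{1}{n_i}$$

the area term of the original habitat-specificity formulation being
excluded (the standard correction when patches are ecologically, not
geometrically, delimited). The printed shorthand "`S_ij = ∑(m_j/n_i)`"
found in the applied literature is ambiguous; the summation-over-present-
species reading adopted here is the only one that is finite, patch-
comparable, and conserves `∑_j S_j = k` (the retained species count) —
an identity the package asserts to 1e-12 on every run and in a dedicated
property test. The index is incidence-based: extra localities of a species
inside a patch do not change any score.

Occupancy is built by even-odd ray casting. Patches must be disjoint
(overlap is an error, not a silent double count). A point exactly on a
shared boundary goes to the lexicographically smallest patch id — an
arbitrary but deterministic tie-break; species observed only outside all
patches are excluded from the matrix and listed.

## Climatic association

**Raster correlation.** Pearson's r over cells valid in both rasters, on a
shared grid; zero-variance bands are an error rather than a NaN.

**Profiles and clustering.** Per-taxon means of the 19 bioclim variables at
occurrence cells (nodata excluded and counted), compared by Euclidean
distance and WPGMA. Standardization before the distance defaults *off*,
matching how such profile tables are typically clustered in the applied
literature; the consequence — that large-magnitude variables like
temperature seasonality (°C·100) and annual precipitation (mm) dominate —
is real, and a `standardize` flag enables z-scoring when that is not
wanted. The package bundles a published five-taxon profile table (three
flea-beetle genera/subgenera and two host-plant genera) as a worked
example; under the unstandardized convention its smallest pairwise distance
(77.8) is the beetle–host pair *Calotheca*–*Searsia*, which therefore forms
the dendrogram's first merge.

**WPGMA.** Implemented directly: merge the closest pair at height equal to
their current distance; the merged cluster's distance to any third is the
plain average `(d₁+d₂)/2` regardless of sizes, which makes the linkage
reducible and the heights non-decreasing (asserted). Ties break
lexicographically on cluster labels (a cluster is labelled by its smallest
leaf), so results are deterministic even on degenerate inputs. The
independent oracle in the tests is `stats::hclust(method = "mcquitty")`:
cophenetic matrices must agree to 1e-12 over 1000 random matrices — a dual
route that keeps the implementation honest without delegating it.

**SVM niche overlap.** Two occurrence clouds in a climate space (the
workflow uses BIO1, BIO7, BIO14, BIO18) are non-overlapping iff a decision
boundary separates them perfectly. A near-hard-margin linear SVM
(cost 1e3) is tried first; on any training misclassification, a
polynomial-kernel SVM (degree 3, coef0 1) is tried; remaining
misclassifications mean overlap, quantified as the misclassified
percentage. Attributes are standardized internally (an affine transform
that changes no separability outcome but keeps the kernel matrix well
conditioned when variables differ by orders of magnitude). The
misclassification convention is the sign of the decision boundary on the
training points. Degenerate inputs (both groups a single duplicated point)
are reported as complete overlap, not an error.

## Geographical Interpolation of Endemism

Each species is summarized by the centroid of its occurrences (mean in
equal-area coordinates, mapped back to lon/lat) and an area-of-influence
radius — the maximum great-circle distance from centroid to occurrence.
Classes are disjoint radius intervals, (0, 100] km (class 1) and
(100, 300] km (class 2); species beyond the last bound are not endemic at
these scales. A `nested = TRUE` flag includes narrow-range species in wider
classes, since both conventions exist in practice and the choice is not
forced by the method.

Within a class, each species contributes a *peak-normalized* quartic kernel
`(1 − d²/h²)²` around its centroid, with `h` the class bound by default (a
per-species option uses the species' own radius floored at one cell).
Peak normalization — rather than the mass normalization of a density — is a
deliberate choice: the summed surface then reads directly in
"species-equivalents overlapping here", so the ≥ 2-synendemic-species
threshold is meaningful as a count. Its consequence is worth stating: cells
reach the threshold 2 only where at least two kernels are jointly high, so
two species whose centroids are far apart relative to `h` will not form an
area even if their kernels barely touch — with three or more species the
threshold is correspondingly easier to reach. Areas of endemism are
8-connected components of threshold cells, each annotated with every
species whose kernel is positive inside it; lowering the threshold can only
grow the area set (monotonicity, tested). The consensus map keeps each
class's areas as distinct labelled layers, preserving nesting. Exported
GeoJSON geometries are the exact cell unions (rectangle runs), not
smoothed outlines. The threshold defaults to 2 but is a parameter, since
single-species areas are sometimes reported in practice.

## The synthetic study system

The generator's defaults mirror the scale of a continental occurrence
study: a 4000 × 3000 km extent anchored in southern-hemisphere latitudes,
132 Voronoi landscape patches (the ecoregion count of the sub-Saharan
layer this emulates), 6343 plant and 162 insect localities with 100 and
17 species (counts taken from a representative host-plant genus and insect
genus in such datasets), insect–plant association strength 0.9 with a
30 km tether, and two endemic assemblages of 4 and 3 species
(`spread_km = 40`, matching the synendemic counts of typical recovered
areas) about 2000 km apart. The analysis grid uses 25 km cells at this
extent — the package supports 1 km cells and the tests exercise them on
small extents, but a continental 1 km grid adds nothing to the validation
logic. These values were fixed once, before any validation was run, and
are not tuned.

Components:

* **Landscape** — Voronoi tessellation of uniform seeds, built by clipping
  the extent rectangle with perpendicular-bisector half-planes
  (Sutherland–Hodgman). Patches are convex, disjoint, and partition the
  extent (asserted to 1e-6 relative area).
* **Climate** — each of the 19 layers is a planar gradient with a
  variable-specific plausible range plus `climate_noise` times a smooth
  bump field and white noise; `BIO5 = BIO6 + positive range` and
  `BIO7 = BIO5 − BIO6` hold everywhere by construction. With
  `climate_noise = 0` every layer is an exact plane, which the tests
  recover by least squares. The layers are *not* a climate model: ratios
  like isothermality are generated as independent planes, not derived.
* **Point patterns** — plants follow a Thomas-like parent–offspring
  process (parents uniform, offspring Gaussian, ~20 offspring per parent,
  50 km spread): the simplest clustered process with tunable clumping.
  Each insect point is, with probability `association_rho`, a random plant
  point plus Gaussian displacement; otherwise uniform. Tethering makes rho
  directly interpretable — it *is* the fraction of insect localities tied
  to the plant pattern — and recoverable: over 20 seeds the kernel-density
  correlation at rho 0.9 beats rho 0 in at least 19 (observed: 20).
* **Endemics** — per assemblage, `k_species` species drawn uniformly in a
  disc of `spread_km`, so every radius is bounded by twice the spread and
  the expected recovery (two class-1 areas with the planted species lists)
  is known exactly.

What passing these tests shows: the implementation computes what it claims
on data whose truth is known. What it does not show: robustness to the
pathologies of real museum data — spatially biased collecting, gross
georeferencing errors, taxonomic drift between sources, coastline-clipped
ranges — none of which the generator emulates. Real ecoregions are also
concave, multi-part, and hole-ridden; the polygon machinery supports such
geometries (and is tested on multipolygons), but the synthetic landscape
never produces them.

## Numerical conventions and degenerate inputs

* Cell membership, tessellation, and duplicate detection are exact float
  operations on half-open intervals; no epsilons except where stated.
* Kernel support is strict (`d < h`); a point exactly at distance `h`
  contributes zero.
* Boundary points in occupancy go to the lexicographically smallest patch;
  WPGMA ties break lexicographically on labels.
* Empty inputs return empty-but-typed results (zero rasters, empty score
  tables, empty area lists); errors are reserved for contract violations
  (overlapping patches, mismatched grids, zero-variance correlation).
* Raster files: ESRI ASCII grids print 17 significant digits, so the round
  trip is bit-exact; the GeoTIFF writer/reader is a minimal single-band
  uncompressed float64 implementation (pixel scale, tiepoint and nodata
  tags) that reads back its own subset bit-exactly and rejects anything
  else.
* All generators and the pipeline are pure functions of (config, seed);
  the test suite asserts bit-identical reruns.

## Problem sizes

The validation suite runs at deliberately reduced sizes chosen as the
smallest that still exercise every code path and planted-structure
recovery: pipeline tests use a 2000 × 1500 km extent with 50 km cells and
a few hundred points; the WPGMA oracle comparison uses 1000 matrices of up
to 8 leaves; the association-recovery experiment uses 20 seeds of a
400-plant/150-insect system. The `analysis/` workflow runs the full
default configuration.

## Known limitations

* The equal-area grid is one projection choice; analyses that used a
  different (or no) equal-area projection will differ at the margins of
  large extents.
* No KDE edge correction: densities within one bandwidth of the study-area
  edge are biased low.
* The SVM overlap test reports training-set separability; it is a
  geometric statement about the sampled points, not a generalization claim.
* GIE's peak-normalized kernels make the synendemic threshold a count, but
  (see above) sparse two-species clusters with well-separated centroids
  can fall below threshold 2; the threshold and bandwidth rules are
  parameters precisely because toolbox conventions vary.
* Shapefile input is not supported; patch layers are GeoJSON (RFC 7946).
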