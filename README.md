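# endemapr

Geostatistical biogeography of species occurrence records in R: from raw
occurrence tables to density surfaces, habitat-specificity scores, climatic
association tests, and areas of endemism.

The package grew out of a recurring analysis pattern in insect–host-plant
biogeography: given museum/GBIF occurrence localities for a few insect taxa
and their candidate host plants, quantify (i) where each group concentrates,
(ii) which landscape patches (ecoregions) contribute disproportionately to
its richness, (iii) whether the insect and plant distributions and climatic
niches are associated, and (iv) where narrow-range endemics cluster into
areas of endemism. Every stage is implemented as a tested, reusable function
and exercised end-to-end on synthetic landscapes with planted structure, so
each statistic can be validated against a known ground truth.

## The statistics at its core

**Corrected Habitat Specificity.** For landscape patches (ecoregions)
`j = 1..p` and species `i = 1..k`, with `n_i` the number of patches species
`i` occupies and `m_j` the number of species present in patch `j`, the
corrected (area-free) habitat specificity of patch `j` is

    S_j = sum over the m_j species present in j of (1 / n_i)

A patch full of one-patch endemics scores high; a patch shared with
widespread species scores low. The index conserves the species count
exactly: `sum_j S_j = k`, which the package asserts on every run.

**Density and richness surfaces.** Point density (count within a circular
neighbourhood / its area) and quartic-kernel density
`K(d) = 3/(pi h^2) (1 - d^2/h^2)^2`, computed on an equal-area projected
grid; species richness on a square tessellation, smoothed into a continuous
surface by kernel-weighting cell centres with their richness. Pairs of
surfaces are compared with Pearson's r over jointly valid cells.

**Climatic association.** Per-taxon means of the 19 bioclim variables,
compared by Euclidean distance and WPGMA (McQuitty) clustering, and a
two-stage SVM overlap test (near-hard-margin linear, then polynomial
kernel): two taxa's climatic niches are non-overlapping iff some boundary
separates their occurrence points perfectly; the misclassified fraction
measures overlap depth.

**Geographical Interpolation of Endemism (GIE).** Each species is reduced
to the centroid of its occurrences and an area-of-influence radius (the
great-circle distance to its farthest occurrence). Species with radius
<= 100 km (class 1) or 100–300 km (class 2) contribute a peak-normalized
quartic kernel around their centroid; summed per class, the surface reads
in "number of overlapping species", and connected regions with >= 2
synendemic species are the areas of endemism, combined across classes into
a consensus map.

## Worked example

```r
library(endemapr)

# bundled mean bioclim profiles of three flea-beetle taxa and two
# host-plant genera
m <- taxon_climate_means()
d <- euclidean_matrix(m)
round(d["Calotheca", "Searsia"], 1)
#> [1] 77.8

tr <- wpgma(d)
tr$merges[1, ]
#>           a       b   height
#> 1 Calotheca Searsia 77.77617
```

The unstandardized Euclidean distance between the *Calotheca* beetle and
*Searsia* plant profiles (77.8, dominated by the temperature-seasonality
and annual-precipitation axes) is the smallest of the ten pairwise
distances, so the WPGMA dendrogram's first merge pairs the beetle with its
host plant — the climatic-profile signature of the association.

A full synthetic study, from landscape generation to the consensus map of
endemism, is the `analysis/` workflow:

```sh
Rscript analysis/01_simulate.R        # landscape, climate, point patterns
Rscript analysis/02_clean.R           # record cleaning with reports
Rscript analysis/03_density_richness.R
Rscript analysis/04_habitat_specificity.R
Rscript analysis/05_association.R
Rscript analysis/06_endemism.R
```

Each script narrates what it finds and writes its tables under `results/`.
On the default configuration (seed 1) the workflow reports, among others:

```
sum(S) = 17.000000000000 vs 17 retained species (conservation check)
density correlation: r = 0.324 (kde), ... rho=0 null r = -0.053
published profiles: first WPGMA merge = {Calotheca, Searsia} at height 77.8
consensus: 2 areas of endemism
  class 1 area 1: 4 species (assemblage1_sp01;...;assemblage1_sp04)
  class 1 area 2: 3 species (assemblage2_sp01;...;assemblage2_sp03)
```

i.e. the specificity index conserves the species count, the planted
insect–plant association (strength 0.9) produces a clearly positive density
correlation against a near-zero null, and GIE recovers exactly the two
planted endemic assemblages with their species lists.

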