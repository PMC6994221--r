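---
title: "Quantifying RyR2 tetramer arrangement, cluster size and calcium-spark statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RyR2 tetramer arrangement, cluster size and calcium-spark statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ryrspat)
```

## The biological problem

Type-2 ryanodine receptors (RyR2) are the calcium-release channels of the
cardiac junctional sarcoplasmic reticulum. Each channel is a homotetramer
whose cytoplasmic face is, to a good approximation, a square about 27 nm on
a side (footprint 729 nm²). Within a dyad the tetramers pack
non-randomly: neighbouring squares either abut almost edge-to-edge
("side-by-side", centre-to-centre spacing near 28 nm) or interdigitate
partially ("checkerboard", spacing near 34 nm with facing edges overlapping
by roughly 7 nm). How much of each motif is present, how large the surface
clusters are, and how many channels a cluster contains all change with the
cell's signalling state, and those changes track the statistics of
spontaneous Ca²⁺ sparks.

`ryrspat` implements the quantitative machinery for this kind of study:

1. **geometry and arrangement** — pair relations between square particles,
   the checkerboard/side-by-side/both/isolated classifier, centre-to-centre
   nearest-neighbour distances (NND), alpha-shape areas and the tetramer
   coverage fraction of an array;
2. **dSTORM pipeline** — blink quality control, rasterization to a 10-nm
   binary grid, 50-nm single-linkage clustering, alpha-shape cluster areas
   with a 1600-nm² noise filter, and estimation of tetramers per cluster;
3. **statistics** — empirical CDFs, the k-sample Anderson–Darling test,
   hierarchical (rat → cell → spark) bootstrap comparison of spark
   parameters, and the Holm–Bonferroni sequential correction;
4. **synthetic data** — generators that emulate tetramer maps, blink
   clouds and nested spark tables so every stage can be exercised and
   calibrated without microscopy data.

## The arrangement classifier

Two tetramers are *adjacent* when their sides are parallel (angular
difference modulo 90° at most `angle_tol`, default 10°), the facing edges
are separated by a gap of less than 3 nm, and the projection of one facing
edge onto the other is positive. Adjacent pairs with projected overlap
below 18 nm (two thirds of the 27-nm side) are *checkerboard*; pairs at or
above 18 nm are *side-by-side*. Per tetramer, the labels of all adjacency
relations are combined: all-checkerboard, all-side-by-side, mixed
("both"), or no adjacency at all ("isolated").

Boundary conventions are deliberate and configurable:

* the gap rule is strict (`gap < 3`), and a slightly negative gap is
  tolerated because manually fitted boxes carry a placement error of a few
  nanometres and may interpenetrate marginally;
* overlap exactly at 18 nm classifies side-by-side;
* zero projected overlap (a corner-to-corner contact) does **not** create
  adjacency, so corner contacts leave a tetramer isolated unless it has
  other neighbours.

Gap and overlap are measured in the frame of the two squares' mean
orientation; for pairs within the 10° parallel tolerance the residual tilt
of each square in that frame is below 5° and is ignored in the edge
arithmetic (the difference is below 1.5% of the gap). The package carries
a second, independent implementation of the same measurement
(`pair_relation_edges()`) that enumerates explicit polygon edges and
computes support-line distances; the test suite verifies exact label
agreement between the two routes on random square pairs.

```{r classifier}
a <- list(x = 0, y = 0, theta = 0)
pair_relation(a, list(x = 28, y = 20, theta = 0))
classify_pair(pair_relation(a, list(x = 28, y = 20, theta = 0)),
              arrangement_params())
```

## Alpha shapes

Cluster and array boundaries are concave, so areas are computed with alpha
shapes rather than convex hulls: the Delaunay triangulation of the point
set is filtered to triangles whose circumradius is at most the alpha
radius, and the area is the sum over kept triangles. The alpha radius
defaults to 50 nm, the same length scale as the cluster linkage rule,
because the original analysis software does not report its alpha value and
50 nm is the scale at which the data itself defines "the same cluster".

The triangulation is a Bowyer–Watson implementation with an incircle
determinant evaluated on coordinates normalised to a centred, power-of-two
scaled box. Two numerical details matter:

* pixel-grid input makes many point quadruples exactly cocircular; the
  determinant is then exactly zero in floating point and either diagonal
  of the quad may be produced — all four candidate triangles share one
  circumcircle, so the alpha filter and the summed area are unaffected by
  the choice;
* the bounding super-triangle is placed beyond any circumcircle of radius
  alpha, which guarantees that every triangle the alpha filter can keep
  survives super-vertex removal. Hull-boundary slivers with larger
  circumradii may be lost, but they are outside the alpha complex by
  construction.

`coverage_fraction()` divides the summed tetramer footprint area
(n × 729 nm²) by the alpha-shape area of all tetramer corners; a single
tetramer's shape is its own footprint (coverage exactly 1).

## The dSTORM pipeline

`dstorm_pipeline()` chains four stages with fixed order:

1. **`qc_filter()`** keeps blinks inside the z slice (default a 150-nm slab)
   with XY error ≤ 10 nm, Z error ≤ 40 nm and goodness of fit ≥ 0.9, then —
   in a second, separate stage — removes survivors whose nearest surviving
   neighbour in 3D is farther than 30 nm. Quality runs before the
   neighbour test so that neighbour support comes only from believable
   localizations; the neighbour test is applied once, not iterated.
2. **`rasterize_localizations()`** maps blinks to 10-nm half-open pixels
   anchored at the minimum x, y of the filtered input; a pixel holding
   exactly one blink with no lit 8-neighbour is switched off.
3. **`link_clusters()`** forms single-linkage components of lit pixels with
   centre separation ≤ 50 nm.
4. **`cluster_areas()`** computes alpha-shape areas from lit-pixel centres
   and drops clusters below 1600 nm² (which also removes isolated single
   tetramers) or with fewer than 3 non-collinear pixel centres.

Tetramer counts follow from
`round(area × coverage / 729)` with rounding half away from zero, where
`coverage` is the group-level coverage fraction measured from tomograms.
Because this is a monotone transform with one group-level scalar, the
median estimated count over a cluster set equals the transformed median
area up to rounding ties.

```{r worked-example}
estimate_tetramers(12200, cluster_params(coverage = 0.495))
```

### Known bias of the pixel-support area

The alpha shape is drawn on lit-pixel centres, and pixels light up wherever
any blink falls. Blink scatter (localization error of ~5 nm after QC) plus
the 10-nm pixel quantization therefore add a rim of roughly 9 nm per side
to a recovered cluster relative to the generating footprint. The bias is
perimeter-proportional — about +18% in area for a 16-tetramer cluster,
+11–15% for a 36-tetramer cluster — and uniform across treatment groups,
so it cancels from group comparisons. The planted-cluster recovery test
plants 36-tetramer clusters (well inside the observed 2–100
tetramers-per-cluster range) so that its 25% area tolerance tests cluster
recovery and not this known offset.

## Statistical machinery

**k-sample Anderson–Darling.** Distributions of NNDs, cluster areas and
tetramer counts are compared with the rank-based k-sample
Anderson–Darling test in its tie-adjusted midrank version — midranks
matter because distances recorded at finite resolution and integer counts
carry heavy ties. The p-value comes from the published five-point
critical-value interpolation of the standardized statistic, extended
log-linearly beyond the largest tabulated point so that p stays monotone
in the statistic; the interpolation is tabulated up to the 0.25 level, so
larger p-values are reported as values at or above 0.25 rather than as
precise probabilities. The suite checks the statistic against an
exhaustive permutation null at small sample sizes and the type-I error at
the 0.01 level by simulation.

**Hierarchical bootstrap.** Spark parameters are nested: sparks within
cells within rats, with non-trivial variance at each level. Group
comparisons resample the hierarchy — rats with replacement, then cells
within each sampled rat, then sparks within each sampled cell — and track
the difference of group means, where a group mean is the mean of rat means
of cell means so that no animal or cell dominates through its spark count.
The two-sided p-value is the tail fraction of the B ≥ 2000 bootstrap
differences around zero with the usual +1 correction. Spark parameters
are compared on the log scale (they are approximately log-normal);
SR-content-normalized frequency is compared untransformed. The resampling
core is compiled (Rcpp) and drawn from R's RNG, so `set.seed()` governs
reproducibility. Simulated calibration at the declared design (two groups,
4 rats × 5 cells × 30 sparks) puts the type-I rate near 0.04–0.05 at
α = 0.05.

**Holm–Bonferroni.** With six treatment groups there are fifteen pairwise
comparisons per parameter. `holm_bonferroni()` emits the full five-column
ledger (comparison, p, unadjusted significance, rank-dependent critical
value α/(m−rank+1), sequential reject flag) with a strict inequality at
the boundary, matching the convention that a p-value exactly at its
critical value is not rejected.

```{r holm}
holm_bonferroni(c(0.0005, 0.012, 0.004, 0.3), alpha = 0.05)
```

## What the synthetic generators emulate — and what they do not

`gen_tetramer_array()` builds arrays from packing motifs: side-by-side
runs at 28-nm spacing, checkerboard runs at 34-nm spacing with 7-nm edge
overlap (lateral offset = side − overlap = 20 nm, axial offset
√(34² − 20²) ≈ 27.5 nm, so the facing-edge gap is ≈ 0.5 nm), mixed triples
and isolated singletons, placed ≥ 100 nm apart with random motif rotation
and per-tetramer positional (1 nm) and angular (2°) jitter. Jitter is
redrawn per motif whenever it would break the intended adjacency class or
interpenetrate footprints by more than ~2% of a footprint (the tolerance
reflects the ~3-nm placement error of manually fitted boxes). The
generator therefore guarantees its ground-truth labels, which is what
makes end-to-end classifier recovery tests meaningful.

`gen_localizations()` scatters a Poisson number of blinks per tetramer
uniformly over the square footprint plus a Gaussian localization error,
adds uniform coverslip background, and marks a configurable fraction of
blinks with failing QC properties. `gen_spark_table()` draws log-normal
spark parameters with additive rat- and cell-level random effects on the
log scale (defaults: geometric means 0.45 ΔF/F₀, 25 ms FDHM, 1.9 µm FWHM;
spark-level log-sd 0.35/0.30/0.25; rat sd 0.08; cell sd 0.15; 4 rats ×
5 cells × 30 sparks per group), values typical for permeabilized rat
ventricular myocytes.

None of the generators model photoswitching kinetics, antibody linkage
displacement, drift, membrane curvature or the 3D geometry of the dyadic
cleft. Passing tests on synthetic data therefore demonstrate that the
pipeline recovers what it is defined to recover under controlled
conditions — not that any particular biological dataset satisfies those
conditions.

## Numerical and design choices

* **Strict 2D geometry.** Tetramers are taken as planar squares with
  orientations reduced modulo 90° (4-fold symmetry); tilt correction and
  membrane curvature are upstream of this package.
* **Overlap measured on the 27-nm body.** Whether overlap should be
  measured on the tetramer body or on the smaller central turret is not
  observable from published material; the body is used.
* **Corner-to-corner contacts** (~39-nm spacing) are descriptive features
  of NND histograms, not a classification category.
* **Rounding** of tetramer counts is half away from zero.
* **Pixel origin** is anchored at the minimum x, y of the filtered
  localizations; a different anchor shifts areas by at most one pixel
  width along each boundary, uniformly across groups.
* **Pairwise AD tests are reported uncorrected** alongside the omnibus
  k-sample test; whether the original analysis corrected its pairwise CDF
  comparisons is not stated, so correction is left to the caller (the
  Holm ledger accepts any p-vector).
* **Simulation sizes** used by the tests and the acceptance script —
  2000 tetramers for fraction recovery, 4 planted 36-tetramer clusters,
  500 Anderson–Darling null replicates, 300 hierarchical-bootstrap null
  replicates at B = 2000 — were chosen so the whole suite runs in a few
  minutes on one core while keeping Monte-Carlo noise well inside each
  test's tolerance.

## Limitations

* The alpha radius of the original cluster boundaries is unknown; 50 nm is
  a declared choice, and absolute areas (though not group contrasts)
  depend on it.
* The asymptotic Anderson–Darling p-value is approximate for small
  samples and heavy ties; the permutation route used in the tests is exact
  but exponential.
* The hierarchical bootstrap slightly underestimates between-rat variance
  with few rats (a generic property of resampling few top-level units);
  at 4 rats per group the measured type-I rate remains close to nominal.
* Absolute tetramers-per-cluster estimates inherit both the coverage
  fraction's sampling error and the pixel-support area bias; they are
  designed for cross-group comparison, not for counting channels in any
  single cluster.
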