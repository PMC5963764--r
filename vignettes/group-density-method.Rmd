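---
title: "Estimating urban carnivore group density from citizen-science sightings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating urban carnivore group density from citizen-science sightings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carnidens)
```

## The problem

Red foxes (*Vulpes vulpes*) and Eurasian badgers (*Meles meles*) live in
social groups defending exclusive territories, so their abundance in towns
is naturally expressed as *social-group density* (groups km^-2^). In
suburbs, the patchwork of private gardens rules out spotlight transects and
field-sign surveys, but it puts a potential observer in almost every
garden. The method implemented here turns that to advantage: questionnaires
delivered to every household ask residents whether they have seen fox cubs
(or badger setts/sightings) at their residence; returns are geocoded, and a
geometric pipeline converts the point data into a relative group density.
Group density is epidemiologically the right currency — rabies and
*Echinococcus* contingency models operate on groups, not individuals — and
it is more stable over time than total population size.

The pipeline has four geometric stages:

1. **Respondent coverage.** Every valid return is buffered by 50 m (about
   two gardens in semi-detached housing — the distance within which a
   householder is assumed aware of cub or sett activity) and the discs are
   unioned (`respondent_coverage()`).
2. **Pocket integration.** The union is concave. Fox territories are
   convex, so an unsurveyed cavity mostly surrounded by surveyed gardens is
   almost certainly part of some territory; excluding it would understate
   the surveyed area and overstate density. A cavity is merged into the
   survey area when at least 75% of its edge borders respondent coverage or
   surveyed greenspace (`integrate_pockets()`).
3. **Record integration.** Fox cubs use several rendezvous sites typically
   under 200 m apart, and badger annex setts usually lie within 150 m of
   the main sett, so multiple households report the same group at different
   points. Records spaced less than 200 m apart are merged into a single
   centroid, one per social group (`cluster_records()`).
4. **Survey area and density.** A 200 m buffer around each centroid is
   merged with the survey boundary; group density is the centroid count
   divided by the resulting area (`overall_survey_area()`,
   `site_density()`).

City-level means, individual densities (group density x mean group size:
3.4 for foxes, 5.5 for badgers), houses-per-group and the national
suburban extrapolation (x 9,116.4 km^2^, the 7% of England classed
suburban) follow by plain arithmetic (`aggregate_city()`,
`national_extrapolation()`).

## A worked example

The bundled site table carries the published per-site results; the summary
operations re-derive every reported aggregate from it:

```{r table2}
t2 <- table2_sites()
fgd <- summarize_mean_se(t2$fgd)
c(mean = round(fgd$mean, 2), se = round(fgd$se, 2))
cities <- aggregate_city(data.frame(city = t2$city, group_density = t2$fgd))
round(mean(cities$mean_group_density), 2)
national_extrapolation(fgd$mean, fgd$se)
```

A full synthetic run:

```{r pipeline}
pts <- system.file("extdata", "synthetic_site", "synthetic_points.csv",
                   package = "carnidens")
cfg <- run_config(sites = list(list(points = pts,
                                    config = list(site_id = "synthetic"))))
res <- suppressMessages(run_pipeline(cfg))
res$estimates[, c("site_id", "n_groups", "survey_area_km2", "group_density")]
```

This fixture (seed 2024, four true groups) deliberately estimates *five*
groups: one group's rendezvous sites spread more than 200 m apart, the
known double-counting failure mode of distance-based integration, which is
why the sensitivity sweep below exists.

## Design decisions

Several steps are stated as intent rather than algorithm in the method's
original GIS formulation; this package makes each one explicit and
deterministic.

**Clustering semantics.** GIS point-snapping tools can be order-dependent.
We use single-linkage connected components of the graph joining records at
pairwise distance *strictly* below the threshold, with the arithmetic-mean
centroid. This is order-invariant and matches the stated rule ("records
spaced less than 200 m apart"). Chaining can produce clusters wider than
the threshold; cluster diameters are logged, and `integration_sweep()`
quantifies the sensitivity of counts and densities to the threshold.

**Pocket detection.** No detection mechanism is prescribed for cavities, so
candidates are found by morphological closing (dilate then erode by 200 m,
the scale of territory geometry): candidate pockets are the closing minus
the coverage, plus interior holes (edge fraction 1 by construction). The
edge fraction of a candidate is the share of its perimeter within 1 m of
the coverage/greenspace boundary, measured on a perimeter sampling no
coarser than the 1 m tolerance; the tolerance absorbs floating-point and
circle-segmentization error. Integration defaults on for both species and
every accept/reject decision is logged with its computed fraction.

**Geometry backend.** All polygon booleans and offsets use the Clipper
library (package `polyclip`); circles are 64-segment polygons (area error
< 0.2%, well below the 2-decimal reporting precision). Area is the planar
shoelace sum over rings (holes subtract) scaled to km^2^; coordinates must
be projected meters, and tables whose coordinates all lie in
longitude/latitude ranges are rejected. Unions of thousands of respondent
discs run through a spatial-tile divide-and-conquer (union per ~250 m
tile, then pairwise merges), which is an order of magnitude faster than a
single boolean call and agrees with it to within Clipper's coordinate
quantization (relative ~1e-8).

**Reporting conventions.** SEs use the sample SD over sqrt(n). The
national extrapolation multiplies the 2-dp-rounded mean density, matching
the printed arithmetic convention, and rounds to whole groups. The 95% CI
is a plain normal approximation and is labelled as such. Spearman's rank
correlation is reported with both df = n - 1 (the convention used
alongside the sightings-density comparison) and the textbook n - 2. The
VIF screen removes the largest VIF at or above 2.5 sequentially, with
exact collinearity reported as infinite and removed first, and ties broken
by column order with a warning.

**Pooling and de-duplication.** Records from both survey years are pooled;
a cub sighting reported at exactly the same coordinates in both years is
counted once (the original method does not state this; exact-coordinate
de-duplication is our assumption, and a year filter is available).
Respondents at identical coordinates — flats at one address — all count
for response-rate reporting but enter the coverage geometry once.

## The synthetic generator

`simulation_config()` encodes the study conditions as defaults: a
1 km^2^ block, true density 3.6 groups km^-2^ (the observed study mean,
within the observed 1.7–4.8 range), centers at least 300 m apart (about
the diameter of the 0.14 km^2^ urban fox home range), 2–5 activity sites
per group within 200 m (fox) or 150 m (badger) of the center, households
on a jittered grid at 2,200 km^-2^ (the study mean), 19% response and a
50 m detection radius. Territories are Voronoi cells of
sequential-inhibition centers — the simplest generative model satisfying
territorial exclusivity; centers are inset from the window edge by the
scatter radius so whole groups lie inside the surveyed block. Sequential
random placement can jam below the feasible count, so placement restarts
when stuck, within a global cap of 10,000 proposals, and errors only if
the cap is exhausted. Detection is deterministic within the detection
radius, with an optional false-positive rate defaulting to zero (field
validation of the original surveys added no extra cub sightings).

What the generator does *not* emulate: uneven questionnaire uptake,
geocoding error, multiple litters per territory, non-convex or
non-exclusive territories, and between-year population change. Passing
recovery tests therefore validate the geometric estimator under its own
assumptions, not the questionnaire process itself.

`recovery_regime_config()` is the well-separated validation regime: a
2 x 2 km block with 12 groups (3 km^-2^), spacing ≥ 500 m, scatter
≤ 100 m and 2,000 households km^-2^. There, merging is geometrically
impossible (500 > 2 x 100 + 200) and splitting cannot reach the strict
200 m threshold, so the estimator should recover the exact count almost
always once response reaches ~0.3. At full response the density is still
biased low by ~7–10%: the survey area dilates the block by the 50 m
respondent buffer and the 200 m centroid buffers spill outside it, while
the true density denominator is the block itself. The bias shrinks with
block size (it scales with perimeter/area, which is why the validation
block is 2 km rather than 1 km a side) and mirrors the method's own
caveat that incomplete coverage inflates or deflates the area
denominator. The recovery experiment reports it rather than correcting
it.

## Problem sizes and numerical tolerances

Recovery experiments use 100 replicates per condition; the clustering
oracle comparison uses 100 random 200-point instances. Unit tests use
smaller instances of the same properties. Geometric equalities are
asserted to 1e-6 relative where file round-trips or Clipper quantization
are involved, 1e-9 where arithmetic is exact, and 1% against closed-form
circle areas (the segmentization error is ~0.16%). Ring validity is
checked by comparing the shoelace area before and after even-odd
resimplification, with a 1 cm^2^ absolute floor so that quantization
slivers are not misflagged.

## Known limitations

- The integration distance is a biological constant, not estimated from
  the data; where home ranges are larger, 200 m double-counts groups
  (hence the sweep).
- Density is *relative*: detection within 50 m of a respondent is assumed
  certain and false positives absent.
- The pocket rule's closing radius (200 m) and adjacency tolerance (1 m)
  are package choices; both are logged per decision so any pocket can be
  hand-checked.
- Published per-site values can be reproduced only from the bundled
  printed table (raw point data were never deposited); the geometric
  stages are validated by construction and simulation instead.
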