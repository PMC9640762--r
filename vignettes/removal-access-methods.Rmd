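---
title: "Methods: facility readiness, referral rationality, and travel-time access"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: facility readiness, referral rationality, and travel-time access}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(removalaccess)
```

This vignette documents the models implemented in `removalaccess`, the
assumptions behind them, the numerical conventions, and what the
synthetic-data generators do and do not emulate.

## 1. Readiness classification

### Model

A facility is classified by a purely conjunctive scheme adapted from the
WHO Service Availability and Readiness Assessment (SARA) tradition: a
facility is ready at a level if and only if *every* required condition at
that level holds. There is no weighting and no partial credit — a single
missing scalpel makes a facility `NOT_READY`, which is the intended
semantics for a surgical service where each item is individually
necessary.

Three components are evaluated (`general_service_ready()`,
`human_resources_ready()`, `equipment_ready()`), and
`classify_readiness()` combines them:

* `DIFFICULT` ⟺ all regular **and** all difficult-removal criteria hold;
* `REGULAR` ⟺ all regular criteria hold (but not all difficult ones);
* `NOT_READY` otherwise.

Difficult-removal criteria are a strict superset of the regular ones, so
`DIFFICULT` facilities always satisfy the regular criteria (a nesting the
test suite asserts for arbitrary inputs, together with monotonicity:
turning any checklist item on can never lower a facility's level).

### Criteria are data

The criteria live in a declarative table (`readiness_criteria()`), not in
code, so the scheme can be adapted to other services or survey
instruments. One rule genuinely admits two readings in the published
record: the sterile-dressing requirement appears both as "antiseptic, and
cotton balls or sterile gauze" and as "sterile gauze, or antiseptic and
cotton balls". We implement the second — `gauze ∨ (antiseptic ∧ cotton)`
— as the default because it is the phrasing used in the by-component
results table this package reproduces, and expose the first as
`readiness_criteria("antiseptic_and_cotton_or_gauze")`. The sterile
equipment tray is required for difficult removals even though the
published summary table has no row for it; its row is included in our
summary output.

Two indicators are deliberately *reported but never scored*: functioning
autoclave and having ≥ 2 removal-trained providers
(`additional_indicators()`). A single trained-in-removal staff count is
used for both levels because the underlying survey instrument did not
distinguish training for regular vs difficult removals.

### Rounding

District summaries print whole percentages rounded half-away-from-zero
(`round_half_up()`), the commercial rounding used in the published
tables (e.g. 23/26 → 88, 31/39 → 79, 8/39 → 21). Base R's
round-half-to-even would disagree on exactly these cells. A 1e-9 epsilon
guards binary-floating-point representations of exact halves.

## 2. Referral networks and rationality

Each surveyed facility reports at most one referral destination, which
yields a functional graph. Networks are the in-neighborhoods of receiving
facilities: a receiving facility plus everyone referring to it. Observed
referral systems are star-shaped; we therefore allow chains (a → b,
b → c) structurally but raise a warning, classify a facility that both
receives and refers as `RECEIVING` (receiver precedence), and treat
cycles as errors.

The rationality audit (`assess_rationality()`) asks whether the
facilities that must absorb cases — receivers, plus standalone facilities
that keep their own cases — are ready for them. Facilities known only as
referral destinations (never surveyed) are reported `UNKNOWN` and
excluded from readiness denominators; they can be included in geographic
modeling by assigning an assumed level (`assumed_levels` in
`run_access_model()`), which is exactly how an unsurveyed referral
hospital should be handled: its existence and location are known even
though its checklist is not.

## 3. Travel-time access

Both access models compute **one-way** travel time to the **nearest
facility ready at the requested level**, band it into half-open hourly
intervals [60k, 60(k+1)) minutes with a terminal "3+" band, and overlay
population. Round-trip reporting (doubling) is available but off by
default. The half-open convention is a deliberate choice: published
"0–1 h / 1–2 h" notation is ambiguous at the boundary, and half-open
bands are the only convention that partitions the time axis.

### Urban model

Dense urban districts are modeled on the road network because clients
travel by public transport and congestion dominates: travel time is

> wait + 60 · (shortest network path in km) / speed

with defaults of a 50-minute wait for pick-up and a 10 km/h average
speed. Origins (neighborhood center points) and facilities snap to their
nearest network node (deterministic tie-break by smallest node id). The
model deliberately ignores walking to the stop and traffic heterogeneity:
one wait, one speed. This can overstate times for women within walking
distance of a facility — a known limitation of the uniform-wait
assumption.

Each neighborhood's travel time is extended to its whole Thiessen
(Voronoi) polygon — the region nearer to its center point than to any
other — so neighborhood population counts inherit their center's band.
Polygons are computed by clipping the (convex) boundary against
perpendicular-bisector half-planes, an exact construction for which the
test suite verifies the nearest-seed property on sampled points.

### Rural model

Rural districts are modeled on a raster cost surface because much of the
population lives away from roads: women walk across off-road surfaces
(walking speeds 1–2.5 km/h by surface class) and switch to motorized
transport on reaching a roadway (10–60 km/h by road class; the road
class overrides the surface class in a cell). The published account
gives only these ranges; the per-class defaults in `speed_schedule()`
(primary 60, secondary 40, tertiary 25, track 10; grassland 2.5,
shrubland 1.8, wetland 1.0 km/h) were fixed once inside those ranges as
plausible values for the setting and are ordinary configuration.

Accumulation is multi-source Dijkstra on the 8-connected cell graph with
step cost `d · (t_a + t_b)/2`, where `d` is the center-to-center distance
(cell size, √2 × cell size diagonally) and `t_c` the traversal time per
meter in cell `c` — standard GIS cost-distance semantics. No-data cells
are impassable; unreachable cells stay no-data and their population is
kept in the proportion denominator under an explicit "unreachable" row.
No maximum accumulation distance is imposed. Facilities falling off the
passable surface snap to the nearest passable cell within 5 cells
(configurable); beyond that it is an error, since silently moving a
facility further would change the geography.

On an 8-connected grid the accumulated time on a uniform surface
overestimates the Euclidean straight-line time by at most the octile
factor ≈ 1.0824; the tests assert `D/v ≤ T ≤ 1.0824·D/v` everywhere, and
cell-exact agreement with an independently written brute-force Dijkstra
on random rasters (including no-data handling).

### Population overlay

`population_by_band()` assigns each raster cell's population to its
band, or — urban mode — each neighborhood's population to its center's
band. Percentages are printed to one decimal and apportioned by largest
remainder so each access table column totals exactly 100.0, matching the
convention of published access tables.

All coordinates are planar meters in a projected CRS; no geodesic
computation is performed anywhere. At district scale (tens of km) the
projection error is negligible relative to the model's assumptions.

## 4. Synthetic data

### The frozen study fixture

`build_study_fixture()` returns a deterministic 40-facility dataset (13
urban + 26 rural assessed facilities + 1 unassessed rural hospital) whose
*aggregate* surface — every per-district component and level percentage,
the facility-type mix, the referral topology (networks of 20, 7 and 4;
28 referring, 9 standalone), and the endpoint readiness counts (7 of 11
regular-ready, 1 difficult-ready) — reproduces a published two-district
survey. Published marginals do not determine the item-level joint
distribution, so the fixture freezes one feasible joint assignment found
by constraint satisfaction (e.g. the three water-lacking and five
equipment-lacking rural facilities must be disjoint sets to leave exactly
18 of 26 regular-ready). `fixture_self_check()` re-derives every frozen
aggregate through the package's own pipeline and errors on any mismatch.
Facility coordinates are synthetic planar positions (the real facility
geocoordinates are confidential); the rural ones are laid out inside the
default synthetic geography extent so fixture and generators compose.

### Generators

* `gen_facilities(n, rates, seed)` draws the three readiness components
  independently per facility and fills item-level booleans consistently
  (a failing component knocks out 1–2 random items). Component
  independence makes the composite regular-ready rate the product of the
  component rates, which is the calibration property the tests check at
  n = 10,000 against a 3-standard-error binomial envelope.
* `gen_rural_scenario(spec)` builds a smoothed random surface-class
  field (von Neumann smoothing passes give spatial clustering), burns a
  road grid, draws a population raster by multinomial allocation (total
  exactly conserved), and places facilities on road cells.
* `gen_urban_scenario(spec)` builds a rectangular grid road network,
  uniform neighborhood centers (default 425, the order of magnitude of
  an urban district's neighborhoods), log-normal population weights
  allocated multinomially, and facilities at network nodes.

All generators are bit-reproducible for a given seed. Default problem
sizes (60 × 60 cells at 500 m; 425 neighborhoods on a 12 × 12 grid) were
chosen as district-scale analyses that run comfortably on a laptop; the
test suite uses 20–30-cell grids for speed.

What the generators do **not** emulate: real road topology (loops,
dead-ends, rivers and bridges), realistic land-cover autocorrelation,
census-based population gradients, or any empirical correlation between
facility readiness components. Passing tests therefore demonstrate
algorithmic correctness and calibration of the machinery, not that any
particular real district's access numbers are reproduced — published
access proportions for the real districts depend on real road,
neighborhood and census geodata and are out of scope here.

## 5. Known limitations

* The urban and rural models are not comparable head-to-head: the urban
  wait-time constant dominates short trips.
* Nearest-*ready*-facility is an optimistic routing assumption; women
  commonly return to the insertion facility first, so modeled times are
  lower bounds on experienced times.
* The readiness scheme is binary per item; stock-outs, quality and
  functionality gradations are not modeled.
* One referral destination per facility; multi-destination referral is
  out of scope.
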