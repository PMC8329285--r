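---
title: "Rule-based geomorphic zonation of coral reefs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based geomorphic zonation of coral reefs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefzoner)
```

## The problem

Shallow tropical coral reefs partition into predictable internal geomorphic
zones — fore reef, reef crest, reef flats, back reef and lagoon — arranged in
parallel to the reef edge. The physical attributes that define these zones
(depth, slope angle, wave exposure, brightness and texture of the sub-surface
reflectance, and the spatial arrangement of zones) are exactly the attributes
observable from satellite remote sensing, which makes geomorphic zonation the
natural level for consistent regional-to-global reef mapping.

`reefzoner` implements the Reef Cover typology of 17 internal reef classes
(plus the Deep Water and Land context classes) as an executable rule engine:

1. a **scheme registry** holding the machine-readable typology — class
   descriptors, attribute memberships, relational adjacency/enclosure rules
   and crosswalks to the two published case-study legends;
2. **attribute derivation** — slope from bathymetry, binary exposure from
   significant wave height, local brightness texture, categorical depth bands;
3. a **zonation classifier** applying a decision tree with explicit spatial
   context;
4. a **relational engine** that segments the map into objects, extracts
   adjacency and enclosure relations, checks them against the typology's
   rules, and repairs violations;
5. **reporting** — areal extents, crosswalked summaries and confusion-matrix
   accuracy assessment; and
6. a **synthetic archetype generator** providing seeded, ground-truthed test
   beds (atoll, fringing, platform, barrier) so the whole pipeline is testable
   without any satellite download.

## The scheme file and its transcription

The typology ships as one versioned YAML document
(`reef_scheme_file()`). The published relational table is a coloured matrix
that has no machine-readable distribution, and its rendering conflates the
colour legend with check/dash glyphs, so the packaged file is this package's
own transcription: `typical` for "typically neighbours / enclosed by",
`sometimes` for "may sometimes be", and absence of an entry meaning `never`
("not usually neighbours / enclosed by"). Entries follow the explicitly stated
relations (a reef crest can never be surrounded by reef flat; crest and outer
reef flat are typical neighbours) and otherwise the canonical
seaward-to-lagoonward ordering of zones; because the transcription lives in
data rather than code, a future corrected transcription is a one-file change.
The transcription was additionally required to be *self-consistent with the
archetype geometry*: every adjacency and enclosure realised by a noise-free
synthetic archetype is non-`never` (the test suite enforces this), which is
how entries with no textual anchor were fixed.

Two transcription notes. The deep lagoon class is stored under the standard
name `Lagoon` with synonym "Deep Lagoon". The second case study's extra class
is stored as a crosswalk `extra_class` named "Terrestrial Flat" (the tabulated
form), not as an eighteenth class; and that crosswalk carries 11 mapped reef
classes plus this extra class, i.e. 12 target labels, although the prose of
the underlying mapping exercise in one place counts eight classes in the
final map product — the crosswalk follows the tabulated usage, and this
discrepancy is recorded here rather than resolved.

## Thresholds

All cutoffs live in `threshold_config()`; nothing is hard-coded, honouring
the typology's position that relative rather than absolute depths define the
classes. Defaults are the case-study calibrations:

| parameter | default | meaning |
|---|---|---|
| `crest_depth_max` | 0.75 m | ceiling separating Reef Crest from flats |
| `shallow_mid_edge` / `mid_deep_edge` | 3 m / 10 m | depth-band edges (front vs slope) |
| `lagoon_depth_min` | 10 m | per-cell shallow/deep lagoon split |
| `fore_reef_slope_min`/`max` | 5° / 90° | fore-reef slope window |
| `wall_slope_min` | 60° | near-vertical wall threshold (editorial: no angle is published for "near vertical") |
| `flat_slope_max` | 5° | horizontal ceiling |
| `exposure_hsig` | 2 m | significant-wave-height exposure threshold |
| `flat_brightness_split` | Otsu | outer/inner flat division |
| `min_mapping_unit` | 9 cells | smallest object kept by repair |
| `patch_small_reef_max_area` | 400 cells | isolated-body relabelling ceiling |
| `deepwater_depth` | 30 m | Deep Water context threshold |

An alternative 18 m front/slope split used in older regional work is
available by setting `mid_deep_edge = 18`. Every comparison keeps the
boundary value in the shallower or less exposed class (exposure requires wave
height *strictly above* 2 m), and these tie-breaks are documented at each
comparison site.

## The decision tree and its spatial context

The per-cell core (`classify_cell()`) is a total function over depth band ×
slope × exposure × side, but the tree's discriminating attributes — which
side of the crest a cell lies on, and whether its water body is enclosed —
are spatial, not per-cell. `classify_zones()` resolves them geometrically:

* **seaward** water is water that can reach Deep Water through a 4-connected
  path without crossing the crest-depth contour (depth ≤ `crest_depth_max`);
* **lagoonward** water is the remainder: it becomes Back Reef Slope when
  sloped, Lagoon / Shallow Lagoon by depth when flat, and joins the reef-flat
  pool when shallower than the shallow band edge;
* the **Reef Crest** is the exposed part of any crest-contour band whose
  connected component touches open water — restricting the crest to the
  exposed seaward margin, where maximum wave shoaling occurs;
* the pooled flat cells split into Outer and Inner Reef Flat at the Otsu
  threshold of their brightness (inner = brighter, depositional), with
  crest-adjacent cells forced outer;
* small isolated bodies (≤ `patch_small_reef_max_area`) are relabelled Patch
  Reef when their neighbours are all lagoon classes and Small Reef when
  surrounded by Deep Water; supratidal non-land cells are Reef Island.

The published material motivates this tree but does not enumerate a branch
order; the pipeline order above (context → enclosed water → seaward slopes →
crest → flats → isolated bodies) is this package's explicit reconstruction
and is part of its contract (the order is tested, deterministic, and
documented here).

Slope is `atan` of the centred-finite-difference gradient magnitude of the
depth grid (one-sided at edges and next to nodata); no slope operator or
stencil is prescribed by the source material, so the 3×3 centred stencil is an
editorial choice. Its consequence is quantified rather than hidden: at a kink
between profile segments the stencil straddles the boundary, so classified
maps can disagree with ground truth in a band at most 2 cells wide along
zone boundaries — the test suite asserts that *all* noise-free disagreement
lies inside that band.

## The synthetic archetypes

The generator emulates the zonation structure the classifier assumes, not
satellite data. Each archetype is a 1-D cross-reef profile (radial for atoll
and platform, shore-normal for fringing and barrier) swept over the grid:
open-water floor at 35 m, a 20° fore-reef incline, a 0.3 m crest ring, 1 m
flats (60 % inner / 40 % outer of a 750 m flat), a 10° back-reef incline, a
5 m shallow-lagoon shelf and a 15 m deep lagoon. Exposure is a sharpened
cosine of bearing relative to the wind direction scaled between leeward
(1.0 m) and windward (2.5 m) significant wave heights, so radial archetypes
carry both exposure classes; the linear archetypes model an open windward
coast. Seeded features — three lagoon patch reefs, one open-water small reef,
one supratidal island on the inner flat — exercise the enclosure-based
classes. Brightness is painted per class from a fixed palette in which the
inner flat (0.80) is far brighter than the outer flat (0.55). Depth and
brightness noise are zero-mean Gaussian perturbations drawn after the
deterministic geometry from the single seeded stream.

Ground-truth labels come from the analytic geometry (exact segment, exact
depth, same thresholds as the classifier). Where the published case studies
state values (0.75 m crest, 2 m exposure, 3–10 m bands, 10 m lagoon floor,
5–90° slopes) those are the shared defaults; the remaining geometry (ring
widths, palette, feature counts and radii, 20°/10° incline angles) is
editorial, chosen once for realism and documented here. Two deliberate
limitations: the default atoll omits the near-vertical wall ring, because at
the 10 m reference cell size a 75° wall is sub-cell wide and no finite
stencil can resolve it (walls are exercised on fine-grid variants in unit
tests); and no hydrodynamic wave modelling, tides, or spectral simulation of
satellite bands is attempted. Passing tests on these archetypes therefore
demonstrate correctness of the rule engine under its own assumptions — clean
zonal geometry and additive Gaussian noise — not robustness to the full error
structure of satellite-derived bathymetry (spatially correlated error, depth-
dependent bias, breaking-wave artefacts).

## The relational engine

Objects are 4-connected regions of one class; adjacency uses 8-connectivity
across class boundaries. This standard raster-topology compromise prevents
diagonal self-connection while still counting diagonal contact as
neighbourhood. Enclosure is defined through paths: A is enclosed by B when A
does not touch the grid edge and every 4-connected path from A to the edge
crosses B. Because 4-connected cell paths correspond exactly to walks on the
4-adjacency object graph, enclosure is computed by cut-vertex removal on that
graph (with a virtual border vertex), and the innermost encloser is the one
nearest to A in object hops. The test oracle recomputes the same definition
by literal flood fill from the grid edge — an independent route to the same
answer. Semi-enclosure (partially open lagoons) has no operational definition
in the source material and is deliberately not implemented.

Only `never`-level relations are violations; `typical`/`sometimes` are
descriptive and pass. Repair merges, in deterministic order (ascending cell
count, then object id), the smaller object of each violating pair — plus any
object under the minimum mapping unit — into its largest-boundary neighbour
whose relations to the remaining neighbours are not `never`. Each pass
re-segments; the loop stops at a fixed point, at the oscillation guard, or
when every remaining candidate is irreparable (reported, never silent).
Repair cannot invent classes, cannot touch nodata, and is idempotent.

## Numerical choices and degenerate inputs

* Otsu's threshold is computed by exhaustive scan over midpoints of
  consecutive distinct values, maximising the between-class variance; ties go
  to the lower split, and a degenerate (all-equal) brightness pool falls back
  to a fixed 0.5 split with a warning.
* Texture is the NaN-aware *population* standard deviation over truncated
  square windows.
* An all-land input yields a context-only map with a warning; a 1×N depth
  grid is an extent error; negative noise sigmas are parameter errors.
* All randomness (feature placement, noise) flows from one integer seed;
  identical seeds give bit-identical rasters, through the CLI included.

## Problem sizes used by the shipped checks

The reference fixture is the 512 × 512, 10 m atoll (the generator defaults).
The multi-archetype rule-consistency checks run on 192 × 192 grids with
proportionally narrowed rings (300 m flats, 100 m shallow-lagoon shelf,
30 m patch radius) so that all zones fit the smaller extent; these are the
package's chosen study sizes and are asserted in `tests/testthat/` and
recomputed by `scripts/acceptance.R`. Oracle cross-checks run on random
12 × 12 grids where exhaustive brute force is exact and cheap.

## Known limitations

* The attribute-membership table and relational matrix are transcriptions;
  per-cell confidence is inherently limited by the non-machine-readable
  source, and corrections belong in the scheme file, not in code.
* Exposure is binary (exposed/sheltered); the typology's intermediate
  "average" level is collapsed, as neither case study used it.
* The published real-world map products (Great Barrier Reef and Micronesia
  extents and class shares) depend on proprietary satellite mosaics, SWAN
  wave modelling and expert training data, and are out of scope; the
  crosswalks let users *report* in those legends, nothing more. Expert
  confidence scores are carried as static metadata and never computed.
* Raster exchange uses ESRI ASCII grids with a CSV legend sidecar;
  georeferencing beyond the affine header is not carried.
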