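---
title: "Rule-based mapping of IUCN habitat types: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based mapping of IUCN habitat types: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitatmapr)
```

## The problem and the model

The IUCN Red List describes species' habitat preferences with a two-level
standard typology: 16 broad Level-1 classes (Forest, Savanna, Wetlands,
Artificial, ...) and more specific Level-2 classes nested within them (e.g.
1.6 *Forest — Subtropical/tropical moist lowland*). Translating wall-to-wall
remote-sensing products into this typology makes it possible to refine a
species' range map to its Area of Habitat by masking out unsuitable classes
and elevations.

`habitatmapr` implements that translation as a *sequential decision tree*
over a stack of co-registered raster layers — land cover, Köppen–Geiger
climate zones, biome flags, terrain, wetland inventories and land-use
pressure layers. An ordered list of rules is evaluated per grid cell with
first-match semantics: each rule pairs a Level-2 habitat code with a boolean
predicate over named stack layers, a cell takes the target of the first rule
whose predicate holds there, and later rules never revisit an assigned cell.
Two structural constraints are enforced at parse time rather than by
convention:

* **anthropogenic precedence** — every artificial-class rule precedes every
  natural-class rule, so human-modified classes mask natural ones;
* **Level-1 defaults** — a block of Level-2 rules may end with one default
  rule (minor code 0) that catches cells matching the broad class but none
  of its specific conditions.

Nodata in any predicate atom evaluates to `FALSE`, never `TRUE`: a cell with
incomplete inputs is left unassigned rather than misassigned.

Level-2 codes are encoded as scalar integers `level1 * 100 + minor`
(1.6 → 106, 14.5 → 1405), so single-band integer rasters carry the full
typology and the Level-1 projection is integer division.

## Derived pressure masks

Several classes are not present in any single input product and are derived
here, each as a small, separately testable builder:

* **Pastureland (14.2)** — non-tree vegetation stocked at ≥ 1 LSU/km²
  (inclusive boundary) on land climatically suitable for forest (Köppen
  groups Tropical/Temperate/Continental), excluding grass/tundra/steppe/
  meadow ecoregions. Head counts of buffalo, cattle, goats, horses and sheep
  are converted to livestock units with per-species, per-region factors
  shipped as an editable table (single default region: cattle/buffalo 0.7,
  horses 0.8, sheep/goats 0.1), since published regional factor tables are
  data, not code.
* **Rural gardens (14.4)** — arable cells in the "very small field size"
  category within 500 m (Euclidean, center-to-center) of urban land cover;
  urban cells themselves are never gardens.
* **Plantations (14.3)** — membership of the managed-forest classes of a
  forest-management layer (replanted > 20-year rotation, short-rotation
  woody, agroforestry, fruit).
* **Expanded wetlands** — a growth-only modal filter over the (coarse)
  wetland inventory: labelled wetland cells never change; unlabelled cells
  acquire the modal wetland code of their window when one occurs there. The
  default window half-width is 2 cells (a 5×5 window, i.e. a ~5 km diameter
  at 1 km input resolution). The window shape (square), size and tie rule
  (smallest code) are explicit package defaults, configurable by the caller,
  because none of them is pinned by the wetland product itself.
* **Montane split** — a mountain mask OR-ed with an optional elevation
  threshold.

## Geometry conventions and numerical choices

All grids are planar with square cells; distances are Euclidean between cell
centers in map units. Geodesic buffering and reprojection are out of scope —
inputs are assumed co-registered (a nearest-neighbour resampler is provided
for harmonising resolutions). Indexing is 1-based row-major from the
top-left corner, as is idiomatic in R. Cells are half-open intervals, so a
point exactly on a shared edge belongs to the cell right/below it; this also
resolves nearest-neighbour ties during resampling deterministically.
Everywhere a modal value is needed (focal filter, majority aggregation,
strict point matching) ties break to the *smallest* code — deterministic and
documented, chosen over randomised tie-breaks so repeated runs are
bit-identical. Buffer membership uses `distance ≤ radius` with a 10⁻⁶ m²
slack on the squared distance to absorb floating-point noise at exact cell
multiples.

Fractional aggregation computes class shares over the *non-nodata* cells of
each coarse block and reports the valid share separately, which keeps the
sum-to-one invariant exactly testable; blocks truncated at non-divisible
edges are flagged in the output.

## Validation procedure

Occurrence records of habitat specialists (species coded to a single
Level-2 class) are filtered by four rules applied in order: inside the
species' range polygon (records of species without a supplied range are
retained and flagged), observation date within 2005–2019, coordinate
uncertainty below the per-source limit (300 m GBIF, 30 m eBird; a missing
uncertainty under a finite limit is rejected — the conservative reading),
and uniqueness per (species, map cell). Deduplication granularity is the map
cell, the finest unit at which two records can disagree with the map.

A retained point is compared with the map through a buffer (default 300 m)
around its cell: the multiset of non-nodata codes within the buffer yields a
single prediction either **leniently** (the expected class wins if present
anywhere in the buffer, mirroring the polygon presence test) or
**strictly** (the modal code regardless). Both modes are first-class because
the reduction from a buffered neighbourhood to one predicted class is a
genuine methodological choice; lenient is the default and the mode is
recorded in outputs. PREDICTS-style sites use their own sampling extent as
the buffer; visually labelled points use a plain cell lookup. Polygon sites
(IBA-style) test presence: does any cell center inside the polygon carry the
expected class?

Classes with fewer than 10 expected records are dropped per (class, dataset)
before the confusion matrix is built (the threshold's granularity is
configurable; per-dataset is the stricter reading). From the matrix we
report overall accuracy, one-vs-rest sensitivity and specificity, their mean
(balanced accuracy, robust to imbalanced record counts), the unweighted
macro average, and cross-dataset mean ± sample SD (n−1; a single entry has
an undefined SD, reported as `NA`). Degenerate denominators yield `NA`
metrics excluded from macro averages. Level-1 summaries project both sides
of each pair before counting, so within-group confusions merge and the
Level-1 overall accuracy can never fall below Level-2's on the same pairs.

## The synthetic world

Real global inputs are neither shipped nor downloaded. Instead
`generate_world()` builds internally consistent fixtures *truth-first*: a
patchy ground-truth habitat map is sampled (seed points carrying codes drawn
from the target class mix; each cell joins its nearest seed, giving
`patch_scale`-sized patches), then every input layer is derived per cell so
that the truth class's rule holds and every earlier rule fails. The default
conditions are a 200×200 grid of 100 m cells, patch scale 8, and a
forest-dominated 25-class mix summing to 0.99 with 1% nodata — a mix chosen
once to exercise every rule of the shipped ruleset with realistic
imbalance. Classification therefore has an exact oracle:
`classify()` must reproduce the truth on 100% of non-nodata cells, for every
seed. Derived masks are built by the real geometric builders, not painted
from truth; the two places where geometry constrains the truth map are
handled by deterministic fix-ups (rural-garden patches get an urban cell
planted inside the 500 m buffer or are relabelled arable; pasture cells
failing the `pasture_fraction` draw are demoted to grassland).

Record generation samples cells in proportion to class areas, captures the
truth class as the specialist's expectation, then applies noise:
mislabelling with probability ε to a uniformly random other mapped class,
isotropic positional displacement (applied *after* the expectation is
captured, mimicking real positional error), and configurable rates of stale
dates and excessive uncertainties. With zero displacement and center-cell
lookup, strict-mode overall accuracy is exactly 1 − ε in expectation, which
the tests recover within three binomial standard errors at n = 2000.
Noise-recovery checks use a 0 m match buffer deliberately: with a 300 m
buffer the modal code near patch edges legitimately differs from the center
cell, so exact recovery is only defined for center-cell lookup.

What the synthetic world does *not* emulate: climate gradients, realistic
patch shapes and adjacency structure, coastlines, taxonomic error, spatial
sampling bias. Green tests certify the machinery — the rule engine, masks,
aggregation and validation arithmetic — on inputs whose answer is known by
construction; they do not certify the ecological fidelity of any particular
ruleset on real data, and the shipped default ruleset is a best-effort
reconstruction intended to be replaced by a user-supplied configuration.

## Problem sizes and defaults used by the test suite

The suite exercises: the exact round trip on twenty 200×200 worlds; 500
randomized rulesets on grids up to 20×20 against a naive per-cell loop; 200
random 40×40 rasters against brute-force focal oracles; 50 random
aggregations; and n = 2000 noise-recovery runs — sizes at which every
property is checked exhaustively in a couple of minutes on one core.
`scripts/acceptance.R` recomputes the same quantities from scratch for any
seed.

## Known limitations

* Marine classes (9–13), artificial aquatic (15) and introduced vegetation
  (16) are registered but unmappable, matching the terrestrial scope of the
  typology's mappable subset.
* One class per cell: mixed savanna-type cells are not representable.
* The shipped ruleset's within-block ordering beyond the documented
  anthropogenic-first and 1.9-before-1.7 structure is a package choice;
  users with an authoritative coded ruleset should supply it as YAML.
* Raster I/O is single-band ESRI ASCII grid with a YAML sidecar — portable
  plain text, but without projection metadata; coordinate-system management
  belongs to the surrounding GIS toolchain.
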