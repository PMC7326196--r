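---
title: "Ecosystem extent-loss accounting and protection gap analysis with ecoextent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecosystem extent-loss accounting and protection gap analysis with ecoextent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoextent)
```

## The accounting model

`ecoextent` implements a change-in-extent account for terrestrial
ecosystem types. The baseline is a *potential distribution* map: an
integer-coded categorical raster assigning to every cell the ecosystem type
expected there today had no conversion to intensive land use occurred. A
*composite conversion layer* over the classes developed, agriculture,
ruderal and water marks where such conversion is observed (circa a chosen
reference epoch). The account rests on one assumption:

> where a conversion class overlaps the potential distribution of a type,
> that area is presumed to have been converted from the type to the land
> use; elsewhere the type persists.

So per type $t$, with potential area $A_{\mathrm{pot}}(t)$ and current
natural area $A_{\mathrm{cur}}(t)$ (both in km², from cell counts times
cell area), the long-term loss fraction is
$L(t) = 1 - A_{\mathrm{cur}}(t)/A_{\mathrm{pot}}(t)$, and criterion A3 of
the IUCN Red List of Ecosystems maps $L$ to Vulnerable ($>0.5$),
Endangered ($>0.7$) or Critically Endangered ($>0.9$).

This is strictly an account of *complete conversion*: degradation or
alteration of vegetation that remains in place is invisible to it, which
biases $L$ low for types whose remaining extent is largely degraded.
Criteria B, C and D of the Red List framework, and condition analyses, are
out of scope.

Protection is assessed by overlaying a protected-area mask on *current*
extent. Categories I–VI are dissolved into a single protected state — the
aim is representativeness within any category, not differential protection
levels. Two ratios are reported per type: percent of potential extent
protected (the headline framing for the Aichi Target 11 "at least 17%"
benchmark, because it keeps heavily converted types visible) and percent of
current extent protected (the conventional gap-analysis figure). Converted
cells inside protected areas count toward no type; they are reported
separately by `protectedConvertedArea()`.

## The classification hierarchy

Types live in an 8-level vegetation-classification hierarchy (Class,
Subclass, Formation, Division, Macrogroup, Group, Alliance, Association;
upper levels physiognomic, lower levels floristic). Assessment happens at a
declared leaf level — in continental practice the macrogroup (level 5) or
the ecological-system grain near the group level (level 6) — and any
per-type statistic aggregates losslessly to coarser levels because each
node has exactly one parent one level up. `loadHierarchy()` enforces that
structure (unique codes, no orphans, no level skips, no cycles) at load
time rather than trusting the table, since a malformed typology would
silently corrupt every aggregated figure. The mapped set and the assessed
set may differ: the loss table is keyed by what is on the map, the
hierarchy by what is classified, and `categoryCounts()` fails loudly on
types it cannot resolve.

## Fusing land-cover products

No single land-cover product covers a continental study area at uniform
quality, so the composite layer is fused from several. Each product is
first recoded to the composite classes through a *crosswalk* that must be
total over the product's legend — an unmapped code is an error, never
silently "no conversion". Products at finer grain are brought to the
analysis grid by majority (modal) resampling, mirroring the common practice
of summarising 30 m products at 270 m. Fusion then applies a *precedence*
rule per cell: the first product in the configured order reporting a class
other than NONE wins. Precedence order is configuration, not code; the
motivating use case puts a vetted national product ahead of global ones,
with optional per-product validity masks for regions where a product is
known to be unreliable. Precedence is purely spatial: the products' epochs
differ (roughly 2000–2010 in the motivating datasets) and no temporal
reconciliation is attempted — the composite is read as "conversion observed
by the preferred available source, circa the common epoch".

## Numerical and design choices

* **Tie-breaks.** Modal resampling breaks ties to the smallest class code:
  deterministic and order-independent, at the cost of a slight bias toward
  low-numbered classes in exactly tied blocks. Voronoi assignment in the
  generator breaks distance ties the same way (smallest type code).
* **Bin closures.** All bin schemes use half-open intervals $[lo, hi)$ with
  the top bin closed, so 0.90 falls in ">90%" and a protection percentage
  of exactly 17 falls in "17–30%" (consistent with counting types "at or
  above the 17% category"). Published accounts of the loss bins differ
  between a results-text reading (<10, 10–30, 30–50, 50–70, 70–90, >90;
  the 10–30 bin is the only reading that leaves no gap, though some texts
  print "10–20%") and a figure-caption reading that splits the top bin at
  95%; both ship (`lossBins("results")`, `lossBins("figure")`), results
  reading default. Likewise `protectionBins("top70")` (default) and
  `"top50"`.
* **Threshold closure.** Criterion A3 uses strict ">" as printed in the
  motivating analysis; `strict = FALSE` switches to "≥", the closure in
  IUCN assessment guidance. Defaults reproduce the published convention.
* **Rounding.** Headline "k of n types (x%)" figures round half away from
  zero to one decimal (`pctOfTypes`). Published tables mix conventions
  (some figures are truncated), so agreement within 0.1 is the honest
  reproduction target; the package applies its single convention
  everywhere.
* **Code ranges.** Land-use classes occupy a reserved block (≥ 9000)
  disjoint from type codes, checked at overlay time, so a legend collision
  cannot silently misattribute area.
* **Areas.** Area is cell count × (cellSize/1000)², valid only in an
  equal-area projection; `tabulateArea()` refuses a grid whose CRS tag is
  not declared equal-area unless a per-cell area matrix is supplied.
* **Degenerate inputs.** Types with zero potential area cannot be assessed
  and are dropped with a classed warning; types absent from current extent
  get loss 1; a current area exceeding potential, or protected exceeding
  current, signals misaligned inputs and is an error, not a clamp (beyond
  1e-9 relative slack for float round-off).
* **Formats.** Rasters are single-band integer Esri ASCII grids with a
  `.prj` sidecar carrying the CRS tag — a plain-text interchange format
  that round-trips codes, nodata and geometry losslessly and keeps every
  artifact human-readable. CSVs are written with doubles at 17 significant
  digits so tables round-trip bit for bit, making byte-identical reruns a
  meaningful determinism check.

## What the synthetic landscapes emulate — and what they do not

The generator reproduces the *statistical* structure the pipeline must
handle, with known truth:

* `genPotential()` builds multi-seed Voronoi mosaics (default 100×100
  cells of 270 m, 8 types, 3 seeds per type). Voronoi patches were chosen
  over Gaussian-field mosaics because they need no heavy numerics, give
  adequate spatial coherence, and are exactly checkable against an
  exhaustive nearest-seed oracle.
* `genConversion()` converts each cell of type $t$ independently with
  probability $p_t$ (iid mode; default intensities spread evenly over
  [0.02, 0.92] so every loss bin and threat category is populated), or
  grows clusters to the same per-type target (clustered mode, radius 3
  cells). Converted cells draw a class from a mix defaulting to
  agriculture-dominated (0.60 agriculture, 0.20 developed, 0.10 ruderal,
  0.10 water), the realistic ranking for continental conversion.
  Realized fractions are emitted as a first-class truth table.
* `genProtected()` places compact rectangular reserves to a target
  coverage (default 0.17, the Target 11 benchmark, in 6 blocks), or — for
  recovery properties that assume independence from the type mosaic —
  scatters iid random cells (`paMode = "scatter"`), under which each
  type's protected share is exactly hypergeometric. Block reserves are
  spatially correlated with the type mosaic, so per-type protection under
  them legitimately disperses more than the hypergeometric rate; that is a
  feature of real reserve networks, not an error.

All generators are deterministic given the config seed (stages use fixed
small offsets from it), and truth tables are returned as data, so tests
never reach into generator internals.

What the mosaics do **not** emulate: realistic biogeography (no climate or
landform covariates, no rare types with linear or fragmented ranges), map
error in the potential distribution, temporal disagreement between
products, or degraded-but-unconverted vegetation. Passing recovery tests
therefore demonstrates that the *accounting machinery* is exact and
unbiased given its inputs — not that any real potential-distribution model
is accurate. Inductive distribution modelling is explicitly out of scope.

## Verification strategy and problem sizes

The test suite checks every operation against an independent oracle or a
closed-form expectation: brute-force counting for tabulation, block
histograms for resampling, exhaustive nearest-seed search for the mosaics,
point-in-rectangle geometry for rasterization, nested tallies for the
count matrices, and binomial / hypergeometric concentration for end-to-end
recovery (within four standard errors, on types of at least 2,000 cells
for the binomial bound). Conservation — potential area equals current
natural plus converted, per type — is asserted to 1e-9 relative tolerance
across 20 seeded 100×100 landscapes of 5–20 types. These sizes give every
type thousands of cells (tight standard errors) while keeping the whole
suite fast; the properties tested are size-free, so nothing about them is
specific to 100×100. `scripts/acceptance.R` re-runs the same measurements
from scratch under a caller-supplied seed and writes the quantities as
JSON.

## Known limitations

* The account measures complete conversion only; no condition or
  degradation signal, so losses are lower bounds where degraded vegetation
  stands.
* Accuracy of the fused composite is inherited from its source products
  and is not assessed here; validation statistics of the components are
  the user's guide.
* Protection is binary (any IUCN I–VI); differential management levels,
  connectivity and other Target 11 qualifiers are not represented.
* The package works on in-memory grids; continental rasters at 30 m would
  need tiled processing, which is out of scope.
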