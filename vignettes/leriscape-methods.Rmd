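---
title: "Grid-based landscape ecological risk assessment with leriscape"
author: "leriscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based landscape ecological risk assessment with leriscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leriscape)
```

## The model

Landscape ecological risk assessment asks where, on a landscape undergoing
land-use change, the combination of structural disturbance and intrinsic
vulnerability puts ecosystems most at risk. `leriscape` implements a
grid-based formulation: the study area is divided into square assessment
units ("risk plots") by a fishnet, and each cell $k$ receives a Landscape
Ecological Risk Index

$$\mathrm{LERI}_k \;=\; \sum_{i=1}^{n} E_{ki}\, F_{ki}\, \frac{A_{ki}}{A_k},$$

a composition-weighted sum over the land-cover classes $i$ present in the
cell, where $A_{ki}$ is the class area, $A_k$ the cell area, $E_{ki}$ the
landscape disturbance index and $F_{ki}$ the landscape vulnerability index.
LERI is therefore the area-weighted mean of $E \times F$ and is bounded by
the largest $E_{ki}F_{ki}$ in the cell.

### Disturbance

Disturbance summarizes how fragmented, isolated and dominant a class's
patches are inside the cell:

$$E_{ki} = a\,C_{ki} + b\,S_{ki} + c\,D_{ki}, \qquad a = 0.5,\; b = 0.3,\; c = 0.2,$$

with fragmentation $C_{ki} = n_{ki}/A_{ki}$ (patches per km²), separation
$S_{ki} = \frac{A_k}{2 A_{ki}} \sqrt{n_{ki}/A_k}$, and dominance
$D_{ki} = (Q_i + M_{ki})/4 + L_{ki}/2$, where $Q_i$ is the fraction of grid
cells in which class $i$ occurs, $M_{ki}$ the class's share of the cell's
patches, and $L_{ki}$ its share of the cell's area. With $Q, M, L \in
[0,1]$, dominance stays in $[0,1]$; treating $Q$ as a raw cell count
instead of a fraction would unbound it, which is why the fractional reading
is pinned here. The printed weighting $a > b > c$ emphasizes fragmentation
as the most direct imprint of disturbance.

Two readings of the separation formula circulate in the literature
(dividing by $2A_{ki}$ or by $A_{ki}^2$); `leriscape` adopts
$\frac{A_k}{2A_{ki}}\sqrt{n_{ki}/A_k}$, which keeps the index dimensionless
when areas share one unit, and isolates the choice in the one-line
`separation()` so the alternative can be swapped in.

Patches are connected components of same-class pixels **within a cell
window**: a patch spanning a cell border counts in both cells, because the
index is strictly per-plot. Connectivity defaults to 8 (diagonal neighbours
join), matching common landscape-pattern software; 4-connectivity is a
parameter. An absent class ($A_{ki}=0$) takes all metrics equal to 0 — it
contributes nothing to LERI anyway because its area weight is 0.

All areas are km² throughout. $C$ and $S$ are not scale-free: computing
them in m² rescales $C$ by $10^{-6}$ and $S$ by $10^{-3}$, so the pipeline
pins km² and the tests assert the rescaling factors.

### Dynamic vulnerability

Classic assessments give each land-cover class a fixed empirical
vulnerability rank: unused land 6, water 5, cropland 4, grassland 3,
woodland 2, urban land 1 (most- to least-vulnerable; built land is
considered most resistant to further disturbance, sparse/unused land least).
`leriscape` makes this **dynamic**: eight environmental indicators — GDP
density, population density, elevation, slope, temperature, precipitation,
NPP and NDVI — are averaged per cell, min–max standardized, combined into a
weighted sum $EQ_k = \sum_j w_j m_{jk}$, and normalized by the grid mean to
give the composite adjustment factor $MN_k = EQ_k/\overline{EQ}$. Then

$$F_{ki} = EV_i \times MN_k.$$

Because $\operatorname{mean}_k MN_k = 1$ by construction, the adjustment
redistributes vulnerability across the grid without inflating its average —
cells under heavier socio-economic and terrain pressure are scaled up,
buffered cells down. When a separate indicator stack is supplied per time
point, $MN$ is recomputed per period, so vulnerability tracks environmental
change through time.

Weights come either as the published fixed set (`fixedIndicatorWeights()`,
summing to exactly 1.0000) or from the entropy method
(`entropyWeights()`): columns that differentiate cells more strongly carry
lower Shannon entropy and hence more weight. Entropy uses the natural
logarithm with $K$ = number of cells, and is computed per period in the
dynamic mode; the fixed set reproduces a single pooled weighting.

Indicator **orientations** are a modelling choice the standardization makes
explicit: GDP, population, elevation, slope and temperature are treated as
positively oriented (larger ⇒ more vulnerable), precipitation, NPP and
NDVI negatively (larger ⇒ better buffered, so the column is reflected,
$m \mapsto 1-m$). These defaults are exposed in `defaultOrientations()` and
can be overridden per stack. Min–max scaling is the entropy-weight
literature's default standardization; a constant column is set to 0.5 with
a warning (it carries no information, and the entropy route would reject
it).

### Temporal statistics and classification

Across time points the package computes, per cell, the annualized risk
rate of change
$\mathrm{RRC} = \frac{L_{T2}-L_{T1}}{L_{T1}}\cdot\frac{1}{\Delta T}\cdot 100$
(% per year; negative means risk decreased) and the coefficient of
variation $\mathrm{CV} = SD/AV$ of the LERI series. CV uses the **sample**
standard deviation ($n-1$); the convention is pinned in the tests because
with five time points the two conventions differ by 12%.

Classification into five levels uses left-closed intervals over the fixed
breaks 0.60 / 1.18 / 1.72 / 2.40 (low, medium-low, medium, medium-high,
high). The printed bins leave the value 2.40 itself unassigned ("< 2.40"
vs "> 2.4"); `leriscape` closes the top class below, so 2.40 is "high".
Alternatively `jenksBreaks()` recomputes breaks from the data by Fisher's
optimal dynamic program (exact minimizer of within-class squared
deviation); the fixed breaks are the default reporting scheme for
reproducibility, and the Jenks mode is how such breaks are derived from a
pooled multi-period distribution in the first place.

### Key risk-management areas

Three cell categories are flagged at a common quantile threshold
$q = 0.15$:

* **stable high-risk** — LERI in the top $q$ fraction in *every* period
  ("remained high for the duration" is read as top-quantile membership in
  all periods, not a mean);
* **reduction-lagged** — full-period RRC in the top $q$ fraction (slowest
  decline or fastest growth);
* **risk-unstable** — CV in the top $q$ fraction.

"Top $q$" means strictly greater than the $(1-q)$ empirical percentile
(linear interpolation, `quantile` type 7); ties at the threshold are
excluded with a warning, so an all-constant ranking flags nothing. With
all-distinct values each category flags exactly $\lfloor qN \rfloor$ cells.
The union of the three is the key-area mask; its share of all cells is the
headline management statistic.

### Land-use transfer matrices

`transferMatrix()` cross-tabulates pixel class pairs between two dates on
the common valid footprint (pixels valid at both dates), times the pixel
area. Row sums equal the first date's class areas, column sums the
second's, and the grand total the common area — exactly, because the
counts are integers; reversing the dates transposes the matrix.

## The assessment grid

`buildFishnet()` anchors a square grid (default 20 km) at the lower-left
corner of the boundary envelope (plus an optional offset for sensitivity
checks), clips each cell to the boundary by Sutherland–Hodgman polygon
clipping, and computes clipped areas with the shoelace formula — exact for
single-ring, hole-free boundaries, which are the supported geometry class.
Cells whose clipped area is below 1% of a full cell are dropped as slivers
(configurable); retained ids are row-major from the origin and stable
across runs. Pixels are assigned to the cell containing their center
(half-open intervals, left/bottom inclusive), and the pixel-counted cell
area — which partitions exactly over classes — is the $A_k$ used in LERI,
so composition conservation is exact rather than approximate.

## The synthetic-data generator

Real assessments start from classified satellite land-cover products and
gridded indicator layers. To make every downstream stage testable without
such inputs, `leriscape` ships a neutral-landscape generator emulating
their statistical structure:

* **Land cover** (`generateLandcover()`): modified random clusters. A
  Bernoulli percolation map at probability $p = 0.58 \times$ clumping
  (kept below the 4-neighbour percolation threshold ≈ 0.593) is labelled
  into 4-connected clusters; each cluster draws a class from the target
  proportions; unassigned pixels take the modal class of their assigned
  8-neighbours in a single pass (random tie-break), and pixels with no
  assigned neighbour draw independently. The single fill pass matters: an
  iterated majority fill acts like a voter model and coarsens low-density
  seed maps so much that fragmentation stops being monotone in the
  clumping knob. With the single pass, mean within-cell patch count
  decreases monotonically in clumping over the whole range; mean
  fragmentation $C$ does so over the practical range but can tick up again
  as clumping → 1, where minor classes survive only as tiny slivers and
  $n/A$ diverges — a property of per-area normalization, not of the
  generator.
* **Indicators** (`generateIndicators()`): white noise smoothed by a
  separable Gaussian kernel (SD = `corLength` pixels, edge-renormalized),
  standardized and rescaled to plausible per-indicator locations and
  spreads (e.g. elevation 1500 ± 800 m, NDVI 0.5 ± 0.15). The fields are
  variance-stabilized, so increasing `corLength` raises spatial
  autocorrelation and local smoothness rather than shrinking the overall
  spread.
* **Change process** (`evolveLandcover()`): per step, a fraction
  `urbanRate` of the cropland pixels 4-adjacent to urban land converts to
  urban — frontier growth mimicking the cropland→urban conversion that
  dominates real multi-decade sequences. Urban area is non-decreasing; a
  map without an urban nucleus never changes, by documented convention.

Default study conditions — six classes with proportions (0.30, 0.15, 0.30,
0.05, 0.10, 0.10) for cropland, woodland, grassland, water, urban, unused;
clumping 0.5; 5 periods at 5-year spacing; urbanRate 0.15 — are chosen once
as a mid-fragmentation agricultural mosaic with accelerating urbanization.
What the generator does **not** emulate: real class-contagion structure
(e.g. water bodies as connected networks), correlations between indicators
and land cover (synthetic elevation is independent of synthetic
grassland), and regional gradients. Passing tests therefore demonstrate
the correctness of the arithmetic and its invariants on realistically
structured inputs, not calibration to any real region's risk levels.

## Numerical choices and degenerate inputs

* Connected components by iterative minimum-label propagation (exact;
  cross-checked against an independent flood-fill oracle in the tests).
* Areas in km²; composition from integer pixel counts, so conservation
  identities are exact, not approximate.
* Constant indicator column → 0.5 + warning; all-zero column → error in
  the entropy route (weight undefined).
* Cells with no valid pixels are dropped from composition with a warning
  and excluded downstream.
* `LERI = 0` cells make RRC undefined (NA + warning); zero-mean series make
  CV undefined likewise.
* Jenks requires at least as many distinct values as classes, else errors.
* Quantile ties at the key-area threshold are excluded, with a warning.
* All generators consume a single integer seed; reruns are byte-identical.

## Problem sizes

The shipped tests and the acceptance script run a five-period study of 500
assessment cells (a 500 × 400 km extent at 2 km pixel resolution, 20 km
cells) plus property sweeps of 20 seeds × 3 clumping levels at 60 × 60
pixels — sizes chosen so the full cycle completes in a few minutes on one
CPU while every stage still operates well above degenerate scale. The same
code handles the thousands of cells of a provincial-scale study; the
per-cell patch labelling dominates the cost and scales linearly in cells.

## Worked example

```{r example}
cfg <- list(seed = 11,
            synthetic = list(extent = c(0, 0, 200, 160), res = 1,
                             nPeriods = 5, clumping = 0.5, urbanRate = 0.15))
res <- runPipeline(cfg, outDir = NULL)
res$panel
res$mask$counts
res$mask$unionSharePct
head(summarizeRisk(res$panel)$classShares)
netChange(res$transfers)
```

## Known limitations

* Boundaries are single-ring polygons without holes; multipolygon coasts
  must be simplified or supplied as rectangles/masks.
* Raster I/O is plain-text ESRI ASCII grid with a YAML sidecar; no
  projected CRS handling — coordinates are taken as kilometres on a plane.
* The empirical vulnerability ranks are expert ordinal scores; the index
  inherits their ordinal (not ratio) character, so LERI comparisons are
  meaningful within a study, not across studies with different EV tables.
* Indicator orientations are a declared modelling default, not an
  inference; swap them via the `orientations` argument where local
  knowledge differs.
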