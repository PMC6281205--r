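---
title: "A spatial economic model of legal and illegal selective logging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spatial economic model of legal and illegal selective logging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timbersim)
```

## The problem

Timber concessions in public forests compete in the same round-wood market
as illegal, conventional logging (CL) on private and undesignated land.
Because CL avoids management planning, intensity caps and re-entry
restrictions, it supplies the same mills at lower effective cost, and can
displace harvest away from concessions — *leakage*. `timbersim` simulates
this competition on a raster landscape over one harvest cycle, comparing a
LEGAL world (reduced-impact logging, RIL, everywhere harvest is allowed)
with an ILLEGAL business-as-usual world (CL outside the sustainable-use
estate).

## Model structure

One simulated year consists of, in order:

1. **Friction surface.** Every cell gets a traversal cost in R$/m³/km:
   barrier zoning (strictly protected, indigenous, military) = 5,000 over
   everything; else the road/waterway class value; else the land-cover
   value, capped at 0.8 inside sustainable-use/undesignated public forest.
   Barriers are prohibitive but finite — routes through them are possible at
   an economically absurd cost, never free.
2. **Cost accumulation.** Multi-source least-cost accumulation (Dijkstra on
   the 8-connected lattice; a step costs the mean of the two endpoint
   frictions times the step length, √2-scaled on diagonals) gives the
   transport cost `TC` to the cheapest active center and the center
   allocation — the *areas of influence*.
3. **Prices and rent.** Each cell inherits its center's round-wood price and
   harvest cost. Unit cost is `(HC + TC)·(1 + Int_rate)`; net rent is
   harvestable volume × cell area × (price − unit cost). Harvestable volume
   is capped at 25.8 m³/ha (0.86 m³/ha/yr × 30 yr) on RIL cells and is the
   full remaining volume on CL cells.
4. **Eligibility.** RIL land is tiled into 27,000-ha FMUs of 30 annual
   900-ha APUs; only the APU whose index matches the cycle year is open, and
   only if untouched (single entry). CL cells are open whenever volume
   remains.
5. **Harvest.** Each center takes its eligible, positive-rent cells in
   decreasing rent order until its annual capacity is filled (the marginal
   cell may be taken partially).
6. **Roads.** Every harvested cell not on the network is connected to the
   nearest network cell by the least-cost path, which becomes unpaved road
   (friction 0.5). Paths are built in rent-descending order so early roads
   cheapen later ones; barrier cells are never converted.
7. **Industry dynamics.** Capacity grows by at most 20 %/yr toward the
   profitable volume remaining in the area of influence, or declines to
   track it exactly; a center reaching zero shuts down, and for each
   shutdown the industry may found one new center of 50,000 m³/yr in the
   cell with the highest windowed profitable volume 200–500 km (straight
   line) from any active center.

Prices, costs and demand are constant over the cycle; there is no regrowth
(one cycle only), and no fine/risk-of-detection cost for CL (no usable
empirical estimate exists).

## Parameters

| Parameter | Default | Unit | Meaning |
|---|---|---|---|
| `cycle_years` | 30 | yr | harvest cycle; number of APUs per FMU |
| `max_intensity` | 0.86 | m³/ha/yr | legal RIL intensity cap |
| `fmu_area` / `apu_area` | 27,000 / 900 | ha | management-unit geometry |
| `newborn_capacity` | 50,000 | m³/yr | initial capacity of spawned centers |
| `max_capacity_growth` | 0.20 | /yr | capacity growth ceiling |
| `min/max_spawn_distance` | 200 / 500 | km | emergence band for new centers |
| `interest_rate` | 0.05 | /yr | opportunity cost of capital |
| `price_drift` | 0 | /yr | prices constant in time |
| `exchange_rate` | 1.995 | BRL/USD | 2009 average, for reporting |
| cell size | 100 | ha | 1 km grid (configurable) |

The source material prints a nominal spatial resolution of 0.09 decimal
degree alongside a ~1 km² cell description; these are inconsistent (0.09° is
roughly 10 km). We follow the ~1 km² description and expose the cell edge as
configuration — coarse grids (e.g. 10 km cells) are useful when exercising
the 200–500 km spawn band on small lattices.

## The synthetic landscape generator

Real applications of this model family use continental land-cover, zoning
and transport rasters that cannot be shipped. `generate_landscape()`
produces seeded stand-ins with the statistical structure the algorithms
assume:

* **Volume**: a log-Gaussian random field (FFT-smoothed white noise, exact
  target mean in expectation) on forest cells, mean 16 m³/ha by default —
  the published baseline stock/area ratio (4,835 Mm³ over 302 Mha). The
  field's covariance is a calibration choice (`volume_sill` 64 (m³/ha)²,
  `correlation_range` 10 cells), not an empirical claim: the source data do
  not state one.
* **Zoning**: quota-bounded multi-seed region growing, yielding contiguous
  mosaics whose realized fractions match the public-forest-registry area
  shares (42 % private, 13 % strictly protected, 15 % indigenous, 8/7 %
  federal/state undesignated, 11 % other sustainable use, 3 % National
  Forest, 1 % military) essentially exactly; the test suite enforces ±5
  percentage points.
* **Land cover**: the same mosaic machinery (60 % forest, matching the
  302/516 Mha forest share of the study region).
* **Roads**: a minimum-spanning-tree trunk network over the centers plus
  random spurs — all centers are always connected.
* **Centers**: uniform draws from the 2009-plausible ranges (capacity
  0.05–0.5 Mm³/yr, price 100–200 R$/m³, harvest cost 30–60 R$/m³). An
  optional `price_floor` mirrors the published data-cleaning rule that
  below-threshold price estimates are discarded and replaced by the mean.

What a green test on synthetic data does **not** establish: agreement with
the continental-scale absolute totals (those depend on the real rasters),
realistic road-network topology, or price/cost spatial gradients. What it
does establish: the harvest rules, accounting identities, cost-distance
algebra and scenario contrasts behave correctly on inputs with the right
statistical shape.

## Numerical and design choices

* **Lattice convention.** The original implementation's connectivity is
  undocumented; we fix 8-connectivity with mean-of-endpoint step costs and
  √2 diagonals, and test the implementation against an independent
  brute-force Dijkstra under the *same* convention — the tests verify the
  algorithm, not the convention.
* **Friction precedence** (barriers ≻ roads ≻ land cover/zoning) is our
  resolution of a table whose rows can overlap; barrier dominance preserves
  the intent that protected areas block transit even where a road exists.
* **FMU tiling** uses rectangular blocks in row-major order (18 × 15 cells
  at the defaults, i.e. a 6 × 5 lattice of 3 × 3-cell APUs); actual
  management units have irregular shapes, but squares match the source's
  own schematic representation. Truncated edge blocks fall back to
  round-robin APU assignment (sizes within one cell of equal); blocks
  smaller than one cell per APU trigger a warning. Year *k* harvests APU
  *k* — no ordering is stated, identity is the reproducible choice.
* **Ties** in harvest allocation are broken by (row, col); spawn-site ties
  by the seeded simulation RNG. Runs are byte-deterministic given the seed.
* **Rent ≤ 0 is never harvested** — "profitable volume" is interpreted
  strictly.
* **Capacity update phase.** Capacity reacts to the *post-harvest*
  profitable volume of the same year, on that year's cost surface; the
  source implies reaction to availability without fixing the phase.
* **Spawn-site scoring** sums profitable volume over a square (Chebyshev)
  window of 50 km half-width via an integral image; the source says only
  "nearby areas with high profitable volume". Straight-line distance is
  used for the 200–500 km band (cost distance to a not-yet-existing center
  would be circular).
* **Per-cell roads.** One least-cost attachment per harvested cell, reusing
  roads built earlier the same year (rent-descending order); whether the
  original builds per cell or per patch is unstated.
* **Logged area** counts a cell once, the first year it is entered, so CL
  re-entry does not double-count area.
* **Contested cells** on area-of-influence boundaries belong to the cheapest
  center by construction; centers never compete for the same cell within a
  year.

## Reporting

`summarize_ledger()` aggregates a run into the per-category table (volume,
newly logged area, net profit in USD at R$1.995/USD);
`compare_scenarios()` computes ILLEGAL-vs-LEGAL differences and percent
changes and fraction-of-baseline statistics, with half-up rounding applied
only at presentation. The shipped `amazon_reference_tables()` dataset
carries the published per-category totals of the continental application, so
the full comparison arithmetic — +7.7 % area, +5.7 % volume, +18.8 % profit,
−59 % National-Forest area, the USD 1.3 B concession loss, and the 69/40/39/
38/25/33 % exposure fractions — is reproducible without the proprietary
rasters. Its printed Amazon-wide total row exceeds the sum of the listed
categories (protected and unclassified land is not broken out); the loader
keeps the printed row as-is, while tables computed from simulated ledgers
satisfy the partition identity exactly. One printed fraction ("~55 %" of
Federal Undesignated area) is inconsistent with its own inputs (20.2/39.7 =
51 %); the package reports the computed value.

## Known limitations

* Single cycle, no regrowth, constant prices/costs — by construction.
* The spawn band (200–500 km) cannot trigger on small fine-grained grids;
  use coarser cells to exercise it.
* Raster I/O is plain-text ASCII grid (no GeoTIFF dependency is available);
  adapters for real datasets are out of scope.
* Synthetic landscapes support correctness and direction-of-effect claims,
  not absolute continental magnitudes.

```{r example}
fx <- generate_fixture("leakage_demo")
pair <- suppressWarnings(run_pair(fx$grid, fx$centers, fx$params))
ti <- summarize_ledger(pair$ILLEGAL)
tl <- summarize_ledger(pair$LEGAL)
# National-Forest logged area shrinks when illegal logging is allowed outside
c(LEGAL = tl$area_Mha[tl$category == "national_forest"],
  ILLEGAL = ti$area_Mha[ti$category == "national_forest"])
```
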