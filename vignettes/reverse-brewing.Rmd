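---
title: "Reverse brewing: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse brewing: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`brewdfo` inverts the usual direction of brewing arithmetic: instead of
predicting a beer's properties from a recipe, it searches an inventory of
constrained ingredients for recipes that *produce* a requested property
profile. This vignette is the package's own account of the science inside
it: the forward fermentation model and its assumptions, the optimiser and
its parameters, how the shipped attribute table was calibrated, the design
decisions that were genuinely open, and what the package's tests do and do
not establish.

## 1. The forward fermentation model

A recipe is a vector of amounts, one per inventory ingredient, bounded
below by zero and above by the in-stock amount. The simulator maps it to
five organoleptic properties. All five models are the standard tools of
craft-brewing calculation; they are deliberately *static* — they summarise
the outcome of mashing, boiling and fermentation without modelling their
kinetics.

**Original gravity.** Each fermentable contributes its laboratory extract
potential `P_f` (specific gravity per pound per US gallon, e.g. 1.038 for a
pale malt), scaled by the brewhouse efficiency `η`:

$$\mathrm{OG} = 1 + \frac{\sum_f m_f^{\mathrm{(lb)}}\,(P_f - 1)\,
  \eta}{V_{\mathrm{gal}}}.$$

Efficiency defaults to 0.58, typical of small-scale equipment; batch volume
defaults to 20 L. Gravity is linear in every fermentable amount, which the
tests exploit (doubling the grist doubles the gravity points).

**Final gravity.** The classical single-number model
`FG = OG − A·(OG − 1)` with apparent attenuation `A` cannot span the
benchmark targets, whose implied apparent attenuations range from roughly
51 % (a sweet stout) to 93 % (a highly attenuated golden ale) under one
yeast strain. The model here therefore attenuates *per fermentable*: the
gravity points contributed by fermentable `f` are multiplied by
`1 − A·φ_f`, where `φ_f ∈ [0, 1]` is that fermentable's fermentability.
Base malts (`φ = 1`) ferment out fully at the strain's attenuation
(`A = 0.75` for the packaged English ale yeast); crystal (`φ = 0.2`),
dextrine (`φ = 0`) and roasted (`φ = 0.3`) malts leave residual extract.
A grist's apparent attenuation is then an extract-weighted average, and
low-attenuation targets become reachable by shifting grist composition —
which is exactly the lever the optimiser uses.

**Alcohol.** Of the common ABV estimators, the package uses

$$\mathrm{ABV} = \frac{76.08\,(\mathrm{OG}-\mathrm{FG})}{1.775-\mathrm{OG}}
  \cdot \frac{\mathrm{FG}}{0.794},$$

the variant that remains accurate for strong beers. The choice is not
arbitrary: applied to the printed (OG, FG) pairs of all 22 packaged
benchmark products it reproduces every printed ABV within ±0.05 (the
simple `131.25·(OG−FG)` rule misses the strong products by several tenths).
The test suite asserts this consistency for all rows.

**Bitterness.** Tinseth's utilisation model: hops contribute
`α_h · m_h · 1000 / V_L` mg/L of alpha acids, of which the fraction

$$U(G_b, t) = 1.65 \cdot 0.000125^{\,G_b - 1}\cdot
  \frac{1 - e^{-0.04\,t}}{4.15}$$

is isomerised, decreasing in the boil gravity `G_b` and saturating in the
boil time `t` (60 min by default). `G_b` is the total extract spread over
the pre-boil volume (24 L), not the batch volume. All hops are treated as a
single full-length boil addition; the benchmark targets carry no addition
timing, so a hop schedule would add unidentifiable degrees of freedom.

**Colour.** Morey's model, `SRM = 1.4922·MCU^0.6859` with
`MCU = Σ_f m_f^(lb) L_f / V_gal` and `L_f` the grain colour in degrees
Lovibond. The sublinear exponent means colour saturates: even consuming
every fermentable in the packaged inventory yields only SRM ≈ 58.9, which
is what makes the five SRM > 70 benchmark products infeasible (section 4).

The yeast dimension is part of the search vector but inert: attenuation is
a strain property, not a pitch-rate effect, so all five properties are
invariant to the yeast amount. Unit conversions (1 kg = 2.20462 lb,
1 L = 0.264172 gal) live inside the calculators; every public interface is
metric.

## 2. The calibrated attribute table

The per-ingredient constants the simulator needs (alpha-acid fractions,
extract potentials, Lovibond colours, fermentabilities, attenuation) are
not part of the benchmark inputs, which list only names and stock amounts.
The package ships a calibrated table —
`inst/extdata/attributes_synthetic.csv`, a synthetic stand-in assembled
from standard maltster and hop references — with two calibration anchors:

1. the full-stock colour ceiling lands at SRM ≈ 58, so that exactly the
   five products with SRM targets above 70 are infeasible while SRM-47 and
   SRM-50 targets remain reachable, and
2. the hop alpha-acid fractions give an IBU ceiling (≈ 380 at benchmark
   gravities) comfortably above the most bitter target (250).

Every value can be overridden by passing your own attribute file to
`brew_inventory()`; the fixture's checksums are pinned in the tests, so an
accidental edit fails loudly.

## 3. The optimiser

Dispersive flies optimisation is a minimal swarm algorithm: position-only
(no velocities), one control parameter beyond population size. The
package's configuration defaults are the benchmark conditions: `N = 50`
flies, restart threshold `Δ = 0.001`, budget 50,000 fitness evaluations,
success at error ≤ 0.05, elitism on, ring topology.

**Update.** Flies are swept in index order and updated in place. Each
component of fly `i` moves to `x_nb + u (x_s − x_i)` with `u ~ U(0,1)`
drawn afresh per component, `x_s` the swarm best and `x_nb` the better (by
the previous sweep's fitness) of the two ring neighbours *at its current
position*. The in-place sweep matters: an improvement found early in the
sweep is visible to higher-indexed flies immediately, so information
cascades around the ring within an iteration rather than one hop per
iteration. We implemented both orders; the snapshot (fully synchronous)
variant converges three to four times slower on this landscape, and only
the in-place sweep reproduces the published efficiency scale of the
reference implementation of the algorithm (overall median ≈ 1000–1200
evaluations to success on the solvable benchmark products). The fitness
evaluation itself is batch-vectorised over the swarm.

**Restart, clamping, elitism.** After the update, each component is
resampled uniformly in its bounds with probability Δ (per component, not
per fly — a partial, dimension-wise restart preserves the rest of the
solution), then clamped to `[0, stock]`. The swarm best is exempt from
both update and restart, which makes the best-error trace non-increasing —
a property the tests assert on every run they touch. The evaluation
counter advances by `N` per iteration (the elite's slot counted although
its error carries over), plus `N` for initialisation, so counts are
multiples of the swarm size.

**Error form.** The fitness is the distance between simulated and target
property vectors. The package defaults to the Euclidean form (root of the
sum of squares) rather than the raw sum of squares: on infeasible products
the best achievable error then equals the colour shortfall in SRM units
(e.g. ≈ 12.7 for the SRM-71 target against the ≈ 58 ceiling), which is the
scale on which such errors are conventionally reported; the squared form
remains available via `error_form = "sum_of_squares"`. Note the error
mixes units (percent ABV, IBU, SRM, gravity points ×10⁻³): gravity
deviations are numerically tiny on the 1.0xx scale, so OG and FG act as
soft preferences while ABV, IBU and SRM dominate the fitness. That is a
property of the published formulation that the package reproduces, not a
choice it makes.

**Ties and reproducibility.** Neighbour-best and swarm-best ties break to
the lower index. One seeded generator drives a whole run; identical seeds
give bit-identical results, and the benchmark derives per-run seeds as
`base_seed + product_no · 1000 + run`.

**Termination.** Success is checked after each full sweep; a sweep is only
started if its `N` evaluations fit in the remaining budget, so `fes_used`
never exceeds the budget.

**Dynamic targets.** `dfo_schedule()` carries the swarm across target
changes without re-initialisation. At a switch the whole swarm is
re-evaluated against the new target (counted in the budget); the
*transition error* recorded for the segment is the incumbent best
solution's error under the new target — the property-space distance
between where the swarm had settled and where it must now go.
`fix_dimensions` support (the `fixed` argument) pins chosen ingredients at
given amounts, excluding them from update and restart; the
forced-consumption sweep uses it to demand full use of one fermentable at
a time.

## 4. What the benchmark establishes

Running the 22 packaged products under the default configuration (the
acceptance script does this with 50 seeded runs per product; the test
suite with 10):

* **Feasibility is colour-driven.** Exactly the five products whose SRM
  target exceeds 70 fail in every run — their best achievable error equals
  the gap between target SRM and the inventory's ≈ 58 ceiling. The other
  17 products are solved.
* **Reliability.** Every solvable product succeeds in the great majority
  of runs (minimum per-product reliability ≈ 86 % at 50 seeds in our
  runs).
* **Efficiency.** The median evaluations-to-success, aggregated over
  solvable products, sits near 1050; the slowest product's median stays
  under ≈ 5000.

These are stochastic quantities; the test suite asserts them with
tolerances reflecting 10-seed binomial noise, and the acceptance script
recomputes them from scratch at 50 seeds.

## 5. Solution diversity and recipe families

Independent runs deliver genuinely different recipes. Diversity is
measured as the mean Euclidean distance to the population centroid — a
centre-based measure robust to outliers — and solution distances as
pairwise Euclidean distances between the successful runs' best recipes.
Both are computed in **canonical kilogram units** (hop grams and yeast
millilitres scaled to kg): on the raw mixed units the gram-scale hop
dimensions would dominate every distance, while in kilograms the heavy
malts carry the variation, matching the scale on which solution diversity
is conventionally reported for this benchmark.

Recipe families come from K-means on **stock-normalised** vectors (each
amount divided by its ingredient's stock, mapping every dimension to
`[0, 1]`); normalisation is essential for the opposite reason — raw
kilograms would let the 7 kg base malt dwarf a 0.5 kg roasted grain that
is, proportionally, the decisive ingredient. The number of clusters is
chosen by majority vote over a battery of validity indices
(Calinski–Harabasz, mean silhouette, Davies–Bouldin, Dunn, Hartigan's
rule, C-index, gap statistic, within-SS elbow; ties to the smaller k,
candidate range 2–6). The published analysis of this benchmark used a
larger, only partially identified battery of twenty indices, so vote
*counts* here are not expected to match it product by product; the tests
instead assert the property that matters — planted cluster structure at
separation ratio ≥ 5 is recovered in ≥ 90 % of seeds across k = 2…6 — and
that unstructured data yields only a weak majority. Per-cluster
consumption profiles flag an ingredient as distinctive (`high`) when a
cluster's mean normalised consumption leads every other cluster by at
least 0.25 — a margin chosen once so that flags appear only for
qualitatively different grist choices, not sampling noise. Hierarchical
linkage (Ward on the same normalised vectors) provides the dendrogram
view; cutting it is left to the user.

## 6. The synthetic-inventory generator

`generate_synthetic_inventory()` draws seeded random inventories (counts,
stocks and attributes uniform within declared ranges) for property-based
testing of the optimiser, the metrics and the file round-trips. It
emulates the *structure* of a real stock list — category-specific
attributes, native units, hard stock bounds — but not its realism: real
malt attributes are correlated (dark grains have lower potentials),
stocks are not uniform, and hop inventories are not independent of style.
Tests passing on synthetic inventories therefore establish the
algorithmic invariants (bounds, determinism, accounting, metric
properties), not agreement with any real brewery.

## 7. Numerical choices and degenerate inputs

* Bounds are enforced with a 10⁻⁹ absolute tolerance; amounts at exactly
  the stock are legal (the forced-consumption mode depends on it).
* An empty recipe is the water baseline (OG = FG = 1, ABV = IBU = SRM
  = 0); an empty grist makes FG equal OG by convention (nothing to
  attenuate).
* OG ≥ 1.775 is outside the alcohol formula's domain and raises an error
  (unreachable from any realistic inventory).
* A zero-stock dimension collapses to 0 for every fly; K-means with k
  equal to the number of solutions returns singletons directly
  (`stats::kmeans` requires k < n).
* The gap statistic uses 25 uniform reference draws over the data's
  bounding box with the first-SE-max rule; K-means uses 10 seeded
  restarts.

## 8. Problem sizes used in the shipped checks

The test suite runs the full 22-product benchmark at 10 seeds per product
and the acceptance script at 50 — sizes chosen so the whole suite completes
in minutes on a laptop while keeping binomial noise on reliability within
the asserted tolerances. Infeasible products always consume the full
50,000-evaluation budget, so they dominate the runtime; the vectorised
evaluator makes this a few hundred milliseconds per run.

## 9. Known limitations

* The simulator ignores mash thermodynamics, water chemistry, fermentation
  kinetics, and flavour/aroma/foam — the properties it matches are the
  five numeric ones only.
* The attribute table is calibrated, not measured; with different malt
  constants the feasibility boundary (which SRM targets are reachable)
  moves.
* Boundary optima with many active bound constraints are the optimiser's
  weakest case: a target sitting exactly at the full-stock corner is
  reached in about 84 % of runs, the rest stalling in a nearby local
  trap — acceptable for recipe discovery (any success yields a recipe) but
  worth knowing for other uses.
* The error form's unit mixture (section 3) means gravity targets are
  matched loosely relative to ABV/IBU/SRM. Re-weighting the five
  properties would change which recipes are "optimal" and is deliberately
  left out of scope.
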