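---
title: "Methods: prey-based maximum-entropy habitat screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prey-based maximum-entropy habitat screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preyhab)
```

## Problem and approach

A carnivore extinct in the wild has no presence records, so `preyhab`
treats the joint habitat of its key prey species as the proxy for its own
potential habitat. Each prey species gets a presence-background species
distribution model; prey maps are overlaid with equal weight into a
predator suitability index; the index is classified, required to stay high
across time horizons, and the surviving area is screened into discrete
candidate sites that are finally expressed as supportable animal numbers.
Every stage is a plain function over matrices bound to a shared grid
geometry (`grid_spec`), so the whole chain is scriptable and seedable.

## The maximum-entropy model

`maxent()` fits a Gibbs distribution over the background cells: the
probability of cell $x$ is $q(x) = e^{\eta(x)}/Z$ with
$\eta(x) = \sum_j \lambda_j f_j(x)$. Features are built by
`build_features()` from the raw layers: linear, squares, pairwise
products, forward/reverse hinges and step functions at interior background
quantile knots (5 per layer by default). Each feature is min–max scaled to
$[0,1]$ on the background; projections onto other stacks clamp to that
range, which is the standard guard against extrapolation.

The objective is the L1-penalized negative presence log-likelihood

$$-\tfrac1m \sum_{\text{pres}} \eta(x) + \log\!\sum_{\text{bg}} e^{\eta(x)}
  + \sum_j \beta_j |\lambda_j|, \qquad
  \beta_j = \mathrm{rm}\cdot w_{\text{class}} \cdot s_j/\sqrt{m},$$

with $s_j$ the presence standard deviation of feature $j$ (floored at
$10^{-6}$ so every feature carries a positive penalty), class weight 0.5
for hinge features and 1 otherwise, and $\mathrm{rm}$ the user-facing
regularization multiplier. This objective is convex; it is minimized by
FISTA (accelerated proximal gradient) with backtracking on the smooth part,
a momentum restart whenever the objective ticks up, and convergence
declared after the objective moves less than $10^{-6}$ for five consecutive
iterations (cap 5000; hitting the cap returns the model flagged
non-converged rather than failing). Correctness is checked against the
optimality conditions rather than a reference binary: at the optimum,
$|E_q[f_j] - \bar f_j^{\text{pres}}| \le \beta_j$ for every feature, which
the tests assert to $10^{-4}$, and the fitted probabilities sum to one over
the background to $10^{-8}$.

The 0–1 suitability index is the cloglog transform
$1 - \exp(-e^{H} q)$ with $H$ the entropy of the fitted distribution
(logistic-era output is deliberately not offered; raw output is). For the
uniform model this gives $1 - e^{-1} \approx 0.632$ everywhere, a useful
closed-form anchor in the tests.

### Evaluation and calibration

* **AUC** is the Mann–Whitney probability that a presence outranks a
  background cell (ties half), computed from ranks; presences are excluded
  from the background sample first. Qualitative bands are fixed:
  [0.5, 0.6) unqualified, [0.6, 0.7) poor, [0.7, 0.8) fair, [0.8, 0.9)
  good, [0.9, 1.0] excellent — left-closed, right-open except the top.
* **Omission rate** uses the inverse-empirical-CDF percentile (default
  10th) of training-presence suitability as threshold; test presences
  strictly below it are omitted.
* **AICc** follows the Warren–Seifert convention: presence likelihood under
  the background-normalized raw distribution, $k$ = nonzero coefficients,
  undefined when $n \le k+1$.
* **Calibration** (`calibrate()`) crosses regularization multipliers
  {0.5, 1, 2, 4} with feature combinations {L, LQ, LQP, LQH, LQPH} by
  default. Candidates are fit on one seeded 75/25 split; rows with test
  omission ≤ 5% are "acceptable", and among them rows within ΔAICc ≤ 2 are
  selected; if nothing is acceptable the overall AICc minimum is selected.
  The partial-ROC significance step used by some calibration workflows is
  intentionally replaced by the omission criterion alone — it would add a
  heavy bootstrap with no effect on any quantity this package reports, and
  the substitution is recorded in the calibration table's metadata.
* **Replicates** (`replicate_run()`): ten seeded 75/25 splits; the final
  map is the cell-wise mean of the replicate cloglog maps.

## From suitability to candidate sites

* `scenario_mean()` averages the four SSP maps of a horizon cell-wise;
  missing data in any input poisons the cell.
* `prey_overlay()` takes the unweighted mean of the prey maps and min–max
  rescales it to $[0,1]$ over valid cells. "Standardize with equal weight"
  admits several readings; the mean-then-rescale one is the simplest that
  returns a 0–1 index, and a degenerate constant mean maps to 0.
* `classify_suitability()` cuts at (0.1, 0.3, 0.5) by default. Published
  workflows rarely state their breaks, and none are stated for the study
  this design follows; the defaults are a common cloglog convention, are
  recorded in every output, and none of the package's published-table
  arithmetic depends on them.
* `stability_superposition()` takes the cell-wise *minimum* level across
  current/2050/2070 — a cell is stably high only if high in all three.
  This is the conservative reading of "superimpose"; a mean-based variant
  was considered and rejected because downstream screening consumes a
  boolean stable-high mask, not a graded one.
* `extract_patches()` labels 8-connected components (the region-group
  convention; 4 by option) with an iterative flood fill, and areas are
  spherical: a cell spanning $\Delta\lambda \times \Delta\phi$ contributes
  $R^2\,\Delta\lambda\,(\sin\phi_t - \sin\phi_b)$, $R = 6371$ km. All
  distances elsewhere (thinning, footprint decay) use the great circle on
  the same sphere, so areas and distances are mutually consistent.
* `screen_patches()` keeps a patch iff area ≥ 100 km² and the
  area-weighted fraction with human footprint index (HFI) strictly above
  8.0 is at most 0.5. Both boundaries are literal: HFI exactly 8.0 does
  not count against a patch, and a patch with exactly half its area
  exceeding is kept ("more than 50%" rejects). Area and footprint filters
  are independent per patch, so their order does not matter; rejections
  are logged with reasons. `derive_hfi_threshold()` reproduces how such a
  ceiling is obtained (a quantile of HFI inside a known long-term survival
  range, rounded *up* to one decimal), but the pipeline takes the ceiling
  from configuration.
* `pa_overlap()` rasterizes protected-area polygons by cell-center
  inclusion — consistent with every other area in the package being a sum
  of cell areas — and reports the overlap percentage to one decimal.

## Carrying capacity

`tiger_capacity()` converts area to animals with sex-specific densities
(defaults 0.46 males and 1.32 females per 100 km²) applied to each sex's
half of the patch: $\lfloor A \cdot 0.5 \cdot d / 100 \rfloor$. The halved
area reflects non-superimposed male and female ranges. The published
20-site table this rule was validated against is shipped under
`inst/extdata/core_site_table.csv`: the rule reproduces 19 of 20 male and
19 of 20 female printed counts exactly, with one off-by-one in each column
(consistent with the printed areas themselves being rounded). The partition
fraction and rounding mode are configurable; the defaults are the validated
ones, and the two discrepant rows are asserted only to within ±1.

A related source-data wrinkle: the published habitat-area table mixes
truncation and rounding in its percent columns (some cells truncate toward
zero at two decimals, others round). `change_table()` therefore carries the
full-precision change alongside a truncated two-decimal column, and the
tests compare printed percentages at a ±0.02 percentage-point band, with
exact (truncated) agreement asserted only for cells where it holds.
`summarize_group_change()` likewise exposes both `round` and `trunc`
reporting because the published summary statistics are themselves
internally inconsistent between the two.

## The synthetic landscape

The generators exist so the whole pipeline is testable offline with known
truth:

* `gen_env_stack()` builds each layer by Gaussian-smoothing white noise
  (separable kernel, rows renormalized at edges), standardizing, and mixing
  layers through the symmetric square root of a target correlation matrix.
  Cross-layer correlations therefore converge to the target as the grid
  grows (tested to ±0.05 at 200 × 200) and a singular target (r = 1)
  yields exactly identical layers. Non-PSD targets are rejected.
* `make_truth_suitability()` evaluates a known generalized-linear niche
  (terms may include squared layers) through a logistic or cloglog link.
* `sample_occurrences()` draws cells proportionally to truth suitability
  and places points at cell centers — deliberately unjittered so cell
  deduplication and thinning have exact expected outcomes.
* `gen_hfi()` sums distance-decay fields $I\,e^{-d/\text{scale}}$ around
  settlement centers; `gen_protected_areas()` draws star-convex polygons
  kept fully inside the grid extent and rasterizes them by cell center.

What the generator does *not* emulate: real bioclim variable semantics,
spatial sampling bias in occurrence data, categorical land-cover layers,
and spatial autocorrelation between presences beyond what the smooth truth
surface induces. Passing tests therefore demonstrate that the machinery is
correct under controlled conditions, not that any particular real-world
prediction is accurate.

### Study conditions used in the checks

The truth-recovery checks use a 100 × 100 grid, two layers, a peaked
linear+quadratic niche, 500 presences and a 10,000-cell background cap —
presence and background sizes typical of national-scale SDM practice — and
require Spearman ≥ 0.9 against truth and test AUC ≥ 0.8 in at least 9 of
10 seeds. The packaged demo (`make_demo()`) is a 60 × 60 grid, six layers
with two collinear pairs (r = 0.9 and 0.85, exercising the |r| ≥ 0.8
screening rule), three prey species with 220–260 sampled occurrences each,
two horizons × four SSPs with forcing-ordered warming shifts, a two-city
footprint field and six protected areas. Its calibration grid is reduced to
rm ∈ {1, 2} × {L, LQ} — the demo's truth niches are linear/quadratic, so
the wider default grid adds nothing to what the demo demonstrates.

## Degenerate inputs and tie-breaks

Constant layers report `NA` correlations (never a silent 0) and score zero
contribution; degenerate features are centered to zero rather than
dividing by a zero range; correlated-pair removal processes the largest
|r| first and breaks score ties by dropping the later layer in input
order; patch ranking breaks area ties by patch id; occurrence-to-cell
mapping uses half-open cells so a point on a shared edge belongs to the
cell it left/top-bounds; thinning is greedy in input order (the behaviour
of the standard GIS tool for this step), hence deterministic and
idempotent, with pairs at exactly the minimum distance both retained.

All randomness — field generation, occurrence sampling, splits, background
subsampling — flows from explicit integer seeds, and `run_pipeline()`
derives every sub-stream from the single config seed, so a rerun with the
same config is byte-identical (checksummed in the run manifest).

## Limitations

The MaxEnt engine targets the model class, not bit-parity with the
reference Java implementation (different optimizer, knot placement and
default grids will move third-decimal coefficients). The thinning distance
behind published point-screening steps is typically unstated; it is an
explicit parameter (default 10 km) rather than a reproduction target.
Prey-density effects, corridor connectivity, road barriers and population
viability are out of scope: patch adjacency is reported, not analyzed.
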