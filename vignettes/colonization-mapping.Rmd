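---
title: "Grid-based mycorrhizal colonization mapping: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based mycorrhizal colonization mapping: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycomaps)
```

## The measurement model

`mycomaps` analyses arbuscular-mycorrhizal (AM) colonization of roots from
grid-coded microscopy. The atomic observation is one *microscopic field*: a
`rows x cols` grid (default 10 x 10) in which every cell records exactly one
state — empty root area, hypha, arbuscule, vesicle or spore. A *mycorrhizal
map* is the ordered run of fields scored along one 1-cm root segment
(default 15 fields, proximal to distal). A *study* crosses treatment x
phenophase variants with replications and segments; the default layout (9
variants x 3 replications x 15 segments x 15 fields) produces 405 maps and
6,075 field records.

The 10 x 10 grid is a convention of this package, not a measured property:
grid-scoring methods for root microscopy differ in resolution, and the
field's colonization tables are printed as percentages, which a 100-cell
field resolves exactly. The dimension is configurable in `study_design()`
and everything downstream adapts.

When a data source reports several structures in one cell, the cell keeps
the highest-precedence one (arbuscule > vesicle > spore > hypha): arbuscules
and vesicles are the functionally scored secondary structures, spores are
rare, and hyphae are the default carrier network present wherever anything
else is.

## Colonization parameters

For one map with fields $f = 1..n$, let $c_f$ be the number of occupied
(non-empty) cells of field $f$ and $N$ the cells per field. With
$\mathcal{C} = \{f : c_f > 0\}$ the colonized fields:

* **Frequency** $F = 100\,|\mathcal{C}|/n$ — the share of fields reached by
  the fungus.
* **Intensity** $I = 100 \sum_{f \in \mathcal{C}} c_f / (N |\mathcal{C}|)$ —
  cell occupancy *within colonized fields*.
* **Structure shares** Arb, Ves, Sp, Hyp — the same denominator as $I$,
  split by structure; they partition $I$ exactly.
* **Non-mycorrhizal area** $nonM = 100 - I$.
* **Colonization degree** $DC = F \cdot I / 100$ — occupancy over *all*
  cells.
* **M/nonM ratio** $I/(100-I)$, set to 0 at $I=0$ and capped at 999 at
  $I=100$ so it stays finite.
* **A/V ratio** — the mean over colonized fields of the per-field
  arbuscule/vesicle cell ratio (see below).

Computing frequency on a field basis and intensity within colonized fields
is the design choice that makes $DC = F\,I/100$ an exact identity and keeps
$100 - I$ distinct from $100 - DC$; as a structural consequence the Pearson
correlation between $I$ and $nonM$ is exactly $-1$ on any data set with
variance, while $nonM$–$DC$ correlations stay strong but imperfect. Those
two facts are useful integrity checks on any pipeline output and are
asserted in the test suite.

### The zero-vesicle problem

Vesicles occupy well under 1% of colonized root area in this system, so
most fields contain none, and the arbuscule/vesicle ratio needs a
convention. `av_ratio()` implements three: `"zero"` (a vesicle-free field
scores 0), `"infinite"` (scores `Inf` when arbuscules are present) and
`"exclude"` (vesicle-free fields drop out of the map mean). The default is
`"zero"`: it is the only convention under which a group can have a mean
arbuscule share an order of magnitude above its mean vesicle share and
still report a mean A/V ratio below 1 — the configuration the
strategy-profile analysis exhibits in practice. This default is a
reconstruction of ambiguous published practice, not an assertion about it;
the policy is a parameter throughout.

## Strategy classification

A colonized unit (map or single field) is classified by two thresholds on
intensity and one on the A/V ratio:

| strategy | rule |
|---|---|
| resistance (Rs) | $I < 10$ |
| proliferative (Ps) | $10 \le I \le 25$ |
| transfer (Ts) | $I > 25$ and $A/V > 1$ |
| storage (Ss) | $I > 25$ and $A/V \le 1$ |

The boundary conventions ($I$ exactly 10 or 25 goes to Ps, $A/V$ exactly 1
to Ss) make the intervals half-open and the classifier total; they are
configurable because the published thresholds name the open intervals only.
Under the `"zero"` policy a vesicle-free study can never produce a transfer
label — a direct, tested consequence of the ratio convention.

## Representative patterns

A study's map database is reduced to interpretable patterns per variant
group:

* **Median triplet** — maps at ranks $\lceil n/2 \rceil - 1$,
  $\lceil n/2 \rceil$, $\lceil n/2 \rceil + 1$ under a ranking parameter
  (default: colonization degree, the one parameter that blends extent and
  density; any metric column can be chosen). Ties break by (replicate,
  segment) so the extraction is order-invariant. Nine variants give 27
  representative maps.
* **Structure maxima** — the maps with the highest arbuscule and vesicle
  percentages (ties to the higher degree, then input order).

`multipoint_compare()` aligns maps of identical geometry on a common
position axis — whole fields, or single grid columns for finer resolution —
and tabulates the structure composition at every position plus each map's
uncolonized gaps (maximal runs of positions with no structure). Gap lengths
and colonized positions always partition the axis.

## Group statistics

ANOVA is one-way over the nine variant cells: the published letter displays
treat the treatment x phenophase combination as a single nine-level factor,
and a two-way decomposition is deliberately out of scope. The LSD post-hoc
uses per-pair group sizes,
$LSD_{ij} = t_{1-\alpha/2,\,df}\sqrt{MSE(1/n_i + 1/n_j)}$, and letters are
assigned by scanning means in descending order and lettering maximal runs
of mutually non-different groups; the display is re-checked against the
full pairwise matrix and warns in the (unbalanced, non-interval) cases
where no letter display is exact. Correlations are Pearson with two-sided
t-tests and an `ns` flag at $\alpha = 0.05$; constant columns are flagged
rather than fatal.

PCA runs on the correlation (standardized) matrix because the parameters
mix percentages and ratios. The `nonM` column is excluded by default —
being exactly $100 - I$ it adds a collinear, information-free axis — with
`include_nonM = TRUE` available when the combined intensity/non-mycorrhizal
vector is wanted in the display.

## Forecast models

For each parameter at each stage from the second onward, candidates are
*all* parameters of *all* strictly earlier stages (so a B5 response sees
4 stages x 8 parameters = 32 candidates). Selection is bidirectional
stepwise from the intercept-only model under
$AIC = n\ln(RSS/n) + 2(k+1)$ — the Gaussian likelihood up to an additive
constant, the same convention as `stats::extractAIC`, which makes
`stats::step` an independent oracle for the whole search path. Each
accepted move must strictly lower the AIC; moves that make the fit
singular (e.g. adding `nonM` on top of `I`) are skipped. The trace of
accepted steps is retained, giving the predictor hierarchy by order of
entry.

Stages are destructively sampled — a segment observed at B3 no longer
exists at B4 — so regression needs a pairing convention. Two are
implemented: `"rank"` (default) pairs the $i$-th ranked map (by
colonization degree) of each stage within a replicate, giving
$n = \text{replicates} \times \text{segments} = 45$ rows per arm;
`"segment"` joins on segment index, which is exact for synthetic data with
longitudinal identity. Neither is asserted to be the published pairing,
which is unstated; this is the largest reconstruction in the package.

Degenerate (zero-variance) responses yield intercept-only models with a
warning rather than an error, so a saturated synthetic stage cannot abort
a full run.

## The synthetic-data generator

The generator emulates the *statistical* structure of grid-scored AM
colonization; it is not a fungal growth model. Per variant,
`colonization_params()` holds:

| parameter | meaning | default source |
|---|---|---|
| $\varphi$ | probability a field is colonized; $E[F] = 100\varphi$ | per-variant scenario |
| $p$ | target occupied-cell fraction within colonized fields; $E[I] = 100p$ | per-variant scenario |
| $\rho$ | lateral column persistence (0.7) | chosen for contiguous colonized runs with realistic gaps |
| $\alpha, \nu, \sigma$ | arbuscule/vesicle/spore share of occupied cells | per-variant scenario |

A field is empty with probability $1-\varphi$; otherwise colonized columns
come from a two-state Markov chain with stationary occupancy $p$ and
persistence $\rho$, redrawn until at least one column is colonized. That
conditioning would inflate occupancy well above $p$ (at $p = 0.2$, $\rho =
0.7$, 10 columns, the all-empty probability is ~0.40), so each colonized
column receives one vertically contiguous occupied run whose random length
has mean $rows \times P(\text{any colonized column})$ — which cancels the
conditioning exactly, making $E[\text{occupied fraction} \mid
\text{colonized field}] = p$ without bias. For $p > 1/(2-\rho)$ no
stationary chain with persistence $\rho$ exists, and the persistence is
raised to $(2p-1)/p$, preserving stationarity at $p$; for very small $p$
(below about $0.03$ on a 10-row grid) the run length floors at one cell
and a slight upward bias remains. Occupied cells are labelled
independently with probabilities $(\alpha, \nu, \sigma, 1-\alpha-\nu-\sigma)$.

Per-map seeds are derived by hashing (master seed, variant, replicate,
segment) into a 31-bit integer, so any subset of a study regenerates
identically on its own and changing any index changes the stream.

The shipped scenarios (`inst/extdata/scenarios.yaml`) set each variant's
$(\varphi, p, \alpha, \nu)$ from the published per-variant means of
frequency, intensity and the structure shares, so the simulated
trajectories rise to the B3/B4 phenophases, fall at maturity and keep
treated plants behind untreated ones, with vesicles under 1% of colonized
area and arbuscules between ~2% and ~12%.

**What the generator does not emulate.** Cells are labelled independently
given occupancy, so vesicles are scattered rather than clustered; a rare
vesicle then tends to co-occur with many arbuscules in its field, which
pushes per-field A/V ratios (and hence transfer-strategy shares) higher
than field data where vesicle-bearing regions are arbuscule-poor. It also
draws fields independently within a map (no along-root trend) and ignores
replicate-level random effects. Passing tests therefore demonstrate the
correctness of the *computations* under a controlled data-generating
process — parameter recovery, identities, count bookkeeping — not that
real roots look like the simulations.

## Numerical conventions and test design

* Monte-Carlo recovery tests assert $E[F] = 100\varphi$ over all maps and
  $E[I] = 100p$ over maps with $F > 0$ (intensity is defined within
  colonized fields; an all-empty map carries the degenerate $I = 0$),
  within 3 Monte-Carlo standard errors at 500 maps.
* The metrics implementation is checked against a brute-force
  cell-enumeration oracle on 1,000 random small maps, exactly.
* Stepwise selection is compared with exhaustive all-subsets search on
  candidate pools of up to 10; greedy search may in principle stop at a
  local optimum (the trace documents it), and the suite checks it attains
  the global optimum in the clear majority of seeded instances and never
  reports an AIC below it.
* The pure-noise behaviour of stepwise AIC is asserted at its closed-form
  rate: a null candidate enters iff its squared sample correlation exceeds
  $1 - e^{-2/n}$, so with $c$ candidates the intercept-only model survives
  with probability about $(1 - P[\text{Beta}(\tfrac12, \tfrac{n-2}{2}) >
  1 - e^{-2/n}])^c$ — about 0.60 for $n = 200$, $c = 3$.
* Coefficient recovery of planted cross-stage effects is judged on the
  full-candidate OLS refit (free of post-selection bias); selection of the
  planted predictor is still required from the stepwise path.
* Analysis problem sizes: the workflow scripts and acceptance checks run
  the full 405-map design; property suites use small random maps (2-6
  cells a side) where exhaustive oracles are cheap.

## Known limitations

* The A/V zero-vesicle policy and the strategy boundary conventions are
  reconstructions of ambiguous published practice (both configurable).
* The stage-pairing convention for forecast regressions is a
  reconstruction; conclusions that depend on pairing should be checked
  under both modes.
* The generator's independence assumptions (above) limit how far simulated
  strategy shares can be read as predictions about real roots.
* Letter displays are exact for balanced groups; with very unbalanced
  sizes a non-interval significance pattern can admit no exact display,
  which the implementation detects and reports.
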