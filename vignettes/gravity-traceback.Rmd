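---
title: "Gravity-modelled grocery flows and Bayesian brand-source traceback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gravity-modelled grocery flows and Bayesian brand-source traceback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gravitrace)
```

## The problem

When a contaminated batch of food is sold through the stores of a single
retail brand, investigators see only the consequences: reported illnesses,
each attached to the postal zone where the patient lives. Connecting those
zones back to a brand requires a model of where the people in each zone
actually buy groceries. The common shortcut — everyone shops in their home
zone — is contradicted by mobility surveys: the mean German home-to-
supermarket trip is 4.65 km, longer than the radius of a typical postal
zone. This package models the missing last-mile link with a calibrated
gravity model and feeds it into an absorbing-Markov-chain source estimator.

## The gravity model

Zone-to-zone monetary flows follow the doubly constrained
entropy-maximising form
$$F_{ij} = A_i\,O_i\,B_j\,D_j\,e^{-\beta c_{ij}},$$
with production marginal $O_i$ (total store revenue of zone $i$),
attraction marginal $D_j = \mathrm{pop}_j/\sum_j \mathrm{pop}_j \cdot
\mathrm{REV}$ (equal per-capita food spend), and exponential distance
deterrence. The two constraint families $\sum_j F_{ij} = O_i$ and
$\sum_i F_{ij} = D_j$ determine the balancing factors; with $n$ zones the
model has $2n + 1$ free parameters including $\beta$.

**Furness balancing.** `furness_balance()` alternates row and column
scaling of the seed matrix $e^{-\beta c}$ until the worst relative marginal
error drops below `tol` (default `1e-6`, at most 10,000 sweeps — IPF
converges linearly and these matrices are small). Balancing factors are
identified only up to a reciprocal scale; we fix the convention that the
$B_j$ over attracting zones average 1 so the factors themselves are
testable. Zones with zero production keep all-zero rows rather than being
dropped, which preserves zone indexing downstream.

**Hyman calibration.** `hyman_calibrate()` adjusts $\beta$ until the
flow-weighted mean trip distance $\sum F_{ij} c_{ij} / \sum F_{ij}$ matches
the survey target within `tol_km` (default 0.01 km). The schedule is the
standard one: $\beta_0 = 1/\bar{c}^{*}$, one proportional step
$\beta_1 = \beta_0\,\bar{c}_0/\bar{c}^{*}$, then secant updates; each outer
candidate is balanced to full Furness convergence before its mean distance
is measured. Because the modelled mean is strictly decreasing in $\beta$
(verified as a property test), the secant iteration is well behaved; we
additionally clamp each step to a factor of five because a wild
extrapolation can push $e^{-\beta c}$ into floating-point underflow, where
the balancing problem loses support. Targets at or above the
no-deterrence ($\beta = 0$) mean are rejected as infeasible up front, and a
flat response of the mean to $\beta$ (e.g. a uniform cost matrix) is
likewise reported as an infeasible target rather than iterated on.

**The survey mean is an input.** Processing of trip microdata is out of
scope; `target_mean_km` is a plain configuration parameter, defaulting to
the 4.65 km mean shopping distance of the German national mobility survey.

## Distances

Off-diagonal costs are Euclidean centroid-to-centroid distances on a planar
km grid; inputs must be pre-projected (no geodesy here — the quantities of
interest are trip lengths, not coordinates). Intra-zonal trips need their
own length scale, and it matters: a zero diagonal would exempt same-zone
flows from deterrence entirely. Two estimators are provided:

- **Circle** (`intrazonal_circle`): the mean distance between two uniform
  random points in a circle of the zone's area,
  $\frac{128}{45\pi}\sqrt{A/\pi}$. Depends only on zone size, so it
  overestimates in store-dense zones.
- **Lattice** (`intrazonal_lattice`, the default): expected distance from a
  uniform consumer to the nearest retailer when the zone's $n$ stores are
  arranged on a lattice, $0.427\,\lambda^{-1/2}$ with density
  $\lambda = n/A$ in stores/km². The density is computed from the stated
  units (stores per km²). Zones without stores fall back to the circle
  formula so the cost matrix stays strictly positive.

Both scale linearly with length, and the lattice estimate undercuts the
circle estimate whenever $\lambda \ge 1$ — the motivation for preferring it
in dense retail landscapes.

`buffer_zones()` restricts a region to the zones within a radius of a focal
zone, the device that keeps per-outbreak gravity models small at national
scale while preserving fine zoning. The default radius of 30 km is a
package choice: more than six times the 4.65 km mean trip, so the truncated
tail flows are negligible.

## The synthetic region generator

Real inputs — store locations from a point-of-interest database, brand
revenues from trade-press reporting, survey microdata — are commercial or
restricted, so the package ships a seeded generator that emulates their
statistical shape for a county of 49 postal zones and 10 brands:

- centroids uniform in a 30 × 30 km box (a county-sized study area), areas
  from a Voronoi-style nearest-centroid partition of the box (positive,
  summing to the box area);
- populations log-uniform on [1,000, 20,000] — heavy-tailed zone sizes like
  real postal zones; the exact law is immaterial to correctness;
- 5–20 stores per brand, brand revenue totals log-uniform on [50M, 500M]
  currency units (small brands a tenth the size of market leaders, echoing
  the skew of real grocery retail), per-store revenue = brand total /
  store count (the equal-split convention; a per-store `weight` column can
  override it where store-size data exist);
- store placement is population-weighted after a first pass that gives
  every zone one store: the emulated county, like the real one, has food
  retail in every postal zone, so all zones both produce and attract flows.

What the generator does *not* emulate: correlated store siting (chains
cluster near competitors), within-brand store-size variation, socio-economic
consumption differences, and road-network detours. Passing tests therefore
demonstrate the correctness and qualitative behaviour of the machinery on a
realistic synthetic landscape, not quantitative agreement with any real
county's flow statistics.

## From flows to a supply network

`flow_probabilities()` row-normalises the balanced flows into the retailer
perspective $p(F_{ij}) = F_{ij}/\sum_j F_{ij}$; the diagonal is the
intra-zonal consumption share. `connectivity_stats()` summarises how many
consumer zones a retailer zone supplies above flow-share thresholds
(strict inequality at the threshold; the home zone counts as supplied,
which is why the 0% column equals the zone count — exponential deterrence
never produces an exactly-zero flow).

The supply network has three layers: brand nodes connect to retailer zones
with the brand's zonal market shares; retailer zones connect to consumer
zones with the gravity flow probabilities (network A) or to their own
consumer zone with probability 1 (network B, the shop-at-home baseline).
In Markov canonical form the transient block $P_Q$ is nilpotent of order 2,
so the absorption matrix $A = (I - P_Q)^{-1}P_R$ equals $(I + P_Q)P_R$;
`absorbing_matrix()` nevertheless uses a general linear solve so deeper
chains (producer → distributor → retailer) can be added without touching
the estimator. Retailer zones with zero production are excluded from the
transient set — they can receive no contaminated goods — which also keeps
$(I - P_Q)$ well conditioned. (Under network B this means a consumer zone
whose home zone sells nothing would be unreachable; with the default
generator every zone sells.)

## Outbreak simulation

Outbreaks are simulated on network A, taken as ground truth. A source
brand is drawn from the market-share prior; then, to produce an outbreak
with a prescribed spread $|\theta|$ (the number of distinct contaminated
zones), the simulator (1) samples $|\theta|$ distinct zones without
replacement with probabilities proportional to the source's absorption row,
(2) seeds one illness in each, and (3) distributes the remaining illnesses
multinomially over the selected zones with renormalised absorption
probabilities. This preserves the relative path probabilities of the
independent-unit transmission model while meeting the spread constraint
exactly; it is a modelling choice, since alternatives (e.g. rejection
sampling of unconstrained runs) would induce a slightly different
conditional distribution. Illness order is shuffled so that "first $m$
illnesses" prefixes are unbiased; infeasible sources are redrawn at most
100 times before failing loudly. Per-outbreak seeds derive deterministically
from the master seed, so batches are reproducible and any single outbreak
can be re-run in isolation.

## Inference

The posterior over brands multiplies the market-share prior by the
likelihood $\prod_{o_l \in \theta} A[b, o_l]$, evaluated entirely in log
space with max-subtraction before normalisation (a 500-term product of
probabilities underflows double precision). Brands whose absorption is zero
at any observed zone get posterior exactly 0 — no flooring — because a
brand with no route to a contaminated zone is genuinely excluded. Ties in
the maximum-posterior estimate resolve to the lowest brand index, and ranks
use competition ranking (1 + number of strictly greater brands); both are
arbitrary conventions the package fixes and documents, with the known
consequence that an all-tied posterior ranks every brand first.

## Evaluation design

`run_scenario()` simulates outbreaks of 500 illnesses at a given spread and
evaluates both networks at each point of an illness grid using nested
prefixes of the shuffled observation list — a variance-reduction and
determinism choice over independent subsamples. Accuracy (share of
outbreaks whose top-posterior brand is the true source) is reported with
binomial Monte Carlo standard errors; mean rank accompanies it. The default
of 300 outbreaks per scenario gives accuracy standard errors below 0.03
while keeping a full scenario sweep interactive on one CPU; the full-scale
experiment uses 1000 (`n_outbreaks = 1000`). The test suite exercises the
full 49-zone, 10-brand configuration; the acceptance checks there run the
complete calibration and 300-outbreak scenarios directly.

On the default synthetic region this reproduces the qualitative pattern the
method is built around: the gravity-informed network identifies the source
in the large majority of outbreaks by 20–30 reported illnesses and keeps
improving with spread, while the shop-at-home baseline plateaus near the
prior mass of the largest brand because observations attach to the wrong
retailer zones. One artefact of the ranking convention deserves note: when
the baseline network rules out *every* brand (all posteriors zero-tied), the
competition rank of the truth is 1, so the baseline's mean rank can look
deceptively good precisely when its posterior is least informative;
accuracy is the primary comparison.

## Numerical choices, degenerate inputs, limitations

- Furness tolerance `1e-6` relative / 10,000 sweeps; Hyman tolerance
  0.01 km; both configurable. Tolerances this tight are cheap at
  county scale ($n \lesssim$ a few hundred zones).
- Near-degenerate transport: for very small or sparse regions the feasible
  band of mean trip distances is narrow and high; targets near its floor
  make IPF converge slowly (the balancing problem approaches a degenerate
  transport plan). The fit warns rather than fails; choosing a target
  inside the feasible band is the caller's responsibility and the
  infeasibility checks catch targets outside it.
- Zero-store zones, zero-production zones, single-zone buffers and empty
  outbreak batches are all defined behaviour, tested explicitly.
- The intra-zonal lattice constant 0.427 is adopted as a fixed constant of
  the nearest-neighbour-on-a-lattice argument; the package does not
  re-derive it.
- Euclidean distances, not road distances; population-weighted centroids
  are not used. Both would refine the cost matrix if the data existed.
- Single-brand contamination only; reporting delay, under-reporting and
  case-confirmation noise are out of scope, as are upstream supply-chain
  layers beyond the brand abstraction and online food retail.
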