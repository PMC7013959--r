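# gravitrace

Widespread foodborne disease outbreaks are hard to trace because the last
link of the supply chain — the consumer — is usually modelled with a crude
assumption: people buy their groceries in the postal zone where they live.
Mobility surveys say otherwise; the mean home-to-supermarket trip in Germany
is 4.65 km, which at postal-zone resolution routes most grocery spending
*out* of the home zone. `gravitrace` is an R package for epidemiological
modellers and food-safety investigators that (i) models last-mile grocery
flows between zones with a calibrated gravity model and (ii) uses those
flows to infer which retail brand sourced an outbreak from the locations of
reported illnesses.

## The model

**Gravity stage.** Monetary flows between retailer zone *i* and consumer
zone *j* follow the doubly constrained entropy-maximising form

    F_ij = A_i O_i B_j D_j exp(-beta c_ij)

where `O_i` is zone *i*'s retail revenue (sum of per-store revenues, each a
brand's total split over its stores), `D_j` the consumption potential
(population share of total revenue), `c_ij` the centroid distance with an
intra-zonal diagonal (`0.427 / sqrt(store density)` via a lattice
nearest-neighbour argument, or the mean distance between random points in an
equal-area circle), and `beta` the deterrence parameter. Balancing factors
`A_i`, `B_j` come from Furness iteration (IPF); `beta` is calibrated by
Hyman's method so the flow-weighted mean trip distance `sum(F c) / sum(F)`
matches the survey mean.

**Traceback stage.** A three-layer network — brand → retailer zone →
consumer zone — carries transition probabilities from brand market shares
and the row-normalised gravity flows. In absorbing Markov chain canonical
form, absorption probabilities are `A = (I - P_Q)^{-1} P_R`, and the
posterior probability that brand *b* sourced the illness multiset θ is

    P(b | θ) ∝ P(b) * prod_{o in θ} A[b, o]

with a market-share prior `P(b) = rev_b / sum(rev)`. The estimator reports
the maximum-posterior brand and the competition rank of the true source.
A Monte Carlo simulator generates outbreaks with a prescribed number of
distinct contaminated zones, and the evaluation harness compares inference
on the gravity network ("A") against the shop-at-home baseline ("B").

## Worked example

```r
library(gravitrace)

reg <- generate_synthetic_region(n_zones = 49, n_brands = 10, seed = 7)
fit <- gravity_model(reg, target_mean_km = 4.65)
summary(fit)
#> Doubly constrained gravity model (exponential deterrence)
#>   zones: 49   beta: 0.3653 1/km
#>   mean trip distance: 4.653 km (target 4.65 km)
#>   Furness sweeps: 77 (max marginal error 9.00e-07)
#> Flow connectivity (mean over retailer zones):
#>   >  0.0% threshold:  49.00 supplied consumer zones
#>   >  5.0% threshold:   4.90 supplied consumer zones
#>   > 10.0% threshold:   2.57 supplied consumer zones
#>   intra-zonal consumption share: 25.4%
```

The calibration drives the modelled mean shopping distance to the 4.65 km
survey target; on this region a retailer zone meaningfully supplies about
5 consumer zones (at the 5% flow threshold) and only about a quarter of
revenue stays in the home zone — the reason the shop-at-home assumption
misleads traceback.

```r
shares <- brand_zone_shares(reg)
net_A  <- build_network_A(shares, predict(fit))   # gravity flows
net_B  <- build_network_B(shares)                 # shop-at-home baseline
prior  <- market_share_prior(reg)

res <- run_scenario(net_A, net_B, prior, n_unique = 20, n_outbreaks = 300,
                    n_ill = 500, illness_grid = c(2, 5, 10, 20, 30, 50),
                    seed = 303)
res$A
#> Scenario |theta| = 20 on network A (300 outbreaks)
#>   m accuracy mean_rank
#>   2    0.533      2.01
#>   5    0.703      1.47
#>  10    0.893      1.13
#>  20    0.963      1.05
#>  30    0.970      1.04
#>  50    0.983      1.02
res$B
#> Scenario |theta| = 20 on network B (300 outbreaks)
#>   m accuracy mean_rank
#>   2    0.290      1.51
#>   5    0.217      1.06
#>  10    0.180      1.00
#>  ...
#>  50    0.173      1.00
```

With gravity flows the estimator identifies the true brand in ~97% of
outbreaks by 30 reported illnesses; under the shop-at-home baseline it
plateaus below 20% because observations attach to the wrong retailer zones.
`run_experiment()` wraps the full pipeline over several spread scenarios,
`summarize_scenarios()` returns the long-format results table, and
`plot_scenario_curves()` draws the accuracy/rank curves. A thin command-line
front end lives at `inst/cli/gravitrace.R`
(`Rscript inst/cli/gravitrace.R evaluate --config cfg.yaml --seed 1 --out out/`).

## Package layout

- `R/region.R` — zones/brands/stores container, synthetic-region generator,
  revenue and consumption marginals, market shares
- `R/distances.R` — centroid distances, intra-zonal estimators, buffers
- `R/gravity.R` — Furness balancing, Hyman calibration, `gravity_model()`
  and its S3 methods, flow probabilities, connectivity statistics
- `R/network.R` — supply networks A/B, absorbing matrix, prior
- `R/outbreak.R` — Monte Carlo outbreak simulator
- `R/inference.R` — Bayesian brand-source posterior, estimate, rank
- `R/evaluation.R` — scenario runner and experiment harness
- `R/io.R` — CSV/JSON/YAML readers and writers
- `vignettes/gravity-traceback.Rmd` — methods and design choices
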