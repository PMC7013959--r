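# Independent oracles and hand-built fixtures, deliberately naive: loops and
# direct products, no shared code with the implementation under test.

# Plain iterative proportional fitting with explicit loops.
ipf_oracle <- function(K, O, D, sweeps = 10000L) {
  F <- K
  n <- nrow(K)
  for (s in seq_len(sweeps)) {
    for (i in seq_len(n)) {
      rs <- sum(F[i, ])
      F[i, ] <- if (rs > 0) F[i, ] * O[i] / rs else 0
    }
    for (j in seq_len(ncol(K))) {
      cs <- sum(F[, j])
      F[, j] <- if (cs > 0) F[, j] * D[j] / cs else 0
    }
  }
  F
}

# Exhaustive path enumeration for a two-layer (brand -> retailer -> consumer)
# network: direct absorption plus all one-intermediate paths.
twohop_oracle <- function(net) {
  n <- length(net$transient_ids)
  A <- net$P_R
  for (q in seq_len(n))
    for (c in seq_len(ncol(net$P_R)))
      A[q, c] <- net$P_R[q, c] +
        sum(net$P_Q[q, ] * net$P_R[, c])
  A
}

# Direct (non-log) posterior evaluation; safe only for short theta.
posterior_oracle <- function(absorb, theta, prior) {
  lik <- vapply(names(prior), function(b) {
    p <- 1
    for (o in theta) p <- p * absorb[b, o]
    p
  }, numeric(1))
  w <- prior * lik
  w / sum(w)
}

# Hand-built region: square of 4 zones on a 10 km grid, 2 brands with
# spatially disjoint store sets (brand D1 in the west pair, D2 in the east).
make_manual_region <- function() {
  zones <- data.frame(
    zone_id = c("W1", "W2", "E1", "E2"),
    x_km = c(0, 0, 10, 10), y_km = c(0, 10, 0, 10),
    area_km2 = rep(25, 4), population = c(100, 300, 200, 400))
  brands <- data.frame(brand_id = c("D1", "D2"),
                       total_revenue = c(1000, 500))
  stores <- data.frame(
    store_id = paste0("s", 1:4),
    brand_id = c("D1", "D1", "D2", "D2"),
    zone_id = c("W1", "W2", "E1", "E2"))
  region(zones, brands, stores)
}

# Small calibrated model reused across tests.
make_small_fit <- function(seed = 11, n_zones = 12, n_brands = 4) {
  reg <- generate_synthetic_region(n_zones, n_brands, seed = seed)
  list(region = reg, fit = gravity_model(reg, target_mean_km = 4.65))
}
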