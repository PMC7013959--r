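test_that("zero deterrence gives the independence solution", {
  O <- c(2, 2); D <- c(1, 3)
  costs <- matrix(c(1, 2, 2, 1), 2)
  bf <- furness_balance(O, D, costs, beta = 0)
  expect_equal(bf$F, matrix(c(0.5, 0.5, 1.5, 1.5), 2),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_true(bf$converged)
})

test_that("single-zone model returns its own marginal", {
  bf <- furness_balance(5, 5, matrix(0.9), beta = 1)
  expect_equal(as.numeric(bf$F), 5, tolerance = 1e-9)
})

test_that("furness matches a brute-force IPF oracle on random instances", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 4
    O <- runif(n, 1, 10)
    D <- runif(n, 1, 10); D <- D * sum(O) / sum(D)
    costs <- matrix(runif(n * n, 0.5, 8), n)
    costs <- (costs + t(costs)) / 2
    bf <- furness_balance(O, D, costs, beta = 0.5, tol = 1e-10)
    oracle <- ipf_oracle(exp(-0.5 * costs), O, D, sweeps = 10000L)
    expect_equal(bf$F, oracle, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("balanced flows satisfy both marginal constraints", {
  set.seed(42)
  n <- 10
  O <- runif(n, 1, 50)
  D <- runif(n, 1, 50); D <- D * sum(O) / sum(D)
  costs <- as.matrix(dist(cbind(runif(n, 0, 20), runif(n, 0, 20))))
  diag(costs) <- 0.5
  bf <- furness_balance(O, D, costs, beta = 0.4)
  expect_lt(max(abs(rowSums(bf$F) - O) / O), 1e-6)
  expect_lt(max(abs(colSums(bf$F) - D) / D), 1e-6)
  expect_true(all(bf$F > 0))
  # factor representation reproduces F under the averaging convention
  expect_equal(bf$F, (bf$A * O) %o% (bf$B * D) * exp(-0.4 * costs),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(mean(bf$B), 1, tolerance = 1e-12)
})

test_that("zero-production zones keep all-zero rows", {
  O <- c(0, 4); D <- c(2, 2)
  costs <- matrix(c(1, 2, 2, 1), 2)
  bf <- furness_balance(O, D, costs, beta = 0.3)
  expect_equal(unname(bf$F[1, ]), c(0, 0))
  expect_equal(sum(bf$F), 4, tolerance = 1e-6)
})

test_that("mismatched marginal totals are rejected", {
  expect_error(furness_balance(c(1, 1), c(3, 1), matrix(1, 2, 2), 0.1),
               "invalid-input")
  expect_error(furness_balance(c(1, 1), c(1, 1), matrix(Inf, 2, 2), 0.1),
               "finite")
})

test_that("mean flow distance is the flow-weighted cost average", {
  costs <- matrix(c(1, 3, 2, 4), 2)
  expect_equal(mean_flow_distance(matrix(1, 2, 2), costs), 2.5)
  Fc <- matrix(0, 2, 2); Fc[2, 1] <- 7
  expect_equal(mean_flow_distance(Fc, costs), 3)
  expect_error(mean_flow_distance(matrix(0, 2, 2), costs), "invalid-input")

  sf <- make_small_fit()
  m <- mean_flow_distance(sf$fit$flows, sf$fit$costs)
  expect_gte(m, min(sf$fit$costs))
  expect_lte(m, max(sf$fit$costs))
})

test_that("hyman recovers the closed-form beta on a symmetric 2-zone model", {
  # intra cost 1, inter cost 2, unit marginals: mean = (1+2e^-b)/(1+e^-b),
  # so target 1.25 km pins beta at log(3)
  costs <- matrix(c(1, 2, 2, 1), 2)
  bf <- hyman_calibrate(c(1, 1), c(1, 1), costs, target_mean = 1.25,
                        tol_km = 1e-6)
  expect_equal(bf$beta, log(3), tolerance = 1e-3)
  expect_equal(bf$mean_distance, 1.25, tolerance = 1e-6)
})

test_that("hyman stops immediately at an already-matching target", {
  costs <- matrix(c(1, 2, 2, 1), 2)
  bf0 <- furness_balance(c(1, 1), c(1, 1), costs, beta = 1 / 1.3)
  m0 <- mean_flow_distance(bf0$F, costs)
  bf <- hyman_calibrate(c(1, 1), c(1, 1), costs, target_mean = m0)
  expect_equal(bf$outer_iterations, 1L)
})

test_that("unreachable targets are reported as infeasible", {
  costs <- matrix(c(1, 2, 2, 1), 2)
  # above the no-deterrence mean of 1.5
  expect_error(hyman_calibrate(c(1, 1), c(1, 1), costs, target_mean = 1.7),
               "infeasible-target")
  # uniform costs: mean is flat in beta
  expect_error(hyman_calibrate(c(1, 1), c(1, 1), matrix(2, 2, 2),
                               target_mean = 1.5),
               "infeasible-target")
})

test_that("mean trip distance decreases strictly in beta", {
  set.seed(7)
  n <- 10
  O <- runif(n, 1, 20); D <- runif(n, 1, 20); D <- D * sum(O) / sum(D)
  costs <- as.matrix(dist(cbind(runif(n, 0, 30), runif(n, 0, 30))))
  diag(costs) <- 1
  betas <- seq(0.1, 2, by = 0.2)
  means <- vapply(betas, function(b)
    mean_flow_distance(furness_balance(O, D, costs, b)$F, costs), numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("flow probabilities are row-normalised with flagged zero rows", {
  F <- matrix(c(2, 3, 5, 0, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("x", "y", "z")))
  P <- flow_probabilities(F)
  expect_equal(unname(P["a", ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(P["b", ]), c(0, 0, 0))
  expect_equal(attr(P, "zero_rows"), "b")

  sf <- make_small_fit()
  P2 <- predict(sf$fit)
  expect_equal(unname(rowSums(P2)), rep(1, nrow(P2)), tolerance = 1e-12)
})

test_that("connectivity statistics count strict threshold exceedances", {
  P <- matrix(rep(c(0.6, 0.3, 0.1), 3), nrow = 3, byrow = TRUE)
  cs <- connectivity_stats(P, thresholds = c(0, 0.05, 0.10))
  expect_equal(cs$by_threshold$mean_supplied_zones, c(3, 3, 2))  # 0.1 !> 0.10
  expect_equal(cs$intrazonal_share, mean(c(0.6, 0.3, 0.1)))

  I <- diag(4)
  csI <- connectivity_stats(I, thresholds = c(0, 0.5, 0.99))
  expect_equal(csI$by_threshold$mean_supplied_zones, c(1, 1, 1))
  expect_equal(csI$intrazonal_share, 1)

  expect_error(connectivity_stats(P, thresholds = c(0, 1)),
               "invalid-argument")
})

test_that("gravity_model methods expose the fit coherently", {
  sf <- make_small_fit()
  fit <- sf$fit
  expect_s3_class(fit, "gravity_model")
  expect_named(coef(fit), "beta")
  expect_equal(fitted(fit), fit$flows)
  expect_lt(max(abs(residuals(fit, "production"))) / max(fit$O), 1e-6)
  expect_lt(max(abs(residuals(fit, "attraction"))) / max(fit$D), 1e-6)
  expect_equal(predict(fit, type = "flows"), fit$flows)
  expect_output(print(summary(fit)), "intra-zonal consumption share")
  # fixed beta skips the outer calibration
  fit2 <- gravity_model(sf$region, beta = fit$beta)
  expect_equal(fit2$flows, fit$flows, tolerance = 1e-8)
  expect_equal(fit2$outer_iterations, 0L)
})
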