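test_that("synthetic region generation is reproducible and seed-sensitive", {
  a <- generate_synthetic_region(49, 10, seed = 7)
  b <- generate_synthetic_region(49, 10, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a$zones), 49)
  expect_equal(nrow(a$brands), 10)

  c1 <- generate_synthetic_region(49, 10, seed = 1)
  c2 <- generate_synthetic_region(49, 10, seed = 2)
  expect_false(identical(c1$stores$zone_id, c2$stores$zone_id))
})

test_that("generated regions satisfy the structural contract", {
  reg <- generate_synthetic_region(20, 5, seed = 3, bbox_km = 25)
  expect_true(all(reg$zones$population > 0))
  expect_true(all(reg$zones$area_km2 > 0))
  expect_true(all(table(reg$stores$brand_id)[reg$brands$brand_id] >= 1))
  # areas partition the bounding box
  expect_lt(abs(sum(reg$zones$area_km2) - 25^2) / 25^2, 0.05)
  # equal revenue split within each brand
  for (b in reg$brands$brand_id) {
    rev <- reg$stores$revenue[reg$stores$brand_id == b]
    tot <- reg$brands$total_revenue[reg$brands$brand_id == b]
    expect_equal(rev, rep(tot / length(rev), length(rev)))
  }
})

test_that("tiny two-zone single-brand region conserves revenue", {
  reg <- generate_synthetic_region(2, 1, seed = 0)
  expect_equal(sum(reg$stores$revenue), reg$brands$total_revenue)
  expect_equal(sort(unique(reg$zones$zone_id)), c("Z01", "Z02"))
})

test_that("generator rejects degenerate arguments", {
  expect_error(generate_synthetic_region(1, 1, seed = 1), "invalid-argument")
  expect_error(generate_synthetic_region(5, 0, seed = 1), "invalid-argument")
  expect_error(generate_synthetic_region(5, 2, seed = 1, bbox_km = -1),
               "invalid-argument")
})

test_that("zone revenues follow the equal-split convention", {
  zones <- data.frame(zone_id = c("a", "b"), x_km = 0:1, y_km = 0,
                      area_km2 = 1, population = c(1, 1))
  brands <- data.frame(brand_id = "k", total_revenue = 100)
  stores <- data.frame(store_id = paste0("s", 1:4), brand_id = "k",
                       zone_id = c("a", "a", "b", "b"))
  reg <- region(zones, brands, stores)
  O <- zone_revenues(reg)
  expect_equal(unname(O["a"]), 50)  # 2 of 4 stores at revenue 25 each
  # zone with no stores
  zones2 <- rbind(zones, data.frame(zone_id = "c", x_km = 2, y_km = 0,
                                    area_km2 = 1, population = 1))
  O2 <- zone_revenues(region(zones2, brands, stores))
  expect_equal(unname(O2["c"]), 0)
})

test_that("revenue is conserved across marginals", {
  reg <- generate_synthetic_region(30, 10, seed = 5)
  O <- zone_revenues(reg)
  D <- consumption_potentials(reg)
  REV <- sum(reg$brands$total_revenue)
  expect_equal(sum(O), REV, tolerance = 1e-12)
  expect_equal(sum(D), REV, tolerance = 1e-12)
})

test_that("consumption potentials are population-proportional", {
  reg <- make_manual_region()  # pops 100,300,200,400; REV = 1500
  D <- consumption_potentials(reg)
  expect_equal(unname(D), c(100, 300, 200, 400) / 1000 * 1500)

  # equal populations split REV evenly
  reg$zones$population <- rep(10, 4)
  D2 <- consumption_potentials(reg)
  expect_equal(unname(D2), rep(1500 / 4, 4))

  reg$zones$population <- rep(0, 4)
  expect_error(consumption_potentials(reg), "invalid-input")
})

test_that("brand zone shares are row-stochastic revenue fractions", {
  zones <- data.frame(zone_id = c("A", "B"), x_km = 0:1, y_km = 0,
                      area_km2 = 1, population = 1)
  brands <- data.frame(brand_id = "k", total_revenue = 100)
  stores <- data.frame(store_id = c("s1", "s2"), brand_id = "k",
                       zone_id = c("A", "B"), revenue = c(30, 70))
  M <- brand_zone_shares(region(zones, brands, stores))
  expect_equal(unname(M["k", ]), c(0.3, 0.7))

  # single store => unit vector
  M1 <- brand_zone_shares(region(zones, brands, stores[1, ]))
  expect_equal(unname(M1["k", ]), c(1, 0))

  reg <- generate_synthetic_region(49, 10, seed = 4)
  S <- brand_zone_shares(reg)
  expect_equal(unname(rowSums(S)), rep(1, 10), tolerance = 1e-12)
  expect_true(all(S >= 0 & S <= 1))
})

test_that("region constructor enforces referential integrity", {
  zones <- data.frame(zone_id = "A", x_km = 0, y_km = 0, area_km2 = 1,
                      population = 1)
  brands <- data.frame(brand_id = "k", total_revenue = 1)
  stores <- data.frame(store_id = "s1", brand_id = "k", zone_id = "nope")
  expect_error(region(zones, brands, stores), "referential-integrity-error")
  expect_error(region(zones[0, ], brands, stores[0, ]), "schema-error")
  zones$area_km2 <- 0
  expect_error(region(zones, brands, stores[0, ]), "strictly positive")
})

test_that("store weight column overrides the equal split", {
  zones <- data.frame(zone_id = c("A", "B"), x_km = 0:1, y_km = 0,
                      area_km2 = 1, population = 1)
  brands <- data.frame(brand_id = "k", total_revenue = 100)
  stores <- data.frame(store_id = c("s1", "s2"), brand_id = "k",
                       zone_id = c("A", "B"), weight = c(3, 1))
  reg <- region(zones, brands, stores)
  expect_equal(reg$stores$revenue, c(75, 25))
})
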