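abs2 <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE,
               dimnames = list(c("b1", "b2"), c("z1", "z2")))

test_that("log-likelihood multiplies absorption over the multiset", {
  expect_equal(log_likelihood(abs2, "z1", "b2"), log(0.2))
  expect_equal(log_likelihood(abs2, c("z1", "z1"), "b1"), 2 * log(0.8))
  zero <- abs2; zero["b2", "z1"] <- 0
  expect_identical(log_likelihood(zero, c("z1", "z2"), "b2"), -Inf)
  expect_error(log_likelihood(abs2, "nowhere", "b1"), "invalid-input")
  expect_error(log_likelihood(abs2, "z1", "b9"), "not-found")
})

test_that("posterior follows Bayes' rule on hand-computable cases", {
  post <- posterior_over_brands(abs2, "z1", c(b1 = 0.5, b2 = 0.5))
  expect_equal(unname(post$probabilities), c(0.8, 0.2))

  # equal likelihoods: the prior passes through
  eq <- matrix(0.5, 2, 2, dimnames = dimnames(abs2))
  post2 <- posterior_over_brands(eq, c("z1", "z2"), c(b1 = 0.6, b2 = 0.4))
  expect_equal(unname(post2$probabilities), c(0.6, 0.4))
})

test_that("log-space evaluation matches the direct product oracle", {
  set.seed(21)
  for (rep in 1:5) {
    A <- matrix(runif(3 * 6, 0.01, 1), 3,
                dimnames = list(paste0("b", 1:3), paste0("z", 1:6)))
    A <- A / rowSums(A)
    prior <- runif(3); prior <- prior / sum(prior)
    names(prior) <- rownames(A)
    theta <- sample(colnames(A), 5, replace = TRUE)
    post <- posterior_over_brands(A, theta, prior)
    expect_equal(post$probabilities, posterior_oracle(A, theta, prior),
                 tolerance = 1e-12)
    expect_equal(sum(post$probabilities), 1, tolerance = 1e-12)
  }
})

test_that("long observation lists do not underflow", {
  post <- posterior_over_brands(abs2, rep(c("z1", "z2"), c(400, 100)),
                                c(b1 = 0.5, b2 = 0.5))
  expect_equal(sum(post$probabilities), 1, tolerance = 1e-12)
  expect_equal(post$estimate, "b1")
})

test_that("brands cut off from an observed zone get exactly zero posterior", {
  cut <- abs2; cut["b2", "z1"] <- 0; cut["b2", "z2"] <- 1
  post <- posterior_over_brands(cut, c("z1", "z2"), c(b1 = 0.5, b2 = 0.5))
  expect_identical(unname(post$probabilities["b2"]), 0)
  allzero <- matrix(0, 2, 2, dimnames = dimnames(abs2))
  expect_error(posterior_over_brands(allzero, "z1", c(b1 = 0.5, b2 = 0.5)),
               "no-feasible-source")
})

test_that("estimate and rank follow the documented tie conventions", {
  p3 <- structure(list(probabilities = c(a = 0.1, b = 0.7, c = 0.2),
                       log_likelihoods = NULL, estimate = "b",
                       rank_of = c(a = 3L, b = 1L, c = 2L)),
                  class = "posterior_result")
  expect_equal(estimate_source(p3), "b")
  expect_equal(rank_of_true(p3, "c"), 2L)
  expect_error(rank_of_true(p3, "zzz"), "not-found")

  tie <- posterior_over_brands(matrix(0.5, 2, 2, dimnames = dimnames(abs2)),
                               "z1", c(b1 = 0.5, b2 = 0.5))
  expect_equal(tie$estimate, "b1")  # lowest index wins ties
  expect_equal(unname(tie$rank_of), c(1L, 1L))  # competition ranking

  ten <- matrix(0.1, 10, 10,
                dimnames = list(paste0("b", 1:10), paste0("z", 1:10)))
  prior10 <- setNames(rep(0.1, 10), rownames(ten))
  tied10 <- posterior_over_brands(ten, "z3", prior10)
  expect_true(all(tied10$rank_of == 1L))
})

test_that("estimate always attains the posterior maximum", {
  set.seed(33)
  for (rep in 1:10) {
    A <- matrix(runif(4 * 5, 0, 1), 4,
                dimnames = list(paste0("b", 1:4), paste0("z", 1:5)))
    A <- A / rowSums(A)
    prior <- setNames(rep(0.25, 4), rownames(A))
    theta <- sample(colnames(A), 3, replace = TRUE)
    post <- posterior_over_brands(A, theta, prior)
    expect_equal(unname(post$probabilities[post$estimate]),
                 max(post$probabilities))
  }
})

test_that("a spatially unique brand is recovered as observations grow", {
  # brand u sells only where no other brand does; 200 observations from its
  # absorption row should concentrate the posterior on it
  A <- rbind(u = c(0.5, 0.5, 0, 0),
             v = c(0.1, 0.1, 0.4, 0.4),
             w = c(0.05, 0.15, 0.5, 0.3))
  colnames(A) <- paste0("z", 1:4)
  prior <- c(u = 1 / 3, v = 1 / 3, w = 1 / 3)
  set.seed(12)
  theta <- sample(colnames(A), 200, replace = TRUE, prob = A["u", ])
  post <- posterior_over_brands(A, theta, prior)
  expect_gt(post$probabilities["u"], 0.99)
})
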