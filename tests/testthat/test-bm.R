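# Brownian-motion ancestral reconstruction against closed-form GLS.

test_that("two equidistant tips average at the root", {
  tr <- parse_newick("(A:1,B:1);")
  rec <- bm_ancestral(tr, c(A = 2, B = 4))
  expect_equal(rec$root_estimate, 3)
  expect_gt(rec$node_estimates$sd[1], 0)
})

test_that("constant tip values give a degenerate, variance-free fit", {
  tr <- random_tree(6, seed = 3)
  rec <- bm_ancestral(tr, setNames(rep(7, 6), tr$tip.label))
  expect_equal(rec$sigma2, 0)
  expect_equal(rec$node_estimates$estimate, rep(7, nrow(rec$node_estimates)))
  expect_equal(rec$node_estimates$sd, rep(0, nrow(rec$node_estimates)))
})

test_that("a three-tip tree matches the hand GLS solution", {
  tr <- parse_newick("((A:1,B:2):1,C:3);")
  x <- c(A = 1, B = 5, C = 10)
  # hand-built tip covariance: C_AA=2, C_BB=3, C_CC=3, C_AB=1, others 0
  Cm <- matrix(c(2, 1, 0,
                 1, 3, 0,
                 0, 0, 3), 3, 3, byrow = TRUE)
  Ci <- solve(Cm)
  one <- rep(1, 3)
  mu <- as.numeric(t(one) %*% Ci %*% x[c("A", "B", "C")]) /
    as.numeric(t(one) %*% Ci %*% one)
  rec <- bm_ancestral(tr, x)
  expect_equal(rec$root_estimate, mu, tolerance = 1e-10)
  # internal node above A, B: covariance with A and B is 1
  cv <- c(1, 1, 0)
  resid <- x[c("A", "B", "C")] - mu
  est_hand <- mu + as.numeric(t(cv) %*% Ci %*% resid)
  inner <- rec$node_estimates$estimate[2]
  expect_equal(inner, est_hand, tolerance = 1e-10)
  # ML sigma2 divides by n
  s2_hand <- as.numeric(t(resid) %*% Ci %*% resid) / 3
  expect_equal(rec$sigma2, s2_hand, tolerance = 1e-12)
})

test_that("the root estimate lies inside the tip range", {
  for (seed in 1:5) {
    tr <- random_tree(10, seed = seed)
    x <- simulate_continuous_trait(tr, sigma2 = 4, root_value = 0,
                                   seed = seed + 40)
    rec <- bm_ancestral(tr, x)
    expect_gte(rec$root_estimate, min(x))
    expect_lte(rec$root_estimate, max(x))
  }
})

test_that("ancestral estimates agree with ape::ace", {
  tr <- simulate_tree(25, seed = 6)
  x <- simulate_continuous_trait(tr, sigma2 = 2, root_value = 10, seed = 8)
  rec <- bm_ancestral(tr, x)
  a <- ape::ace(x[tr$tip.label], tr, type = "continuous", method = "ML")
  expect_equal(unname(rec$node_estimates$estimate), unname(as.numeric(a$ace)),
               tolerance = 1e-4)
})

test_that("degenerate inputs are rejected", {
  tr <- parse_newick("(A:1,B:1);")
  expect_error(bm_ancestral(tr, c(A = 1)), "at least 2 tips")
  zero <- parse_newick("(A:0,B:0);")
  expect_error(bm_ancestral(zero, c(A = 1, B = 2)), "zero total depth")
})

test_that("the diffusion variance is recovered within a factor at 100 tips", {
  s2 <- vapply(1:20, function(s) {
    tr <- simulate_tree(100, seed = 700 + s)
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
    x <- simulate_continuous_trait(tr, sigma2 = 3, root_value = 0,
                                   seed = 800 + s)
    bm_ancestral(tr, x)$sigma2
  }, numeric(1))
  expect_gte(median(s2), 1.5)
  expect_lte(median(s2), 4.5)
})
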