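# Generators: determinism, degenerate limits, and distributional checks.

test_that("tree simulation is seeded and produces valid cherries", {
  tr2 <- simulate_tree(2, seed = 1)
  expect_equal(length(tr2$tip.label), 2)
  expect_true(all(tr2$edge.length > 0))
  a <- write_newick(simulate_tree(9, seed = 42))
  b <- write_newick(simulate_tree(9, seed = 42))
  c <- write_newick(simulate_tree(9, seed = 43))
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("codon simulation is seed-reproducible", {
  tr <- simulate_tree(6, seed = 2)
  a1 <- simulate_codon_alignment(tr, 40, seed = 5)
  a2 <- simulate_codon_alignment(tr, 40, seed = 5)
  a3 <- simulate_codon_alignment(tr, 40, seed = 6)
  expect_identical(a1$codons, a2$codons)
  expect_false(identical(a1$codons, a3$codons))
})

test_that("omega = 0 everywhere forbids amino-acid change", {
  tr <- simulate_tree(8, seed = 3)
  aln <- simulate_codon_alignment(tr, 60, kappa = 2,
                                  per_edge_omega = rep(0, nrow(tr$edge)),
                                  seed = 4)
  ct <- codon_table()
  aas <- apply(aln$codons, 2, function(col) unique(ct$aa[col]))
  expect_true(all(lengths(aas) == 1))
})

test_that("simulated codon frequencies approach the stationary distribution", {
  # near-zero branch lengths: tips are fresh draws from the root distribution
  tr <- simulate_tree(4, seed = 7)
  tr$edge.length <- tr$edge.length * 1e-8
  set.seed(8)
  freqs <- runif(61, 0.5, 2); freqs <- freqs / sum(freqs)
  aln <- simulate_codon_alignment(tr, 4000, kappa = 2, codon_freqs = freqs,
                                  seed = 9)
  emp <- tabulate(aln$codons[1, ], nbins = 61) / aln$n_sites
  expect_lt(max(abs(emp - freqs)), 0.03)
})

test_that("discrete trait simulation hits both degenerate limits", {
  tr <- simulate_tree(10, seed = 5)
  Q0 <- mk_generator(0, c("a", "b"), "ER")
  expect_true(all(simulate_discrete_trait(tr, Q0, "b", seed = 1) == "b"))
  Qbig <- mk_generator(500, c("a", "b"), "ER")
  many <- unlist(lapply(1:40, function(s) {
    simulate_discrete_trait(tr, Qbig, "a", seed = s)
  }))
  # stationary distribution of symmetric ER is uniform
  expect_equal(mean(many == "a"), 0.5, tolerance = 0.08)
  expect_identical(simulate_discrete_trait(tr, Qbig, "a", seed = 3),
                   simulate_discrete_trait(tr, Qbig, "a", seed = 3))
})

test_that("Brownian tip variance scales with depth and shared paths", {
  tr <- parse_newick("((A:1,B:1):2,C:3);")
  reps <- vapply(1:200, function(s) {
    simulate_continuous_trait(tr, sigma2 = 1, root_value = 0, seed = s)
  }, numeric(3))
  expect_equal(var(reps["A", ]), 3, tolerance = 0.5)
  expect_equal(var(reps["C", ]), 3, tolerance = 0.5)
  # sister tips share the root->ancestor path: cov = 2
  expect_equal(cov(reps["A", ], reps["B", ]), 2, tolerance = 0.5)
  expect_equal(cov(reps["A", ], reps["C", ]), 0, tolerance = 0.4)
  expect_true(all(simulate_continuous_trait(tr, 0, 5, seed = 1) == 5))
})

test_that("a one-ratio fit recovers the simulated dN/dS", {
  omegas <- vapply(1:10, function(s) {
    tr <- simulate_tree(10, seed = s)
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
    aln <- simulate_codon_alignment(tr, 300, kappa = 2,
                                    classes = data.frame(omega = 0.2,
                                                         weight = 1),
                                    seed = s + 30)
    fit <- fit_branch_model(aln, tr, "one_ratio", seed = 1, n_starts = 1)
    fit$estimates$omega
  }, numeric(1))
  expect_gte(median(omegas), 0.1)
  expect_lte(median(omegas), 0.35)
})
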