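# Mk discrete-character machinery against enumeration oracles and ape.

test_that("Mk generators have the declared structure", {
  Qe <- mk_generator(0.5, c("a", "b", "c"), "ER")
  expect_equal(unname(Qe[1, 2]), 0.5)
  expect_equal(rowSums(Qe), rep(0, 3), ignore_attr = TRUE)
  Qs <- mk_generator(c(1, 2, 3), c("a", "b", "c"), "SYM")
  expect_equal(Qs - diag(diag(Qs)), t(Qs - diag(diag(Qs))))
  Qa <- mk_generator(1:6, c("a", "b", "c"), "ARD")
  expect_equal(unname(Qa[1, 2]), 1)
  expect_equal(unname(Qa[3, 2]), 6)
  expect_error(mk_generator(c(1, 2), c("a", "b", "c"), "ER"))
})

test_that("Mk likelihood and marginals equal brute-force enumeration", {
  for (seed in 1:3) {
    set.seed(100 + seed)
    tr <- random_tree(4, seed = seed)
    states <- c("a", "b")
    Q <- mk_generator(exp(runif(2, -1, 1)), states, "ARD")
    tips <- setNames(sample(c(states, NA), 4, replace = TRUE,
                            prob = c(0.4, 0.4, 0.2)), tr$tip.label)
    if (all(is.na(tips))) next
    pr <- opsinevo:::mk_pruning(tr, tips, Q)
    Ps <- lapply(seq_len(nrow(tr$edge)), function(e) {
      opsinevo:::mat_exp(Q * tr$edge.length[e])
    })
    tip_idx <- match(tips[tr$tip.label], states)
    expected <- log(enum_site_lik(tr, list(Ps), 1, tip_idx, rep(0.5, 2)))
    expect_equal(pr$loglik, expected, tolerance = 1e-8)

    fit <- structure(list(scheme = "ARD", states = states,
                          Q = Q, lnL = pr$loglik, np = 2, converged = TRUE,
                          tree = tr, tip_states = tips, seed = 1),
                     class = "mk_fit")
    rec <- marginal_ancestral_states(fit)
    for (i in seq_len(nrow(rec$node_probs))) {
      node <- rec$node_probs$node[i]
      expected_m <- enum_marginal(tr, Ps, tip_idx, rep(0.5, 2), node)
      expect_equal(unname(as.numeric(rec$node_probs[i, states])), expected_m,
                   tolerance = 1e-8)
    }
  }
})

test_that("a symmetric two-tip tree gives a half/half root under ER", {
  tr <- parse_newick("(A:0.4,B:0.4);")
  fit <- fit_mk(tr, c(A = "x", B = "y"), "ER", seed = 1, n_starts = 1)
  rec <- marginal_ancestral_states(fit)
  expect_equal(as.numeric(rec$node_probs[1, c("x", "y")]), c(0.5, 0.5),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a uniform character with a declared state set degenerates cleanly", {
  tr <- random_tree(5, seed = 2)
  tips <- setNames(rep("A", 5), tr$tip.label)
  expect_error(fit_mk(tr, tips, "ER"), "fewer than 2 observed states")
  fit <- fit_mk(tr, tips, "ER", states = c("A", "B"), seed = 1, n_starts = 1)
  rec <- marginal_ancestral_states(fit)
  expect_true(all(rec$node_probs$A > 0.999))
})

test_that("state-label permutation permutes the reconstruction", {
  tr <- random_tree(6, seed = 8)
  tips <- setNames(c("n", "d", "n", "n", "d", "n"), tr$tip.label)
  f1 <- fit_mk(tr, tips, "ARD", seed = 1, n_starts = 1)
  r1 <- marginal_ancestral_states(f1)
  swap <- c(n = "d", d = "n")
  f2 <- fit_mk(tr, setNames(swap[tips], names(tips)), "ARD", seed = 1,
               n_starts = 1)
  r2 <- marginal_ancestral_states(f2)
  expect_equal(unname(r1$node_probs$n), unname(r2$node_probs$d),
               tolerance = 1e-4)
})

test_that("ER fits agree with ape::ace up to the root-prior convention", {
  tr <- simulate_tree(40, seed = 11)
  td <- simulate_discrete_trait(tr, mk_generator(0.6, c("a", "b", "c"), "ER"),
                                "a", seed = 3)
  f <- fit_mk(tr, td, "ER", seed = 1, n_starts = 2)
  a <- ape::ace(factor(td[tr$tip.label]), tr, type = "discrete", model = "ER")
  expect_equal(unname(f$rates), unname(a$rates), tolerance = 1e-4)
  # ace's loglik omits the flat root prior factor log(1/k)
  expect_equal(f$lnL + log(3), a$loglik, tolerance = 1e-4)
})

test_that("scheme comparison defaults to the parameter-count df", {
  tr <- simulate_tree(30, seed = 4)
  td <- simulate_discrete_trait(tr, mk_generator(0.8, c("a", "b", "c"), "ER"),
                                "a", seed = 5)
  fs <- fit_mk(tr, td, "SYM", seed = 1, n_starts = 1)
  fa <- fit_mk(tr, td, "ARD", seed = 1, n_starts = 1)
  cmp <- compare_mk_schemes(fs, fa)
  expect_equal(cmp$df, 3) # k = 3: 6 - 3 rate parameters
  cmp1 <- compare_mk_schemes(fs, fa, df_override = 1)
  expect_equal(cmp1$df, 1)
  # identical fits give a null test
  cmp0 <- compare_mk_schemes(fs, fs)
  expect_equal(cmp0$statistic, 0)
  expect_equal(cmp0$p_value, 1)
})

test_that("ER rates are recovered within a factor at 100 tips", {
  rates <- vapply(1:20, function(s) {
    tr <- simulate_tree(100, seed = 300 + s)
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
    td <- simulate_discrete_trait(tr, mk_generator(0.5, c("a", "b"), "ER"),
                                  "a", seed = 400 + s)
    if (length(unique(td)) < 2) return(NA_real_)
    fit_mk(tr, td, "ER", seed = 1, n_starts = 1)$rates
  }, numeric(1))
  expect_gte(median(rates, na.rm = TRUE), 0.25)
  expect_lte(median(rates, na.rm = TRUE), 0.75)
})

test_that("marginal reconstruction beats the flat prior at the root", {
  hits <- vapply(1:30, function(s) {
    tr <- simulate_tree(50, seed = 500 + s)
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
    root_state <- c("a", "b")[1 + s %% 2]
    td <- simulate_discrete_trait(tr, mk_generator(0.6, c("a", "b"), "ER"),
                                  root_state, seed = 600 + s)
    if (length(unique(td)) < 2) return(NA_real_)
    fit <- fit_mk(tr, td, "ER", seed = 1, n_starts = 1)
    rec <- marginal_ancestral_states(fit)
    rec$node_probs[1, root_state]
  }, numeric(1))
  expect_gt(mean(hits, na.rm = TRUE), 0.5)
})
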