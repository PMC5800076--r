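# The GY94-style rate matrix and its building blocks, checked against a
# hand-applied rule table for one parameter set.

test_that("rate matrix entries follow the substitution rule table", {
  ct <- codon_table()
  set.seed(4)
  freqs <- runif(61, 0.5, 2)
  freqs <- freqs / sum(freqs)
  names(freqs) <- ct$codon
  kappa <- 3.1; omega <- 0.4
  Q <- codon_rate_matrix(kappa, omega, freqs)
  sc <- attr(Q, "rate") # unscaled expected rate; Q was divided by it
  q <- function(a, b) Q[a, b] * sc
  # AAA->AAG: synonymous (K->K) transition => kappa * pi_AAG
  expect_equal(q("AAA", "AAG"), kappa * freqs["AAG"], ignore_attr = TRUE)
  # AAA->AAT: nonsynonymous (K->N) transversion => omega * pi_AAT
  expect_equal(q("AAA", "AAT"), omega * freqs["AAT"], ignore_attr = TRUE)
  # ratio form quoted as the hand rule
  expect_equal(q("AAA", "AAG") / q("AAA", "AAT"),
               kappa * freqs[["AAG"]] / (omega * freqs[["AAT"]]))
  # AAA->AGA: nonsynonymous (K->R) transition => omega * kappa * pi
  expect_equal(q("AAA", "AGA"), omega * kappa * freqs["AGA"],
               ignore_attr = TRUE)
  # multi-nucleotide changes are forbidden
  expect_equal(q("AAA", "ACC"), 0)
  expect_equal(q("AAA", "CCC"), 0)
  # rows sum to zero
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
})

test_that("kappa = omega = 1 with uniform frequencies gives equal single-step rates", {
  Q <- codon_rate_matrix(1, 1, rep(1 / 61, 61))
  off <- Q[row(Q) != col(Q)]
  pos <- off[off > 0]
  expect_true(length(unique(round(pos, 15))) == 1)
})

test_that("the generator is reversible and unit-scaled", {
  for (seed in 1:3) {
    set.seed(seed)
    freqs <- runif(61, 0.2, 3); freqs <- freqs / sum(freqs)
    kappa <- exp(runif(1, 0, 2)); omega <- runif(1, 0, 3)
    Q <- codon_rate_matrix(kappa, omega, freqs)
    # detailed balance pi_i q_ij = pi_j q_ji
    flux <- freqs * Q
    expect_equal(max(abs(flux - t(flux))), 0, tolerance = 1e-14)
    # one expected substitution per unit time at this omega
    expect_equal(-sum(freqs * diag(Q)), 1, tolerance = 1e-12)
  }
})

test_that("non-normalized frequencies are rejected", {
  expect_error(codon_rate_matrix(2, 1, rep(0.02, 61)), "sum to 1")
})

test_that("transition probabilities behave like a semigroup with the right limits", {
  set.seed(9)
  freqs <- runif(61, 0.5, 2); freqs <- freqs / sum(freqs)
  Q <- codon_rate_matrix(2, 0.5, freqs)
  expect_equal(transition_probabilities(Q, 0), diag(61), tolerance = 1e-12,
               ignore_attr = TRUE)
  P <- transition_probabilities(Q, 0.7)
  expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-10)
  expect_true(min(P) >= 0)
  # ergodic limit: rows converge to the stationary frequencies
  Pinf <- transition_probabilities(Q, 1e3)
  expect_equal(max(abs(sweep(Pinf, 2, freqs))), 0, tolerance = 1e-8)
  # P(2t) = P(t) P(t)
  expect_equal(transition_probabilities(Q, 1.4), P %*% P, tolerance = 1e-8)
})

test_that("beta discretization uses equal-probability bin means", {
  d <- discretize_beta(1, 1, 2)
  expect_equal(d$omega, c(0.25, 0.75))
  expect_equal(d$weight, c(0.5, 0.5))
  d1 <- discretize_beta(2.2, 3.7, 1)
  expect_equal(d1$omega, 2.2 / (2.2 + 3.7), tolerance = 1e-9)
  d10 <- discretize_beta(0.5, 1.5, 10)
  expect_equal(sum(d10$omega * d10$weight), 0.5 / 2, tolerance = 1e-6)
  expect_true(all(diff(d10$omega) > 0) && all(d10$omega > 0 & d10$omega < 1))
})
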