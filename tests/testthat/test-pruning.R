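# Pruning likelihood against exhaustive enumeration over internal states.

make_class_Ps <- function(tree, kappa, freqs, classes, rate_mult = 1) {
  scale <- codon_mixture_scale(kappa, classes$omega, classes$weight, freqs)
  lapply(classes$omega, function(om) {
    Q <- codon_rate_matrix(kappa, om, freqs, scale_rate = scale)
    lapply(seq_len(nrow(tree$edge)), function(e) {
      transition_probabilities(Q, tree$edge.length[e] * rate_mult)
    })
  })
}

test_that("a single tip's site likelihood is its codon frequency", {
  tr <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                       edge.length = 0.5, Nnode = 1L, tip.label = "A"),
                  class = "phylo")
  aln <- codon_alignment(matrix(7L, 1, 1, dimnames = list("A", NULL)))
  set.seed(2)
  freqs <- runif(61, 0.5, 2); freqs <- freqs / sum(freqs)
  ll <- pruning_loglik(tr, aln, kappa = 2, codon_freqs = freqs)
  expect_equal(as.numeric(ll), log(freqs[7]), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("pruning equals brute-force enumeration on small instances", {
  set.seed(31)
  freqs <- runif(61, 0.3, 2); freqs <- freqs / sum(freqs)
  cases <- list(
    list(newick = "(A:0.4,B:0.9);", classes = data.frame(omega = 1, weight = 1)),
    list(newick = "((A:0.3,B:0.5):0.2,C:0.7);",
         classes = data.frame(omega = c(0.2, 2.5), weight = c(0.7, 0.3))),
    list(newick = "(A:0.2,B:0.4,C:0.6);", # polytomy at the root
         classes = data.frame(omega = c(0.05, 1), weight = c(0.5, 0.5))),
    list(newick = "((A:0.3,B:0.5):0.2,(C:0.4,D:0.1):0.6);",
         classes = data.frame(omega = c(0.3, 4), weight = c(0.9, 0.1))),
    list(newick = "(((A:0.2,B:0.3):0.2,C:0.4):0.3,D:0.8);", # caterpillar
         classes = data.frame(omega = 0.6, weight = 1))
  )
  for (case in cases) {
    tr <- parse_newick(case$newick)
    ntip <- length(tr$tip.label)
    aln <- random_codon_aln(tr$tip.label, 3, seed = ntip, p_missing = 0.2)
    kappa <- 2.3; rate_mult <- 1.3
    ll <- pruning_loglik(tr, aln, kappa, freqs, classes = case$classes,
                         rate_mult = rate_mult)
    Ps <- make_class_Ps(tr, kappa, freqs, case$classes, rate_mult)
    for (s in seq_len(aln$n_sites)) {
      expected <- log(enum_site_lik(tr, Ps, case$classes$weight,
                                    aln$codons[tr$tip.label, s], freqs))
      expect_equal(as.numeric(ll[s]), expected, tolerance = 1e-8)
    }
  }
})

test_that("fully missing columns contribute zero log-likelihood", {
  tr <- parse_newick("((A:0.3,B:0.5):0.2,C:0.7);")
  m <- matrix(NA_integer_, 3, 2, dimnames = list(c("A", "B", "C"), NULL))
  m[, 1] <- c(5L, 5L, 9L)
  aln <- codon_alignment(m)
  ll <- pruning_loglik(tr, aln, 2, rep(1 / 61, 61))
  expect_equal(as.numeric(ll[2]), 0, tolerance = 1e-10)
})

test_that("halving the rate while doubling branch lengths leaves lnL unchanged", {
  tr <- random_tree(6, seed = 12)
  aln <- random_codon_aln(tr$tip.label, 10, seed = 5)
  set.seed(6)
  freqs <- runif(61, 0.5, 2); freqs <- freqs / sum(freqs)
  classes <- data.frame(omega = c(0.1, 1.2), weight = c(0.6, 0.4))
  ll1 <- pruning_loglik(tr, aln, 2, freqs, classes, rate_mult = 1)
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 2
  ll2 <- pruning_loglik(tr2, aln, 2, freqs, classes, rate_mult = 0.5)
  expect_equal(attr(ll1, "total"), attr(ll2, "total"), tolerance = 1e-8)
})

test_that("per-branch omegas reproduce enumeration too", {
  tr <- parse_newick("((A:0.3,B:0.5):0.2,C:0.7);")
  aln <- random_codon_aln(tr$tip.label, 2, seed = 8, p_missing = 0)
  set.seed(10)
  freqs <- runif(61, 0.5, 2); freqs <- freqs / sum(freqs)
  om <- c(0.1, 3, 0.5, 1.2)
  ll <- pruning_loglik(tr, aln, 2, freqs, per_edge_omega = om)
  Ps <- list(lapply(seq_len(nrow(tr$edge)), function(e) {
    transition_probabilities(codon_rate_matrix(2, om[e], freqs),
                             tr$edge.length[e])
  }))
  for (s in 1:2) {
    expected <- log(enum_site_lik(tr, Ps, 1, aln$codons[tr$tip.label, s],
                                  freqs))
    expect_equal(as.numeric(ll[s]), expected, tolerance = 1e-8)
  }
})
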