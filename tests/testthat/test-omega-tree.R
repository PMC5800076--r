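# Omega-tree construction, linearization and outlier standardization.

test_that("outlier branches are recalculated once as dN / median(dS)", {
  tr <- parse_newick("((A:1,B:1):1,C:1);")
  pb <- data.frame(edge = 1:4,
                   omega = c(0.1, 0.2, 50, 0.3),
                   dN = c(0.001, 0.002, 0.3, 0.003),
                   dS = c(0.01, 0.02, 1e-6, 0.01))
  ot <- build_omega_tree(tr, pb)
  pv <- attr(ot, "provenance")
  # median dS over positive values {0.01, 0.02, 1e-6, 0.01} = 0.01
  expect_equal(ot$edge.length[3], 0.3 / 0.01)
  expect_equal(pv$flag, c("direct", "direct", "recalculated", "direct"))
  # one pass: 30 still exceeds 10 but is not recalculated again
  expect_equal(sum(ot$edge.length > 10), 1)
  # original estimates preserved
  expect_equal(pv$omega_original[3], 50)
})

test_that("boundary and degenerate outlier cases", {
  tr <- parse_newick("(A:1,B:1);")
  pb <- data.frame(edge = 1:2, omega = c(10, 0.5), dN = c(0.1, 0.05),
                   dS = c(0.01, 0.1))
  ot <- build_omega_tree(tr, pb)
  # omega exactly 10: strict inequality, untouched
  expect_equal(ot$edge.length, c(10, 0.5))
  expect_true(all(attr(ot, "provenance")$flag == "direct"))
  pb0 <- data.frame(edge = 1:2, omega = c(20, 0.5), dN = c(0.1, 0.05),
                    dS = c(0, 0))
  expect_error(build_omega_tree(tr, pb0), "median dS undefined")
  # recalculation never increases the number of above-cutoff branches
  pb2 <- data.frame(edge = 1:2, omega = c(30, 2), dN = c(0.5, 0.1),
                    dS = c(1e-5, 0.2))
  ot2 <- build_omega_tree(tr, pb2)
  expect_lte(sum(ot2$edge.length > 10), sum(pb2$omega > 10))
})

test_that("omega-lineages are root-to-tip sums", {
  tr <- parse_newick("(A:0.3,B:0.7);")
  lin <- omega_lineages(tr)
  expect_equal(lin$raw[match(c("A", "B"), lin$tip)], c(0.3, 0.7))
  chain <- parse_newick("((A:0.3,B:0.4):0.2,C:0.1);")
  lin2 <- omega_lineages(chain)
  expect_equal(lin2$raw[lin2$tip == "A"], 0.5)
  expect_equal(lin2$raw[lin2$tip == "B"], 0.6)
  # oracle: explicit path sums on random 30-tip trees
  tr3 <- random_tree(30, seed = 5)
  lin3 <- omega_lineages(tr3)
  for (tip in tr3$tip.label[c(1, 12, 30)]) {
    root_tip <- path_distance_to_root(tr3, tip)
    expect_equal(lin3$raw[lin3$tip == tip], root_tip, tolerance = 1e-12)
  }
})

test_that("median/IQR standardization matches the stated convention", {
  z <- standardize_scores(1:5)
  expect_equal(z, c(-1, -0.5, 0, 0.5, 1))
  set.seed(3)
  x <- rexp(20)
  expect_equal(median(standardize_scores(x)), 0)
  expect_error(standardize_scores(rep(2, 5)), "IQR is zero")
  # idempotent: standardized scores have median 0, IQR 1
  expect_equal(standardize_scores(standardize_scores(x)),
               standardize_scores(x), tolerance = 1e-12)
})

test_that("outlier flags behave under thresholding and location shifts", {
  lin <- data.frame(tip = c("a", "b", "c"), raw = c(0, 0.2, 2.1))
  fl <- flag_outliers(lin, threshold = 1.5)
  expect_equal(fl$tip[fl$outlier], "c")
  expect_equal(fl$rank, 1:3)
  fl_inf <- flag_outliers(lin, threshold = 1e12)
  expect_equal(sum(fl_inf$outlier), 0)
  # location invariance: adding a constant to all raw scores changes nothing
  lin2 <- transform(lin, raw = raw + 100)
  fl2 <- flag_outliers(lin2, threshold = 1.5)
  expect_equal(fl2$outlier, fl$outlier)
  expect_equal(fl2$standardized, fl$standardized, tolerance = 1e-12)
})
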