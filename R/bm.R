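# Brownian-motion ancestral reconstruction of continuous traits on trees
# whose branch values provide the evolutionary distance (here: omega-trees,
# inheriting the convention of reconstructing eye-design variables on
# dN/dS branch lengths).

# shared root-to-node path length between node j and every tip
node_tip_shared_depth <- function(tree, paths, node, tips) {
  el <- attr(paths, "edge.length")
  pj <- paths[[node]]
  vapply(tips, function(tp) sum(el[intersect(pj, paths[[tp]])]), numeric(1))
}

#' Brownian-motion ancestral estimates
#'
#' Maximum-likelihood ancestral reconstruction of a continuous trait under
#' Brownian motion: the root value is the generalized-least-squares mean over
#' the tips, internal-node estimates are the conditional (GLS) expectations
#' given the tip values, and their standard deviations combine the
#' conditional variance with the uncertainty of the root mean. The diffusion
#' variance `sigma2` is estimated by maximum likelihood (divide-by-n).
#'
#' @param tree Rooted `phylo` with non-negative branch values; total depth
#'   must be positive.
#' @param tip_values Named numeric vector (names = tip labels); at least two
#'   tips must have values. Tips without values are dropped.
#' @return An `ancestral_recon` (type `"continuous"`): list with
#'   `node_estimates` (data.frame: `node`, `estimate`, `sd`), `sigma2`,
#'   `root_estimate` and `lnL`.
#' @export
bm_ancestral <- function(tree, tip_values) {
  validate_tree(tree)
  vals <- tip_values[!is.na(tip_values)]
  if (length(vals) < 2) stop("need at least 2 tips with trait values")
  keep <- intersect(tree$tip.label, names(vals))
  if (length(keep) < 2) stop("tip_values must be named with tip labels")
  if (length(keep) < length(tree$tip.label)) {
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, keep))
  }
  x <- vals[tree$tip.label]
  n <- length(x)
  ntip <- n
  nnode <- ntip + tree$Nnode
  paths <- node_paths(tree)
  depth <- node_depths(tree)
  if (max(depth) <= 0) stop("tree has zero total depth")

  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    C[i, ] <- node_tip_shared_depth(tree, paths, i, seq_len(n))
  }
  # guard: tips at zero distance from the root make C singular
  Ci <- tryCatch(solve(C), error = function(e) {
    solve(C + diag(1e-10 * max(depth), n))
  })
  one <- rep(1, n)
  denom <- as.numeric(t(one) %*% Ci %*% one)
  mu <- as.numeric(t(one) %*% Ci %*% x) / denom
  resid <- x - mu
  sigma2 <- as.numeric(t(resid) %*% Ci %*% resid) / n
  lnL <- if (sigma2 > 0) {
    -0.5 * (n * log(2 * pi * sigma2) + determinant(C)$modulus[1] + n)
  } else NA_real_ # degenerate: constant tip values

  internal <- (ntip + 1):nnode
  est <- numeric(length(internal))
  sdv <- numeric(length(internal))
  for (idx in seq_along(internal)) {
    v <- internal[idx]
    cv <- node_tip_shared_depth(tree, paths, v, seq_len(n))
    w <- Ci %*% cv
    est[idx] <- mu + sum(w * resid)
    cond_var <- depth[v] - sum(cv * w)
    mean_var <- (1 - sum(w)) ^ 2 / denom
    sdv[idx] <- sqrt(pmax(0, sigma2 * (cond_var + mean_var)))
  }
  node_estimates <- data.frame(node = internal, estimate = est, sd = sdv)
  structure(list(type = "continuous", node_estimates = node_estimates,
                 sigma2 = sigma2, root_estimate = est[1],
                 lnL = lnL, tree = tree),
            class = "ancestral_recon")
}

#' Moran's I phylogenetic autocorrelation test
#'
#' Tests a tip trait for phylogenetic autocorrelation given a tip-by-tip
#' proximity weight matrix, using the standard double-sum statistic
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with the null expectation `E[I] = -1/(n-1)`, the variance under the
#' randomization assumption (the Cliff-Ord moments involving the sample
#' kurtosis), and a two-sided normal-approximation p-value.
#' Weights are used exactly as supplied (no row normalization); pass
#' `row_normalize = TRUE` to reproduce implementations that rescale each row
#' to sum to one.
#'
#' @param values Named numeric vector of tip values (n >= 3, non-constant).
#' @param weights Square weight matrix with zero diagonal, rows/columns in
#'   the same order as `values`.
#' @param row_normalize Rescale each weight row to sum to one before use.
#' @return A list with `observed`, `expected`, `variance` and `p_value`.
#' @export
morans_i <- function(values, weights, row_normalize = FALSE) {
  n <- length(values)
  stopifnot(n >= 3, is.matrix(weights), nrow(weights) == n, ncol(weights) == n)
  if (any(diag(weights) != 0)) stop("weight matrix must have a zero diagonal")
  if (var(values) == 0) stop("values are constant; Moran's I is undefined")
  w <- weights
  if (row_normalize) w <- w / rowSums(w)
  x <- as.numeric(values) - mean(values)
  s0 <- sum(w)
  obs <- (n / s0) * sum(w * outer(x, x)) / sum(x ^ 2)
  expd <- -1 / (n - 1)
  s1 <- sum((w + t(w)) ^ 2) / 2
  s2 <- sum((rowSums(w) + colSums(w)) ^ 2)
  kurt <- (sum(x ^ 4) / n) / (sum(x ^ 2) / n) ^ 2
  vr <- (n * ((n ^ 2 - 3 * n + 3) * s1 - n * s2 + 3 * s0 ^ 2) -
           kurt * (n * (n - 1) * s1 - 2 * n * s2 + 6 * s0 ^ 2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0 ^ 2) - 1 / (n - 1) ^ 2
  p <- 2 * stats::pnorm(abs(obs - expd) / sqrt(vr), lower.tail = FALSE)
  list(observed = obs, expected = expd, variance = vr, p_value = min(1, p))
}

#' Inverse-distance Moran weights from a tree
#'
#' Builds the proximity matrix `w_ij = 1 / d_ij` from the patristic distances
#' of a tree (here typically an omega-tree), with zero diagonal and no row
#' normalization. Zero off-diagonal distances are an error.
#'
#' @param tree A valid `phylo`.
#' @return A tip-by-tip weight matrix.
#' @export
moran_weights <- function(tree) {
  d <- patristic_distances(tree)
  off <- d[upper.tri(d)]
  if (any(off == 0)) stop("zero patristic distance between distinct tips")
  w <- 1 / d
  diag(w) <- 0
  w
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum (Mann-Whitney) test: the exact null distribution is
#' enumerated when the combined sample size is at most 20 and there are no
#' ties; otherwise the normal approximation with continuity and tie
#' correction is used. Delegates to `stats::wilcox.test`.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return A list with `statistic` (the Mann-Whitney U of `group_a`),
#'   `p_value` and `method` (`"exact"` or `"normal_approx"`).
#' @export
wilcoxon_ranksum <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  n <- length(group_a) + length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- n <= 20 && !ties
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b, alternative = "two.sided", exact = exact,
                correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1 # degenerate: no rank variation under the null
  list(statistic = unname(wt$statistic), p_value = p,
       method = if (exact) "exact" else "normal_approx")
}
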