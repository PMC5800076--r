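# Independent oracles used across the suite. These deliberately avoid the
# package's pruning code paths: likelihoods are computed by exhaustive
# enumeration over internal-node states, distances by explicit path sums.

# exhaustive-state-enumeration likelihood for one site under a state mixture.
# Ps_per_class: list over classes of lists (per tree edge) of transition
# matrices; tip_state: integer per tip (NA = missing); prior: root frequencies
enum_site_lik <- function(tree, Ps_per_class, weights, tip_state, prior) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  internals <- (ntip + 1):nnode
  k <- length(prior)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  mix <- 0
  for (cl in seq_along(weights)) {
    Ps <- Ps_per_class[[cl]]
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      st <- integer(nnode)
      st[internals] <- grid[g, ]
      st[seq_len(ntip)] <- tip_state
      pr <- prior[st[root]]
      for (e in seq_len(nrow(tree$edge))) {
        ch <- tree$edge[e, 2]
        if (ch <= ntip && is.na(tip_state[ch])) next
        pr <- pr * Ps[[e]][st[tree$edge[e, 1]], st[ch]]
      }
      tot <- tot + pr
    }
    mix <- mix + weights[cl] * tot
  }
  mix
}

# enumeration-based marginal state probabilities at one internal node
enum_marginal <- function(tree, Ps, tip_state, prior, node) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  internals <- (ntip + 1):nnode
  k <- length(prior)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  marg <- numeric(k)
  for (g in seq_len(nrow(grid))) {
    st <- integer(nnode)
    st[internals] <- grid[g, ]
    st[seq_len(ntip)] <- tip_state
    pr <- prior[st[root]]
    for (e in seq_len(nrow(tree$edge))) {
      ch <- tree$edge[e, 2]
      if (ch <= ntip && is.na(tip_state[ch])) next
      pr <- pr * Ps[[e]][st[tree$edge[e, 1]], st[ch]]
    }
    marg[st[node]] <- marg[st[node]] + pr
  }
  marg / sum(marg)
}

# patristic distance between two tips by explicit root-to-tip path sums
path_distance <- function(tree, tip_a, tip_b) {
  to_root <- function(node) {
    path <- c()
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (!length(e)) break
      path <- c(path, e)
      node <- tree$edge[e, 1]
    }
    path
  }
  pa <- to_root(match(tip_a, tree$tip.label))
  pb <- to_root(match(tip_b, tree$tip.label))
  shared <- intersect(pa, pb)
  sum(tree$edge.length[setdiff(pa, shared)]) +
    sum(tree$edge.length[setdiff(pb, shared)])
}

# exact two-sided rank-sum p-value by enumeration of all group assignments
enum_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  r <- rank(pooled)
  obs <- sum(r[seq_along(a)])
  combos <- utils::combn(n, length(a))
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- length(a) * (n + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# root-to-tip path sum by explicit edge walking
path_distance_to_root <- function(tree, tip) {
  node <- match(tip, tree$tip.label)
  total <- 0
  repeat {
    e <- which(tree$edge[, 2] == node)
    if (!length(e)) break
    total <- total + tree$edge.length[e]
    node <- tree$edge[e, 1]
  }
  total
}

# random rooted binary tree with exponential branch lengths
random_tree <- function(n_tips, seed, mean_bl = 0.3) {
  with_seed <- get("with_seed", asNamespace("opsinevo"))
  with_seed(seed, {
    tr <- ape::rtree(n_tips, rooted = TRUE)
    tr$tip.label <- paste0("s", seq_len(n_tips))
    tr$edge.length <- rexp(nrow(tr$edge), 1 / mean_bl) + 0.01
    tr
  })
}

# random codon alignment matrix (no simulation; arbitrary codons + missing)
random_codon_aln <- function(tip_labels, n_sites, seed, p_missing = 0.1) {
  with_seed <- get("with_seed", asNamespace("opsinevo"))
  with_seed(seed, {
    m <- matrix(sample.int(61, length(tip_labels) * n_sites, replace = TRUE),
                length(tip_labels), n_sites,
                dimnames = list(tip_labels, NULL))
    m[runif(length(m)) < p_missing] <- NA
    codon_alignment(m)
  })
}
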