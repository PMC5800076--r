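# Seeded simulators for trees, codon alignments and traits. These emulate
# the generating assumptions of the analysis chain (site-class and
# branch-heterogeneous GY94 codon evolution, Mk discrete traits, Brownian
# continuous traits) so every stage can be validated by simulate-then-fit.
# Codon and discrete states are propagated by exact transition-probability
# sampling at branch ends rather than by event-level simulation.

#' Simulate a tree
#'
#' Pure-birth (Yule) tree conditioned on the number of tips, via
#' `ape::rphylo`; reproducible under `seed`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth Birth rate of the Yule process.
#' @param seed Integer seed.
#' @param tip_prefix Prefix for tip labels (`t1`, `t2`, ... by default).
#' @return A rooted `phylo` with positive branch lengths.
#' @export
simulate_tree <- function(n_tips, birth = 1, seed = 1, tip_prefix = "t") {
  stopifnot(n_tips >= 2)
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = birth, death = 0))
  tr$tip.label <- paste0(tip_prefix, seq_len(n_tips))
  # guard against zero-length branches from the sampler
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  validate_tree(tr)
  tr
}

# sample child states given parent states and a transition matrix
.sample_transition <- function(parent_states, P) {
  out <- integer(length(parent_states))
  for (st in unique(parent_states)) {
    idx <- parent_states == st
    out[idx] <- sample.int(ncol(P), sum(idx), replace = TRUE, prob = P[st, ])
  }
  out
}

#' Simulate a codon alignment
#'
#' Evolves in-frame codon sequences along a tree under a GY94-style model,
#' with either a site-class dN/dS mixture (class membership drawn i.i.d. per
#' site; one common rate normalization at the mixture) or branch-specific
#' dN/dS values (each branch normalized at its own omega). Root codons are
#' drawn from the stationary frequencies.
#'
#' @inheritParams pruning_loglik
#' @param n_sites Number of codon sites.
#' @param codon_freqs Stationary codon frequencies; default uniform over the
#'   61 sense codons.
#' @param seed Integer seed.
#' @return A [codon_alignment()] with attribute `site_class` giving each
#'   site's simulated class index (for site-class models).
#' @export
simulate_codon_alignment <- function(tree, n_sites, kappa = 2,
                                     codon_freqs = rep(1 / 61, 61),
                                     classes = data.frame(omega = 1, weight = 1),
                                     rate_mult = 1, per_edge_omega = NULL,
                                     seed = 1) {
  validate_tree(tree)
  stopifnot(n_sites >= 1)
  with_seed(seed, {
    nedge <- nrow(tree$edge)
    if (is.null(per_edge_omega)) {
      scale <- codon_mixture_scale(kappa, classes$omega, classes$weight,
                                   codon_freqs)
      site_class <- sample.int(nrow(classes), n_sites, replace = TRUE,
                               prob = classes$weight)
      Qs <- lapply(classes$omega, function(om) {
        codon_rate_matrix(kappa, om, codon_freqs, scale_rate = scale)
      })
      edge_class_P <- function(e) {
        lapply(Qs, function(Q) {
          transition_probabilities(Q, tree$edge.length[e] * rate_mult)
        })
      }
      class_of_site <- site_class
    } else {
      if (length(per_edge_omega) != nedge) {
        stop("per_edge_omega must have one value per tree edge")
      }
      Qs_edge <- lapply(per_edge_omega, function(om) {
        codon_rate_matrix(kappa, om, codon_freqs)
      })
      edge_class_P <- function(e) {
        list(transition_probabilities(Qs_edge[[e]],
                                      tree$edge.length[e] * rate_mult))
      }
      class_of_site <- rep(1L, n_sites)
      site_class <- NULL
    }
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    states <- matrix(NA_integer_, nnode, n_sites)
    root <- tree_root(tree)
    states[root, ] <- sample.int(61, n_sites, replace = TRUE,
                                 prob = codon_freqs)
    tr <- ape::reorder.phylo(tree, "cladewise")
    # map reordered edges back to original rows so per-branch omegas align
    orig_row <- match(tr$edge[, 2], tree$edge[, 2])
    for (i in seq_len(nedge)) {
      e <- orig_row[i]
      Ps <- edge_class_P(e)
      par <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
      for (c in unique(class_of_site)) {
        idx <- class_of_site == c
        states[ch, idx] <- .sample_transition(states[par, idx],
                                              Ps[[min(c, length(Ps))]])
      }
    }
    m <- states[seq_len(ntip), , drop = FALSE]
    rownames(m) <- tree$tip.label
    aln <- codon_alignment(m)
    attr(aln, "site_class") <- site_class
    aln
  })
}

#' Simulate a discrete trait under an Mk model
#'
#' @param tree Rooted `phylo`; branch values are the evolutionary distance.
#' @param Q An Mk generator (see [mk_generator()]) with state names.
#' @param root_state State at the root (one of `rownames(Q)`).
#' @param seed Integer seed.
#' @return Named character vector of tip states.
#' @export
simulate_discrete_trait <- function(tree, Q, root_state, seed = 1) {
  validate_tree(tree)
  states <- rownames(Q)
  stopifnot(!is.null(states), root_state %in% states)
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    st <- integer(nnode)
    st[tree_root(tree)] <- match(root_state, states)
    tr <- ape::reorder.phylo(tree, "cladewise")
    for (i in seq_len(nrow(tr$edge))) {
      P <- pmax(mat_exp(Q * tr$edge.length[i]), 0)
      P <- P / rowSums(P)
      st[tr$edge[i, 2]] <- .sample_transition(st[tr$edge[i, 1]], P)
    }
    setNames(states[st[seq_len(ntip)]], tree$tip.label)
  })
}

#' Simulate a continuous trait under Brownian motion
#'
#' @param tree Rooted `phylo`; branch values are the evolutionary distance.
#' @param sigma2 Diffusion variance per unit branch value (>= 0).
#' @param root_value Trait value at the root.
#' @param seed Integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_continuous_trait <- function(tree, sigma2, root_value, seed = 1) {
  validate_tree(tree)
  stopifnot(sigma2 >= 0)
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    x <- numeric(nnode)
    x[tree_root(tree)] <- root_value
    tr <- ape::reorder.phylo(tree, "cladewise")
    for (i in seq_len(nrow(tr$edge))) {
      x[tr$edge[i, 2]] <- x[tr$edge[i, 1]] +
        rnorm(1, 0, sqrt(sigma2 * tr$edge.length[i]))
    }
    setNames(x[seq_len(ntip)], tree$tip.label)
  })
}
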