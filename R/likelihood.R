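# Phylogenetic likelihood of a codon alignment under GY94-style models,
# via Felsenstein pruning (compiled core in src/pruning.cpp).

# Prepare postorder edge structures shared by every likelihood evaluation.
prepare_pruning <- function(tree, aln) {
  tips <- match_alignment_tree(aln, tree)
  post <- postorder_edges(tree)
  list(edge = post$edge,
       elen = post$edge.length,
       # row of the ORIGINAL tree$edge for each postorder edge (edges are
       # uniquely identified by their child node)
       orig_row = match(post$edge[, 2], tree$edge[, 2]),
       tip_states = tips,
       # spectral-decomposition cache reused across likelihood evaluations
       # of one fit (branch-model gradient steps change one omega at a time)
       eigen_cache = new.env(parent = emptyenv()))
}

#' Per-site codon log-likelihoods by pruning
#'
#' Computes site log-likelihoods of a codon alignment on a rooted tree under
#' a GY94-style model, either with a mixture of dN/dS site classes (shared by
#' all branches, one common rate normalization at the mixture) or with
#' branch-specific dN/dS values (each branch normalized at its own omega).
#' Missing codons contribute partial likelihood one.
#'
#' @param tree Rooted `phylo`; tip labels must match the alignment ids.
#' @param aln A [codon_alignment()].
#' @param kappa Transition/transversion rate ratio.
#' @param codon_freqs Stationary codon frequencies (61-vector).
#' @param classes A data.frame with columns `omega` and `weight` describing
#'   the site-class mixture (a single row for one-class models). Ignored when
#'   `per_edge_omega` is given.
#' @param rate_mult Global multiplier applied to all branch lengths.
#' @param per_edge_omega Optional numeric vector of dN/dS values, one per row
#'   of `tree$edge`, for branch-heterogeneous models.
#' @return Numeric vector of per-site log-likelihoods, with attributes
#'   `total` (their sum) and `class_logliks` (sites x classes matrix of
#'   per-class log-likelihoods).
#' @export
pruning_loglik <- function(tree, aln, kappa, codon_freqs,
                           classes = data.frame(omega = 1, weight = 1),
                           rate_mult = 1, per_edge_omega = NULL) {
  prep <- prepare_pruning(tree, aln)
  codon_loglik_prepared(prep, kappa, codon_freqs, classes, rate_mult,
                        per_edge_omega)
}

codon_loglik_prepared <- function(prep, kappa, codon_freqs, classes,
                                  rate_mult = 1, per_edge_omega = NULL) {
  nedge <- nrow(prep$edge)
  if (is.null(per_edge_omega)) {
    w <- classes$weight
    if (abs(sum(w) - 1) > 1e-8) stop("class weights must sum to 1")
    scale <- codon_mixture_scale(kappa, classes$omega, w, codon_freqs)
    eigs <- lapply(classes$omega, function(om) {
      codon_eigen(codon_rate_matrix(kappa, om, codon_freqs, scale_rate = scale))
    })
    eig_index <- matrix(rep(seq_along(eigs), each = nedge), nedge)
    logw <- log(w)
  } else {
    if (length(per_edge_omega) != nedge) {
      stop("per_edge_omega must have one value per tree edge")
    }
    om_edges <- per_edge_omega[prep$orig_row]
    uom <- unique(om_edges)
    cache <- prep$eigen_cache
    eigs <- lapply(uom, function(om) {
      if (is.null(cache)) {
        return(codon_eigen(codon_rate_matrix(kappa, om, codon_freqs)))
      }
      key <- sprintf("%.17g_%.17g", kappa, om)
      hit <- get0(key, envir = cache, inherits = FALSE)
      if (!is.null(hit)) return(hit)
      val <- codon_eigen(codon_rate_matrix(kappa, om, codon_freqs))
      if (length(ls(cache)) > 400) rm(list = ls(cache), envir = cache)
      assign(key, val, envir = cache)
      val
    })
    eig_index <- matrix(match(om_edges, uom), nedge, 1)
    logw <- 0
  }
  tip_states <- prep$tip_states
  tip_states[is.na(tip_states)] <- 0L
  storage.mode(tip_states) <- "integer"
  storage.mode(eig_index) <- "integer"
  edge <- prep$edge
  storage.mode(edge) <- "integer"
  cls <- class_site_logliks_cpp(tip_states, edge, prep$elen * rate_mult,
                                eigs, eig_index, codon_freqs)
  per_site <- apply(cls, 1L, function(r) logsumexp(r + logw))
  attr(per_site, "total") <- sum(per_site)
  attr(per_site, "class_logliks") <- cls
  per_site
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
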