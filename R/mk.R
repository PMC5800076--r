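# Mk models (continuous-time Markov chains over k discrete states) on
# trees whose branch values provide the evolutionary distance — here
# typically omega-trees. Schemes: ER (one rate), SYM (one rate per unordered
# state pair) and ARD (one rate per ordered pair).

mk_n_rates <- function(k, scheme) {
  switch(scheme, ER = 1L, SYM = as.integer(k * (k - 1) / 2),
         ARD = as.integer(k * (k - 1)))
}

#' Mk generator matrix
#'
#' Builds the k-state generator for a rate scheme. Rate parameters are laid
#' out row-major over ordered pairs for ARD (1->2, 1->3, ..., 2->1, ...) and
#' over unordered pairs (1,2), (1,3), ..., (2,3), ... for SYM.
#'
#' @param rates Non-negative rate parameters (length 1 for ER,
#'   `k(k-1)/2` for SYM, `k(k-1)` for ARD).
#' @param states Character vector of state labels (k >= 2).
#' @param scheme `"ER"`, `"SYM"` or `"ARD"`.
#' @return A k x k generator with rows summing to zero.
#' @export
mk_generator <- function(rates, states, scheme = c("ER", "SYM", "ARD")) {
  scheme <- match.arg(scheme)
  k <- length(states)
  stopifnot(k >= 2, all(rates >= 0),
            length(rates) == mk_n_rates(k, scheme))
  Q <- matrix(0, k, k, dimnames = list(states, states))
  if (scheme == "ER") {
    Q[] <- rates[1]
  } else if (scheme == "SYM") {
    r <- 1L
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      Q[i, j] <- Q[j, i] <- rates[r]
      r <- r + 1L
    }
  } else {
    r <- 1L
    for (i in 1:k) for (j in 1:k) {
      if (i != j) {
        Q[i, j] <- rates[r]
        r <- r + 1L
      }
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# tip_states: named character vector (names = tip labels), NA = unknown.
# Returns k x ntip indicator matrix of partial likelihoods.
mk_tip_partials <- function(tree, tip_states, states) {
  st <- tip_states[tree$tip.label]
  if (anyNA(names(st)) || length(st) != length(tree$tip.label)) {
    stop("tip_states must be named with the tree's tip labels")
  }
  known <- !is.na(st)
  bad <- known & !(st %in% states)
  if (any(bad)) stop("unknown state(s): ", paste(unique(st[bad]), collapse = ", "))
  L <- matrix(1, length(states), length(st), dimnames = list(states, names(st)))
  for (i in which(known)) L[, i] <- as.numeric(states == st[i])
  L
}

# pruning in R; returns list(loglik, partials (k x nnode, scaled),
# logscale per node, P per postorder edge)
mk_pruning <- function(tree, tip_states, Q, root_prior = NULL) {
  states <- rownames(Q)
  k <- nrow(Q)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tipL <- mk_tip_partials(tree, tip_states, states)
  post <- postorder_edges(tree)
  partial <- matrix(NA_real_, k, nnode)
  partial[, seq_len(ntip)] <- tipL
  logscale <- numeric(nnode)
  Ps <- vector("list", nrow(post$edge))
  for (e in seq_len(nrow(post$edge))) {
    Ps[[e]] <- pmax(mat_exp(Q * post$edge.length[e]), 0)
  }
  seeded <- logical(nnode)
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]; ch <- post$edge[e, 2]
    msg <- as.vector(Ps[[e]] %*% partial[, ch])
    if (!seeded[par]) {
      partial[, par] <- msg
      seeded[par] <- TRUE
    } else {
      partial[, par] <- partial[, par] * msg
    }
    logscale[par] <- logscale[par] + logscale[ch]
    m <- max(partial[, par])
    if (m > 0 && (m < 1e-8 || m > 1e8)) {
      partial[, par] <- partial[, par] / m
      logscale[par] <- logscale[par] + log(m)
    }
  }
  root <- tree_root(tree)
  lik <- sum(root_prior * partial[, root])
  list(loglik = log(lik) + logscale[root], partial = partial,
       logscale = logscale, P = Ps, edge = post$edge, root = root,
       root_prior = root_prior, states = states)
}

#' Fit an Mk model by maximum likelihood
#'
#' Estimates the rate parameters of an ER, SYM or ARD Mk model on a tree
#' whose branch values act as evolutionary distance (e.g. an omega-tree),
#' by bounded quasi-Newton optimization of the pruning log-likelihood on the
#' log-rate scale, with seeded restarts. Tips with unknown state (NA)
#' contribute partial likelihood one; the root prior is flat.
#'
#' @param tree Rooted `phylo`.
#' @param tip_states Named character vector of tip states (names = tip
#'   labels); NA marks unknown states. At least two distinct observed states
#'   are required.
#' @param scheme `"ER"`, `"SYM"` or `"ARD"`.
#' @param states Optional explicit (ordered) state set; defaults to the
#'   sorted observed states.
#' @param seed Integer seed for the optimizer restarts.
#' @param n_starts Number of optimizer starts.
#' @return An object of class `mk_fit` with `rates`, `Q`, `lnL`, `np`,
#'   `scheme`, `states` and a `converged` flag.
#' @export
fit_mk <- function(tree, tip_states, scheme = c("ER", "SYM", "ARD"),
                   states = NULL, seed = 1, n_starts = 3) {
  scheme <- match.arg(scheme)
  validate_tree(tree)
  obs <- unique(tip_states[!is.na(tip_states)])
  if (is.null(states)) {
    # with no declared state set, a single observed state leaves the chain
    # undefined; with an explicit set the fit degenerates gracefully (rate
    # near zero, ancestral probability concentrated on the observed state)
    if (length(obs) < 2) stop("fewer than 2 observed states")
    states <- sort(obs)
  }
  if (length(states) < 2) stop("state set must contain at least 2 states")
  if (!all(obs %in% states)) stop("observed states outside the declared state set")
  nr <- mk_n_rates(length(states), scheme)

  # scale-aware default rate: one expected change per mean root-to-tip depth
  depth <- mean(node_depths(tree)[seq_along(tree$tip.label)])
  base_rate <- if (depth > 0) 1 / depth else 1

  negll <- function(logr) {
    Q <- mk_generator(exp(logr), states, scheme)
    ll <- tryCatch(mk_pruning(tree, tip_states, Q)$loglik,
                   error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  starts <- with_seed(seed, {
    s <- list(rep(log(base_rate), nr))
    for (i in seq_len(max(0L, n_starts - 1L))) {
      s[[i + 1L]] <- log(base_rate) + runif(nr, -2, 2)
    }
    s
  })
  best <- NULL; any_ok <- FALSE
  for (st in starts) {
    opt <- tryCatch(
      nlminb(st, negll, lower = rep(log(1e-8), nr), upper = rep(log(1e4), nr),
             control = list(rel.tol = 1e-10, iter.max = 500)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    any_ok <- any_ok || opt$convergence == 0
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stop("Mk optimization failed from every start")
  rates <- exp(best$par)
  Q <- mk_generator(rates, states, scheme)
  structure(list(scheme = scheme, states = states, rates = rates, Q = Q,
                 lnL = -best$objective, np = nr, converged = any_ok,
                 tree = tree, tip_states = tip_states, seed = seed),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk fit (", x$scheme, "), states: ", paste(x$states, collapse = ", "),
      "\n  lnL = ", format(x$lnL, digits = 10), ", np = ", x$np,
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' Marginal ancestral state probabilities
#'
#' Computes, for every internal node, the marginal posterior probability of
#' each state under a fitted Mk model, by the standard two-pass
#' (postorder/preorder) conditioning with a flat root prior. Probability
#' vectors are normalized to sum to one.
#'
#' @param fit An [fit_mk()] result.
#' @return An object of class `ancestral_recon` (type `"discrete"`): a list
#'   with `node_probs` (data.frame: `node`, one probability column per
#'   state), the `fit`, and `lnL`.
#' @export
marginal_ancestral_states <- function(fit) {
  stopifnot(inherits(fit, "mk_fit"))
  tree <- fit$tree
  pr <- mk_pruning(tree, fit$tip_states, fit$Q)
  k <- length(fit$states)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  edge <- pr$edge
  # children and messages per parent (messages indexed by postorder edge)
  msg <- vector("list", nrow(edge))
  for (e in seq_len(nrow(edge))) {
    msg[[e]] <- as.vector(pr$P[[e]] %*% pr$partial[, edge[e, 2]])
  }
  # preorder traversal: parents before children
  down <- matrix(NA_real_, k, nnode)
  down[, pr$root] <- pr$root_prior
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    sib <- which(edge[, 1] == par & edge[, 2] != ch)
    above <- down[, par]
    for (s in sib) above <- above * msg[[s]]
    down[, ch] <- as.vector(t(pr$P[[e]]) %*% above)
  }
  internal <- (ntip + 1):nnode
  probs <- t(vapply(internal, function(v) {
    p <- down[, v] * pr$partial[, v]
    p / sum(p)
  }, numeric(k)))
  colnames(probs) <- fit$states
  node_probs <- data.frame(node = internal, probs, check.names = FALSE)
  structure(list(type = "discrete", node_probs = node_probs, fit = fit,
                 states = fit$states, lnL = pr$loglik),
            class = "ancestral_recon")
}

#' @export
print.ancestral_recon <- function(x, ...) {
  cat("ancestral reconstruction (", x$type, "), ",
      nrow(if (is.null(x$node_probs)) x$node_estimates else x$node_probs),
      " internal nodes\n", sep = "")
  invisible(x)
}

#' Compare two Mk rate schemes by LRT
#'
#' Likelihood-ratio test of a restricted Mk scheme (e.g. SYM) against a
#' richer one (e.g. ARD) fitted to the same data and tree. By default the
#' degrees of freedom equal the difference in free-parameter counts;
#' `df_override` pins the degrees of freedom instead (published analyses of
#' this comparison sometimes report df = 1).
#'
#' @param fit_null,fit_alt `mk_fit` objects for the restricted and richer
#'   scheme.
#' @param df_override Optional degrees of freedom to use instead of the
#'   parameter-count difference.
#' @return A list with `statistic`, `df` and `p_value` (see [lrt()]).
#' @export
compare_mk_schemes <- function(fit_null, fit_alt, df_override = NULL) {
  stopifnot(inherits(fit_null, "mk_fit"), inherits(fit_alt, "mk_fit"))
  if (!identical(fit_null$states, fit_alt$states)) {
    stop("fits use different state sets")
  }
  df <- if (is.null(df_override)) max(1L, fit_alt$np - fit_null$np)
  else df_override
  lrt(fit_null$lnL, fit_alt$lnL, df = df)
}
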