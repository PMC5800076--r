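# Branch models: one-ratio, two-ratio (foreground/background) and
# free-ratios (one dN/dS per branch), with per-branch dN and dS bookkeeping.

.BRANCH_OMEGA_BOUNDS <- c(1e-4, 50)

# resolve a foreground specification (tip labels for terminal branches, or
# row indices into tree$edge) to edge rows
resolve_foreground <- function(tree, foreground) {
  if (is.numeric(foreground)) {
    idx <- as.integer(foreground)
    if (any(idx < 1L | idx > nrow(tree$edge))) {
      stop("foreground edge index out of range", call. = FALSE)
    }
    return(unique(idx))
  }
  tipn <- match(foreground, tree$tip.label)
  if (anyNA(tipn)) {
    stop("foreground branch not in tree: ",
         paste(foreground[is.na(tipn)], collapse = ", "), call. = FALSE)
  }
  match(tipn, tree$edge[, 2])
}

#' Fit a branch-heterogeneous codon model
#'
#' Fits GY94-style models in which dN/dS varies across branches rather than
#' sites: a single ratio shared by all branches (`one_ratio`), a foreground
#' ratio for a designated set of branches against a background ratio
#' (`two_ratio`), or an independent ratio for every branch (`free_ratios`,
#' the model used to turn a gene tree into an omega-tree). Branch lengths are
#' taken from the tree with one optimized rate multiplier; each branch's
#' generator is normalized at its own dN/dS so branch length times the
#' multiplier is the branch's expected substitutions per codon.
#'
#' @inheritParams fit_site_model
#' @param scheme One of `"one_ratio"`, `"two_ratio"`, `"free_ratios"`.
#' @param foreground For `two_ratio`: tip labels (their terminal branches) or
#'   row indices into `tree$edge`; must be non-empty.
#' @return A `codon_fit` whose `per_branch` component tabulates, per edge:
#'   the dN/dS estimate, branch length `t` (expected substitutions per codon,
#'   after the rate multiplier), and the `dN`/`dS` estimates derived from the
#'   model's synonymous/nonsynonymous site proportions.
#' @export
fit_branch_model <- function(aln, tree,
                             scheme = c("one_ratio", "two_ratio", "free_ratios"),
                             foreground = NULL, seed = 1,
                             freq_model = c("F3x4", "F61"), n_starts = 3,
                             reltol = 1e-8) {
  scheme <- match.arg(scheme)
  freq_model <- match.arg(freq_model)
  validate_tree(tree)
  nedge <- nrow(tree$edge)
  if (scheme == "two_ratio") {
    if (is.null(foreground) || length(foreground) == 0L) {
      stop("two_ratio requires a non-empty foreground set")
    }
    fg <- resolve_foreground(tree, foreground)
  }
  pi <- switch(freq_model, F3x4 = codon_freqs_f3x4(aln),
               F61 = codon_freqs_f61(aln))
  prep <- prepare_pruning(tree, aln)

  n_omega <- switch(scheme, one_ratio = 1L, two_ratio = 2L,
                    free_ratios = nedge)
  par_names <- c("kappa", paste0("omega", seq_len(n_omega)), "rate_mult")
  lower <- c(.SITE_BOUNDS$kappa[1], rep(.BRANCH_OMEGA_BOUNDS[1], n_omega),
             .SITE_BOUNDS$rate_mult[1])
  upper <- c(.SITE_BOUNDS$kappa[2], rep(.BRANCH_OMEGA_BOUNDS[2], n_omega),
             .SITE_BOUNDS$rate_mult[2])

  expand_omegas <- function(om) {
    switch(scheme,
           one_ratio = rep(om[1], nedge),
           two_ratio = {
             v <- rep(om[1], nedge); v[fg] <- om[2]; v
           },
           free_ratios = om)
  }

  negll <- function(par) {
    om <- expand_omegas(par[2:(1 + n_omega)])
    ll <- tryCatch(
      codon_loglik_prepared(prep, par[1], pi,
                            classes = data.frame(omega = 1, weight = 1),
                            rate_mult = par[length(par)],
                            per_edge_omega = om),
      error = function(e) NULL)
    if (is.null(ll) || !is.finite(attr(ll, "total"))) return(1e10)
    -attr(ll, "total")
  }

  starts <- with_seed(seed, {
    s <- list(c(2, rep(0.3, n_omega), 1))
    for (i in seq_len(max(0L, n_starts - 1L))) {
      s[[i + 1L]] <- c(runif(1, 0.5, 8), exp(runif(n_omega, log(0.02), log(3))),
                       exp(runif(1, -1, 1)))
    }
    s
  })

  best <- NULL
  any_ok <- FALSE
  for (st in starts) {
    opt <- tryCatch(
      nlminb(st, negll, lower = lower, upper = upper,
             control = list(rel.tol = reltol, iter.max = 1000,
                            eval.max = 10000)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    any_ok <- any_ok || opt$convergence == 0
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stop("branch-model optimization failed from every start")
  if (!any_ok) {
    warning("optimizer did not report convergence for scheme ", scheme,
            "; result flagged", call. = FALSE)
  }

  par <- setNames(best$par, par_names)
  om_edges <- expand_omegas(par[2:(1 + n_omega)])
  per_site <- codon_loglik_prepared(prep, par[1], pi,
                                    classes = data.frame(omega = 1, weight = 1),
                                    rate_mult = par[length(par)],
                                    per_edge_omega = om_edges)
  per_branch <- branch_dnds_table(tree, om_edges, par[1], pi,
                                  rate_mult = par[length(par)])
  est <- list(kappa = unname(par[1]), rate_mult = unname(par[length(par)]),
              omega = unname(par[2:(1 + n_omega)]), codon_freqs = pi,
              per_edge_omega = om_edges)
  if (scheme == "two_ratio") est$foreground_edges <- fg
  structure(list(model = scheme, estimates = est, lnL = attr(per_site, "total"),
                 np = length(par_names), classes = data.frame(omega = NA_real_,
                                                              weight = 1),
                 per_site = per_site, per_branch = per_branch,
                 converged = any_ok, n_starts = n_starts, seed = seed,
                 freq_model = freq_model),
            class = "codon_fit")
}

# Per-branch dN/dS bookkeeping. With each branch generator normalized at its
# own omega, t_e * rate_mult is the branch's expected substitutions per
# codon; these are split into synonymous and nonsynonymous counts by the
# model's relative flows, then divided by the per-codon numbers of
# synonymous/nonsynonymous sites (defined from the neutral, omega = 1 flows)
# so that dN/dS equals the branch's omega exactly.
branch_dnds_table <- function(tree, om_edges, kappa, pi, rate_mult = 1) {
  flows <- syn_nonsyn_flows(kappa, pi)
  a <- flows[["syn"]]; b <- flows[["nonsyn"]]
  pS <- a / (a + b); pN <- b / (a + b)
  t_codon <- tree$edge.length * rate_mult
  syn_subs <- t_codon * a / (a + om_edges * b)
  nonsyn_subs <- t_codon * om_edges * b / (a + om_edges * b)
  child <- tree$edge[, 2]
  ntip <- length(tree$tip.label)
  data.frame(edge = seq_len(nrow(tree$edge)),
             parent = tree$edge[, 1], child = child,
             label = ifelse(child <= ntip, tree$tip.label[child],
                            paste0("node", child)),
             omega = om_edges, t = t_codon,
             dN = nonsyn_subs / (3 * pN), dS = syn_subs / (3 * pS),
             stringsAsFactors = FALSE)
}
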