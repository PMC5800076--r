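# Site-class model fits: M7 (beta), M8 (beta + omega_s >= 1) and
# M8a (beta + omega = 1), the model pair behind the positive-selection and
# neutrality likelihood-ratio tests.

# evaluate RNG-dependent code under a local, seeded RNG stream
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

.SITE_BOUNDS <- list(
  kappa     = c(0.05, 50),
  beta_p    = c(0.005, 50),
  beta_q    = c(0.005, 50),
  p1        = c(0, 1),
  omega_s   = c(1, 999),
  rate_mult = c(1e-3, 1e3)
)

site_model_classes <- function(model, beta_p, beta_q, p1 = 0, omega_s = 1,
                               K = 10) {
  cls <- discretize_beta(beta_p, beta_q, K)
  if (model == "M7") return(cls)
  if (model == "M8a") omega_s <- 1
  rbind(data.frame(omega = cls$omega, weight = cls$weight * (1 - p1)),
        data.frame(omega = omega_s, weight = p1))
}

#' Fit a site-class codon model
#'
#' Maximum-likelihood fit of M7 (dN/dS beta-distributed in (0,1), discretized
#' into `K` equal-probability classes), M8 (M7 plus an extra class with
#' dN/dS >= 1, proportion `p1`) or M8a (the extra class fixed at dN/dS = 1).
#' Branch lengths are taken from the tree and a single rate multiplier is
#' optimized; codon frequencies are estimated from the alignment and held
#' fixed. Optimization is bounded quasi-Newton (`nlminb`) from `n_starts`
#' seeded starting points.
#'
#' @param aln A [codon_alignment()].
#' @param tree Rooted `phylo` with branch lengths; tips must match `aln`.
#' @param model One of `"M7"`, `"M8"`, `"M8a"`.
#' @param K Number of beta discretization classes.
#' @param seed Integer seed controlling the optimizer restarts.
#' @param freq_model `"F3x4"` (default) or `"F61"` codon frequencies.
#' @param n_starts Number of seeded optimizer starts (the first is a fixed
#'   default point).
#' @param reltol Relative convergence tolerance on the log-likelihood.
#' @return An object of class `codon_fit`: a list with `model`, `estimates`,
#'   `lnL`, `np`, `classes` (the fitted site-class mixture), `per_site`
#'   log-likelihoods (with per-class matrix in `class_logliks`), and a
#'   `converged` flag. Non-convergence after all restarts is flagged and
#'   warned about, never silent.
#' @export
fit_site_model <- function(aln, tree, model = c("M7", "M8", "M8a"), K = 10,
                           seed = 1, freq_model = c("F3x4", "F61"),
                           n_starts = 3, reltol = 1e-8) {
  model <- match.arg(model)
  freq_model <- match.arg(freq_model)
  validate_tree(tree)
  pi <- switch(freq_model, F3x4 = codon_freqs_f3x4(aln),
               F61 = codon_freqs_f61(aln))
  prep <- prepare_pruning(tree, aln)

  par_names <- switch(model,
                      M7 = c("kappa", "beta_p", "beta_q", "rate_mult"),
                      M8a = c("kappa", "beta_p", "beta_q", "p1", "rate_mult"),
                      M8 = c("kappa", "beta_p", "beta_q", "p1", "omega_s",
                             "rate_mult"))
  lower <- vapply(.SITE_BOUNDS[par_names], `[`, numeric(1), 1L)
  upper <- vapply(.SITE_BOUNDS[par_names], `[`, numeric(1), 2L)

  negll <- function(par) {
    names(par) <- par_names
    cls <- site_model_classes(model, par["beta_p"], par["beta_q"],
                              p1 = if ("p1" %in% par_names) par["p1"] else 0,
                              omega_s = if ("omega_s" %in% par_names)
                                par["omega_s"] else 1,
                              K = K)
    ll <- tryCatch(
      codon_loglik_prepared(prep, par["kappa"], pi, cls,
                            rate_mult = par["rate_mult"]),
      error = function(e) NULL)
    if (is.null(ll) || !is.finite(attr(ll, "total"))) return(1e10)
    -attr(ll, "total")
  }

  default_start <- c(kappa = 2, beta_p = 0.8, beta_q = 1.6, p1 = 0.1,
                     omega_s = 2, rate_mult = 1)[par_names]
  starts <- with_seed(seed, {
    s <- list(default_start)
    for (i in seq_len(max(0L, n_starts - 1L))) {
      s[[i + 1L]] <- c(kappa = runif(1, 0.5, 8), beta_p = runif(1, 0.05, 3),
                       beta_q = runif(1, 0.05, 3), p1 = runif(1, 0.01, 0.4),
                       omega_s = 1 + rexp(1, 1 / 3),
                       rate_mult = exp(runif(1, -1, 1)))[par_names]
    }
    s
  })

  best <- NULL
  any_ok <- FALSE
  for (st in starts) {
    opt <- tryCatch(
      nlminb(st, negll, lower = lower, upper = upper,
             control = list(rel.tol = reltol, iter.max = 500, eval.max = 2000)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    ok <- opt$convergence == 0
    any_ok <- any_ok || ok
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stop("site-model optimization failed from every start")
  if (!any_ok) {
    warning("optimizer did not report convergence for model ", model,
            " after ", n_starts, " starts; result flagged", call. = FALSE)
  }

  est <- as.list(setNames(best$par, par_names))
  cls <- site_model_classes(model, est$beta_p, est$beta_q,
                            p1 = if (!is.null(est$p1)) est$p1 else 0,
                            omega_s = if (!is.null(est$omega_s))
                              est$omega_s else 1, K = K)
  per_site <- codon_loglik_prepared(prep, est$kappa, pi, cls,
                                    rate_mult = est$rate_mult)
  structure(list(model = model, estimates = c(est, list(codon_freqs = pi)),
                 lnL = attr(per_site, "total"), np = length(par_names),
                 K = K, classes = cls, per_site = per_site,
                 converged = any_ok, n_starts = n_starts, seed = seed,
                 freq_model = freq_model),
            class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("codon model fit:", x$model, "\n")
  cat("  lnL =", format(x$lnL, digits = 10), " np =", x$np,
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  est <- x$estimates[setdiff(names(x$estimates), c("codon_freqs", "per_edge_omega"))]
  cat("  ", paste(names(est), signif(unlist(est), 4), sep = " = ",
                  collapse = ", "), "\n")
  invisible(x)
}

#' Naive empirical Bayes site posteriors
#'
#' Posterior probability of each site-class for every codon site, computed at
#' the maximum-likelihood parameter estimates: `post(site, c)` is
#' proportional to the class weight times the site's class likelihood. Sites
#' whose posterior mass on the positively-selected class (the final class of
#' an M8 fit, dN/dS >= 1) exceeds `threshold` are flagged.
#'
#' @param fit A `codon_fit` from [fit_site_model()].
#' @param threshold Posterior probability above which a site is flagged.
#' @return A data.frame with one row per codon site: `site`, one `p_class*`
#'   column per site class, `p_selected` (posterior of the final class) and
#'   logical `flagged`. Rows sum to one over the class columns.
#' @export
site_posteriors <- function(fit, threshold = 0.75) {
  stopifnot(inherits(fit, "codon_fit"))
  cls_ll <- attr(fit$per_site, "class_logliks")
  logw <- log(fit$classes$weight)
  lp <- sweep(cls_ll, 2L, logw, "+")
  norm <- apply(lp, 1L, logsumexp)
  post <- exp(sweep(lp, 1L, norm, "-"))
  colnames(post) <- paste0("p_class", seq_len(ncol(post)))
  sel <- post[, ncol(post)]
  data.frame(site = seq_len(nrow(post)), post,
             p_selected = sel,
             flagged = fit$model == "M8" & sel > threshold)
}
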