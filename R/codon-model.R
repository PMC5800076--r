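# Goldman-Yang style codon substitution model.
#
# Instantaneous rates between sense codons i != j:
#   q_ij = 0                       if i and j differ at more than one position
#   q_ij = pi_j                    synonymous transversion
#   q_ij = kappa * pi_j            synonymous transition
#   q_ij = omega * pi_j            nonsynonymous transversion
#   q_ij = omega * kappa * pi_j    nonsynonymous transition
# The generator is normalized so that the expected number of substitutions
# per codon per unit branch length equals one at a reference omega mixture.

#' Codon frequencies from an alignment
#'
#' `codon_freqs_f3x4()` estimates position-specific nucleotide frequencies
#' and forms codon frequencies as their product, renormalized over the 61
#' sense codons (the F3x4 convention); `codon_freqs_f61()` uses empirical
#' sense-codon frequencies directly. Both floor frequencies at `floor_at`
#' and renormalize so that every codon keeps positive stationary mass.
#'
#' @param aln A [codon_alignment()].
#' @param floor_at Minimum frequency per codon before renormalization.
#' @return A named numeric 61-vector summing to one.
#' @export
codon_freqs_f3x4 <- function(aln, floor_at = 1e-5) {
  stopifnot(inherits(aln, "codon_alignment"))
  obs <- aln$codons[!is.na(aln$codons)]
  if (!length(obs)) stop("alignment has no observed codons")
  nf <- matrix(0, 3, 4) # position x nucleotide
  for (pos in 1:3) {
    nf[pos, ] <- tabulate(.codon_nuc_idx[obs, pos], nbins = 4)
  }
  nf <- nf / rowSums(nf)
  pi61 <- nf[1, .codon_nuc_idx[, 1]] * nf[2, .codon_nuc_idx[, 2]] *
    nf[3, .codon_nuc_idx[, 3]]
  .finish_freqs(pi61, floor_at)
}

#' @rdname codon_freqs_f3x4
#' @export
codon_freqs_f61 <- function(aln, floor_at = 1e-5) {
  stopifnot(inherits(aln, "codon_alignment"))
  obs <- aln$codons[!is.na(aln$codons)]
  if (!length(obs)) stop("alignment has no observed codons")
  .finish_freqs(tabulate(obs, nbins = .N_CODON) / length(obs), floor_at)
}

.finish_freqs <- function(pi61, floor_at) {
  pi61 <- pmax(pi61, floor_at)
  pi61 <- pi61 / sum(pi61)
  names(pi61) <- .SENSE_CODONS
  pi61
}

#' Build a codon rate matrix
#'
#' Constructs the 61x61 generator for given kappa (transition/transversion
#' rate ratio), omega (dN/dS) and stationary codon frequencies. By default the
#' generator is scaled so one unit of branch length equals one expected
#' substitution per codon at this omega; passing `scale_rate` (an expected
#' flow computed at a mixture of omegas, see [codon_mixture_scale()]) applies
#' a common scaling across the site classes of a mixture model instead.
#'
#' @param kappa Transition/transversion rate ratio, positive.
#' @param omega dN/dS ratio, non-negative.
#' @param codon_freqs Positive 61-vector summing to one.
#' @param scale_rate Optional externally supplied expected substitution rate
#'   used as the normalization constant; `NULL` scales at this omega.
#' @return A 61x61 generator matrix (rows sum to zero) with attributes
#'   `rate` (the unscaled expected flow at this omega) and `pi`.
#' @export
codon_rate_matrix <- function(kappa, omega, codon_freqs, scale_rate = NULL) {
  stopifnot(kappa > 0, omega >= 0, length(codon_freqs) == .N_CODON)
  if (abs(sum(codon_freqs) - 1) > 1e-8 || any(codon_freqs <= 0)) {
    stop("codon_freqs must be positive and sum to 1")
  }
  single <- .codon_rel$diff == 1L
  Q <- matrix(0, .N_CODON, .N_CODON,
              dimnames = list(.SENSE_CODONS, .SENSE_CODONS))
  Q[single] <- rep(codon_freqs, each = .N_CODON)[single]
  Q[single & .codon_rel$ts] <- Q[single & .codon_rel$ts] * kappa
  Q[single & .codon_rel$nonsyn] <- Q[single & .codon_rel$nonsyn] * omega
  diag(Q) <- -rowSums(Q)
  rate <- -sum(codon_freqs * diag(Q))
  sc <- if (is.null(scale_rate)) rate else scale_rate
  if (sc <= 0) stop("degenerate model: zero expected substitution rate")
  Q <- Q / sc
  attr(Q, "rate") <- rate
  attr(Q, "pi") <- codon_freqs
  Q
}

#' Expected substitution rate of an omega mixture
#'
#' Computes the expected substitutions per codon per unit time of the
#' unscaled generator, averaged over site classes with weights `w` and
#' dN/dS values `omegas`. Used to apply one common scaling to all classes
#' of a site-class model.
#'
#' @inheritParams codon_rate_matrix
#' @param omegas Numeric vector of class dN/dS values.
#' @param w Class weights (positive, summing to one).
#' @return The mixture expected rate (a positive scalar).
#' @export
codon_mixture_scale <- function(kappa, omegas, w, codon_freqs) {
  stopifnot(length(omegas) == length(w), abs(sum(w) - 1) < 1e-8)
  flows <- syn_nonsyn_flows(kappa, codon_freqs)
  sum(w * (flows["syn"] + omegas * flows["nonsyn"]))
}

# expected synonymous and nonsynonymous flow of the unscaled generator at
# omega = 1: rate(omega) = syn + omega * nonsyn
syn_nonsyn_flows <- function(kappa, codon_freqs) {
  single <- .codon_rel$diff == 1L
  base <- rep(codon_freqs, each = .N_CODON) *
    ifelse(.codon_rel$ts, kappa, 1) * single
  flow <- codon_freqs * base # pi_i * q_ij contributions
  c(syn = sum(flow[single & !.codon_rel$nonsyn]),
    nonsyn = sum(flow[single & .codon_rel$nonsyn]))
}

# Eigendecomposition of a reversible generator via the symmetrizing
# similarity transform; returns V, d, Vinv with Q = V diag(d) Vinv.
codon_eigen <- function(Q, pi = attr(Q, "pi")) {
  s <- sqrt(pi)
  B <- diag(s) %*% Q %*% diag(1 / s)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(V = e$vectors / s, d = e$values, Vinv = t(e$vectors) * rep(s, each = length(s)))
}

#' Transition probability matrix
#'
#' Matrix exponential `P(t) = exp(Qt)` of a generator. For reversible codon
#' generators the spectral decomposition is used; tiny negative entries from
#' round-off are clipped to zero (with a warning when any entry falls below
#' -1e-12).
#'
#' @param Q A generator matrix (rows summing to zero).
#' @param t Non-negative elapsed distance.
#' @param pi Stationary distribution of `Q` when it is reversible; `NULL`
#'   falls back to a general matrix exponential.
#' @return A stochastic matrix (rows sum to one).
#' @export
transition_probabilities <- function(Q, t, pi = attr(Q, "pi")) {
  stopifnot(t >= 0)
  if (!is.null(pi)) {
    e <- codon_eigen(Q, pi)
    P <- e$V %*% (exp(e$d * t) * e$Vinv)
  } else {
    P <- mat_exp(Q * t)
  }
  if (min(P) < -1e-12) {
    warning("transition matrix had entries below -1e-12; clipped",
            call. = FALSE)
  }
  P[P < 0] <- 0
  P / rowSums(P)
}

# general small-matrix exponential: eigendecomposition (complex-safe) with
# Matrix::expm fallback when the eigenvector basis is ill-conditioned
mat_exp <- function(A) {
  e <- tryCatch(eigen(A), error = function(err) NULL)
  if (!is.null(e) && all(is.finite(Mod(e$values)))) {
    V <- e$vectors
    rc <- tryCatch(rcond(Re(V %*% Conj(t(V)))), error = function(err) 0)
    if (is.finite(rc) && rc > 1e-10) {
      out <- tryCatch(Re(V %*% (exp(e$values) * solve(V))),
                      error = function(err) NULL)
      if (!is.null(out) && all(is.finite(out))) return(out)
    }
  }
  as.matrix(Matrix::expm(Matrix::Matrix(A)))
}

#' Discretize a beta distribution into equal-probability classes
#'
#' Splits Beta(p, q) into `K` bins of probability 1/K and represents each bin
#' by its conditional mean (computed in closed form via the incomplete-beta
#' identity), the convention used for beta-distributed dN/dS site classes.
#'
#' @param p,q Beta shape parameters, positive.
#' @param K Number of classes, at least one.
#' @return A data.frame with columns `omega` (bin means) and `weight`
#'   (all `1/K`).
#' @examples
#' discretize_beta(1, 1, 2) # bin means 0.25 and 0.75
#' @export
discretize_beta <- function(p, q, K) {
  stopifnot(p > 0, q > 0, K >= 1)
  brk <- qbeta(seq(0, 1, length.out = K + 1), p, q)
  mu <- p / (p + q)
  # integral of x * dbeta(x; p, q) over a bin = mu * diff(pbeta(.; p+1, q))
  mass <- diff(pbeta(brk, p + 1, q))
  omega <- mu * mass * K
  omega <- pmin(pmax(omega, 0), 1)
  data.frame(omega = omega, weight = rep(1 / K, K))
}
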