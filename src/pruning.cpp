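// Felsenstein pruning for codon (or any finite-state) substitution models.
//
// Works on a rooted tree given as a postorder edge list (ape node numbering:
// tips 1..ntip, internal nodes above). Transition matrices are formed from
// spectral decompositions of the per-class (or per-branch) generators, so a
// single set of eigen systems serves every branch length. Per-site partial
// likelihoods are rescaled per message to avoid underflow; the returned
// values are per-class per-site log-likelihoods including those scalers.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// tip_states: ntip x nsites, 1-based state index, 0 = missing
// edge:       nedge x 2 (parent, child), postorder, 1-based ape node ids
// elen:       branch length per edge (already rate-scaled)
// eigs:       list of spectral decompositions list(V, d, Vinv)
// eig_index:  nedge x nclass, 1-based index into eigs per (edge, class)
// root_freqs: state frequencies at the root
// returns nsites x nclass matrix of log-likelihoods
// [[Rcpp::export]]
arma::mat class_site_logliks_cpp(const arma::imat& tip_states,
                                 const arma::imat& edge,
                                 const arma::vec& elen,
                                 const Rcpp::List& eigs,
                                 const arma::imat& eig_index,
                                 const arma::vec& root_freqs) {
  const uword ntip = tip_states.n_rows;
  const uword nsites = tip_states.n_cols;
  const uword nedge = edge.n_rows;
  const uword nclass = eig_index.n_cols;
  const uword s = root_freqs.n_elem;
  const uword nnode = edge.max();

  // root = parent that never occurs as a child
  std::vector<bool> is_child(nnode + 1, false);
  for (uword e = 0; e < nedge; ++e) is_child[edge(e, 1)] = true;
  uword root = 0;
  for (uword e = 0; e < nedge; ++e)
    if (!is_child[edge(e, 0)]) { root = edge(e, 0); break; }

  const uword neig = eigs.size();
  std::vector<mat> V(neig), Vinv(neig);
  std::vector<vec> d(neig);
  for (uword k = 0; k < neig; ++k) {
    Rcpp::List ek = eigs[k];
    V[k] = Rcpp::as<mat>(ek["V"]);
    d[k] = Rcpp::as<vec>(ek["d"]);
    Vinv[k] = Rcpp::as<mat>(ek["Vinv"]);
  }

  mat out(nsites, nclass);

  for (uword c = 0; c < nclass; ++c) {
    std::vector<mat> partial(nnode + 1);
    std::vector<bool> seeded(nnode + 1, false);
    rowvec logscale(nsites, fill::zeros);

    for (uword e = 0; e < nedge; ++e) {
      const uword par = edge(e, 0), ch = edge(e, 1);
      const uword k = eig_index(e, c) - 1;
      mat P = V[k] * diagmat(exp(d[k] * elen(e))) * Vinv[k];
      P.clamp(0.0, datum::inf);

      mat msg(s, nsites);
      if (ch <= ntip) {
        const vec ones_s(s, fill::ones);
        const vec Prow1 = sum(P, 1); // message for a missing tip state
        for (uword i = 0; i < nsites; ++i) {
          const int st = tip_states(ch - 1, i);
          msg.col(i) = (st == 0) ? Prow1 : P.col(st - 1);
        }
      } else {
        msg = P * partial[ch];
        partial[ch].reset(); // free
        rowvec m = max(msg, 0);
        m.transform([](double x) { return x > 0 ? x : 1.0; });
        msg.each_row() /= m;
        logscale += log(m);
      }

      if (!seeded[par]) {
        partial[par] = msg;
        seeded[par] = true;
      } else {
        partial[par] %= msg;
      }
    }

    rowvec lik = root_freqs.t() * partial[root];
    out.col(c) = (log(lik) + logscale).t();
  }
  return out;
}
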