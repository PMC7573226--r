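// Felsenstein pruning over the 61 sense-codon states, one pass per omega
// class of a site mixture.  Transition matrices are computed by
// eigendecomposition of the pi-symmetrized reversible rate matrix, the same
// Q that R-side transitionMatrix() exponentiates.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// edge: E x 2 (parent, child), 1-based, in postorder (children before the
// edge to their parent).  tip_states: n_tip x S with 1..61, 0 = missing.
// Q: 61 x 61 x K rate matrices (already normalized per class).
// Returns S x K per-site log-likelihoods log P(site | tree, class k).
// [[Rcpp::export]]
arma::mat prune_loglik_cpp(const arma::imat& edge,
                           const arma::vec& elen,
                           const int n_tip,
                           const int n_node,
                           const int root,
                           const arma::imat& tip_states,
                           const arma::cube& Q,
                           const arma::vec& pi) {
  const int S = tip_states.n_cols;
  const int K = Q.n_slices;
  const int E = edge.n_rows;

  vec piv = pi;
  piv.transform([](double x) { return x < 1e-300 ? 1e-300 : x; });
  const vec d = sqrt(piv);
  const vec dinv = 1.0 / d;

  // per-tip gather indices (state - 1; missing handled separately)
  std::vector<uvec> tipidx(n_tip);
  std::vector<uvec> tipmiss(n_tip);
  for (int t = 0; t < n_tip; ++t) {
    uvec idx(S);
    std::vector<uword> miss;
    for (int s = 0; s < S; ++s) {
      const int st = tip_states(t, s);
      if (st == 0) {
        idx(s) = 0;
        miss.push_back(s);
      } else {
        idx(s) = st - 1;
      }
    }
    tipidx[t] = idx;
    tipmiss[t] = uvec(miss);
  }

  mat out(S, K);
  std::vector<mat> partial(n_node);
  std::vector<bool> has(n_node);
  mat lsc(n_node, S);
  mat contrib;

  for (int k = 0; k < K; ++k) {
    mat B = Q.slice(k);
    B.each_col() %= d;
    B.each_row() %= dinv.t();
    B = 0.5 * (B + B.t());
    vec eval;
    mat evec;
    eig_sym(eval, evec, B);
    const mat evt = evec.t();

    for (int v = 0; v < n_node; ++v) has[v] = false;
    lsc.zeros();

    for (int e = 0; e < E; ++e) {
      const int par = edge(e, 0) - 1;
      const int chi = edge(e, 1) - 1;
      const vec ex = exp(eval * elen(e));

      if (chi < n_tip) {
        // tips need explicit P columns: P = D^{-1/2} U exp(L t) U' D^{1/2}
        mat P = (evec.each_row() % ex.t()) * evt;
        P.each_col() %= dinv;
        P.each_row() %= d.t();
        P.transform([](double x) { return x < 0 ? 0.0 : x; });
        contrib = P.cols(tipidx[chi]);
        if (!tipmiss[chi].is_empty()) {
          const vec prow = sum(P, 1);  // P * ones for missing states
          for (uword j : tipmiss[chi]) contrib.col(j) = prow;
        }
      } else {
        // rescale the child's partials to avoid underflow
        mat& L = partial[chi];
        rowvec m = max(L, 0);
        for (int s = 0; s < S; ++s) {
          if (m(s) > 0 && m(s) < 1e-100) {
            L.col(s) /= m(s);
            lsc(chi, s) += std::log(m(s));
          }
        }
        // apply exp(Qt) in the eigenbasis without forming P:
        // contrib = D^{-1/2} U (ex .* (U' (D^{1/2} L)))
        mat Y = L;
        Y.each_col() %= d;
        Y = evt * Y;
        Y.each_col() %= ex;
        contrib = evec * Y;
        contrib.each_col() %= dinv;
        contrib.transform([](double x) { return x < 0 ? 0.0 : x; });
        lsc.row(par) += lsc.row(chi);
      }

      if (!has[par]) {
        partial[par] = contrib;
        has[par] = true;
      } else {
        partial[par] %= contrib;
      }
    }

    const int r = root - 1;
    const mat& LR = partial[r];
    for (int s = 0; s < S; ++s)
      out(s, k) = std::log(dot(piv, LR.col(s))) + lsc(r, s);
  }
  return out;
}
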