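// Felsenstein pruning over the 61-state sense-codon space.
// Transition matrices are rebuilt per edge from the spectral decomposition
// of each omega-class generator; partial likelihoods are scaled per node to
// avoid underflow on deep trees.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// tipStates: nTips x nPat, values 1..nState, 0 = missing (gap/ambiguous).
// edge: nEdge x 2 (parent, child), 1-based ape node ids, postorder.
// eclass: 1-based index into eig (list of U, Uinv, lambda per omega class).
// Returns per-pattern log-likelihoods.
// [[Rcpp::export]]
arma::vec codon_loglik_patterns(const arma::imat& tipStates,
                                const arma::imat& edge,
                                const arma::vec& elen,
                                const arma::ivec& eclass,
                                const List& eig,
                                const arma::vec& pi,
                                int nNode) {
  const int nTips = tipStates.n_rows;
  const int nPat = tipStates.n_cols;
  const int nState = pi.n_elem;
  const int nEdge = edge.n_rows;
  const int nClass = eig.size();

  std::vector<arma::mat> U(nClass), Uinv(nClass);
  std::vector<arma::vec> lam(nClass);
  for (int c = 0; c < nClass; ++c) {
    List e = eig[c];
    U[c] = as<arma::mat>(e["U"]);
    Uinv[c] = as<arma::mat>(e["Uinv"]);
    lam[c] = as<arma::vec>(e["lambda"]);
  }

  // partial likelihoods for internal nodes only (ids nTips+1 .. nNode)
  std::vector<arma::mat> L(nNode - nTips);
  std::vector<bool> init(nNode - nTips, false);
  arma::rowvec logScale(nPat, arma::fill::zeros);

  int root = edge(nEdge - 1, 0);  // postorder: last edge's parent

  for (int e = 0; e < nEdge; ++e) {
    int parent = edge(e, 0), child = edge(e, 1);
    int c = eclass(e) - 1;
    arma::mat P = U[c] * arma::diagmat(arma::exp(lam[c] * elen(e))) * Uinv[c];
    P.transform([](double x) { return x < 0.0 ? 0.0 : x; });

    arma::mat down(nState, nPat);
    if (child <= nTips) {
      arma::vec ones(nState, arma::fill::ones);
      arma::vec rs = P * ones;  // row sums (~1), used for missing tips
      for (int k = 0; k < nPat; ++k) {
        int s = tipStates(child - 1, k);
        if (s > 0) down.col(k) = P.col(s - 1);
        else down.col(k) = rs;
      }
    } else {
      arma::mat& Lc = L[child - nTips - 1];
      // scale the completed child before propagating
      arma::rowvec m = arma::max(Lc, 0);
      m.transform([](double x) { return x > 0.0 ? x : 1.0; });
      Lc.each_row() /= m;
      logScale += arma::log(m);
      down = P * Lc;
    }
    int pidx = parent - nTips - 1;
    if (!init[pidx]) {
      L[pidx] = down;
      init[pidx] = true;
    } else {
      L[pidx] %= down;
    }
  }

  arma::mat& Lr = L[root - nTips - 1];
  arma::vec out(nPat);
  for (int k = 0; k < nPat; ++k) {
    double lik = arma::dot(pi, Lr.col(k));
    out(k) = std::log(lik) + logScale(k);
  }
  return out;
}
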