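// Felsenstein pruning and marginal ancestral reconstruction for a k-state
// continuous-time Markov model on a rooted tree. Trees arrive as ape-style
// postorder edge matrices (1-based node ids; tips 1..ntip, root ntip+1).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Scaling-and-squaring matrix exponential with a high-order Taylor core,
// specialized for the small dense generators used here (fixed 3x3 fast
// path; Armadillo expmat fallback for other sizes). With the scaled norm
// kept below 1/4 the order-12 Taylor remainder is ~1e-16.
static void expm3(const double* A, double* E) {
  double nrm = 0.0;                      // infinity norm
  for (int i = 0; i < 3; ++i) {
    double r = std::fabs(A[i]) + std::fabs(A[i + 3]) + std::fabs(A[i + 6]);
    if (r > nrm) nrm = r;
  }
  int s = 0;
  while (nrm > 0.25) { nrm *= 0.5; ++s; }
  const double sc = std::ldexp(1.0, -s);
  double B[9];
  for (int i = 0; i < 9; ++i) B[i] = A[i] * sc;

  // Horner evaluation of sum_{k=0..12} B^k / k! :
  // T <- I, then T <- I + (B T)/k for k = 12..1
  double T[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1}, W[9];
  for (int ord = 12; ord >= 1; --ord) {
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r)
        W[r + 3 * c] = B[r] * T[3 * c] + B[r + 3] * T[1 + 3 * c] +
                       B[r + 6] * T[2 + 3 * c];
    for (int i = 0; i < 9; ++i) T[i] = W[i] / ord;
    T[0] += 1.0; T[4] += 1.0; T[8] += 1.0;
  }
  for (int i = 0; i < 9; ++i) E[i] = T[i];
  for (int k = 0; k < s; ++k) {
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r)
        W[r + 3 * c] = E[r] * E[3 * c] + E[r + 3] * E[1 + 3 * c] +
                       E[r + 6] * E[2 + 3 * c];
    for (int i = 0; i < 9; ++i) E[i] = W[i];
  }
}

static arma::mat pmat(const arma::mat& Q, double t) {
  arma::mat P;
  if (Q.n_rows == 3) {
    arma::mat A = Q * t;
    P.set_size(3, 3);
    expm3(A.memptr(), P.memptr());
  } else {
    P = arma::expmat(Q * t);
  }
  P.clamp(0.0, arma::datum::inf);
  return P;
}

// [[Rcpp::export(".cpp_transition_matrix")]]
arma::mat cpp_transition_matrix(const arma::mat& Q, double t) {
  return pmat(Q, t);
}

// [[Rcpp::export(".cpp_prune_loglik")]]
double cpp_prune_loglik(const arma::imat& edge,
                        const arma::vec& edge_length,
                        const arma::mat& tipvec,
                        const arma::mat& Q,
                        const arma::vec& pi) {
  const int ntip = tipvec.n_rows;
  const int k = Q.n_rows;
  const int nnode_total = edge.max();
  arma::mat L(nnode_total, k, arma::fill::ones);
  L.rows(0, ntip - 1) = tipvec;
  double logscale = 0.0;

  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    const int parent = edge(e, 0) - 1;
    const int child  = edge(e, 1) - 1;
    arma::rowvec Lc = L.row(child);
    if (child >= ntip) {                 // internal child complete: rescale
      double s = arma::accu(Lc);
      if (s <= 0.0) return R_NegInf;
      logscale += std::log(s);
      Lc /= s;
    }
    arma::mat P = pmat(Q, edge_length(e));
    L.row(parent) %= (P * Lc.t()).t();
  }

  const int root = ntip;                 // ape convention: root = ntip + 1
  double lik = arma::dot(pi, L.row(root).t());
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik) + logscale;
}

// Marginal posterior state probabilities at every node (tips included),
// via the standard outside-inside two-pass. Returns (nnode_total x k),
// rows normalized to sum 1. Requires positive total likelihood.
// [[Rcpp::export(".cpp_node_marginals")]]
arma::mat cpp_node_marginals(const arma::imat& edge,
                             const arma::vec& edge_length,
                             const arma::mat& tipvec,
                             const arma::mat& Q,
                             const arma::vec& pi) {
  const int ntip = tipvec.n_rows;
  const int k = Q.n_rows;
  const int nnode_total = edge.max();
  const int nedge = edge.n_rows;

  arma::mat L(nnode_total, k, arma::fill::ones);
  L.rows(0, ntip - 1) = tipvec;
  arma::mat contrib(nedge, k);           // per-edge P * L_child, normalized
  std::vector<arma::mat> Pmats(nedge);

  for (int e = 0; e < nedge; ++e) {
    const int parent = edge(e, 0) - 1;
    const int child  = edge(e, 1) - 1;
    arma::rowvec Lc = L.row(child);
    double s = arma::accu(Lc);
    if (s <= 0.0) stop("zero conditional likelihood below node %d", child + 1);
    Lc /= s;                             // scale freely; marginals renormalize
    Pmats[e] = pmat(Q, edge_length(e));
    arma::rowvec cb = (Pmats[e] * Lc.t()).t();
    double cs = arma::accu(cb);
    if (cs <= 0.0) stop("zero edge contribution at edge %d", e + 1);
    contrib.row(e) = cb / cs;
    L.row(parent) %= contrib.row(e);
  }

  const int root = ntip;
  arma::mat G(nnode_total, k, arma::fill::zeros);   // outside partials
  G.row(root) = pi.t();

  // preorder = reverse postorder on edges
  for (int e = nedge - 1; e >= 0; --e) {
    const int parent = edge(e, 0) - 1;
    const int child  = edge(e, 1) - 1;
    // sibling product: L[parent] held the product of ALL child contributions
    // after the down pass; divide this edge's own contribution back out,
    // guarding zeros by explicit recomputation when needed.
    arma::rowvec sib(k);
    bool safe = true;
    for (int s = 0; s < k; ++s) {
      if (contrib(e, s) <= 0.0) { safe = false; break; }
      sib(s) = L(parent, s) / contrib(e, s);
    }
    if (!safe) {
      sib.ones();
      for (int e2 = 0; e2 < nedge; ++e2)
        if (edge(e2, 0) - 1 == parent && e2 != e) sib %= contrib.row(e2);
    }
    arma::rowvec gtilde = G.row(parent) % sib;
    arma::rowvec gc = (gtilde * Pmats[e]);
    double gs = arma::accu(gc);
    if (gs > 0.0) gc /= gs;
    G.row(child) = gc;
  }

  arma::mat M = G % L;                   // unnormalized joint at each node
  M.row(root) = pi.t() % L.row(root);
  for (int v = 0; v < nnode_total; ++v) {
    double s = arma::accu(M.row(v));
    if (s <= 0.0) stop("non-positive marginal at node %d", v + 1);
    M.row(v) /= s;
  }
  return M;
}
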