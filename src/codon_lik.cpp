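// Felsenstein pruning over the 61 sense codons for a GY94 process.
// The caller supplies the single-nucleotide pair-type matrix (precomputed
// once in R), per-edge omega values (branch-site models make these differ
// on the foreground edge) and branch lengths already expressed on the
// desired rate scale.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void build_Q(double kappa, double omega, const vec& pi,
                    const imat& pairtype, mat& Q) {
  const uword n = pi.n_elem;
  double mult[5] = {0.0, 1.0, kappa, omega, kappa * omega};
  Q.zeros(n, n);
  for (uword i = 0; i < n; ++i) {
    double rowsum = 0.0;
    for (uword j = 0; j < n; ++j) {
      if (i == j) continue;
      double q = mult[pairtype(i, j)] * pi(j);
      Q(i, j) = q;
      rowsum += q;
    }
    Q(i, i) = -rowsum;
  }
}

struct EigQ {
  mat U;       // eigenvectors of the symmetrized generator
  vec lam;     // eigenvalues
};

static EigQ eig_for_omega(double kappa, double omega, const vec& pi,
                          const imat& pairtype) {
  const uword n = pi.n_elem;
  mat Q;
  build_Q(kappa, omega, pi, pairtype, Q);
  vec d = sqrt(pi);
  mat B = Q;
  for (uword i = 0; i < n; ++i)
    for (uword j = 0; j < n; ++j)
      B(i, j) *= d(i) / d(j);
  B = 0.5 * (B + B.t());
  EigQ e;
  eig_sym(e.lam, e.U, B);
  return e;
}

static mat pmat_from_eig(const EigQ& e, const vec& pi, double t) {
  vec d = sqrt(pi);
  mat P = e.U * diagmat(exp(e.lam * t)) * e.U.t();
  const uword n = pi.n_elem;
  for (uword i = 0; i < n; ++i)
    for (uword j = 0; j < n; ++j) {
      double v = P(i, j) * d(j) / d(i);
      P(i, j) = v < 0 ? 0.0 : v;
    }
  // renormalize rows (numerical guard)
  P.each_col() /= sum(P, 1);
  return P;
}

// Shared worker: pruning for one omega-per-edge assignment using a cache
// of eigen decompositions keyed by omega.
static vec prune_once(const imat& tipdata, const imat& edge, const vec& blen,
                      const vec& omega_edge, double kappa, const vec& pi,
                      const imat& pairtype, int nnode,
                      std::map<double, EigQ>& cache) {
  const uword n = pi.n_elem;
  const uword npat = tipdata.n_cols;
  const uword ntip = tipdata.n_rows;
  const uword nedge = edge.n_rows;

  for (uword e = 0; e < nedge; ++e) {
    double w = omega_edge(e);
    if (cache.find(w) == cache.end())
      cache[w] = eig_for_omega(kappa, w, pi, pairtype);
  }

  std::vector<mat> partial(nnode);
  std::vector<bool> used(nnode, false);
  vec logscale(npat, fill::zeros);

  for (uword e = 0; e < nedge; ++e) {
    int par = edge(e, 0) - 1;
    int child = edge(e, 1) - 1;
    mat P = pmat_from_eig(cache[omega_edge(e)], pi, blen(e));
    mat contrib(n, npat);
    if ((uword)child < ntip) {
      for (uword p = 0; p < npat; ++p) {
        int s = tipdata(child, p);
        if (s < 0)
          contrib.col(p) = ones<vec>(n);   // gap = missing data
        else
          contrib.col(p) = P.col(s);
      }
    } else {
      contrib = P * partial[child];
      partial[child].reset();
    }
    if (!used[par]) {
      partial[par] = contrib;
      used[par] = true;
    } else {
      partial[par] %= contrib;
    }
    if (e % 4 == 3 || e == nedge - 1) {
      rowvec mx = max(partial[par], 0);
      for (uword p = 0; p < npat; ++p) {
        double m = mx(p);
        if (m > 0 && m < 1e-200) {
          partial[par].col(p) /= m;
          logscale(p) += std::log(m);
        }
      }
    }
  }

  int root = edge(nedge - 1, 0) - 1;
  vec out(npat);
  for (uword p = 0; p < npat; ++p)
    out(p) = std::log(dot(pi, partial[root].col(p))) + logscale(p);
  return out;
}

// Per-pattern log-likelihood for several site classes in one call.
// omega_mat: nedge x nclass, per-edge omega for each class (branch-site
// classes differ on the foreground edge). Eigen decompositions are shared
// across classes through the cache.
// [[Rcpp::export]]
arma::mat cr_site_loglik_classes(const arma::imat& tipdata,
                                 const arma::imat& edge,
                                 const arma::vec& blen,
                                 const arma::mat& omega_mat, double kappa,
                                 const arma::vec& pi,
                                 const arma::imat& pairtype, int nnode) {
  const uword ncls = omega_mat.n_cols;
  mat out(tipdata.n_cols, ncls);
  std::map<double, EigQ> cache;
  for (uword k = 0; k < ncls; ++k)
    out.col(k) = prune_once(tipdata, edge, blen, omega_mat.col(k), kappa,
                            pi, pairtype, nnode, cache);
  return out;
}

// tipdata: ntip x npat, 0-based codon index, -1 for gap/missing.
// edge: nedge x 2 (parent, child), 1-based node indices, ordered so that
// every child edge appears before the edge above it (children first).
// Returns per-pattern log-likelihood at the root.
// [[Rcpp::export]]
arma::vec cr_site_loglik(const arma::imat& tipdata, const arma::imat& edge,
                         const arma::vec& blen, const arma::vec& omega_edge,
                         double kappa, const arma::vec& pi,
                         const arma::imat& pairtype, int nnode) {
  std::map<double, EigQ> cache;
  return prune_once(tipdata, edge, blen, omega_edge, kappa, pi, pairtype,
                    nnode, cache);
}
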