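// Felsenstein pruning for discrete-state likelihoods on rooted trees.
//
// Two entry points: a closed-form two-state chain (the Mk1 / asymmetric
// binary model) and a general k-state chain driven by an arbitrary rate
// matrix (the 4-state joint chain of Pagel's correlated-evolution test).
// Edge matrices follow ape conventions (1-based ids, tips 1..ntip) and must
// be supplied in postorder so each child is complete before its parent.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double SCALE_FLOOR = 1e-140;

// [[Rcpp::export]]
double cpp_loglik_2state(const IntegerMatrix& edge,
                         const NumericVector& el,
                         int ntip,
                         const NumericMatrix& tipL,
                         double q01, double q10,
                         const NumericVector& prior) {
  const int nedge = edge.nrow();
  const int nnode = ntip + nedge; // upper bound; actual ids <= ntip + Nnode
  arma::mat L(nnode + 1, 2);      // 1-based indexing; row 0 unused
  L.fill(1.0);
  for (int i = 0; i < ntip; ++i) {
    L(i + 1, 0) = tipL(i, 0);
    L(i + 1, 1) = tipL(i, 1);
  }
  arma::vec logscale(nnode + 1, arma::fill::zeros);

  const double r = q01 + q10;
  for (int e = 0; e < nedge; ++e) {
    const int par = edge(e, 0), chi = edge(e, 1);
    const double t = el[e];
    // P(t) = stationary + decaying part; reduces to the Mk1 closed form
    // (1/2 +/- exp(-2qt)/2) when q01 == q10.
    double p00, p01, p10, p11;
    if (r <= 0.0) {
      p00 = 1.0; p01 = 0.0; p10 = 0.0; p11 = 1.0;
    } else {
      const double ex = std::exp(-r * t);
      p01 = (q01 / r) * (1.0 - ex);
      p00 = 1.0 - p01;
      p10 = (q10 / r) * (1.0 - ex);
      p11 = 1.0 - p10;
    }
    const double c0 = p00 * L(chi, 0) + p01 * L(chi, 1);
    const double c1 = p10 * L(chi, 0) + p11 * L(chi, 1);
    L(par, 0) *= c0;
    L(par, 1) *= c1;
    logscale(par) += logscale(chi);
    const double m = std::max(L(par, 0), L(par, 1));
    if (m < SCALE_FLOOR && m > 0.0) {
      L(par, 0) /= m; L(par, 1) /= m;
      logscale(par) += std::log(m);
    }
  }
  const int root = edge(nedge - 1, 0);
  const double lik = prior[0] * L(root, 0) + prior[1] * L(root, 1);
  if (lik <= 0.0) return -std::numeric_limits<double>::infinity();
  return std::log(lik) + logscale(root);
}

// Transition matrix machinery for a general rate matrix: eigendecompose Q
// once per likelihood evaluation, then P(t) = Re(V exp(Lambda t) V^-1) per
// edge.  Falls back to scaling-and-squaring if Q is numerically defective.
struct QExp {
  bool use_eig;
  arma::cx_mat V, Vinv;
  arma::cx_vec lambda;
  arma::mat Q;
  explicit QExp(const arma::mat& Qm) : Q(Qm) {
    use_eig = false;
    arma::cx_vec eval;
    arma::cx_mat evec;
    if (arma::eig_gen(eval, evec, Qm)) {
      arma::cx_mat inv;
      if (arma::inv(inv, evec)) {
        // accept the decomposition only if it reproduces Q
        arma::mat recon = arma::real(evec * arma::diagmat(eval) * inv);
        if (arma::norm(recon - Qm, "fro") <
            1e-8 * (1.0 + arma::norm(Qm, "fro"))) {
          V = evec; Vinv = inv; lambda = eval; use_eig = true;
        }
      }
    }
  }
  arma::mat P(double t) const {
    arma::mat out;
    if (use_eig) {
      arma::cx_vec e = arma::exp(lambda * t);
      out = arma::real(V * arma::diagmat(e) * Vinv);
    } else {
      out = arma::expmat(Q * t);
    }
    out.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    // renormalise rows (guards tiny eigendecomposition error)
    for (arma::uword i = 0; i < out.n_rows; ++i) {
      double s = arma::accu(out.row(i));
      if (s > 0.0) out.row(i) /= s;
    }
    return out;
  }
};

// Negative log-likelihood of the dependent Pagel model as a function of the
// eight log-rates (order q12, q13, q21, q24, q31, q34, q42, q43). This is
// the optimiser's inner loop, so the 4x4 eigendecomposition propagation is
// hand-unrolled on fixed-size arrays.
static double pagel_negll_core(const double* logrates,
                               const IntegerMatrix& edge,
                               const NumericVector& el,
                               int ntip,
                               const NumericMatrix& tipL,
                               const NumericVector& prior) {
  double r[8];
  for (int i = 0; i < 8; ++i) r[i] = std::exp(logrates[i]);
  arma::mat Q(4, 4, arma::fill::zeros);
  Q(0, 1) = r[0]; Q(0, 2) = r[1];
  Q(1, 0) = r[2]; Q(1, 3) = r[3];
  Q(2, 0) = r[4]; Q(2, 3) = r[5];
  Q(3, 1) = r[6]; Q(3, 2) = r[7];
  for (int i = 0; i < 4; ++i) Q(i, i) = -arma::accu(Q.row(i));

  arma::cx_vec lam;
  arma::cx_mat V, Vinv;
  bool use_eig = arma::eig_gen(lam, V, Q) && arma::inv(Vinv, V);
  if (use_eig) {
    // cheap conditioning guard: a defective / near-defective Q has a badly
    // conditioned eigenvector basis; fall back to expmat there
    use_eig = arma::norm(V, "inf") * arma::norm(Vinv, "inf") < 1e7;
  }
  std::complex<double> Vc[4][4], Wc[4][4], lamc[4];
  if (use_eig) {
    for (int i = 0; i < 4; ++i) {
      lamc[i] = lam(i);
      for (int j = 0; j < 4; ++j) { Vc[i][j] = V(i, j); Wc[i][j] = Vinv(i, j); }
    }
  }

  const int nedge = edge.nrow();
  const int nnode = ntip + nedge;
  std::vector<double> L(4 * (nnode + 1), 1.0);
  for (int i = 0; i < ntip; ++i)
    for (int j = 0; j < 4; ++j) L[4 * (i + 1) + j] = tipL(i, j);
  std::vector<double> logscale(nnode + 1, 0.0);

  double P[4][4];
  for (int e = 0; e < nedge; ++e) {
    const int par = edge(e, 0), chi = edge(e, 1);
    const double t = el[e];
    if (use_eig) {
      std::complex<double> ex[4];
      for (int i = 0; i < 4; ++i) ex[i] = std::exp(lamc[i] * t);
      for (int i = 0; i < 4; ++i) {
        double rowsum = 0.0;
        for (int j = 0; j < 4; ++j) {
          std::complex<double> s(0.0, 0.0);
          for (int m = 0; m < 4; ++m) s += Vc[i][m] * ex[m] * Wc[m][j];
          double v = s.real();
          P[i][j] = v < 0.0 ? 0.0 : v;
          rowsum += P[i][j];
        }
        if (rowsum > 0.0)
          for (int j = 0; j < 4; ++j) P[i][j] /= rowsum;
      }
    } else {
      arma::mat Pm = arma::expmat(Q * t);
      Pm.transform([](double v) { return v < 0.0 ? 0.0 : v; });
      for (int i = 0; i < 4; ++i) {
        double rowsum = arma::accu(Pm.row(i));
        for (int j = 0; j < 4; ++j)
          P[i][j] = rowsum > 0.0 ? Pm(i, j) / rowsum : Pm(i, j);
      }
    }
    double* Lp = &L[4 * par];
    const double* Lc = &L[4 * chi];
    double mx = 0.0;
    for (int i = 0; i < 4; ++i) {
      double cond = P[i][0] * Lc[0] + P[i][1] * Lc[1] +
                    P[i][2] * Lc[2] + P[i][3] * Lc[3];
      Lp[i] *= cond;
      if (Lp[i] > mx) mx = Lp[i];
    }
    logscale[par] += logscale[chi];
    if (mx < SCALE_FLOOR && mx > 0.0) {
      for (int i = 0; i < 4; ++i) Lp[i] /= mx;
      logscale[par] += std::log(mx);
    }
  }
  const int root = edge(nedge - 1, 0);
  double lik = 0.0;
  for (int j = 0; j < 4; ++j) lik += prior[j] * L[4 * root + j];
  if (lik <= 0.0) return std::numeric_limits<double>::infinity();
  return -(std::log(lik) + logscale[root]);
}

// [[Rcpp::export]]
double cpp_pagel_negll(const NumericVector& logrates,
                       const IntegerMatrix& edge,
                       const NumericVector& el,
                       int ntip,
                       const NumericMatrix& tipL,
                       const NumericVector& prior) {
  return pagel_negll_core(&logrates[0], edge, el, ntip, tipL, prior);
}

// Forward-difference gradient of the negative log-likelihood in the eight
// log-rates, sharing the pruning core (9 evaluations per call).
// [[Rcpp::export]]
NumericVector cpp_pagel_negll_grad(const NumericVector& logrates,
                                   const IntegerMatrix& edge,
                                   const NumericVector& el,
                                   int ntip,
                                   const NumericMatrix& tipL,
                                   const NumericVector& prior) {
  const double h = 1e-6;
  double x[8];
  for (int i = 0; i < 8; ++i) x[i] = logrates[i];
  const double f0 = pagel_negll_core(x, edge, el, ntip, tipL, prior);
  NumericVector g(8);
  for (int i = 0; i < 8; ++i) {
    const double xi = x[i];
    x[i] = xi + h;
    g[i] = (pagel_negll_core(x, edge, el, ntip, tipL, prior) - f0) / h;
    x[i] = xi;
  }
  g.attr("value") = f0;
  return g;
}

// [[Rcpp::export]]
double cpp_loglik_kstate(const IntegerMatrix& edge,
                         const NumericVector& el,
                         int ntip,
                         const NumericMatrix& tipL,
                         const NumericMatrix& Qmat,
                         const NumericVector& prior) {
  const int k = Qmat.ncol();
  const int nedge = edge.nrow();
  const int nnode = ntip + nedge;
  arma::mat Q(Qmat.begin(), k, k);
  QExp qe(Q);

  arma::mat L(nnode + 1, k, arma::fill::ones);
  for (int i = 0; i < ntip; ++i)
    for (int j = 0; j < k; ++j) L(i + 1, j) = tipL(i, j);
  arma::vec logscale(nnode + 1, arma::fill::zeros);

  for (int e = 0; e < nedge; ++e) {
    const int par = edge(e, 0), chi = edge(e, 1);
    arma::mat P = qe.P(el[e]);
    arma::rowvec cond = L.row(chi) * P.t(); // cond[i] = sum_j P(i,j) L(chi,j)
    L.row(par) %= cond;
    logscale(par) += logscale(chi);
    const double m = L.row(par).max();
    if (m < SCALE_FLOOR && m > 0.0) {
      L.row(par) /= m;
      logscale(par) += std::log(m);
    }
  }
  const int root = edge(nedge - 1, 0);
  double lik = 0.0;
  for (int j = 0; j < k; ++j) lik += prior[j] * L(root, j);
  if (lik <= 0.0) return -std::numeric_limits<double>::infinity();
  return std::log(lik) + logscale(root);
}
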