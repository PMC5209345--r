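#include <Rcpp.h>
using namespace Rcpp;

// Core of the E-step: assembles the n x (G*Q) matrix of log joint terms
//   log pi_g + log w_q + sum_i log P_i(x_vi | theta_gq),
// returns the per-person log-likelihood (log-sum-exp over columns), the
// responsibilities (row softmax) and, optionally, the expected
// item-category counts (m_i + 1) x (G*Q).
//
// vals: n x I integer responses with -1 for missing.
// LP:   list of G*I matrices (Q x (m_i + 1)), item index fastest.
// The joint-term matrix is held transposed, (G*Q) x n, so every inner loop
// walks contiguous memory; the responsibilities come back in that layout
// and are transposed once on the R side.
// [[Rcpp::export(name = ".cpp_estep")]]
List cpp_estep(IntegerMatrix vals, List LP, NumericVector logpi,
               NumericVector logw, bool want_counts) {
  const int n = vals.nrow(), I = vals.ncol();
  const int G = logpi.size(), Q = logw.size();
  const int GQ = G * Q;
  NumericMatrix Bt(GQ, n);
  std::vector<double> base(GQ);
  for (int g = 0; g < G; ++g) {
    for (int q = 0; q < Q; ++q) base[g * Q + q] = logpi[g] + logw[q];
  }
  std::vector<const double *> lp(G * I);
  for (int k = 0; k < G * I; ++k) {
    NumericMatrix L = LP[k];
    lp[k] = &L(0, 0);
  }
  for (int v = 0; v < n; ++v) {
    double *col = &Bt(0, v);
    std::copy(base.begin(), base.end(), col);
    for (int i = 0; i < I; ++i) {
      const int x = vals(v, i);
      if (x < 0) continue;
      for (int g = 0; g < G; ++g) {
        const double *lcol = lp[g * I + i] + (std::size_t)x * Q;  // length Q
        double *dst = col + g * Q;
        for (int q = 0; q < Q; ++q) dst[q] += lcol[q];
      }
    }
  }

  NumericVector ll(n);
  NumericMatrix rt(GQ, n);
  for (int v = 0; v < n; ++v) {
    const double *col = &Bt(0, v);
    double *rc = &rt(0, v);
    double mx = col[0];
    for (int c = 1; c < GQ; ++c) if (col[c] > mx) mx = col[c];
    double s = 0.0;
    for (int c = 0; c < GQ; ++c) { rc[c] = std::exp(col[c] - mx); s += rc[c]; }
    for (int c = 0; c < GQ; ++c) rc[c] /= s;
    ll[v] = mx + std::log(s);
  }

  List out = List::create(Named("ll") = ll, Named("rt") = rt);
  if (want_counts) {
    List counts(I);
    for (int i = 0; i < I; ++i) {
      NumericMatrix Li = LP[i];         // only for the category count m_i + 1
      const int K = Li.ncol();
      NumericMatrix C(K, GQ);
      for (int v = 0; v < n; ++v) {
        const int x = vals(v, i);
        if (x < 0) continue;
        const double *rc = &rt(0, v);
        for (int c = 0; c < GQ; ++c) C(x, c) += rc[c];
      }
      counts[i] = C;
    }
    out["counts"] = counts;
  }
  return out;
}

// Expected complete-data log-likelihood and gradient for one item.
// C: (m+1) x Q x G counts (flattened, category fastest), theta: G x Q,
// tau: m x G, delta: length G.  Returns the objective, d/dtau (m x G) and
// d/ddelta (length G, natural scale).
// [[Rcpp::export(name = ".cpp_item_objgrad")]]
List cpp_item_objgrad(NumericVector C, NumericMatrix theta,
                      NumericMatrix tau, NumericVector delta) {
  const int m = tau.nrow(), G = theta.nrow(), Q = theta.ncol();
  const int K = m + 1;
  std::vector<double> S(K), P(K), cum(K);
  NumericMatrix gtau(m, G);
  NumericVector gdelta(G);
  double val = 0.0;

  for (int g = 0; g < G; ++g) {
    cum[0] = 0.0;
    for (int s = 0; s < m; ++s) cum[s + 1] = cum[s] + tau(s, g);
    const double d = delta[g];
    for (int q = 0; q < Q; ++q) {
      const double th = theta(g, q);
      double mx = -1e300;
      for (int x = 0; x < K; ++x) {
        S[x] = d * (th * x - cum[x]);
        if (S[x] > mx) mx = S[x];
      }
      double Z = 0.0;
      for (int x = 0; x < K; ++x) { P[x] = std::exp(S[x] - mx); Z += P[x]; }
      double Ntot = 0.0, Cx = 0.0, CA = 0.0, Abar = 0.0, logZ = std::log(Z);
      for (int x = 0; x < K; ++x) {
        P[x] /= Z;
        const double cxq = C[x + K * (q + Q * g)];
        Ntot += cxq;
        val += cxq * (S[x] - mx - logZ);
        const double A = th * x - cum[x];
        CA += cxq * A;
        Abar += P[x] * A;
      }
      gdelta[g] += CA - Ntot * Abar;
      // d/dtau_s = -delta * (#{x >= s} - Ntot * P(X >= s)), s = 1..m
      double cge = 0.0, pge = 0.0;
      for (int s = m; s >= 1; --s) {
        cge += C[s + K * (q + Q * g)];
        pge += P[s];
        gtau(s - 1, g) += -d * (cge - Ntot * pge);
      }
      (void)Cx;
    }
  }
  return List::create(Named("value") = val, Named("gtau") = gtau,
                      Named("gdelta") = gdelta);
}

// Objective for the variance update of one class: sum over items and nodes
// of counts times log P at theta = sigma * z.
// [[Rcpp::export(name = ".cpp_sigma_obj")]]
double cpp_sigma_obj(List Citems, List taus, NumericVector deltas,
                     NumericVector z, double sigma, int g, int G) {
  const int I = Citems.size(), Q = z.size();
  double val = 0.0;
  std::vector<double> S;
  for (int i = 0; i < I; ++i) {
    NumericVector C = Citems[i];
    NumericVector tau = taus[i];
    const int m = tau.size(), K = m + 1;
    const double d = deltas[i];
    std::vector<double> cum(K);
    cum[0] = 0.0;
    for (int s = 0; s < m; ++s) cum[s + 1] = cum[s] + tau[s];
    S.resize(K);
    for (int q = 0; q < Q; ++q) {
      const double th = sigma * z[q];
      double mx = -1e300;
      for (int x = 0; x < K; ++x) {
        S[x] = d * (th * x - cum[x]);
        if (S[x] > mx) mx = S[x];
      }
      double Z = 0.0;
      for (int x = 0; x < K; ++x) Z += std::exp(S[x] - mx);
      const double logZ = std::log(Z) + mx;
      for (int x = 0; x < K; ++x) {
        val += C[x + K * (q + Q * g)] * (S[x] - logZ);
      }
    }
  }
  return val;
}
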