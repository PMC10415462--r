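// Compiled core of the permutation inference: threshold-free cluster
// enhancement over a vertex adjacency graph, and the Freedman-Lane
// permutation loop for one-column GLM contrasts.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// TFCE over a CSR adjacency graph. enh(v) = sum_h e(h,v)^E * h^H * dh for
// thresholds h = dh, 2dh, ... up to stat(v); negative input maps to 0.
static arma::vec tfce_graph(const arma::vec &stat, const arma::ivec &ptr,
                            const arma::ivec &idx, double H, double E,
                            double dh) {
  const int V = stat.n_elem;
  arma::vec enh(V, arma::fill::zeros);
  double vmax = stat.max();
  if (vmax <= 0.0) return enh;
  if (dh <= 0.0) dh = vmax / 100.0;
  std::vector<int> label(V), queue(V);
  std::vector<int> members(V);
  const double eps = 1e-12;
  int nstep = (int)std::floor(vmax / dh + 1e-9);
  for (int k = 1; k <= nstep; ++k) {
    double h = k * dh;
    std::fill(label.begin(), label.end(), -1);
    double hpow = std::pow(h, H);
    for (int v = 0; v < V; ++v) {
      if (label[v] >= 0 || stat[v] < h - eps) continue;
      // BFS the suprathreshold component containing v
      int head = 0, tail = 0, csize = 0;
      queue[tail++] = v;
      label[v] = v;
      while (head < tail) {
        int u = queue[head++];
        members[csize++] = u;
        for (int e = ptr[u]; e < ptr[u + 1]; ++e) {
          int w = idx[e];
          if (label[w] < 0 && stat[w] >= h - eps) {
            label[w] = v;
            queue[tail++] = w;
          }
        }
      }
      double add = std::pow((double)csize, E) * hpow * dh;
      for (int m = 0; m < csize; ++m) enh[members[m]] += add;
    }
  }
  return enh;
}

// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector adj_ptr,
                       IntegerVector adj_idx, double H, double E, double dh) {
  arma::vec s(stat.begin(), stat.size(), false);
  arma::ivec ptr(adj_ptr.size()), idx(adj_idx.size());
  for (int i = 0; i < adj_ptr.size(); ++i) ptr[i] = adj_ptr[i];
  for (int i = 0; i < adj_idx.size(); ++i) idx[i] = adj_idx[i];
  arma::vec clamped = s;
  clamped.transform([](double x) { return x > 0.0 ? x : 0.0; });
  arma::vec out = tfce_graph(clamped, ptr, idx, H, E, dh);
  return NumericVector(out.begin(), out.end());
}

// One-column contrast t-statistics for a data matrix D (nobs x V) given the
// precomputed pieces of the OLS fit.
static arma::rowvec tvals(const arma::mat &D, const arma::mat &X,
                          const arma::mat &A, int con, double M, double df) {
  arma::mat B = A * D;                 // p x V
  arma::mat R = D - X * B;             // residuals
  arma::rowvec ss = arma::sum(arma::square(R), 0) / df;
  arma::rowvec scale = arma::mean(arma::square(D), 0);
  arma::rowvec se = arma::sqrt(ss * M);
  arma::rowvec t = B.row(con);
  for (arma::uword v = 0; v < t.n_elem; ++v) {
    // numerically-zero residual variance (constant data) -> t = 0
    bool degen = ss[v] <= 1e-20 * (scale[v] + 1e-300);
    t[v] = (se[v] > 0.0 && !degen) ? t[v] / se[v] : 0.0;
  }
  return t;
}

// Freedman-Lane permutation test for a one-column contrast; optionally the
// compared statistic is TFCE-enhanced. Returns observed maps plus
// uncorrected and max-statistic familywise-error permutation p-values.
// [[Rcpp::export(name = ".perm_core_cpp")]]
List perm_core_cpp(const arma::mat &Y, const arma::mat &X, int con,
                   const arma::imat &perms, bool use_tfce,
                   IntegerVector adj_ptr, IntegerVector adj_idx, double H,
                   double E) {
  const int nobs = Y.n_rows, V = Y.n_cols, p = X.n_cols;
  const int nperm = perms.n_rows;
  arma::mat XtXi = arma::inv_sympd(arma::symmatu(X.t() * X));
  arma::mat A = XtXi * X.t();
  double M = XtXi(con, con);
  double df = nobs - p;

  // nuisance-only residual-forming matrix
  arma::mat Z(nobs, p - 1);
  int j = 0;
  for (int c = 0; c < p; ++c)
    if (c != con) Z.col(j++) = X.col(c);
  arma::mat Rz;
  if (Z.n_cols > 0) {
    arma::mat ZtZi = arma::inv_sympd(arma::symmatu(Z.t() * Z));
    Rz = arma::eye(nobs, nobs) - Z * ZtZi * Z.t();
  } else {
    Rz = arma::eye(nobs, nobs);
  }
  arma::mat Yz = Rz * Y;

  arma::ivec ptr(adj_ptr.size()), idx(adj_idx.size());
  for (int i = 0; i < adj_ptr.size(); ++i) ptr[i] = adj_ptr[i];
  for (int i = 0; i < adj_idx.size(); ++i) idx[i] = adj_idx[i];

  arma::rowvec t_obs = tvals(Y, X, A, con, M, df);
  arma::vec stat_obs;
  if (use_tfce) {
    arma::vec tpos = t_obs.t();
    tpos.transform([](double x) { return x > 0.0 ? x : 0.0; });
    stat_obs = tfce_graph(tpos, ptr, idx, H, E, 0.0);
  } else {
    stat_obs = t_obs.t();
  }

  arma::vec count_unc(V, arma::fill::zeros);
  arma::vec max_null(nperm);
  const double eps = 1e-12;
  arma::mat D(nobs, V);
  for (int pp = 0; pp < nperm; ++pp) {
    for (int r = 0; r < nobs; ++r) D.row(r) = Yz.row(perms(pp, r));
    arma::rowvec t_p = tvals(D, X, A, con, M, df);
    arma::vec stat_p;
    if (use_tfce) {
      arma::vec tpos = t_p.t();
      tpos.transform([](double x) { return x > 0.0 ? x : 0.0; });
      stat_p = tfce_graph(tpos, ptr, idx, H, E, 0.0);
    } else {
      stat_p = t_p.t();
    }
    max_null[pp] = stat_p.max();
    for (int v = 0; v < V; ++v)
      if (stat_p[v] >= stat_obs[v] - eps) count_unc[v] += 1.0;
  }
  arma::vec p_unc = (count_unc + 1.0) / (nperm + 1.0);
  arma::vec p_fwe(V);
  for (int v = 0; v < V; ++v) {
    double c = 0;
    for (int pp = 0; pp < nperm; ++pp)
      if (max_null[pp] >= stat_obs[v] - eps) c += 1.0;
    p_fwe[v] = (c + 1.0) / (nperm + 1.0);
  }
  return List::create(
      _["t_obs"] = NumericVector(t_obs.begin(), t_obs.end()),
      _["stat_obs"] = NumericVector(stat_obs.begin(), stat_obs.end()),
      _["p_unc"] = NumericVector(p_unc.begin(), p_unc.end()),
      _["p_fwe"] = NumericVector(p_fwe.begin(), p_fwe.end()),
      _["max_null"] = NumericVector(max_null.begin(), max_null.end()));
}
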