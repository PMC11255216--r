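// Nested leave-one-participant-out cross-validation engine:
// k-best univariate edge selection (absolute Pearson correlation, ties
// broken toward the lower column index) followed by ridge regression with
// an unpenalized intercept. Feature standardization statistics are
// computed inside each training partition only, so the held-out subject
// never influences selection or weights. The inner LOPO loop picks
// (k, alpha) by mean squared error (ties: smaller k, then larger alpha).
//
// Column sums are maintained incrementally across inner folds, making a
// full nested run O(n^2 * (E + k^2 * n)) rather than O(n^2 * E * n),
// which is what keeps permutation tests and calibration simulations fast.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

static const double EPS = 1e-12;

// indices of the kmax best-scoring columns, score desc, ties index asc
static std::vector<int> top_order(const arma::vec &score, int kmax) {
  const int E = score.n_elem;
  std::vector<int> idx(E);
  std::iota(idx.begin(), idx.end(), 0);
  auto cmp = [&](int a, int b) {
    if (score[a] != score[b]) return score[a] > score[b];
    return a < b;
  };
  if (kmax < E) {
    std::nth_element(idx.begin(), idx.begin() + kmax, idx.end(), cmp);
    idx.resize(kmax);
  }
  std::sort(idx.begin(), idx.end(), cmp);
  return idx;
}

static arma::vec ridge_solve(const arma::mat &G, const arma::vec &b,
                             double alpha) {
  mat A = G;
  A.diag() += alpha;
  vec w;
  bool ok = solve(w, A, b, solve_opts::no_approx);
  if (!ok) w = pinv(A) * b; // singular unpenalized system: minimum-norm fit
  return w;
}

// |Pearson correlation| of every column with y from running sums
static void col_scores(const rowvec &s1, const rowvec &s2, const vec &sxy,
                       double sy, double syy, int n, vec &score) {
  const int E = s1.n_elem;
  const double my = sy / n;
  const double vy = syy - sy * sy / n;
  if (vy <= EPS) {
    score.zeros();
    return;
  }
  for (int e = 0; e < E; ++e) {
    double ssx = s2[e] - s1[e] * s1[e] / n;
    if (ssx <= EPS) {
      score[e] = 0.0;
      continue;
    }
    score[e] = std::fabs(sxy[e] - s1[e] * my) / std::sqrt(ssx * vy);
  }
}

struct FitResult {
  std::vector<int> sel; // 0-based column indices, ascending
  vec w;
  vec center, scale;
  double intercept;
};

static void accumulate_sums(const mat &X, const uvec &rows, const vec &y,
                            rowvec &s1, rowvec &s2, vec &sxy, double &sy,
                            double &syy) {
  const int E = X.n_cols;
  s1.zeros(E);
  s2.zeros(E);
  sxy.zeros(E);
  sy = 0.0;
  syy = 0.0;
  for (uword j = 0; j < rows.n_elem; ++j) {
    rowvec xr = X.row(rows[j]);
    double yj = y[rows[j]];
    s1 += xr;
    s2 += xr % xr;
    sxy += xr.t() * yj;
    sy += yj;
    syy += yj * yj;
  }
}

// inner LOPO grid search over (k, alpha) on the given training rows
static void inner_select(const mat &X, const uvec &rows, const vec &y,
                         const std::vector<int> &ks,
                         const std::vector<double> &alphas,
                         bool scale_features, int &best_k,
                         double &best_alpha) {
  const int ntr = rows.n_elem;
  const int E = X.n_cols;
  int kmax = std::min(*std::max_element(ks.begin(), ks.end()), E);
  const int K = ks.size(), A = alphas.size();

  rowvec s1, s2;
  vec sxy;
  double sy, syy;
  accumulate_sums(X, rows, y, s1, s2, sxy, sy, syy);

  mat sse(K, A, fill::zeros);
  vec score(E);
  vec centers(kmax), scales(kmax), zi(kmax);

  for (int j = 0; j < ntr; ++j) {
    const uword r = rows[j];
    const int n2 = ntr - 1;
    rowvec xr = X.row(r);
    rowvec s1p = s1 - xr;
    rowvec s2p = s2 - xr % xr;
    vec sxyp = sxy - xr.t() * y[r];
    double syp = sy - y[r], syyp = syy - y[r] * y[r];
    col_scores(s1p, s2p, sxyp, syp, syyp, n2, score);
    std::vector<int> ord = top_order(score, kmax);
    const double my = syp / n2;

    for (int c = 0; c < kmax; ++c) {
      int col = ord[c];
      double mean = s1p[col] / n2;
      double ss = s2p[col] - s1p[col] * s1p[col] / n2;
      centers[c] = mean;
      scales[c] = (scale_features && ss > EPS) ? std::sqrt(ss / (n2 - 1)) : 1.0;
    }
    mat Z(n2, kmax);
    vec yc(n2);
    int zr = 0;
    for (int jj = 0; jj < ntr; ++jj) {
      if (jj == j) continue;
      const uword rr = rows[jj];
      for (int c = 0; c < kmax; ++c)
        Z(zr, c) = (X(rr, ord[c]) - centers[c]) / scales[c];
      yc[zr] = y[rr] - my;
      ++zr;
    }
    for (int c = 0; c < kmax; ++c)
      zi[c] = (X(r, ord[c]) - centers[c]) / scales[c];

    mat G = Z.t() * Z;
    vec bfull = Z.t() * yc;
    for (int ki = 0; ki < K; ++ki) {
      int k = std::min(ks[ki], kmax);
      mat Gk = G.submat(0, 0, k - 1, k - 1);
      vec bk = bfull.head(k);
      for (int ai = 0; ai < A; ++ai) {
        vec w = ridge_solve(Gk, bk, alphas[ai]);
        double pred = my + dot(zi.head(k), w);
        double e = pred - y[r];
        sse(ki, ai) += e * e;
      }
    }
  }

  // smaller k wins ties, then larger alpha (alphas are sorted ascending)
  double best = datum::inf;
  best_k = std::min(ks[0], kmax);
  best_alpha = alphas[A - 1];
  for (int ki = 0; ki < K; ++ki) {
    for (int ai = A - 1; ai >= 0; --ai) {
      if (sse(ki, ai) < best) {
        best = sse(ki, ai);
        best_k = std::min(ks[ki], kmax);
        best_alpha = alphas[ai];
      }
    }
  }
}

// select + standardize + ridge with fixed (k, alpha) on the given rows
static FitResult fit_fixed(const mat &X, const uvec &rows, const vec &y,
                           int k, double alpha, bool scale_features) {
  const int ntr = rows.n_elem;
  const int E = X.n_cols;
  k = std::min(k, E);

  rowvec s1, s2;
  vec sxy;
  double sy, syy;
  accumulate_sums(X, rows, y, s1, s2, sxy, sy, syy);
  vec score(E);
  col_scores(s1, s2, sxy, sy, syy, ntr, score);
  std::vector<int> sel = top_order(score, k);
  std::sort(sel.begin(), sel.end());

  FitResult fr;
  fr.sel = sel;
  fr.center.set_size(k);
  fr.scale.set_size(k);
  const double my = sy / ntr;
  for (int c = 0; c < k; ++c) {
    int col = sel[c];
    double mean = s1[col] / ntr;
    double ss = s2[col] - s1[col] * s1[col] / ntr;
    fr.center[c] = mean;
    fr.scale[c] = (scale_features && ss > EPS) ? std::sqrt(ss / (ntr - 1)) : 1.0;
  }
  mat Z(ntr, k);
  vec yc(ntr);
  for (int j = 0; j < ntr; ++j) {
    const uword r = rows[j];
    for (int c = 0; c < k; ++c)
      Z(j, c) = (X(r, sel[c]) - fr.center[c]) / fr.scale[c];
    yc[j] = y[r] - my;
  }
  fr.w = ridge_solve(Z.t() * Z, Z.t() * yc, alpha);
  fr.intercept = my;
  return fr;
}

static double predict_row(const mat &X, uword r, const FitResult &fr) {
  double pred = fr.intercept;
  for (size_t c = 0; c < fr.sel.size(); ++c)
    pred += fr.w[c] * (X(r, fr.sel[c]) - fr.center[c]) / fr.scale[c];
  return pred;
}

static double pearson_r(const vec &a, const vec &b) {
  double sa = stddev(a), sb = stddev(b);
  if (sa <= EPS || sb <= EPS) return 0.0;
  return as_scalar(cor(a, b));
}

// outer LOPO loop: per-fold inner selection, fit, and held-out prediction
static vec outer_predictions(const mat &X, const vec &y,
                             const std::vector<int> &ks,
                             const std::vector<double> &alphas,
                             bool scale_features,
                             std::vector<int> *fold_k = nullptr,
                             std::vector<double> *fold_alpha = nullptr,
                             std::vector<FitResult> *fold_fits = nullptr) {
  const int n = X.n_rows;
  vec pred(n);
  uvec all = regspace<uvec>(0, n - 1);
  for (int o = 0; o < n; ++o) {
    uvec tr = find(all != (uword)o);
    int bk;
    double ba;
    inner_select(X, tr, y, ks, alphas, scale_features, bk, ba);
    FitResult fr = fit_fixed(X, tr, y, bk, ba, scale_features);
    pred[o] = predict_row(X, o, fr);
    if (fold_k) fold_k->push_back(bk);
    if (fold_alpha) fold_alpha->push_back(ba);
    if (fold_fits) fold_fits->push_back(fr);
  }
  return pred;
}

// [[Rcpp::export]]
List cpp_nested_cv(const arma::mat &X, const arma::vec &y, IntegerVector ks,
                   NumericVector alphas, bool keep_fold_models = false,
                   bool scale_features = false) {
  std::vector<int> ksv = as<std::vector<int>>(ks);
  std::vector<double> av = as<std::vector<double>>(alphas);

  std::vector<int> fold_k;
  std::vector<double> fold_alpha;
  std::vector<FitResult> fold_fits;
  vec pred = outer_predictions(X, y, ksv, av, scale_features, &fold_k,
                               &fold_alpha,
                               keep_fold_models ? &fold_fits : nullptr);

  // final hyperparameters: inner criterion applied to the full sample
  uvec all = regspace<uvec>(0, X.n_rows - 1);
  int final_k;
  double final_alpha;
  inner_select(X, all, y, ksv, av, scale_features, final_k, final_alpha);
  FitResult fin = fit_fixed(X, all, y, final_k, final_alpha, scale_features);

  List fold_models;
  if (keep_fold_models) {
    fold_models = List(fold_fits.size());
    for (size_t i = 0; i < fold_fits.size(); ++i) {
      fold_models[i] = List::create(
          _["selected"] = wrap(fold_fits[i].sel),
          _["weights"] = fold_fits[i].w, _["center"] = fold_fits[i].center,
          _["scale"] = fold_fits[i].scale,
          _["intercept"] = fold_fits[i].intercept);
    }
  }
  return List::create(
      _["outer_pred"] = pred, _["fold_k"] = wrap(fold_k),
      _["fold_alpha"] = wrap(fold_alpha), _["final_k"] = final_k,
      _["final_alpha"] = final_alpha, _["selected"] = wrap(fin.sel),
      _["weights"] = fin.w, _["center"] = fin.center, _["scale"] = fin.scale,
      _["intercept"] = fin.intercept, _["fold_models"] = fold_models);
}

// Null distribution of the internal LOPO correlation: one full nested
// rerun per column of Yperm (each a permutation of the target).
// [[Rcpp::export]]
arma::vec cpp_perm_null(const arma::mat &X, const arma::mat &Yperm,
                        IntegerVector ks, NumericVector alphas,
                        bool scale_features = false) {
  std::vector<int> ksv = as<std::vector<int>>(ks);
  std::vector<double> av = as<std::vector<double>>(alphas);
  const int B = Yperm.n_cols;
  vec out(B);
  for (int b = 0; b < B; ++b) {
    vec yb = Yperm.col(b);
    vec pred = outer_predictions(X, yb, ksv, av, scale_features);
    out[b] = pearson_r(pred, yb);
    if (b % 8 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
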