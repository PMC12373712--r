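// Shrinkage-regularized linear discriminant engine for searchlight
// decoding. The pooled within-class covariance of each sphere is shrunk
// toward a scaled identity with the Ledoit-Wolf analytic coefficient,
// which keeps the discriminant well-defined when sphere size approaches
// or exceeds the balanced training count. Ties (discriminant exactly 0)
// go to class 0, the first class in sorted label order.
//
// Performance: per train/test split the class-centered Gram matrix over
// ALL retained voxels is computed once; every sphere's covariance is a
// submatrix slice of it. This makes per-iteration recomputation of the
// whole map, as the permutation null requires, tractable on one core.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct SplitContext {
  mat Z;       // training rows, class means removed (n x V)
  mat G;       // Z' * Z (V x V)
  mat Z2;      // elementwise Z^2
  rowvec m0, m1;
  mat Xte;     // test rows (m x V)
  uvec yte;
  double n;
};

static void build_context(const mat& Xtr_full, const mat& Xte_full,
                          const uvec& tr, const uvec& te,
                          const uvec& ytr_full, const uvec& yte_full,
                          SplitContext& ctx) {
  mat Xtr = Xtr_full.rows(tr);
  uvec y = ytr_full.elem(tr);
  uvec i0 = find(y == 0), i1 = find(y == 1);
  ctx.m0 = mean(Xtr.rows(i0), 0);
  ctx.m1 = mean(Xtr.rows(i1), 0);
  ctx.Z = Xtr;
  for (uword i = 0; i < i0.n_elem; ++i) ctx.Z.row(i0(i)) -= ctx.m0;
  for (uword i = 0; i < i1.n_elem; ++i) ctx.Z.row(i1(i)) -= ctx.m1;
  ctx.G = ctx.Z.t() * ctx.Z;
  ctx.Z2 = square(ctx.Z);
  ctx.Xte = Xte_full.rows(te);
  ctx.yte = yte_full.elem(te);
  ctx.n = static_cast<double>(Xtr.n_rows);
}

// scratch buffers reused across sphere fits (avoids per-fit allocation)
struct Workspace {
  std::vector<double> S, w, delta, rs;
  void reserve(size_t p, size_t n) {
    if (S.size() < p * p) S.resize(p * p);
    if (w.size() < p) { w.resize(p); delta.resize(p); }
    if (rs.size() < n) rs.resize(n);
  }
};

// in-place lower Cholesky; returns false if not positive definite
static bool chol_solve(std::vector<double>& A, const std::vector<double>& b,
                       std::vector<double>& x, int p) {
  for (int j = 0; j < p; ++j) {
    double d = A[j * p + j];
    for (int k = 0; k < j; ++k) d -= A[j * p + k] * A[j * p + k];
    if (d <= 0) return false;
    d = std::sqrt(d);
    A[j * p + j] = d;
    for (int i = j + 1; i < p; ++i) {
      double s = A[i * p + j];
      for (int k = 0; k < j; ++k) s -= A[i * p + k] * A[j * p + k];
      A[i * p + j] = s / d;
    }
  }
  // forward: L y = b, then backward: L' x = y (x aliases work vector)
  for (int i = 0; i < p; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= A[i * p + k] * x[k];
    x[i] = s / A[i * p + i];
  }
  for (int i = p - 1; i >= 0; --i) {
    double s = x[i];
    for (int k = i + 1; k < p; ++k) s -= A[k * p + i] * x[k];
    x[i] = s / A[i * p + i];
  }
  return true;
}

// accuracy of one sphere under a prepared split
static double sphere_accuracy(const SplitContext& ctx, const uvec& sph,
                              Workspace& ws) {
  const int p = static_cast<int>(sph.n_elem);
  const int n = static_cast<int>(ctx.n);
  ws.reserve(p, n);

  // S = pooled within-class covariance submatrix, sliced from the Gram
  double tr_s = 0, ss = 0;
  for (int j = 0; j < p; ++j) {
    const double* gcol = ctx.G.colptr(sph(j));
    for (int i = 0; i < p; ++i) {
      double v = gcol[sph(i)] / ctx.n;
      ws.S[j * p + i] = v;
      ss += v * v;
    }
    tr_s += ws.S[j * p + j];
  }
  const double mu = tr_s / p;
  const double d2 = ss - p * mu * mu; // ||S - mu I||_F^2

  for (int j = 0; j < p; ++j) {
    ws.delta[j] = ctx.m1(sph(j)) - ctx.m0(sph(j));
  }

  bool ok = false;
  if (mu > 0) {
    // Ledoit-Wolf: b2 from per-row squared norms of the centered data
    std::fill(ws.rs.begin(), ws.rs.begin() + n, 0.0);
    for (int j = 0; j < p; ++j) {
      const double* zcol = ctx.Z2.colptr(sph(j));
      for (int i = 0; i < n; ++i) ws.rs[i] += zcol[i];
    }
    double rs2 = 0;
    for (int i = 0; i < n; ++i) rs2 += ws.rs[i] * ws.rs[i];
    double b2 = rs2 / (ctx.n * ctx.n) - ss / ctx.n;
    if (b2 < 0) b2 = 0;
    double lambda = 1.0;
    if (d2 > 0) {
      if (b2 > d2) b2 = d2;
      lambda = b2 / d2;
    }
    for (int j = 0; j < p; ++j) {
      for (int i = 0; i < p; ++i) ws.S[j * p + i] *= (1.0 - lambda);
      ws.S[j * p + j] += lambda * mu;
    }
    ok = chol_solve(ws.S, ws.delta, ws.w, p);
  }
  if (!ok) {
    // zero within-class scatter: LDA limit is the nearest-mean rule
    for (int j = 0; j < p; ++j) ws.w[j] = ws.delta[j];
  }
  double thresh = 0;
  for (int j = 0; j < p; ++j) {
    thresh += 0.5 * ws.w[j] * (ctx.m0(sph(j)) + ctx.m1(sph(j)));
  }
  const int m = static_cast<int>(ctx.Xte.n_rows);
  int hits = 0;
  for (int i = 0; i < m; ++i) {
    double s = 0;
    for (int j = 0; j < p; ++j) s += ctx.Xte(i, sph(j)) * ws.w[j];
    int pred = (s - thresh) > 0 ? 1 : 0;
    if (pred == static_cast<int>(ctx.yte(i))) ++hits;
  }
  return static_cast<double>(hits) / m;
}

static std::vector<uvec> convert_spheres(const Rcpp::List& spheres) {
  std::vector<uvec> sph(spheres.size());
  for (int s = 0; s < spheres.size(); ++s) {
    sph[s] = conv_to<uvec>::from(Rcpp::as<ivec>(spheres[s])) - 1;
  }
  return sph;
}

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_lda_predict(const arma::mat& Xtr,
                                    const arma::ivec& ytr,
                                    const arma::mat& Xte) {
  SplitContext ctx;
  uvec all_tr = regspace<uvec>(0, Xtr.n_rows - 1);
  uvec all_te = regspace<uvec>(0, Xte.n_rows - 1);
  uvec y = conv_to<uvec>::from(ytr);
  uvec dummy = zeros<uvec>(Xte.n_rows);
  build_context(Xtr, Xte, all_tr, all_te, y, dummy, ctx);
  uvec sph = regspace<uvec>(0, Xtr.n_cols - 1);
  // reuse sphere_accuracy's discriminant by recomputing predictions here
  const uword p = sph.n_elem;
  mat S = ctx.G / ctx.n;
  const double mu = trace(S) / p;
  const double d2 = accu(square(S)) - p * mu * mu;
  vec delta = (ctx.m1 - ctx.m0).t();
  vec w;
  bool ok = false;
  if (mu > 0) {
    vec rs = sum(ctx.Z2, 1);
    double b2 = dot(rs, rs) / (ctx.n * ctx.n) - accu(square(S)) / ctx.n;
    if (b2 < 0) b2 = 0;
    double lambda = 1.0;
    if (d2 > 0) {
      if (b2 > d2) b2 = d2;
      lambda = b2 / d2;
    }
    mat Sstar = (1.0 - lambda) * S;
    Sstar.diag() += lambda * mu;
    ok = solve(w, Sstar, delta, solve_opts::likely_sympd + solve_opts::no_approx);
  }
  if (!ok) w = delta;
  const double thresh = 0.5 * dot(w, (ctx.m0 + ctx.m1).t());
  vec score = Xte * w;
  Rcpp::IntegerVector pred(Xte.n_rows);
  for (uword i = 0; i < score.n_elem; ++i) {
    pred[i] = (score(i) - thresh) > 0 ? 1 : 0;
  }
  return pred;
}

// Accuracy of every sphere under every train/test split.
// spheres: list of 1-based column index vectors into Xtr_full / Xte_full
// train_idx: list of 1-based row indices into Xtr_full (balanced sets)
// test_idx:  list of 1-based row indices into Xte_full (split s pairs
//            train_idx[s] with test_idx[s])
// Returns an n_spheres x n_splits accuracy matrix.
// [[Rcpp::export]]
arma::mat cpp_sphere_split_accuracy(const arma::mat& Xtr_full,
                                    const arma::mat& Xte_full,
                                    const Rcpp::List& spheres,
                                    const Rcpp::List& train_idx,
                                    const Rcpp::List& test_idx,
                                    const arma::ivec& ytr_full,
                                    const arma::ivec& yte_full) {
  const int n_spl = train_idx.size();
  if (test_idx.size() != n_spl)
    Rcpp::stop("train_idx and test_idx must have the same length");
  std::vector<uvec> sph = convert_spheres(spheres);
  uvec ytr = conv_to<uvec>::from(ytr_full);
  uvec yte = conv_to<uvec>::from(yte_full);

  mat acc(sph.size(), n_spl);
  SplitContext ctx;
  Workspace ws;
  for (int k = 0; k < n_spl; ++k) {
    uvec tr = conv_to<uvec>::from(Rcpp::as<ivec>(train_idx[k])) - 1;
    uvec te = conv_to<uvec>::from(Rcpp::as<ivec>(test_idx[k])) - 1;
    build_context(Xtr_full, Xte_full, tr, te, ytr, yte, ctx);
    for (size_t s = 0; s < sph.size(); ++s) {
      acc(s, k) = sphere_accuracy(ctx, sph[s], ws);
    }
  }
  return acc;
}

// mean of the top-`round(frac * n_surviving)` (half-up, floor 1) sphere
// accuracies above `cutoff`; ties at the boundary resolved toward the
// lower sphere index (spheres arrive in ascending center order). Returns
// `cutoff` when nothing survives.
static double selected_mean(const vec& acc, double cutoff, double frac) {
  uvec surv = find(acc > cutoff);
  if (surv.n_elem == 0) return cutoff;
  int k = static_cast<int>(std::floor(frac * surv.n_elem + 0.5));
  if (k < 1) k = 1;
  vec a = acc.elem(surv);
  // stable sort descending: stable_sort_index on -a keeps index order at ties
  uvec ord = stable_sort_index(-a);
  double total = 0;
  for (int i = 0; i < k; ++i) total += a(ord(i));
  return total / k;
}

// Permutation-null distribution in one call. For iteration j the engine
// computes every sphere's mean accuracy over that iteration's splits,
// then either reselects the top spheres (reselect = true) or averages
// over the fixed `centers_idx` (1-based sphere positions).
// iter_train / iter_test: per-iteration lists of per-split 1-based row
// indices; ytr / yte: one label column (0/1) per iteration.
// [[Rcpp::export]]
arma::vec cpp_perm_null(const arma::mat& Xtr_full,
                        const arma::mat& Xte_full,
                        const Rcpp::List& spheres,
                        const Rcpp::List& iter_train,
                        const Rcpp::List& iter_test,
                        const arma::imat& ytr,
                        const arma::imat& yte,
                        double cutoff, double top_fraction,
                        bool reselect,
                        const arma::ivec& centers_idx) {
  const int n_iter = iter_train.size();
  std::vector<uvec> sph = convert_spheres(spheres);
  vec out(n_iter);
  SplitContext ctx;
  Workspace ws;
  for (int j = 0; j < n_iter; ++j) {
    Rcpp::List tr_j = iter_train[j];
    Rcpp::List te_j = iter_test[j];
    uvec ytr_j = conv_to<uvec>::from(ivec(ytr.col(j)));
    uvec yte_j = conv_to<uvec>::from(ivec(yte.col(j)));
    vec acc(sph.size(), fill::zeros);
    const int n_spl = tr_j.size();
    for (int k = 0; k < n_spl; ++k) {
      uvec tr = conv_to<uvec>::from(Rcpp::as<ivec>(tr_j[k])) - 1;
      uvec te = conv_to<uvec>::from(Rcpp::as<ivec>(te_j[k])) - 1;
      build_context(Xtr_full, Xte_full, tr, te, ytr_j, yte_j, ctx);
      for (size_t s = 0; s < sph.size(); ++s) {
        acc(s) += sphere_accuracy(ctx, sph[s], ws);
      }
    }
    acc /= n_spl;
    if (reselect) {
      out(j) = selected_mean(acc, cutoff, top_fraction);
    } else {
      double total = 0;
      for (uword i = 0; i < centers_idx.n_elem; ++i) {
        total += acc(centers_idx(i) - 1);
      }
      out(j) = total / centers_idx.n_elem;
    }
    if (j % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
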