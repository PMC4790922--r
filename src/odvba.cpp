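// Core numerical kernels: the non-negative discriminative projection (NDP)
// solver, the whole-brain tallied-statistic map evaluated over many group
// relabelings, and 3D connected-component labeling.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct NdpFit {
  vec w;
  double f;
  int iters;
  bool converged;
};

// Clip negatives to zero and renormalize to the unit sphere.
// Returns false if the clipped vector is identically zero.
bool project_feasible(vec &w) {
  w.transform([](double x) { return x > 0.0 ? x : 0.0; });
  double n = norm(w);
  if (n <= 0.0) return false;
  w /= n;
  return true;
}

// Projected gradient ascent with backtracking for
//   max f(w) = w' A w   s.t.  w >= 0, ||w||_2 = 1
// from one feasible start. The accepted objective sequence is non-decreasing.
NdpFit pg_ascend(const mat &A, vec w, int max_iter, double tol) {
  double f = as_scalar(w.t() * A * w);
  double eta = 1.0 / (norm(A, "fro") + 1e-12);
  int it = 0;
  bool conv = false;
  for (; it < max_iter; ++it) {
    vec g = 2.0 * (A * w);
    double step = eta;
    bool accepted = false;
    vec wnew;
    double fnew = f;
    for (int b = 0; b < 40; ++b) {
      vec v = w + step * g;
      if (!project_feasible(v)) { step *= 0.5; continue; }
      double fv = as_scalar(v.t() * A * v);
      if (fv >= f) {
        wnew = v; fnew = fv; accepted = true;
        eta = step * 1.5;
        break;
      }
      step *= 0.5;
    }
    if (!accepted) { conv = true; break; }  // no uphill feasible step remains
    double impr = fnew - f;
    w = wnew; f = fnew;
    if (impr <= tol) { conv = true; ++it; break; }
  }
  return {w, f, it, conv};
}

// Multi-start NDP solve: runs pg_ascend from each feasible column of
// `starts`, and always considers the best single-coordinate solution
// argmax_i A_ii (the collapse fallback). Best objective wins.
NdpFit ndp_solve_impl(const mat &A, const mat &starts, int max_iter, double tol) {
  NdpFit best;
  best.f = -datum::inf;
  best.iters = 0;
  best.converged = true;
  for (uword k = 0; k < starts.n_cols; ++k) {
    vec w0 = starts.col(k);
    if (!project_feasible(w0)) continue;
    NdpFit fit = pg_ascend(A, w0, max_iter, tol);
    if (fit.f > best.f) best = fit;
  }
  uword imax = A.diag().index_max();
  if (best.f < A(imax, imax) || !best.w.is_finite() || best.w.n_elem == 0) {
    vec e = zeros<vec>(A.n_rows);
    e(imax) = 1.0;
    best.w = e;
    best.f = A(imax, imax);
    best.iters = 0;
    best.converged = true;
  }
  return best;
}

// Default deterministic starts for a scatter-derived objective
// A = S_b - lambda S_w with S_b = d d': uniform, the clipped +/- d
// directions, and the dominant diagonal coordinate.
mat default_starts(const mat &A, const vec &d) {
  uword m = A.n_rows;
  mat S(m, 4, fill::zeros);
  S.col(0).fill(1.0 / std::sqrt((double)m));
  S.col(1) = clamp(d, 0.0, datum::inf);
  S.col(2) = clamp(-d, 0.0, datum::inf);
  uword imax = A.diag().index_max();
  S(imax, 3) = 1.0;
  return S;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List ndp_solve_cpp(const arma::mat &A, const arma::mat &starts,
                         int max_iter, double tol) {
  NdpFit fit = ndp_solve_impl(A, starts, max_iter, tol);
  return Rcpp::List::create(
      Rcpp::Named("w") = fit.w,
      Rcpp::Named("objective") = fit.f,
      Rcpp::Named("iterations") = fit.iters,
      Rcpp::Named("converged") = fit.converged);
}

// Tallied statistic maps for a set of labelings.
//
// X: subjects x V matrix of in-mask tissue densities (V in-mask voxels in a
//    fixed enumeration). labmat: L x subjects matrix of 0/1 labels (1 = the
//    direction-of-interest group A). members: list of 1-based integer vectors
//    indexing columns of X (one neighborhood each). lambda < 0 requests the
//    per-neighborhood trace heuristic. sign_dir: +1 tests A < B, -1 tests
//    A > B. Returns an L x V matrix of tallied statistics phi.
// [[Rcpp::export]]
arma::mat odvba_phi_cpp(const arma::mat &X, const arma::imat &labmat,
                        const Rcpp::List &members, double lambda,
                        int max_iter, double tol, int sign_dir) {
  const uword n = X.n_rows, V = X.n_cols;
  const uword L = labmat.n_rows;
  const uword K = members.size();
  mat phi(L, V, fill::zeros);

  // pre-extract member index vectors (convert to 0-based once)
  std::vector<uvec> memb(K);
  for (uword k = 0; k < K; ++k) {
    Rcpp::IntegerVector mi = members[k];
    uvec u(mi.size());
    for (int j = 0; j < mi.size(); ++j) u(j) = (uword)(mi[j] - 1);
    memb[k] = u;
  }

  for (uword l = 0; l < L; ++l) {
    // split subjects by label
    std::vector<uword> ia, ib;
    for (uword i = 0; i < n; ++i) {
      if (labmat(l, i) == 1) ia.push_back(i); else ib.push_back(i);
    }
    uvec idxA = conv_to<uvec>::from(ia), idxB = conv_to<uvec>::from(ib);
    const double nA = idxA.n_elem, nB = idxB.n_elem;
    if (nA < 2 || nB < 2) Rcpp::stop("each group needs at least 2 subjects");

    for (uword k = 0; k < K; ++k) {
      const uvec &mb = memb[k];
      const uword m = mb.n_elem;
      mat XA = X.submat(idxA, mb);
      mat XB = X.submat(idxB, mb);
      rowvec mA = mean(XA, 0), mB = mean(XB, 0);
      vec d = (mB - mA).t();  // B minus A
      double trSb = dot(d, d);
      if (trSb <= 0.0) continue;  // identical class means: s = 0 contribution
      XA.each_row() -= mA;
      XB.each_row() -= mB;
      mat Sw = (XA.t() * XA + XB.t() * XB) / (nA + nB - 2.0);
      double lam = lambda >= 0.0 ? lambda : trSb / std::max(trace(Sw), 1e-12);
      mat Acrit = d * d.t() - lam * Sw;
      NdpFit fit = ndp_solve_impl(Acrit, default_starts(Acrit, d),
                                  max_iter, tol);
      // pooled two-sample t of the projected values
      vec yA = XA * fit.w;  // centered within class already
      vec yB = XB * fit.w;
      double sp2 = (dot(yA, yA) + dot(yB, yB)) / (nA + nB - 2.0);
      if (sp2 <= 0.0) continue;
      double s = sign_dir * dot(d, fit.w) /
                 std::sqrt(sp2 * (1.0 / nA + 1.0 / nB));
      for (uword j = 0; j < m; ++j) phi(l, mb(j)) += fit.w(j) * s;
    }
  }
  return phi;
}

// Connected-component labeling of a 3D logical array under 6/18/26
// connectivity. Returns an integer vector (same length as bin) with 0 for
// background and components numbered 1.. in discovery order (column-major
// scan), each a maximal connected set.
// [[Rcpp::export]]
Rcpp::IntegerVector label_components_cpp(Rcpp::LogicalVector bin,
                                         Rcpp::IntegerVector dims,
                                         int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (bin.size() != nvox) Rcpp::stop("dims do not match array length");
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nn = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nn == 0) continue;
        if ((connectivity == 6 && nn > 1) || (connectivity == 18 && nn > 2))
          continue;
        off.push_back({dx, dy, dz});
      }
  Rcpp::IntegerVector lab(nvox, 0);
  int next = 0;
  std::vector<R_xlen_t> queue;
  for (R_xlen_t s = 0; s < nvox; ++s) {
    if (!bin[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      R_xlen_t v = queue.back();
      queue.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      for (const auto &o : off) {
        int X2 = x + o[0], Y2 = y + o[1], Z2 = z + o[2];
        if (X2 < 0 || X2 >= nx || Y2 < 0 || Y2 >= ny || Z2 < 0 || Z2 >= nz)
          continue;
        R_xlen_t u = X2 + (R_xlen_t)nx * (Y2 + (R_xlen_t)ny * Z2);
        if (bin[u] && lab[u] == 0) {
          lab[u] = next;
          queue.push_back(u);
        }
      }
    }
  }
  return lab;
}
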