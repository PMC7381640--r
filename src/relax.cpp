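#include <Rcpp.h>
using namespace Rcpp;

// Minimum-curvature gridding: iterative solution of the constrained
// discrete biharmonic problem.
//
// Operator rows: at non-corner nodes B_t u = (1 - t) * L(L u) - t * L u,
// where L is the 5-point Laplacian with "natural" boundary conditions --
// a directional second difference is dropped when one of its neighbours is
// missing (equivalent to a ghost node linearly extrapolated as
// 2*u_edge - u_interior, i.e. zero second derivative normal to the edge).
// Corner nodes, where that Laplacian degenerates, are closed with planar
// extrapolation from their three neighbours. Planes solve every row
// exactly for any tension t.
//
// Cells holding data are fixed; the free cells are relaxed by conjugate
// gradients on the normal equations (CGNR), which converges for this
// non-symmetric operator where simple sweeps do not. Iteration stops when
// the largest cell update falls below the tolerance.

static inline bool is_corner(int i, int j, int nr, int nc) {
  return (i == 0 || i == nr - 1) && (j == 0 || j == nc - 1);
}

// natural-BC Laplacian, full grid (corner rows evaluate to 0)
static void lap(const NumericMatrix& u, NumericMatrix& out) {
  int nr = u.nrow(), nc = u.ncol();
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double c = u(i, j), s = 0.0;
      if (i > 0 && i < nr - 1) s += u(i - 1, j) + u(i + 1, j) - 2.0 * c;
      if (j > 0 && j < nc - 1) s += u(i, j - 1) + u(i, j + 1) - 2.0 * c;
      out(i, j) = s;
    }
}

// transpose of the natural-BC Laplacian
static void lapT(const NumericMatrix& v, NumericMatrix& out) {
  int nr = v.nrow(), nc = v.ncol();
  for (int k = 0; k < nr; ++k)
    for (int l = 0; l < nc; ++l) {
      int ndir = 0;
      if (k > 0 && k < nr - 1) ++ndir;
      if (l > 0 && l < nc - 1) ++ndir;
      double s = -2.0 * ndir * v(k, l);
      // row at vertical neighbour (k+-1, l) contains (k, l) iff that row's
      // vertical term is active, i.e. the neighbour is not on a top/bottom edge
      if (k - 1 >= 0 && (k - 1) > 0 && (k - 1) < nr - 1) s += v(k - 1, l);
      if (k + 1 <= nr - 1 && (k + 1) > 0 && (k + 1) < nr - 1) s += v(k + 1, l);
      if (l - 1 >= 0 && (l - 1) > 0 && (l - 1) < nc - 1) s += v(k, l - 1);
      if (l + 1 <= nc - 1 && (l + 1) > 0 && (l + 1) < nc - 1) s += v(k, l + 1);
      out(k, l) = s;
    }
}

// full operator P u (corner rows replaced by planar closure)
static void applyP(const NumericMatrix& u, double t, NumericMatrix& out,
                   NumericMatrix& scratch) {
  int nr = u.nrow(), nc = u.ncol();
  lap(u, scratch);
  lap(scratch, out);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      out(i, j) = (1.0 - t) * out(i, j) - t * scratch(i, j);
  if (nr > 1 && nc > 1) {
    out(0, 0)           = u(0, 0) - u(1, 0) - u(0, 1) + u(1, 1);
    out(0, nc - 1)      = u(0, nc - 1) - u(1, nc - 1) - u(0, nc - 2) + u(1, nc - 2);
    out(nr - 1, 0)      = u(nr - 1, 0) - u(nr - 2, 0) - u(nr - 1, 1) + u(nr - 2, 1);
    out(nr - 1, nc - 1) = u(nr - 1, nc - 1) - u(nr - 2, nc - 1) -
                          u(nr - 1, nc - 2) + u(nr - 2, nc - 2);
  }
}

// transpose apply: out = P^T v
static void applyPT(const NumericMatrix& v, double t, NumericMatrix& out,
                    NumericMatrix& w, NumericMatrix& scratch) {
  int nr = v.nrow(), nc = v.ncol();
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      w(i, j) = v(i, j);
  // corner rows do not follow the Laplacian composition
  double c00 = 0, c0n = 0, cn0 = 0, cnn = 0;
  if (nr > 1 && nc > 1) {
    c00 = w(0, 0); c0n = w(0, nc - 1); cn0 = w(nr - 1, 0); cnn = w(nr - 1, nc - 1);
    w(0, 0) = w(0, nc - 1) = w(nr - 1, 0) = w(nr - 1, nc - 1) = 0.0;
  }
  lapT(w, scratch);
  lapT(scratch, out);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      out(i, j) = (1.0 - t) * out(i, j) - t * scratch(i, j);
  if (nr > 1 && nc > 1) {
    out(0, 0) += c00;            out(1, 0) -= c00;
    out(0, 1) -= c00;            out(1, 1) += c00;
    out(0, nc - 1) += c0n;       out(1, nc - 1) -= c0n;
    out(0, nc - 2) -= c0n;       out(1, nc - 2) += c0n;
    out(nr - 1, 0) += cn0;       out(nr - 2, 0) -= cn0;
    out(nr - 1, 1) -= cn0;       out(nr - 2, 1) += cn0;
    out(nr - 1, nc - 1) += cnn;  out(nr - 2, nc - 1) -= cnn;
    out(nr - 1, nc - 2) -= cnn;  out(nr - 2, nc - 2) += cnn;
  }
}

// [[Rcpp::export(name = ".applyMinCurvOperator")]]
NumericMatrix applyMinCurvOperator(NumericMatrix u, double tension) {
  NumericMatrix out(u.nrow(), u.ncol()), scratch(u.nrow(), u.ncol());
  applyP(u, tension, out, scratch);
  return out;
}

// [[Rcpp::export(name = ".relaxMinCurv")]]
List relaxMinCurv(NumericMatrix u0, LogicalMatrix fixed, double tension,
                  double tol, int maxIter, double omega) {
  (void)omega;  // retained for interface stability; CGNR needs no relaxation factor
  int nr = u0.nrow(), nc = u0.ncol();
  NumericMatrix u = clone(u0);
  NumericMatrix r(nr, nc), s(nr, nc), p(nr, nc), q(nr, nc);
  NumericMatrix t1(nr, nc), t2(nr, nc);

  // r = -P(u) on free rows
  applyP(u, tension, r, t1);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      r(i, j) = fixed(i, j) ? 0.0 : -r(i, j);

  applyPT(r, tension, s, t1, t2);
  double gamma = 0.0;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      if (fixed(i, j)) { s(i, j) = 0.0; continue; }
      p(i, j) = s(i, j);
      gamma += s(i, j) * s(i, j);
    }
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      p(i, j) = fixed(i, j) ? 0.0 : s(i, j);

  double maxUpd = 0.0, maxRes = 0.0;
  int iter = 0;
  for (iter = 0; iter < maxIter; ++iter) {
    if (gamma <= 0.0) break;
    applyP(p, tension, q, t1);  // p is zero on fixed cells: q = A p on free rows
    double qq = 0.0;
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < nc; ++j) {
        if (fixed(i, j)) { q(i, j) = 0.0; continue; }
        qq += q(i, j) * q(i, j);
      }
    if (qq <= 0.0) break;
    double alpha = gamma / qq;
    maxUpd = 0.0;
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < nc; ++j) {
        if (fixed(i, j)) continue;
        double upd = alpha * p(i, j);
        u(i, j) += upd;
        r(i, j) -= alpha * q(i, j);
        double au = std::fabs(upd);
        if (au > maxUpd) maxUpd = au;
      }
    if (maxUpd < tol) { ++iter; break; }
    applyPT(r, tension, s, t1, t2);
    double gammaNew = 0.0;
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < nc; ++j) {
        if (fixed(i, j)) { s(i, j) = 0.0; continue; }
        gammaNew += s(i, j) * s(i, j);
      }
    double beta = gammaNew / gamma;
    gamma = gammaNew;
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < nc; ++j)
        p(i, j) = fixed(i, j) ? 0.0 : s(i, j) + beta * p(i, j);
  }
  maxRes = 0.0;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      if (!fixed(i, j) && std::fabs(r(i, j)) > maxRes) maxRes = std::fabs(r(i, j));
  return List::create(_["surface"] = u, _["iterations"] = iter,
                      _["maxUpdate"] = maxUpd, _["residual"] = maxRes,
                      _["converged"] = maxUpd < tol || gamma <= 0.0);
}
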