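#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 6-connected component labeling of a 3D logical mask (column-major,
// dims = c(nx, ny, nz)).  Returns integer labels, 0 for background.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n);
  const int *m = LOGICAL(mask);
  int *L = INTEGER(lab);
  for (R_xlen_t s = 0; s < n; ++s) L[s] = 0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (m[s] != TRUE || L[s]) continue;
    ++cur;
    L[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i = (int)(v % nx);
      R_xlen_t rest = v / nx;
      int j = (int)(rest % ny);
      int k = (int)(rest / ny);
      if (i > 0)      { R_xlen_t w = v - sx; if (m[w] == TRUE && !L[w]) { L[w] = cur; stack.push_back(w); } }
      if (i < nx - 1) { R_xlen_t w = v + sx; if (m[w] == TRUE && !L[w]) { L[w] = cur; stack.push_back(w); } }
      if (j > 0)      { R_xlen_t w = v - sy; if (m[w] == TRUE && !L[w]) { L[w] = cur; stack.push_back(w); } }
      if (j < ny - 1) { R_xlen_t w = v + sy; if (m[w] == TRUE && !L[w]) { L[w] = cur; stack.push_back(w); } }
      if (k > 0)      { R_xlen_t w = v - sz; if (m[w] == TRUE && !L[w]) { L[w] = cur; stack.push_back(w); } }
      if (k < nz - 1) { R_xlen_t w = v + sz; if (m[w] == TRUE && !L[w]) { L[w] = cur; stack.push_back(w); } }
    }
  }
  return lab;
}

// Binary erosion/dilation with an arbitrary offset set (rows of `offsets`
// are (di, dj, dk)).  Out-of-bounds neighbors are ignored, so the image
// border does not erode the structure (border-replicate semantics).
// [[Rcpp::export]]
LogicalVector cpp_morph3d(LogicalVector mask, IntegerVector dims,
                          IntegerMatrix offsets, bool dilate) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  const int no = offsets.nrow();
  LogicalVector out(n);
  const int *m = LOGICAL(mask);
  int *o = LOGICAL(out);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        bool any = false, all = true;
        for (int t = 0; t < no; ++t) {
          int ii = i + offsets(t, 0), jj = j + offsets(t, 1), kk = k + offsets(t, 2);
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
          R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          if (m[w] == TRUE) any = true; else all = false;
          if (dilate && any) break;
          if (!dilate && !all) break;
        }
        o[v] = dilate ? (any ? TRUE : FALSE) : (all ? TRUE : FALSE);
      }
    }
  }
  return out;
}

// y = K x for the global stiffness operator of a uniform-geometry hex mesh:
// K = sum_e Escale[e] * Ke scattered through the element dof map.
// elems is m x 8, ZERO-based node ids; dof layout is (3*node + comp).
static void hex_matvec(const int *elems, R_xlen_t m, const double *Ke,
                       const double *Escale, const double *x, double *y,
                       R_xlen_t ndof) {
  for (R_xlen_t d = 0; d < ndof; ++d) y[d] = 0.0;
  double xe[24], ye[24];
  int dof[24];
  for (R_xlen_t e = 0; e < m; ++e) {
    const double Ee = Escale[e];
    for (int a = 0; a < 8; ++a) {
      const int node = elems[e + a * m];
      dof[3 * a]     = 3 * node;
      dof[3 * a + 1] = 3 * node + 1;
      dof[3 * a + 2] = 3 * node + 2;
    }
    for (int i = 0; i < 24; ++i) xe[i] = x[dof[i]];
    for (int i = 0; i < 24; ++i) {
      double s = 0.0;
      const double *row = Ke + (R_xlen_t)i * 24;  // Ke passed row-major
      for (int j = 0; j < 24; ++j) s += row[j] * xe[j];
      ye[i] = Ee * s;
    }
    for (int i = 0; i < 24; ++i) y[dof[i]] += ye[i];
  }
}

// [[Rcpp::export]]
NumericVector cpp_hex_matvec(IntegerMatrix elems, NumericVector KeRowMajor,
                             NumericVector Escale, int nnodes,
                             NumericVector x) {
  const R_xlen_t m = elems.nrow();
  const R_xlen_t ndof = (R_xlen_t)3 * nnodes;
  if (x.size() != ndof) stop("x has wrong length");
  NumericVector y(ndof);
  hex_matvec(INTEGER(elems), m, REAL(KeRowMajor), REAL(Escale), REAL(x),
             REAL(y), ndof);
  return y;
}

// Jacobi-preconditioned conjugate gradients on the Dirichlet-reduced system.
// fixed marks constrained dofs, ufix holds their prescribed values; u0 is a
// warm start for the free dofs.  Returns the full displacement vector.
// [[Rcpp::export]]
List cpp_pcg_hex(IntegerMatrix elems, NumericVector KeRowMajor,
                 NumericVector Escale, int nnodes, LogicalVector fixed,
                 NumericVector ufix, NumericVector u0, double tol,
                 int maxit) {
  const R_xlen_t m = elems.nrow();
  const R_xlen_t ndof = (R_xlen_t)3 * nnodes;
  if (fixed.size() != ndof || ufix.size() != ndof || u0.size() != ndof)
    stop("dof vector length mismatch");
  const int *E = INTEGER(elems);
  const double *Ke = REAL(KeRowMajor);
  const double *Es = REAL(Escale);
  const int *fx = LOGICAL(fixed);

  // Diagonal of K for the Jacobi preconditioner.
  std::vector<double> diag(ndof, 0.0);
  for (R_xlen_t e = 0; e < m; ++e) {
    const double Ee = Es[e];
    for (int a = 0; a < 8; ++a) {
      const int node = E[e + a * m];
      for (int c = 0; c < 3; ++c) {
        const int i = 3 * a + c;
        diag[3 * node + c] += Ee * Ke[(R_xlen_t)i * 24 + i];
      }
    }
  }
  for (R_xlen_t d = 0; d < ndof; ++d)
    if (fx[d] == TRUE || diag[d] <= 0.0) diag[d] = 1.0;

  std::vector<double> x(ndof), b(ndof), r(ndof), z(ndof), p(ndof), q(ndof),
      tmp(ndof);

  // b = -K * u_prescribed, restricted to free dofs.
  for (R_xlen_t d = 0; d < ndof; ++d)
    tmp[d] = (fx[d] == TRUE) ? ufix[d] : 0.0;
  hex_matvec(E, m, Ke, Es, tmp.data(), b.data(), ndof);
  for (R_xlen_t d = 0; d < ndof; ++d) b[d] = (fx[d] == TRUE) ? 0.0 : -b[d];

  double bnorm = 0.0;
  for (R_xlen_t d = 0; d < ndof; ++d) bnorm += b[d] * b[d];
  bnorm = std::sqrt(bnorm);

  for (R_xlen_t d = 0; d < ndof; ++d)
    x[d] = (fx[d] == TRUE) ? 0.0 : u0[d];

  int iter = 0;
  double relres = 0.0;
  if (bnorm > 0.0) {
    // r = b - A x  (A = K restricted to free dofs)
    hex_matvec(E, m, Ke, Es, x.data(), q.data(), ndof);
    for (R_xlen_t d = 0; d < ndof; ++d)
      r[d] = (fx[d] == TRUE) ? 0.0 : b[d] - q[d];
    double rz = 0.0;
    for (R_xlen_t d = 0; d < ndof; ++d) {
      z[d] = r[d] / diag[d];
      rz += r[d] * z[d];
    }
    for (R_xlen_t d = 0; d < ndof; ++d) p[d] = z[d];
    double rnorm = 0.0;
    for (R_xlen_t d = 0; d < ndof; ++d) rnorm += r[d] * r[d];
    relres = std::sqrt(rnorm) / bnorm;
    while (relres > tol && iter < maxit) {
      ++iter;
      hex_matvec(E, m, Ke, Es, p.data(), q.data(), ndof);
      for (R_xlen_t d = 0; d < ndof; ++d)
        if (fx[d] == TRUE) q[d] = 0.0;
      double pq = 0.0;
      for (R_xlen_t d = 0; d < ndof; ++d) pq += p[d] * q[d];
      if (pq <= 0.0) break;  // indefinite direction: numerically singular block
      const double alpha = rz / pq;
      rnorm = 0.0;
      for (R_xlen_t d = 0; d < ndof; ++d) {
        x[d] += alpha * p[d];
        r[d] -= alpha * q[d];
        rnorm += r[d] * r[d];
      }
      relres = std::sqrt(rnorm) / bnorm;
      if (relres <= tol) break;
      double rz_new = 0.0;
      for (R_xlen_t d = 0; d < ndof; ++d) {
        z[d] = r[d] / diag[d];
        rz_new += r[d] * z[d];
      }
      const double beta = rz_new / rz;
      rz = rz_new;
      for (R_xlen_t d = 0; d < ndof; ++d) p[d] = z[d] + beta * p[d];
    }
  }

  NumericVector u(ndof);
  for (R_xlen_t d = 0; d < ndof; ++d)
    u[d] = (fx[d] == TRUE) ? ufix[d] : x[d];
  return List::create(_["u"] = u, _["iterations"] = iter,
                      _["relres"] = relres, _["converged"] = (relres <= tol));
}
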