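#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Matrix-free preconditioned conjugate gradient for voxel hex8 meshes.
// All elements share one canonical 24x24 stiffness matrix (identical cubes),
// so K*x is evaluated element-by-element by gather/multiply/scatter.
// Dirichlet constraints are imposed by projection: constrained DOFs are
// masked out of the Krylov space and their prescribed values enter through
// the right-hand side b = -K u_c.

struct EbeOperator {
  const int* elems;      // 8 x m node ids (0-based), column-major per element
  R_xlen_t m;
  const double* Ke;      // 24 x 24 column-major
  const char* fixed;     // per-DOF flag
  R_xlen_t ndof;

  // y = P K P x  (P zeroes constrained DOFs); x must already be P x.
  void apply(const std::vector<double>& x, std::vector<double>& y) const {
    std::fill(y.begin(), y.end(), 0.0);
    double xe[24], ye[24];
    for (R_xlen_t e = 0; e < m; e++) {
      const int* nd = elems + 8 * e;
      for (int a = 0; a < 8; a++) {
        R_xlen_t base = 3 * (R_xlen_t)nd[a];
        xe[3 * a]     = x[base];
        xe[3 * a + 1] = x[base + 1];
        xe[3 * a + 2] = x[base + 2];
      }
      for (int r = 0; r < 24; r++) ye[r] = 0.0;
      for (int c = 0; c < 24; c++) {
        double xc = xe[c];
        if (xc == 0.0) continue;
        const double* col = Ke + 24 * c;
        for (int r = 0; r < 24; r++) ye[r] += col[r] * xc;
      }
      for (int a = 0; a < 8; a++) {
        R_xlen_t base = 3 * (R_xlen_t)nd[a];
        y[base]     += ye[3 * a];
        y[base + 1] += ye[3 * a + 1];
        y[base + 2] += ye[3 * a + 2];
      }
    }
    for (R_xlen_t i = 0; i < ndof; i++)
      if (fixed[i]) y[i] = 0.0;
  }

  // y = K x without projection (reaction recovery).
  void apply_full(const std::vector<double>& x, std::vector<double>& y) const {
    std::fill(y.begin(), y.end(), 0.0);
    double xe[24], ye[24];
    for (R_xlen_t e = 0; e < m; e++) {
      const int* nd = elems + 8 * e;
      for (int a = 0; a < 8; a++) {
        R_xlen_t base = 3 * (R_xlen_t)nd[a];
        xe[3 * a]     = x[base];
        xe[3 * a + 1] = x[base + 1];
        xe[3 * a + 2] = x[base + 2];
      }
      for (int r = 0; r < 24; r++) ye[r] = 0.0;
      for (int c = 0; c < 24; c++) {
        double xc = xe[c];
        if (xc == 0.0) continue;
        const double* col = Ke + 24 * c;
        for (int r = 0; r < 24; r++) ye[r] += col[r] * xc;
      }
      for (int a = 0; a < 8; a++) {
        R_xlen_t base = 3 * (R_xlen_t)nd[a];
        y[base]     += ye[3 * a];
        y[base + 1] += ye[3 * a + 1];
        y[base + 2] += ye[3 * a + 2];
      }
    }
  }
};

// [[Rcpp::export]]
List fe_solve_cg_cpp(IntegerMatrix elems, int n_nodes, NumericMatrix Ke,
                     IntegerVector fixed_dofs, NumericVector fixed_vals,
                     NumericVector x0, double tol, int max_iter) {
  const R_xlen_t m = elems.nrow();
  const R_xlen_t ndof = 3 * (R_xlen_t)n_nodes;
  // 0-based node ids per element, stored 8-contiguous
  std::vector<int> conn(8 * m);
  for (R_xlen_t e = 0; e < m; e++)
    for (int a = 0; a < 8; a++)
      conn[8 * e + a] = elems(e, a) - 1;
  std::vector<char> fixed(ndof, 0);
  std::vector<double> u(ndof, 0.0);
  for (R_xlen_t i = 0; i < (R_xlen_t)fixed_dofs.size(); i++) {
    fixed[fixed_dofs[i] - 1] = 1;
    u[fixed_dofs[i] - 1] = fixed_vals[i];
  }
  EbeOperator A;
  A.elems = conn.data();
  A.m = m;
  A.Ke = REAL(Ke);
  A.fixed = fixed.data();
  A.ndof = ndof;

  // Jacobi preconditioner from the assembled diagonal
  std::vector<double> diag(ndof, 0.0);
  for (R_xlen_t e = 0; e < m; e++) {
    const int* nd = conn.data() + 8 * e;
    for (int a = 0; a < 8; a++)
      for (int c = 0; c < 3; c++) {
        int ld = 3 * a + c;
        diag[3 * (R_xlen_t)nd[a] + c] += Ke(ld, ld);
      }
  }
  for (R_xlen_t i = 0; i < ndof; i++)
    if (diag[i] <= 0.0) diag[i] = 1.0; // unattached node (should not occur)

  // b = -K u_c on free DOFs
  std::vector<double> uc(ndof, 0.0), b(ndof, 0.0);
  for (R_xlen_t i = 0; i < ndof; i++)
    if (fixed[i]) uc[i] = u[i];
  A.apply_full(uc, b);
  for (R_xlen_t i = 0; i < ndof; i++)
    b[i] = fixed[i] ? 0.0 : -b[i];
  double bnorm = 0.0;
  for (R_xlen_t i = 0; i < ndof; i++) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);

  std::vector<double> x(ndof, 0.0);
  for (R_xlen_t i = 0; i < ndof; i++)
    if (!fixed[i]) x[i] = x0[i];
  std::vector<double> r(ndof), z(ndof), p(ndof), Ap(ndof);
  A.apply(x, Ap);
  for (R_xlen_t i = 0; i < ndof; i++) r[i] = b[i] - Ap[i];
  double relres = 1.0;
  int it = 0;
  if (bnorm == 0.0) {
    relres = 0.0;
  } else {
    double rz = 0.0;
    for (R_xlen_t i = 0; i < ndof; i++) {
      z[i] = fixed[i] ? 0.0 : r[i] / diag[i];
      rz += r[i] * z[i];
      p[i] = z[i];
    }
    for (it = 0; it < max_iter; it++) {
      double rn = 0.0;
      for (R_xlen_t i = 0; i < ndof; i++) rn += r[i] * r[i];
      relres = std::sqrt(rn) / bnorm;
      if (relres <= tol) break;
      A.apply(p, Ap);
      double pAp = 0.0;
      for (R_xlen_t i = 0; i < ndof; i++) pAp += p[i] * Ap[i];
      if (pAp <= 0.0) break; // breakdown (singular beyond rigid modes)
      double alpha = rz / pAp;
      for (R_xlen_t i = 0; i < ndof; i++) {
        x[i] += alpha * p[i];
        r[i] -= alpha * Ap[i];
      }
      double rznew = 0.0;
      for (R_xlen_t i = 0; i < ndof; i++) {
        z[i] = fixed[i] ? 0.0 : r[i] / diag[i];
        rznew += r[i] * z[i];
      }
      double beta = rznew / rz;
      rz = rznew;
      for (R_xlen_t i = 0; i < ndof; i++) p[i] = z[i] + beta * p[i];
      if ((it & 63) == 63) Rcpp::checkUserInterrupt();
    }
  }
  // full solution and reactions
  for (R_xlen_t i = 0; i < ndof; i++)
    u[i] = fixed[i] ? uc[i] : x[i];
  std::vector<double> Ku(ndof);
  A.apply_full(u, Ku);
  NumericVector disp(ndof), reac(fixed_dofs.size());
  for (R_xlen_t i = 0; i < ndof; i++) disp[i] = u[i];
  for (R_xlen_t i = 0; i < (R_xlen_t)fixed_dofs.size(); i++)
    reac[i] = Ku[fixed_dofs[i] - 1];
  return List::create(_["displacements"] = disp,
                      _["reactions"] = reac,
                      _["relres"] = relres,
                      _["iterations"] = it);
}
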