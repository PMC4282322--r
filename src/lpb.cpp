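// Preconditioned conjugate-gradient solver for the 7-point finite-difference
// discretization of the linearized Poisson-Boltzmann operator
//   -div(eps grad phi) + kappa_bar^2 phi = 4 pi k_e rho
// scaled by h^2:  [sum_e eps_e + kbar2*h^2] phi_i - sum_e eps_e phi_nb = b_i.
// Dirichlet boundary values are carried in phi and held fixed; the system is
// symmetric positive definite over interior nodes, so CG with a Jacobi
// preconditioner converges deterministically.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// A*x over interior nodes; x must be zero (or boundary values) elsewhere.
// epsx: (nx-1) x ny x nz edges along x, epsy: nx x (ny-1) x nz,
// epsz: nx x ny x (nz-1); kap2h2: node array of kappa_bar^2 * h^2.
static void apply_A(const double* x, double* out,
                    const double* ex, const double* ey, const double* ez,
                    const double* kap, int nx, int ny, int nz) {
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        const int c = idx3(i, j, k, nx, ny);
        const double exm = ex[(i - 1) + (nx - 1) * (j + ny * k)];
        const double exp_ = ex[i + (nx - 1) * (j + ny * k)];
        const double eym = ey[i + nx * ((j - 1) + (ny - 1) * k)];
        const double eyp = ey[i + nx * (j + (ny - 1) * k)];
        const double ezm = ez[i + nx * (j + ny * (k - 1))];
        const double ezp = ez[i + nx * (j + ny * k)];
        const double diag = exm + exp_ + eym + eyp + ezm + ezp + kap[c];
        out[c] = diag * x[c]
          - exm * x[c - 1] - exp_ * x[c + 1]
          - eym * x[c - nx] - eyp * x[c + nx]
          - ezm * x[c - nx * ny] - ezp * x[c + nx * ny];
      }
}

// [[Rcpp::export]]
List lpb_cg(IntegerVector dims, NumericVector epsx, NumericVector epsy,
            NumericVector epsz, NumericVector kap2h2, NumericVector b,
            NumericVector phi_bc, double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if ((int)phi_bc.size() != n || (int)b.size() != n || (int)kap2h2.size() != n)
    stop("array size mismatch");

  std::vector<double> u(n, 0.0), r(n, 0.0), z(n, 0.0), p(n, 0.0), Ap(n, 0.0);
  std::vector<double> diag(n, 1.0);
  const double* ex = epsx.begin();
  const double* ey = epsy.begin();
  const double* ez = epsz.begin();
  const double* kap = kap2h2.begin();

  // Jacobi diagonal
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        const int c = idx3(i, j, k, nx, ny);
        diag[c] = ex[(i - 1) + (nx - 1) * (j + ny * k)]
          + ex[i + (nx - 1) * (j + ny * k)]
          + ey[i + nx * ((j - 1) + (ny - 1) * k)]
          + ey[i + nx * (j + (ny - 1) * k)]
          + ez[i + nx * (j + ny * (k - 1))]
          + ez[i + nx * (j + ny * k)] + kap[c];
      }

  // r = b - A*phi_bc (interior); u starts at 0 (interior correction)
  apply_A(phi_bc.begin(), Ap.data(), ex, ey, ez, kap, nx, ny, nz);
  double bnorm2 = 0.0;
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        const int c = idx3(i, j, k, nx, ny);
        r[c] = b[c] - Ap[c];
        bnorm2 += r[c] * r[c];
      }
  if (bnorm2 == 0.0) {
    NumericVector phi = clone(phi_bc);
    return List::create(_["phi"] = phi, _["iterations"] = 0,
                        _["rel_residual"] = 0.0, _["converged"] = true);
  }

  double rz = 0.0;
  for (int c = 0; c < n; ++c) { z[c] = r[c] / diag[c]; p[c] = z[c]; }
  for (int c = 0; c < n; ++c) rz += r[c] * z[c];

  int it = 0;
  double rel = 1.0;
  for (it = 1; it <= maxit; ++it) {
    apply_A(p.data(), Ap.data(), ex, ey, ez, kap, nx, ny, nz);
    double pAp = 0.0;
    for (int k = 1; k < nz - 1; ++k)
      for (int j = 1; j < ny - 1; ++j)
        for (int i = 1; i < nx - 1; ++i) {
          const int c = idx3(i, j, k, nx, ny);
          pAp += p[c] * Ap[c];
        }
    const double alpha = rz / pAp;
    double rnorm2 = 0.0;
    for (int k = 1; k < nz - 1; ++k)
      for (int j = 1; j < ny - 1; ++j)
        for (int i = 1; i < nx - 1; ++i) {
          const int c = idx3(i, j, k, nx, ny);
          u[c] += alpha * p[c];
          r[c] -= alpha * Ap[c];
          rnorm2 += r[c] * r[c];
        }
    rel = std::sqrt(rnorm2 / bnorm2);
    if (rel <= tol) break;
    double rz_new = 0.0;
    for (int k = 1; k < nz - 1; ++k)
      for (int j = 1; j < ny - 1; ++j)
        for (int i = 1; i < nx - 1; ++i) {
          const int c = idx3(i, j, k, nx, ny);
          z[c] = r[c] / diag[c];
          rz_new += r[c] * z[c];
        }
    const double beta = rz_new / rz;
    rz = rz_new;
    for (int k = 1; k < nz - 1; ++k)
      for (int j = 1; j < ny - 1; ++j)
        for (int i = 1; i < nx - 1; ++i) {
          const int c = idx3(i, j, k, nx, ny);
          p[c] = z[c] + beta * p[c];
        }
  }

  NumericVector phi(n);
  for (int c = 0; c < n; ++c) phi[c] = phi_bc[c] + u[c];
  return List::create(_["phi"] = phi, _["iterations"] = it,
                      _["rel_residual"] = rel,
                      _["converged"] = (rel <= tol));
}
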