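#include <Rcpp.h>
using namespace Rcpp;

// Constant-strain tetrahedron kernels. Shape-function gradients come from the
// inverse edge matrix; the isotropic stiffness is assembled directly from
//   K[ai][bj] = V * (lambda*ga_i*gb_j + mu*ga_j*gb_i + mu*delta_ij*(ga.gb))
// which is algebraically identical to V * B^T C B in Voigt form.

static inline void tet_grads(const NumericMatrix& coords, const int* nd,
                             double grads[4][3], double& vol, int elem1) {
  double d[3][3];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c)
      d[r][c] = coords(nd[r + 1], c) - coords(nd[0], c);
  double det =
      d[0][0] * (d[1][1] * d[2][2] - d[1][2] * d[2][1]) -
      d[0][1] * (d[1][0] * d[2][2] - d[1][2] * d[2][0]) +
      d[0][2] * (d[1][0] * d[2][1] - d[1][1] * d[2][0]);
  vol = det / 6.0;
  if (vol <= 0.0)
    stop("non-positive volume in element %d (signed volume %g)", elem1, vol);
  // inv(d); grad N_a (a=1..3) is column a-1 of inv(d) read as row of inv(d)^T
  double inv[3][3];
  inv[0][0] = (d[1][1] * d[2][2] - d[1][2] * d[2][1]) / det;
  inv[0][1] = (d[0][2] * d[2][1] - d[0][1] * d[2][2]) / det;
  inv[0][2] = (d[0][1] * d[1][2] - d[0][2] * d[1][1]) / det;
  inv[1][0] = (d[1][2] * d[2][0] - d[1][0] * d[2][2]) / det;
  inv[1][1] = (d[0][0] * d[2][2] - d[0][2] * d[2][0]) / det;
  inv[1][2] = (d[0][2] * d[1][0] - d[0][0] * d[1][2]) / det;
  inv[2][0] = (d[1][0] * d[2][1] - d[1][1] * d[2][0]) / det;
  inv[2][1] = (d[0][1] * d[2][0] - d[0][0] * d[2][1]) / det;
  inv[2][2] = (d[0][0] * d[1][1] - d[0][1] * d[1][0]) / det;
  // x - x0 = E^T xi with E rows = edge vectors => grad xi_a = row a of inv(E)^T
  for (int a = 1; a < 4; ++a)
    for (int j = 0; j < 3; ++j) grads[a][j] = inv[j][a - 1];
  for (int j = 0; j < 3; ++j)
    grads[0][j] = -(grads[1][j] + grads[2][j] + grads[3][j]);
}

// [[Rcpp::export]]
NumericVector cpp_tet_volumes(const NumericMatrix& coords,
                              const IntegerMatrix& tets) {
  const int m = tets.nrow();
  NumericVector vol(m);
  for (int e = 0; e < m; ++e) {
    int nd[4];
    for (int a = 0; a < 4; ++a) nd[a] = tets(e, a) - 1;
    double d[3][3];
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c)
        d[r][c] = coords(nd[r + 1], c) - coords(nd[0], c);
    double det =
        d[0][0] * (d[1][1] * d[2][2] - d[1][2] * d[2][1]) -
        d[0][1] * (d[1][0] * d[2][2] - d[1][2] * d[2][0]) +
        d[0][2] * (d[1][0] * d[2][1] - d[1][1] * d[2][0]);
    vol[e] = det / 6.0;
  }
  return vol;
}

// [[Rcpp::export]]
List cpp_assemble_elasticity(const NumericMatrix& coords,
                             const IntegerMatrix& tets,
                             const NumericVector& E,
                             const NumericVector& nu) {
  const int m = tets.nrow();
  IntegerVector ii(static_cast<R_xlen_t>(m) * 144);
  IntegerVector jj(static_cast<R_xlen_t>(m) * 144);
  NumericVector xx(static_cast<R_xlen_t>(m) * 144);
  R_xlen_t p = 0;
  for (int e = 0; e < m; ++e) {
    int nd[4];
    for (int a = 0; a < 4; ++a) nd[a] = tets(e, a) - 1;
    double g[4][3], vol;
    tet_grads(coords, nd, g, vol, e + 1);
    double lam = E[e] * nu[e] / ((1.0 + nu[e]) * (1.0 - 2.0 * nu[e]));
    double mu = E[e] / (2.0 * (1.0 + nu[e]));
    for (int a = 0; a < 4; ++a) {
      for (int b = 0; b < 4; ++b) {
        double gab = g[a][0] * g[b][0] + g[a][1] * g[b][1] + g[a][2] * g[b][2];
        for (int i = 0; i < 3; ++i) {
          for (int j = 0; j < 3; ++j) {
            double k = lam * g[a][i] * g[b][j] + mu * g[a][j] * g[b][i];
            if (i == j) k += mu * gab;
            ii[p] = 3 * nd[a] + i + 1;
            jj[p] = 3 * nd[b] + j + 1;
            xx[p] = vol * k;
            ++p;
          }
        }
      }
    }
  }
  return List::create(_["i"] = ii, _["j"] = jj, _["x"] = xx);
}

// [[Rcpp::export]]
List cpp_assemble_conductance(const NumericMatrix& coords,
                              const IntegerMatrix& tets,
                              const NumericVector& k) {
  const int m = tets.nrow();
  IntegerVector ii(static_cast<R_xlen_t>(m) * 16);
  IntegerVector jj(static_cast<R_xlen_t>(m) * 16);
  NumericVector xx(static_cast<R_xlen_t>(m) * 16);
  R_xlen_t p = 0;
  for (int e = 0; e < m; ++e) {
    int nd[4];
    for (int a = 0; a < 4; ++a) nd[a] = tets(e, a) - 1;
    double g[4][3], vol;
    tet_grads(coords, nd, g, vol, e + 1);
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        ii[p] = nd[a] + 1;
        jj[p] = nd[b] + 1;
        xx[p] = vol * k[e] *
                (g[a][0] * g[b][0] + g[a][1] * g[b][1] + g[a][2] * g[b][2]);
        ++p;
      }
  }
  return List::create(_["i"] = ii, _["j"] = jj, _["x"] = xx);
}

// [[Rcpp::export]]
NumericVector cpp_thermal_load(const NumericMatrix& coords,
                               const IntegerMatrix& tets,
                               const NumericVector& E,
                               const NumericVector& nu,
                               const NumericVector& alpha_dT) {
  const int m = tets.nrow();
  NumericVector f(3 * static_cast<R_xlen_t>(coords.nrow()));
  for (int e = 0; e < m; ++e) {
    if (alpha_dT[e] == 0.0) continue;
    int nd[4];
    for (int a = 0; a < 4; ++a) nd[a] = tets(e, a) - 1;
    double g[4][3], vol;
    tet_grads(coords, nd, g, vol, e + 1);
    double lam = E[e] * nu[e] / ((1.0 + nu[e]) * (1.0 - 2.0 * nu[e]));
    double mu = E[e] / (2.0 * (1.0 + nu[e]));
    double s0 = (3.0 * lam + 2.0 * mu) * alpha_dT[e];
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) f[3 * nd[a] + i] += vol * s0 * g[a][i];
  }
  return f;
}

// Per-element Voigt stress (xx, yy, zz, yz, xz, xy; engineering shear) and
// von Mises, with thermal strain alpha*dT subtracted before the law.
// [[Rcpp::export]]
NumericMatrix cpp_element_stress(const NumericMatrix& coords,
                                 const IntegerMatrix& tets,
                                 const NumericVector& E,
                                 const NumericVector& nu,
                                 const NumericVector& alpha_dT,
                                 const NumericVector& u) {
  const int m = tets.nrow();
  NumericMatrix s(m, 7);
  for (int e = 0; e < m; ++e) {
    int nd[4];
    for (int a = 0; a < 4; ++a) nd[a] = tets(e, a) - 1;
    double g[4][3], vol;
    tet_grads(coords, nd, g, vol, e + 1);
    double h[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};  // du_i/dx_j
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) h[i][j] += u[3 * nd[a] + i] * g[a][j];
    double exx = h[0][0] - alpha_dT[e];
    double eyy = h[1][1] - alpha_dT[e];
    double ezz = h[2][2] - alpha_dT[e];
    double gyz = h[1][2] + h[2][1];
    double gxz = h[0][2] + h[2][0];
    double gxy = h[0][1] + h[1][0];
    double lam = E[e] * nu[e] / ((1.0 + nu[e]) * (1.0 - 2.0 * nu[e]));
    double mu = E[e] / (2.0 * (1.0 + nu[e]));
    double tr = lam * (exx + eyy + ezz);
    double sxx = tr + 2.0 * mu * exx;
    double syy = tr + 2.0 * mu * eyy;
    double szz = tr + 2.0 * mu * ezz;
    double syz = mu * gyz, sxz = mu * gxz, sxy = mu * gxy;
    s(e, 0) = sxx; s(e, 1) = syy; s(e, 2) = szz;
    s(e, 3) = syz; s(e, 4) = sxz; s(e, 5) = sxy;
    double a2 = (sxx - syy) * (sxx - syy) + (syy - szz) * (syy - szz) +
                (szz - sxx) * (szz - sxx) +
                6.0 * (syz * syz + sxz * sxz + sxy * sxy);
    s(e, 6) = std::sqrt(0.5 * a2);
  }
  return s;
}
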