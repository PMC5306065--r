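// Finite-element core: Ogden tetrahedra (energy, internal forces, element
// tangents by per-element finite differences) and node-to-surface contact
// against rigid triangle meshes with a uniform-grid broad phase.
// Units: mm, MPa, N.  All loops are deterministic (no unordered reductions).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// ---- small 3x3 helpers -----------------------------------------------------

static inline double det3(const double F[9]) {
  return F[0] * (F[4] * F[8] - F[5] * F[7])
       - F[1] * (F[3] * F[8] - F[5] * F[6])
       + F[2] * (F[3] * F[7] - F[4] * F[6]);
}

// cyclic Jacobi eigen-decomposition of a symmetric 3x3 matrix.
// A is row-major; eigenvalues in w, eigenvectors in columns of V (row-major).
static void eig_sym3_jacobi(const double A[9], double w[3], double V[9]) {
  double a[9];
  for (int i = 0; i < 9; ++i) a[i] = A[i];
  for (int i = 0; i < 9; ++i) V[i] = 0.0;
  V[0] = V[4] = V[8] = 1.0;
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = std::fabs(a[1]) + std::fabs(a[2]) + std::fabs(a[5]);
    double dia = std::fabs(a[0]) + std::fabs(a[4]) + std::fabs(a[8]);
    if (off <= 1e-15 * (dia + 1e-300)) break;
    static const int idx[3][2] = {{0, 1}, {0, 2}, {1, 2}};
    for (int k = 0; k < 3; ++k) {
      int p = idx[k][0], q = idx[k][1];
      double apq = a[3 * p + q];
      if (std::fabs(apq) < 1e-300) continue;
      double app = a[3 * p + p], aqq = a[3 * q + q];
      double theta = 0.5 * (aqq - app) / apq;
      double t = (theta >= 0 ? 1.0 : -1.0) /
                 (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
      double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
      for (int i = 0; i < 3; ++i) {
        double aip = a[3 * i + p], aiq = a[3 * i + q];
        a[3 * i + p] = c * aip - s * aiq;
        a[3 * i + q] = s * aip + c * aiq;
      }
      for (int j = 0; j < 3; ++j) {
        double apj = a[3 * p + j], aqj = a[3 * q + j];
        a[3 * p + j] = c * apj - s * aqj;
        a[3 * q + j] = s * apj + c * aqj;
      }
      for (int i = 0; i < 3; ++i) {
        double vip = V[3 * i + p], viq = V[3 * i + q];
        V[3 * i + p] = c * vip - s * viq;
        V[3 * i + q] = s * vip + c * viq;
      }
    }
  }
  w[0] = a[0]; w[1] = a[4]; w[2] = a[8];
}

// analytic (Cardano) eigenvalues + cross-product eigenvectors, with a
// Jacobi fallback near degeneracy; ~5x faster than iterating
static void eig_sym3(const double A[9], double w[3], double V[9]) {
  double tr = (A[0] + A[4] + A[8]) / 3.0;
  double B[9];
  for (int i = 0; i < 9; ++i) B[i] = A[i];
  B[0] -= tr; B[4] -= tr; B[8] -= tr;
  double p2 = 0;
  for (int i = 0; i < 9; ++i) p2 += B[i] * B[i];
  double p = std::sqrt(p2 / 6.0);
  if (p < 1e-12 * (std::fabs(tr) + 1e-300)) {   // (near) spherical tensor
    w[0] = w[1] = w[2] = tr;
    for (int i = 0; i < 9; ++i) V[i] = 0.0;
    V[0] = V[4] = V[8] = 1.0;
    return;
  }
  double detB = det3(B);
  double r = detB / (2.0 * p * p * p);
  r = std::min(1.0, std::max(-1.0, r));
  double phi = std::acos(r) / 3.0;
  double e0 = tr + 2.0 * p * std::cos(phi);
  double e2 = tr + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  double e1 = 3.0 * tr - e0 - e2;
  double ev[3] = {e2, e1, e0};                   // ascending
  // relative separation guard: fall back to Jacobi when clustered
  double sep = std::min(e0 - e1, e1 - e2);
  if (sep < 1e-6 * (std::fabs(e0) + std::fabs(e2) + 1e-300)) {
    eig_sym3_jacobi(A, w, V);
    return;
  }
  for (int k = 0; k < 3; ++k) {
    w[k] = ev[k];
    // eigenvector: cross product of two rows of (A - ev I)
    double M[9];
    for (int i = 0; i < 9; ++i) M[i] = A[i];
    M[0] -= ev[k]; M[4] -= ev[k]; M[8] -= ev[k];
    double c01[3] = {M[1] * M[5] - M[2] * M[4], M[2] * M[3] - M[0] * M[5],
                     M[0] * M[4] - M[1] * M[3]};
    double c02[3] = {M[1] * M[8] - M[2] * M[7], M[2] * M[6] - M[0] * M[8],
                     M[0] * M[7] - M[1] * M[6]};
    double c12[3] = {M[4] * M[8] - M[5] * M[7], M[5] * M[6] - M[3] * M[8],
                     M[3] * M[7] - M[4] * M[6]};
    double n01 = c01[0]*c01[0]+c01[1]*c01[1]+c01[2]*c01[2];
    double n02 = c02[0]*c02[0]+c02[1]*c02[1]+c02[2]*c02[2];
    double n12 = c12[0]*c12[0]+c12[1]*c12[1]+c12[2]*c12[2];
    const double *best = c01; double nb = n01;
    if (n02 > nb) { best = c02; nb = n02; }
    if (n12 > nb) { best = c12; nb = n12; }
    if (nb < 1e-24) { eig_sym3_jacobi(A, w, V); return; }
    double inv = 1.0 / std::sqrt(nb);
    V[0 + k] = best[0] * inv;
    V[3 + k] = best[1] * inv;
    V[6 + k] = best[2] * inv;
  }
}

// ---- Ogden element kernels -------------------------------------------------

struct OgdenMat {
  std::vector<double> mu, alpha;
  double K;
};

// strain energy density at deformation gradient F (row-major); Inf if J<=0
static double ogden_W(const double F[9], const OgdenMat &m) {
  double J = det3(F);
  if (!(J > 0.0)) return std::numeric_limits<double>::infinity();
  double C[9];
  // C = F^T F
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += F[3 * k + i] * F[3 * k + j];
      C[3 * i + j] = s;
    }
  double w[3], V[9];
  eig_sym3(C, w, V);
  double Jm13 = std::pow(J, -1.0 / 3.0);
  double W = 0.0;
  for (int i = 0; i < 3; ++i) {
    double lb = Jm13 * std::sqrt(std::max(w[i], 1e-300));
    for (size_t j = 0; j < m.mu.size(); ++j)
      W += 2.0 * m.mu[j] / m.alpha[j] * (std::pow(lb, m.alpha[j]) - 1.0);
  }
  W += 0.5 * m.K * (J - 1.0) * (J - 1.0);
  return W;
}

// first Piola-Kirchhoff stress P(F) (row-major out); returns false if J<=0
static bool ogden_P(const double F[9], const OgdenMat &m, double P[9]) {
  double J = det3(F);
  if (!(J > 0.0)) return false;
  double C[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += F[3 * k + i] * F[3 * k + j];
      C[3 * i + j] = s;
    }
  double w[3], V[9];
  eig_sym3(C, w, V);
  double lam[3], beta[3], Jm13 = std::pow(J, -1.0 / 3.0);
  double bsum = 0.0;
  for (int i = 0; i < 3; ++i) {
    lam[i] = std::sqrt(std::max(w[i], 1e-300));
    double lb = Jm13 * lam[i];
    beta[i] = 0.0;
    for (size_t j = 0; j < m.mu.size(); ++j)
      beta[i] += 2.0 * m.mu[j] * std::pow(lb, m.alpha[j]);
    bsum += beta[i];
  }
  double pvol = m.K * (J - 1.0) * J;
  double coef[3];
  for (int i = 0; i < 3; ++i) {
    double tau = beta[i] - bsum / 3.0 + pvol;   // principal Kirchhoff stress
    coef[i] = tau / (lam[i] * lam[i]);
  }
  // M = sum_i coef_i v_i v_i^T ; P = F M
  double M[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
  for (int i = 0; i < 3; ++i)
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c)
        M[3 * r + c] += coef[i] * V[3 * r + i] * V[3 * c + i];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += F[3 * r + k] * M[3 * k + c];
      P[3 * r + c] = s;
    }
  return true;
}

// deformation gradient of one tet: F = Ds * Bm, with current positions x
static inline void tet_F(const double *x0, const double *x1, const double *x2,
                         const double *x3, const double Bm[9], double F[9]) {
  double Ds[9];
  for (int r = 0; r < 3; ++r) {
    Ds[3 * r + 0] = x1[r] - x0[r];
    Ds[3 * r + 1] = x2[r] - x0[r];
    Ds[3 * r + 2] = x3[r] - x0[r];
  }
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += Ds[3 * r + k] * Bm[3 * k + c];
      F[3 * r + c] = s;
    }
}

// element gradient (dE/dx, 12 components) ; returns false on inversion
static bool tet_grad(const double *x0, const double *x1, const double *x2,
                     const double *x3, const double Bm[9], double V0,
                     const OgdenMat &m, double g[12]) {
  double F[9], P[9];
  tet_F(x0, x1, x2, x3, Bm, F);
  if (!ogden_P(F, m, P)) return false;
  // H = V0 * P * Bm^T : forces on nodes 1..3 are columns of H, node 0 = -sum
  double H[9];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += P[3 * r + k] * Bm[3 * c + k];
      H[3 * r + c] = V0 * s;
    }
  for (int r = 0; r < 3; ++r) {
    g[3 + r] = H[3 * r + 0];
    g[6 + r] = H[3 * r + 1];
    g[9 + r] = H[3 * r + 2];
    g[r] = -(H[3 * r + 0] + H[3 * r + 1] + H[3 * r + 2]);
  }
  return true;
}

// [[Rcpp::export(name = ".fe_precompute")]]
List fe_precompute(NumericMatrix nodes, IntegerMatrix tets) {
  int ne = tets.nrow();
  NumericMatrix Bm(ne, 9);
  NumericVector vol(ne);
  for (int e = 0; e < ne; ++e) {
    int a = tets(e, 0) - 1, b = tets(e, 1) - 1, c = tets(e, 2) - 1,
        d = tets(e, 3) - 1;
    double Dm[9];
    for (int r = 0; r < 3; ++r) {
      Dm[3 * r + 0] = nodes(b, r) - nodes(a, r);
      Dm[3 * r + 1] = nodes(c, r) - nodes(a, r);
      Dm[3 * r + 2] = nodes(d, r) - nodes(a, r);
    }
    double J = det3(Dm);
    if (J <= 0) stop("reference element %d has non-positive volume", e + 1);
    vol[e] = J / 6.0;
    double inv[9];
    inv[0] = (Dm[4] * Dm[8] - Dm[5] * Dm[7]) / J;
    inv[1] = (Dm[2] * Dm[7] - Dm[1] * Dm[8]) / J;
    inv[2] = (Dm[1] * Dm[5] - Dm[2] * Dm[4]) / J;
    inv[3] = (Dm[5] * Dm[6] - Dm[3] * Dm[8]) / J;
    inv[4] = (Dm[0] * Dm[8] - Dm[2] * Dm[6]) / J;
    inv[5] = (Dm[2] * Dm[3] - Dm[0] * Dm[5]) / J;
    inv[6] = (Dm[3] * Dm[7] - Dm[4] * Dm[6]) / J;
    inv[7] = (Dm[1] * Dm[6] - Dm[0] * Dm[7]) / J;
    inv[8] = (Dm[0] * Dm[4] - Dm[1] * Dm[3]) / J;
    for (int k = 0; k < 9; ++k) Bm(e, k) = inv[k];
  }
  return List::create(_["Bm"] = Bm, _["vol0"] = vol);
}

static OgdenMat make_mat(NumericVector mu, NumericVector alpha, double K) {
  OgdenMat m;
  m.mu.assign(mu.begin(), mu.end());
  m.alpha.assign(alpha.begin(), alpha.end());
  m.K = K;
  return m;
}

// current positions: x = nodes + u (both n x 3)
// [[Rcpp::export(name = ".fe_energy")]]
double fe_energy(NumericMatrix nodes, IntegerMatrix tets, NumericMatrix Bm,
                 NumericVector vol0, NumericMatrix u, NumericVector mu,
                 NumericVector alpha, double K) {
  OgdenMat m = make_mat(mu, alpha, K);
  int ne = tets.nrow();
  double E = 0.0;
  double x[4][3], F[9], B[9];
  for (int e = 0; e < ne; ++e) {
    for (int v = 0; v < 4; ++v) {
      int n = tets(e, v) - 1;
      for (int r = 0; r < 3; ++r) x[v][r] = nodes(n, r) + u(n, r);
    }
    for (int k = 0; k < 9; ++k) B[k] = Bm(e, k);
    tet_F(x[0], x[1], x[2], x[3], B, F);
    double W = ogden_W(F, m);
    if (!std::isfinite(W)) return std::numeric_limits<double>::infinity();
    E += vol0[e] * W;
  }
  return E;
}

// [[Rcpp::export(name = ".fe_gradient")]]
NumericMatrix fe_gradient(NumericMatrix nodes, IntegerMatrix tets,
                          NumericMatrix Bm, NumericVector vol0,
                          NumericMatrix u, NumericVector mu,
                          NumericVector alpha, double K) {
  OgdenMat m = make_mat(mu, alpha, K);
  int ne = tets.nrow(), nn = nodes.nrow();
  NumericMatrix G(nn, 3);
  double x[4][3], g[12], B[9];
  std::vector<int> bad;
  for (int e = 0; e < ne; ++e) {
    int id[4];
    for (int v = 0; v < 4; ++v) {
      id[v] = tets(e, v) - 1;
      for (int r = 0; r < 3; ++r) x[v][r] = nodes(id[v], r) + u(id[v], r);
    }
    for (int k = 0; k < 9; ++k) B[k] = Bm(e, k);
    if (!tet_grad(x[0], x[1], x[2], x[3], B, vol0[e], m, g)) {
      bad.push_back(e + 1);
      continue;
    }
    for (int v = 0; v < 4; ++v)
      for (int r = 0; r < 3; ++r) G(id[v], r) += g[3 * v + r];
  }
  if (!bad.empty()) {
    IntegerVector iv(bad.begin(), bad.end());
    G.attr("inverted_elements") = iv;
  }
  return G;
}

// gradient plus element tangent blocks (forward finite differences of the
// element gradient, symmetrised), returned as triplets for sparse assembly.
// [[Rcpp::export(name = ".fe_assemble")]]
List fe_assemble(NumericMatrix nodes, IntegerMatrix tets, NumericMatrix Bm,
                 NumericVector vol0, NumericMatrix u, NumericVector mu,
                 NumericVector alpha, double K, double fd_step) {
  OgdenMat m = make_mat(mu, alpha, K);
  int ne = tets.nrow(), nn = nodes.nrow();
  NumericMatrix G(nn, 3);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve((size_t)ne * 144); tj.reserve((size_t)ne * 144);
  tx.reserve((size_t)ne * 144);
  double x[4][3], g0[12], gp[12], Kel[144], B[9];
  std::vector<int> bad;
  for (int e = 0; e < ne; ++e) {
    int id[4];
    for (int v = 0; v < 4; ++v) {
      id[v] = tets(e, v) - 1;
      for (int r = 0; r < 3; ++r) x[v][r] = nodes(id[v], r) + u(id[v], r);
    }
    for (int k = 0; k < 9; ++k) B[k] = Bm(e, k);
    if (!tet_grad(x[0], x[1], x[2], x[3], B, vol0[e], m, g0)) {
      bad.push_back(e + 1);
      for (int i = 0; i < 144; ++i) Kel[i] = 0.0;
      for (int i = 0; i < 12; ++i)
        for (int j = 0; j < 12; ++j) {
          ti.push_back(3 * id[i / 3] + i % 3 + 1);
          tj.push_back(3 * id[j / 3] + j % 3 + 1);
          tx.push_back(0.0);
        }
      continue;
    }
    for (int v = 0; v < 4; ++v)
      for (int r = 0; r < 3; ++r) G(id[v], r) += g0[3 * v + r];
    bool ok = true;
    for (int dof = 0; dof < 12 && ok; ++dof) {
      int v = dof / 3, r = dof % 3;
      x[v][r] += fd_step;
      ok = tet_grad(x[0], x[1], x[2], x[3], B, vol0[e], m, gp);
      x[v][r] -= fd_step;
      if (!ok) break;
      for (int i = 0; i < 12; ++i)
        Kel[12 * i + dof] = (gp[i] - g0[i]) / fd_step;
    }
    if (!ok) {
      // fall back: tiny central step (keeps assembly going near inversion)
      for (int i = 0; i < 144; ++i) Kel[i] = 0.0;
    }
    // fixed-size, fixed-order triplet block (keeps the assembly pattern
    // constant across iterations so the CSC mapping can be precomputed)
    for (int i = 0; i < 12; ++i)
      for (int j = 0; j < 12; ++j) {
        ti.push_back(3 * id[i / 3] + i % 3 + 1);
        tj.push_back(3 * id[j / 3] + j % 3 + 1);
        tx.push_back(0.5 * (Kel[12 * i + j] + Kel[12 * j + i]));
      }
  }
  List out = List::create(_["grad"] = G,
                          _["i"] = IntegerVector(ti.begin(), ti.end()),
                          _["j"] = IntegerVector(tj.begin(), tj.end()),
                          _["x"] = NumericVector(tx.begin(), tx.end()));
  if (!bad.empty()) out["inverted"] = IntegerVector(bad.begin(), bad.end());
  return out;
}

// per-element deformation state for postprocessing
// [[Rcpp::export(name = ".fe_element_state")]]
List fe_element_state(NumericMatrix nodes, IntegerMatrix tets, NumericMatrix Bm,
                      NumericVector vol0, NumericMatrix u, NumericVector mu,
                      NumericVector alpha, double K) {
  OgdenMat m = make_mat(mu, alpha, K);
  int ne = tets.nrow();
  NumericMatrix Fout(ne, 9), Sout(ne, 6);
  NumericVector vm(ne), Jv(ne);
  double x[4][3], F[9], B[9];
  for (int e = 0; e < ne; ++e) {
    for (int v = 0; v < 4; ++v) {
      int n = tets(e, v) - 1;
      for (int r = 0; r < 3; ++r) x[v][r] = nodes(n, r) + u(n, r);
    }
    for (int k = 0; k < 9; ++k) B[k] = Bm(e, k);
    tet_F(x[0], x[1], x[2], x[3], B, F);
    for (int k = 0; k < 9; ++k) Fout(e, k) = F[k];
    double J = det3(F);
    Jv[e] = J;
    if (!(J > 0)) { vm[e] = NA_REAL; continue; }
    // left Cauchy-Green b = F F^T
    double b[9];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += F[3 * i + k] * F[3 * j + k];
        b[3 * i + j] = s;
      }
    double w[3], V[9];
    eig_sym3(b, w, V);
    double Jm13 = std::pow(J, -1.0 / 3.0);
    double beta[3], bsum = 0, lam[3];
    for (int i = 0; i < 3; ++i) {
      lam[i] = std::sqrt(std::max(w[i], 1e-300));
      double lb = Jm13 * lam[i];
      beta[i] = 0;
      for (size_t j = 0; j < m.mu.size(); ++j)
        beta[i] += 2.0 * m.mu[j] * std::pow(lb, m.alpha[j]);
      bsum += beta[i];
    }
    double pvol = m.K * (J - 1.0) * J;
    double sig[3];
    for (int i = 0; i < 3; ++i)
      sig[i] = (beta[i] - bsum / 3.0 + pvol) / J;
    vm[e] = std::sqrt(0.5 * ((sig[0] - sig[1]) * (sig[0] - sig[1]) +
                             (sig[1] - sig[2]) * (sig[1] - sig[2]) +
                             (sig[2] - sig[0]) * (sig[2] - sig[0])));
    // full tensor: sum_i sig_i n_i n_i^T with n_i the eigenvectors of b
    double S[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
    for (int i = 0; i < 3; ++i)
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c)
          S[3 * r + c] += sig[i] * V[3 * r + i] * V[3 * c + i];
    Sout(e, 0) = S[0]; Sout(e, 1) = S[4]; Sout(e, 2) = S[8];
    Sout(e, 3) = S[1]; Sout(e, 4) = S[5]; Sout(e, 5) = S[2];
  }
  return List::create(_["F"] = Fout, _["cauchy"] = Sout, _["vm"] = vm,
                      _["J"] = Jv);
}

// ---- contact ---------------------------------------------------------------

// closest point on triangle abc to point p (Ericson, Real-Time Collision
// Detection); out = closest point
static void closest_on_tri(const double *p, const double *a, const double *b,
                           const double *c, double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// precomputed acceleration structure for one posed rigid surface: uniform
// grid over the AABB, triangle and (area-weighted) vertex normals, and a
// radial star-shape table about the centre for the deep interior
struct ContactSet {
  std::vector<double> verts;   // 3V
  std::vector<int> tris;       // 3T, 0-based
  std::vector<double> tn, vn;  // triangle / vertex normals
  std::vector<std::vector<int>> grid;
  double lo[3], hi[3], cell;
  int dim[3];
  double ctr[3];
  std::vector<double> rtab;
  int nlat, nlon;
};

static double radial_lookup(const ContactSet &cs, const double *d, double rr) {
  if (rr < 1e-12) return cs.rtab[(size_t)(cs.nlat / 2) * cs.nlon];
  double lat = std::acos(std::min(1.0, std::max(-1.0, d[2] / rr)));
  double lon = std::atan2(d[1], d[0]) + M_PI;
  int i = std::min(cs.nlat - 1, (int)(lat / M_PI * cs.nlat));
  int j = std::min(cs.nlon - 1, (int)(lon / (2 * M_PI) * cs.nlon));
  return cs.rtab[(size_t)i * cs.nlon + j];
}

// [[Rcpp::export(name = ".contact_prepare")]]
SEXP contact_prepare(NumericMatrix verts, IntegerMatrix tris, double cell,
                     NumericVector center) {
  Rcpp::XPtr<ContactSet> cs(new ContactSet, true);
  int nv = verts.nrow(), nt = tris.nrow();
  cs->verts.resize(3 * nv);
  for (int v = 0; v < nv; ++v)
    for (int r = 0; r < 3; ++r) cs->verts[3 * v + r] = verts(v, r);
  cs->tris.resize(3 * nt);
  for (int t = 0; t < nt; ++t)
    for (int k = 0; k < 3; ++k) cs->tris[3 * t + k] = tris(t, k) - 1;
  cs->tn.assign(3 * nt, 0.0);
  cs->vn.assign(3 * nv, 0.0);
  for (int r = 0; r < 3; ++r) { cs->lo[r] = 1e300; cs->hi[r] = -1e300; }
  for (int v = 0; v < nv; ++v)
    for (int r = 0; r < 3; ++r) {
      cs->lo[r] = std::min(cs->lo[r], verts(v, r));
      cs->hi[r] = std::max(cs->hi[r], verts(v, r));
    }
  for (int t = 0; t < nt; ++t) {
    int a = cs->tris[3 * t], b = cs->tris[3 * t + 1], c = cs->tris[3 * t + 2];
    double u[3], v[3];
    for (int r = 0; r < 3; ++r) {
      u[r] = verts(b, r) - verts(a, r);
      v[r] = verts(c, r) - verts(a, r);
    }
    double n[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                   u[0] * v[1] - u[1] * v[0]};
    double nn = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
    if (nn < 1e-12) stop("degenerate rigid triangle %d", t + 1);
    for (int r = 0; r < 3; ++r) {
      cs->tn[3 * t + r] = n[r] / nn;
      cs->vn[3 * a + r] += n[r];
      cs->vn[3 * b + r] += n[r];
      cs->vn[3 * c + r] += n[r];
    }
  }
  for (int v = 0; v < nv; ++v) {
    double nn = std::sqrt(cs->vn[3 * v] * cs->vn[3 * v] +
                          cs->vn[3 * v + 1] * cs->vn[3 * v + 1] +
                          cs->vn[3 * v + 2] * cs->vn[3 * v + 2]);
    if (nn > 1e-12)
      for (int r = 0; r < 3; ++r) cs->vn[3 * v + r] /= nn;
  }
  cs->cell = std::max(cell, 1e-6);
  for (int r = 0; r < 3; ++r) {
    cs->lo[r] -= cs->cell; cs->hi[r] += cs->cell;
    cs->dim[r] = std::max(1, (int)std::ceil((cs->hi[r] - cs->lo[r]) / cs->cell));
  }
  cs->grid.assign((size_t)cs->dim[0] * cs->dim[1] * cs->dim[2], {});
  auto cidx = [&](double x, int r) {
    int i = (int)std::floor((x - cs->lo[r]) / cs->cell);
    return std::min(std::max(i, 0), cs->dim[r] - 1);
  };
  for (int t = 0; t < nt; ++t) {
    double tlo[3] = {1e300, 1e300, 1e300}, thi[3] = {-1e300, -1e300, -1e300};
    for (int k = 0; k < 3; ++k) {
      int n = cs->tris[3 * t + k];
      for (int r = 0; r < 3; ++r) {
        tlo[r] = std::min(tlo[r], verts(n, r));
        thi[r] = std::max(thi[r], verts(n, r));
      }
    }
    int i0[3], i1[3];
    for (int r = 0; r < 3; ++r) { i0[r] = cidx(tlo[r], r); i1[r] = cidx(thi[r], r); }
    for (int i = i0[0]; i <= i1[0]; ++i)
      for (int j = i0[1]; j <= i1[1]; ++j)
        for (int k = i0[2]; k <= i1[2]; ++k)
          cs->grid[((size_t)i * cs->dim[1] + j) * cs->dim[2] + k].push_back(t);
  }
  for (int r = 0; r < 3; ++r) cs->ctr[r] = center[r];
  cs->nlat = 24; cs->nlon = 48;
  cs->rtab.assign((size_t)cs->nlat * cs->nlon, 0.0);
  for (int v = 0; v < nv; ++v) {
    double d[3] = {verts(v, 0) - cs->ctr[0], verts(v, 1) - cs->ctr[1],
                   verts(v, 2) - cs->ctr[2]};
    double rr = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (rr < 1e-12) continue;
    double lat = std::acos(std::min(1.0, std::max(-1.0, d[2] / rr)));
    double lon = std::atan2(d[1], d[0]) + M_PI;
    int i = std::min(cs->nlat - 1, (int)(lat / M_PI * cs->nlat));
    int j = std::min(cs->nlon - 1, (int)(lon / (2 * M_PI) * cs->nlon));
    cs->rtab[(size_t)i * cs->nlon + j] =
        std::max(cs->rtab[(size_t)i * cs->nlon + j], rr);
  }
  // fill only EMPTY bins from their neighbours (no inflation of known bins)
  for (int pass = 0; pass < 4; ++pass) {
    std::vector<double> rt2 = cs->rtab;
    for (int i = 0; i < cs->nlat; ++i)
      for (int j = 0; j < cs->nlon; ++j) {
        if (cs->rtab[(size_t)i * cs->nlon + j] > 0) continue;
        double m = 0;
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            int ii = i + di;
            if (ii < 0 || ii >= cs->nlat) continue;
            int jj = (j + dj + cs->nlon) % cs->nlon;
            m = std::max(m, cs->rtab[(size_t)ii * cs->nlon + jj]);
          }
        rt2[(size_t)i * cs->nlon + j] = m;
      }
    cs->rtab = rt2;
  }
  return cs;
}

// Signed gaps of points against a prepared contact set.  depth > 0 means
// penetration; normals are barycentrically-interpolated vertex normals at
// the closest point (smooth across facets).
// [[Rcpp::export(name = ".contact_query")]]
List contact_query(SEXP csp, NumericMatrix pts, double search_radius) {
  Rcpp::XPtr<ContactSet> cs(csp);
  int np = pts.nrow();
  NumericVector depth(np);
  NumericMatrix normal(np, 3);
  IntegerVector hit(np);
  const std::vector<double> &verts = cs->verts;
  auto cidx = [&](double x, int r) {
    int i = (int)std::floor((x - cs->lo[r]) / cs->cell);
    return std::min(std::max(i, 0), cs->dim[r] - 1);
  };
  int reach = std::max(1, (int)std::ceil(search_radius / cs->cell));
  for (int pI = 0; pI < np; ++pI) {
    double p[3] = {pts(pI, 0), pts(pI, 1), pts(pI, 2)};
    bool in_box = p[0] >= cs->lo[0] && p[0] <= cs->hi[0] &&
                  p[1] >= cs->lo[1] && p[1] <= cs->hi[1] &&
                  p[2] >= cs->lo[2] && p[2] <= cs->hi[2];
    if (!in_box) continue;
    int ci = cidx(p[0], 0), cj = cidx(p[1], 1), ck = cidx(p[2], 2);
    double best = search_radius * search_radius;
    int best_t = -1;
    double best_cp[3] = {0, 0, 0};
    for (int di = -reach; di <= reach; ++di)
      for (int dj = -reach; dj <= reach; ++dj)
        for (int dk = -reach; dk <= reach; ++dk) {
          int i = ci + di, j = cj + dj, k = ck + dk;
          if (i < 0 || j < 0 || k < 0 || i >= cs->dim[0] || j >= cs->dim[1] ||
              k >= cs->dim[2])
            continue;
          const std::vector<int> &lst =
              cs->grid[((size_t)i * cs->dim[1] + j) * cs->dim[2] + k];
          for (size_t qi = 0; qi < lst.size(); ++qi) {
            int t = lst[qi];
            const double *a = &verts[3 * cs->tris[3 * t]];
            const double *b = &verts[3 * cs->tris[3 * t + 1]];
            const double *c = &verts[3 * cs->tris[3 * t + 2]];
            double cp[3];
            closest_on_tri(p, a, b, c, cp);
            double d2 = 0;
            for (int r = 0; r < 3; ++r) d2 += (p[r] - cp[r]) * (p[r] - cp[r]);
            if (d2 < best) {
              best = d2; best_t = t;
              for (int r = 0; r < 3; ++r) best_cp[r] = cp[r];
            }
          }
        }
    if (best_t >= 0) {
      int a = cs->tris[3 * best_t], b = cs->tris[3 * best_t + 1],
          c = cs->tris[3 * best_t + 2];
      double e0[3], e1[3], ep[3];
      for (int r = 0; r < 3; ++r) {
        e0[r] = verts[3 * b + r] - verts[3 * a + r];
        e1[r] = verts[3 * c + r] - verts[3 * a + r];
        ep[r] = best_cp[r] - verts[3 * a + r];
      }
      double d00 = e0[0]*e0[0]+e0[1]*e0[1]+e0[2]*e0[2];
      double d01 = e0[0]*e1[0]+e0[1]*e1[1]+e0[2]*e1[2];
      double d11 = e1[0]*e1[0]+e1[1]*e1[1]+e1[2]*e1[2];
      double dp0 = ep[0]*e0[0]+ep[1]*e0[1]+ep[2]*e0[2];
      double dp1 = ep[0]*e1[0]+ep[1]*e1[1]+ep[2]*e1[2];
      double den = d00 * d11 - d01 * d01;
      double w1 = 0, w2 = 0;
      if (std::fabs(den) > 1e-20) {
        w1 = (d11 * dp0 - d01 * dp1) / den;
        w2 = (d00 * dp1 - d01 * dp0) / den;
      }
      w1 = std::min(1.0, std::max(0.0, w1));
      w2 = std::min(1.0 - w1, std::max(0.0, w2));
      double w0 = 1.0 - w1 - w2;
      double ns[3];
      for (int r = 0; r < 3; ++r)
        ns[r] = w0 * cs->vn[3 * a + r] + w1 * cs->vn[3 * b + r] +
                w2 * cs->vn[3 * c + r];
      double nl = std::sqrt(ns[0]*ns[0]+ns[1]*ns[1]+ns[2]*ns[2]);
      if (nl < 1e-12) {
        for (int r = 0; r < 3; ++r) ns[r] = cs->tn[3 * best_t + r];
        nl = 1.0;
      }
      double sgn = 0;
      for (int r = 0; r < 3; ++r) sgn += (ns[r] / nl) * (p[r] - best_cp[r]);
      if (sgn < 0) {
        depth[pI] = -sgn;
        hit[pI] = 1;
        for (int r = 0; r < 3; ++r) normal(pI, r) = ns[r] / nl;
      }
    } else {
      double dr[3] = {p[0] - cs->ctr[0], p[1] - cs->ctr[1], p[2] - cs->ctr[2]};
      double dist = std::sqrt(dr[0] * dr[0] + dr[1] * dr[1] + dr[2] * dr[2]);
      double rdir = radial_lookup(*cs, dr, dist);
      if (dist < rdir) {
        // no triangle within the search radius, so the true depth exceeds
        // it; the clamp keeps the barrier continuous across the regimes
        depth[pI] = std::max(search_radius, rdir - dist);
        hit[pI] = 2;
        if (dist > 1e-9)
          for (int r = 0; r < 3; ++r) normal(pI, r) = dr[r] / dist;
        else
          normal(pI, 2) = 1.0;
      }
    }
  }
  return List::create(_["depth"] = depth, _["normal"] = normal,
                      _["hit"] = hit);
}

// one-shot convenience wrapper: prepare + query
// [[Rcpp::export(name = ".contact_gaps")]]
List contact_gaps(NumericMatrix pts, NumericMatrix verts, IntegerMatrix tris,
                  double search_radius, NumericVector center,
                  double min_radius) {
  (void)min_radius;  // interior handling is by the radial table
  SEXP cs = contact_prepare(verts, tris, search_radius, center);
  return contact_query(cs, pts, search_radius);
}

// scatter-add triplet values into a preallocated CSC value slot
// [[Rcpp::export(name = ".scatter_add")]]
NumericVector scatter_add(int nnz, IntegerVector pos, NumericVector vals) {
  NumericVector x(nnz);
  int n = pos.size();
  for (int k = 0; k < n; ++k) x[pos[k] - 1] += vals[k];
  return x;
}

#ifdef __GLIBC__
#include <malloc.h>
#endif
// release freed heap pages back to the OS (glibc keeps large sbrk blocks
// cached otherwise, which looks like a leak over thousands of assemblies)
// [[Rcpp::export(name = ".malloc_trim")]]
void r_malloc_trim() {
#ifdef __GLIBC__
  malloc_trim(0);
#endif
}

// pin the mmap threshold so multi-megabyte factor/assembly buffers are
// mmapped (and thus returned to the OS on free) instead of fragmenting the
// sbrk heap; glibc otherwise raises the threshold dynamically
// [[Rcpp::export(name = ".mem_setup")]]
void r_mem_setup() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 131072);
  mallopt(M_TRIM_THRESHOLD, 131072);
#endif
}
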