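// Total-Lagrangian St. Venant-Kirchhoff kernels for 4-node linear
// tetrahedra (one-point quadrature, exact for constant-strain elements).
// All element loops live here; sparse assembly and the Newton driver are
// on the R side (Matrix package).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Mat3 {
  double a[9]; // row-major
  double &operator()(int i, int j) { return a[3 * i + j]; }
  double operator()(int i, int j) const { return a[3 * i + j]; }
};

inline Mat3 mul(const Mat3 &A, const Mat3 &B) {
  Mat3 C;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += A(i, k) * B(k, j);
      C(i, j) = s;
    }
  return C;
}

inline Mat3 transpose(const Mat3 &A) {
  Mat3 C;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) C(i, j) = A(j, i);
  return C;
}

inline double det3(const Mat3 &A) {
  return A(0, 0) * (A(1, 1) * A(2, 2) - A(1, 2) * A(2, 1)) -
         A(0, 1) * (A(1, 0) * A(2, 2) - A(1, 2) * A(2, 0)) +
         A(0, 2) * (A(1, 0) * A(2, 1) - A(1, 1) * A(2, 0));
}

inline Mat3 inverse(const Mat3 &A, double d) {
  Mat3 C;
  C(0, 0) = (A(1, 1) * A(2, 2) - A(1, 2) * A(2, 1)) / d;
  C(0, 1) = (A(0, 2) * A(2, 1) - A(0, 1) * A(2, 2)) / d;
  C(0, 2) = (A(0, 1) * A(1, 2) - A(0, 2) * A(1, 1)) / d;
  C(1, 0) = (A(1, 2) * A(2, 0) - A(1, 0) * A(2, 2)) / d;
  C(1, 1) = (A(0, 0) * A(2, 2) - A(0, 2) * A(2, 0)) / d;
  C(1, 2) = (A(0, 2) * A(1, 0) - A(0, 0) * A(1, 2)) / d;
  C(2, 0) = (A(1, 0) * A(2, 1) - A(1, 1) * A(2, 0)) / d;
  C(2, 1) = (A(0, 1) * A(2, 0) - A(0, 0) * A(2, 1)) / d;
  C(2, 2) = (A(0, 0) * A(1, 1) - A(0, 1) * A(1, 0)) / d;
  return C;
}

// Green-Lagrange strain E = (F'F - I)/2
inline Mat3 green_strain(const Mat3 &F) {
  Mat3 E = mul(transpose(F), F);
  for (int i = 0; i < 9; ++i) E.a[i] *= 0.5;
  E(0, 0) -= 0.5; E(1, 1) -= 0.5; E(2, 2) -= 0.5;
  return E;
}

// Generalized Hookean stress S = lambda tr(E) I + 2 mu E
inline Mat3 svk_stress(const Mat3 &E, double lambda, double mu) {
  double tr = E(0, 0) + E(1, 1) + E(2, 2);
  Mat3 S;
  for (int i = 0; i < 9; ++i) S.a[i] = 2.0 * mu * E.a[i];
  S(0, 0) += lambda * tr; S(1, 1) += lambda * tr; S(2, 2) += lambda * tr;
  return S;
}

inline double ddot(const Mat3 &A, const Mat3 &B) {
  double s = 0;
  for (int i = 0; i < 9; ++i) s += A.a[i] * B.a[i];
  return s;
}

// Gather reference-shape data for element e: Bm = Dm^{-1}, V0
inline void element_setup(const NumericMatrix &nodes, const IntegerMatrix &tets,
                          int e, Mat3 &Bm, double &V0, bool &ok) {
  int n0 = tets(e, 0) - 1, n1 = tets(e, 1) - 1, n2 = tets(e, 2) - 1,
      n3 = tets(e, 3) - 1;
  Mat3 Dm;
  for (int k = 0; k < 3; ++k) {
    Dm(k, 0) = nodes(n1, k) - nodes(n0, k);
    Dm(k, 1) = nodes(n2, k) - nodes(n0, k);
    Dm(k, 2) = nodes(n3, k) - nodes(n0, k);
  }
  double d = det3(Dm);
  V0 = d / 6.0;
  ok = d > 0;
  if (ok) Bm = inverse(Dm, d);
}

inline Mat3 def_gradient(const NumericMatrix &u, const IntegerMatrix &tets,
                         int e, const Mat3 &Bm) {
  int n0 = tets(e, 0) - 1, n1 = tets(e, 1) - 1, n2 = tets(e, 2) - 1,
      n3 = tets(e, 3) - 1;
  Mat3 Du;
  for (int k = 0; k < 3; ++k) {
    Du(k, 0) = u(n1, k) - u(n0, k);
    Du(k, 1) = u(n2, k) - u(n0, k);
    Du(k, 2) = u(n3, k) - u(n0, k);
  }
  Mat3 F = mul(Du, Bm);
  F(0, 0) += 1.0; F(1, 1) += 1.0; F(2, 2) += 1.0;
  return F;
}

} // namespace

// [[Rcpp::export(name = ".fem_force")]]
NumericMatrix fem_force(NumericMatrix nodes, IntegerMatrix tets,
                        NumericMatrix u, NumericVector lambda,
                        NumericVector mu) {
  int n = nodes.nrow(), m = tets.nrow();
  NumericMatrix force(n, 3);
  for (int e = 0; e < m; ++e) {
    Mat3 Bm; double V0; bool ok;
    element_setup(nodes, tets, e, Bm, V0, ok);
    if (!ok) stop("inverted reference element %d", e + 1);
    Mat3 F = def_gradient(u, tets, e, Bm);
    Mat3 E = green_strain(F);
    Mat3 S = svk_stress(E, lambda[e], mu[e]);
    Mat3 P = mul(F, S);
    Mat3 H = mul(P, transpose(Bm)); // columns: forces on nodes 2..4 / V0
    for (int k = 0; k < 3; ++k) {
      double f1 = V0 * H(k, 0), f2 = V0 * H(k, 1), f3 = V0 * H(k, 2);
      force(tets(e, 1) - 1, k) += f1;
      force(tets(e, 2) - 1, k) += f2;
      force(tets(e, 3) - 1, k) += f3;
      force(tets(e, 0) - 1, k) -= f1 + f2 + f3;
    }
  }
  return force;
}

// Consistent tangent: exact directional derivatives of the internal force,
// assembled as COO triplets (1-based DOF indices, dof = 3*(node-1)+k+1).
// [[Rcpp::export(name = ".fem_tangent_triplets")]]
List fem_tangent_triplets(NumericMatrix nodes, IntegerMatrix tets,
                          NumericMatrix u, NumericVector lambda,
                          NumericVector mu) {
  int m = tets.nrow();
  IntegerVector I(144 * (R_xlen_t)m), J(144 * (R_xlen_t)m);
  NumericVector X(144 * (R_xlen_t)m);
  R_xlen_t pos = 0;
  for (int e = 0; e < m; ++e) {
    Mat3 Bm; double V0; bool ok;
    element_setup(nodes, tets, e, Bm, V0, ok);
    if (!ok) stop("inverted reference element %d", e + 1);
    Mat3 F = def_gradient(u, tets, e, Bm);
    Mat3 E = green_strain(F);
    Mat3 S = svk_stress(E, lambda[e], mu[e]);
    int nd[4] = {tets(e, 0) - 1, tets(e, 1) - 1, tets(e, 2) - 1,
                 tets(e, 3) - 1};
    double Ke[12][12];
    // column (j,k): perturb node j, coordinate k
    for (int j = 0; j < 4; ++j) {
      for (int k = 0; k < 3; ++k) {
        Mat3 dDu;
        for (int i = 0; i < 9; ++i) dDu.a[i] = 0;
        if (j == 0) {
          dDu(k, 0) = -1; dDu(k, 1) = -1; dDu(k, 2) = -1;
        } else {
          dDu(k, j - 1) = 1;
        }
        Mat3 dF = mul(dDu, Bm);
        // dE = (dF'F + F'dF)/2
        Mat3 dE = mul(transpose(dF), F);
        Mat3 FtdF = mul(transpose(F), dF);
        for (int i = 0; i < 9; ++i) dE.a[i] = 0.5 * (dE.a[i] + FtdF.a[i]);
        Mat3 dS = svk_stress(dE, lambda[e], mu[e]);
        Mat3 dP = mul(dF, S);
        Mat3 FdS = mul(F, dS);
        for (int i = 0; i < 9; ++i) dP.a[i] += FdS.a[i];
        Mat3 dH = mul(dP, transpose(Bm));
        int col = 3 * j + k;
        for (int kk = 0; kk < 3; ++kk) {
          double g1 = V0 * dH(kk, 0), g2 = V0 * dH(kk, 1),
                 g3 = V0 * dH(kk, 2);
          Ke[3 * 1 + kk][col] = g1;
          Ke[3 * 2 + kk][col] = g2;
          Ke[3 * 3 + kk][col] = g3;
          Ke[3 * 0 + kk][col] = -(g1 + g2 + g3);
        }
      }
    }
    for (int a = 0; a < 4; ++a)
      for (int ka = 0; ka < 3; ++ka)
        for (int b = 0; b < 4; ++b)
          for (int kb = 0; kb < 3; ++kb) {
            I[pos] = 3 * nd[a] + ka + 1;
            J[pos] = 3 * nd[b] + kb + 1;
            X[pos] = Ke[3 * a + ka][3 * b + kb];
            ++pos;
          }
  }
  return List::create(_["i"] = I, _["j"] = J, _["x"] = X);
}

// Total strain energy, nonlinear (St.V-K on Green-Lagrange strain) or
// small-strain linear-elastic on the same displacement field.
// [[Rcpp::export(name = ".fem_energy")]]
double fem_energy(NumericMatrix nodes, IntegerMatrix tets, NumericMatrix u,
                  NumericVector lambda, NumericVector mu, bool linear) {
  int m = tets.nrow();
  double W = 0;
  for (int e = 0; e < m; ++e) {
    Mat3 Bm; double V0; bool ok;
    element_setup(nodes, tets, e, Bm, V0, ok);
    if (!ok) stop("inverted reference element %d", e + 1);
    Mat3 F = def_gradient(u, tets, e, Bm);
    Mat3 E;
    if (linear) {
      // eps = (grad u + grad u')/2, grad u = F - I
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          E(i, j) = 0.5 * (F(i, j) + F(j, i)) - (i == j ? 1.0 : 0.0);
    } else {
      E = green_strain(F);
    }
    Mat3 S = svk_stress(E, lambda[e], mu[e]);
    W += 0.5 * V0 * ddot(S, E);
  }
  return W;
}

// Smallest deformed-element volume (inversion guard for load stepping).
// [[Rcpp::export(name = ".fem_min_det")]]
double fem_min_det(NumericMatrix nodes, IntegerMatrix tets, NumericMatrix u) {
  int m = tets.nrow();
  double mind = R_PosInf;
  for (int e = 0; e < m; ++e) {
    Mat3 Bm; double V0; bool ok;
    element_setup(nodes, tets, e, Bm, V0, ok);
    if (!ok) stop("inverted reference element %d", e + 1);
    Mat3 F = def_gradient(u, tets, e, Bm);
    double d = det3(F);
    if (d < mind) mind = d;
  }
  return mind;
}
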