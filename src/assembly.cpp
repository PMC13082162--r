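// Core quadrature-point constitutive evaluation and volume-term assembly for
// the stabilized mixed (P1-P1) quasi-static momentum balance.
//
// Units: lengths mm, stresses kPa, times ms.  Linear tetrahedra with one
// quadrature point per element (F and p-gradient are element-wise constant;
// the pressure unknown itself is nodal/linear).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct MatPar { double C, bff, bxx, bfx; };
struct ActPar { double Ca0, Camax, B, l0, lref; };

inline double det3(const double F[3][3]) {
  return F[0][0] * (F[1][1] * F[2][2] - F[1][2] * F[2][1])
       - F[0][1] * (F[1][0] * F[2][2] - F[1][2] * F[2][0])
       + F[0][2] * (F[1][0] * F[2][1] - F[1][1] * F[2][0]);
}

// inverse transpose: (F^-T)_ij = cof(F)_ij / J
inline void invT3(const double F[3][3], double J, double FiT[3][3]) {
  FiT[0][0] = (F[1][1] * F[2][2] - F[1][2] * F[2][1]) / J;
  FiT[0][1] = (F[1][2] * F[2][0] - F[1][0] * F[2][2]) / J;
  FiT[0][2] = (F[1][0] * F[2][1] - F[1][1] * F[2][0]) / J;
  FiT[1][0] = (F[0][2] * F[2][1] - F[0][1] * F[2][2]) / J;
  FiT[1][1] = (F[0][0] * F[2][2] - F[0][2] * F[2][0]) / J;
  FiT[1][2] = (F[0][1] * F[2][0] - F[0][0] * F[2][1]) / J;
  FiT[2][0] = (F[0][1] * F[1][2] - F[0][2] * F[1][1]) / J;
  FiT[2][1] = (F[0][2] * F[1][0] - F[0][0] * F[1][2]) / J;
  FiT[2][2] = (F[0][0] * F[1][1] - F[0][1] * F[1][0]) / J;
}

inline void bmatrix(const MatPar& mp, double b[3][3]) {
  b[0][0] = mp.bff;
  b[0][1] = b[1][0] = b[0][2] = b[2][0] = mp.bfx;
  b[1][1] = b[2][2] = b[1][2] = b[2][1] = mp.bxx;
}

// Fung-type transversely isotropic strain energy W = C/2 (exp(Q) - 1),
// Q = sum_ij b_ij Ehat_ij^2 with Ehat the Green-Lagrange strain expressed in
// the (fiber, sheet, sheet-normal) triad.  Returns second Piola-Kirchhoff
// stress S and (optionally) the material tangent D = dS/dE, both in the
// global frame.  R rows are the triad vectors.  Returns false on exp overflow.
bool fung_eval(const double E[3][3], const double R[3][3], const MatPar& mp,
               double S[3][3], double D[3][3][3][3], double* W, bool wantD) {
  double b[3][3];
  bmatrix(mp, b);
  double Eh[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0.0;
      for (int a = 0; a < 3; ++a)
        for (int c = 0; c < 3; ++c) s += R[i][a] * E[a][c] * R[j][c];
      Eh[i][j] = s;
    }
  double Q = 0.0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) Q += b[i][j] * Eh[i][j] * Eh[i][j];
  if (Q > 250.0) return false;  // exp overflow guard
  double k = mp.C * std::exp(Q);
  if (W) *W = 0.5 * (k - mp.C);  // C/2 (e^Q - 1)
  double Sh[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) Sh[i][j] = k * b[i][j] * Eh[i][j];
  for (int a = 0; a < 3; ++a)
    for (int c = 0; c < 3; ++c) {
      double s = 0.0;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) s += R[i][a] * Sh[i][j] * R[j][c];
      S[a][c] = s;
    }
  if (wantD) {
    // D_abcd = k sum_ij b_ij M^(ij)_ab M^(ij)_cd + (2/k) S_ab S_cd,
    // M^(ij)_ab = R_ia R_jb
    for (int a = 0; a < 3; ++a)
      for (int c = 0; c < 3; ++c)
        for (int e = 0; e < 3; ++e)
          for (int f = 0; f < 3; ++f) D[a][c][e][f] = (2.0 / k) * S[a][c] * S[e][f];
    // minor-symmetrized in the last index pair so that contraction with the
    // unsymmetrized F^T dF yields the correct dS
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double bij = k * b[i][j];
        for (int a = 0; a < 3; ++a)
          for (int c = 0; c < 3; ++c) {
            double m1 = R[i][a] * R[j][c];
            if (m1 == 0.0) continue;
            for (int e = 0; e < 3; ++e)
              for (int f = 0; f < 3; ++f)
                D[a][c][e][f] += 0.5 * bij * m1 *
                  (R[i][e] * R[j][f] + R[i][f] * R[j][e]);
          }
      }
  }
  return true;
}

// length-dependent activation gate g(l) = Ca0^2 / (Ca0^2 + ECa50(l)^2) with
// ECa50 = Ca0max / sqrt(exp(B (l - l0)) - 1); defined 0 for l <= l0.
inline void gate_eval(double l, const ActPar& ap, double* g, double* dgdl) {
  double x = ap.B * (l - ap.l0);
  if (x <= 0.0) { *g = 0.0; if (dgdl) *dgdl = 0.0; return; }
  double ex = std::expm1(x);  // e^x - 1
  double c02 = ap.Ca0 * ap.Ca0, cm2 = ap.Camax * ap.Camax;
  double den = c02 * ex + cm2;
  *g = c02 * ex / den;
  if (dgdl) *dgdl = ap.B * c02 * (ex + 1.0) * cm2 / (den * den);
}

// active first Piola-Kirchhoff stress P = T(lam) w f0^T / lam, w = F f0,
// T(lam) = act * gate(lref lam); act = T_ref * C_t(t) supplied by caller.
// Optionally the tangent A_iJkL = dP_iJ/dF_kL.
bool active_eval(const double F[3][3], const double f0[3], double act,
                 const ActPar& ap, double P[3][3], double A[3][3][3][3],
                 bool wantA, double* l_out, double* g_out) {
  double w[3];
  for (int i = 0; i < 3; ++i)
    w[i] = F[i][0] * f0[0] + F[i][1] * f0[1] + F[i][2] * f0[2];
  double lam = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (lam <= 1e-12) return false;
  double l = ap.lref * lam, g, dgdl;
  gate_eval(l, ap, &g, &dgdl);
  if (l_out) *l_out = l;
  if (g_out) *g_out = g;
  double T = act * g;
  double dTdlam = act * dgdl * ap.lref;
  for (int i = 0; i < 3; ++i)
    for (int J = 0; J < 3; ++J) P[i][J] = (T / lam) * w[i] * f0[J];
  if (wantA) {
    double c1 = (dTdlam / lam - T / (lam * lam)) / lam;
    for (int i = 0; i < 3; ++i)
      for (int J = 0; J < 3; ++J)
        for (int k = 0; k < 3; ++k)
          for (int L = 0; L < 3; ++L) {
            double v = c1 * w[k] * f0[L] * w[i] * f0[J];
            if (i == k) v += (T / lam) * f0[J] * f0[L];
            A[i][J][k][L] = v;
          }
  }
  return true;
}

inline MatPar as_matpar(const NumericVector& v) {
  MatPar m; m.C = v[0]; m.bff = v[1]; m.bxx = v[2]; m.bfx = v[3]; return m;
}
inline ActPar as_actpar(const NumericVector& v) {
  ActPar a; a.Ca0 = v[0]; a.Camax = v[1]; a.B = v[2]; a.l0 = v[3]; a.lref = v[4];
  return a;
}

}  // namespace

// [[Rcpp::export]]
List cpp_fung_point(NumericMatrix Fmat, NumericMatrix triad, NumericVector matpar) {
  MatPar mp = as_matpar(matpar);
  double F[3][3], R[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) { F[i][j] = Fmat(i, j); R[i][j] = triad(i, j); }
  double J = det3(F);
  // E = (F^T F - I)/2
  double E[3][3];
  for (int a = 0; a < 3; ++a)
    for (int c = 0; c < 3; ++c) {
      double s = 0.0;
      for (int i = 0; i < 3; ++i) s += F[i][a] * F[i][c];
      E[a][c] = 0.5 * (s - (a == c ? 1.0 : 0.0));
    }
  double S[3][3], D[3][3][3][3], W;
  if (!fung_eval(E, R, mp, S, D, &W, false))
    stop("strain-energy exponent overflow (|E| too large)");
  NumericMatrix Sout(3, 3), Pout(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      Sout(i, j) = S[i][j];
      double s = 0.0;
      for (int a = 0; a < 3; ++a) s += F[i][a] * S[a][j];
      Pout(i, j) = s;  // P = F S
    }
  return List::create(_["W"] = W, _["S"] = Sout, _["P"] = Pout, _["J"] = J);
}

// [[Rcpp::export]]
NumericVector cpp_gate(NumericVector l, NumericVector actpar) {
  ActPar ap = as_actpar(actpar);
  NumericVector out(l.size());
  for (R_xlen_t i = 0; i < l.size(); ++i) {
    double g, d;
    gate_eval(l[i], ap, &g, &d);
    out[i] = g;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_active_point(NumericMatrix Fmat, NumericVector f0v, double act,
                      NumericVector actpar) {
  ActPar ap = as_actpar(actpar);
  double F[3][3], f0[3] = { f0v[0], f0v[1], f0v[2] };
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) F[i][j] = Fmat(i, j);
  double P[3][3], A[3][3][3][3], l, g;
  if (!active_eval(F, f0, act, ap, P, A, false, &l, &g))
    stop("degenerate kinematics: |F e_f0| = 0");
  NumericMatrix Pout(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) Pout(i, j) = P[i][j];
  return List::create(_["P"] = Pout, _["l"] = l, _["gate"] = g);
}

// Assemble volume contributions of the weak form residual and (optionally)
// its consistent tangent:
//   R_u : int (F S + P_act - p J F^-T) : grad(du) dV
//   R_p : -int dp (J - 1) dV
// Surface terms (Robin, follower cavity pressure) and the pressure
// stabilization matrix are added on the R side.
//
// verts: N x 3, tets: M x 4 (1-based), u: 3N (interleaved per node), p: N,
// triads: M x 9 (rows e_f0, e_s0, e_n0 flattened row-major),
// act: M (element-wise active tension scale T_ref,e * C_t).
// Returned triplet indices are 1-based; u dof of node a, component i is
// 3(a-1)+i and p dof of node a is 3N+a.
// [[Rcpp::export]]
List fem_assemble_volume(NumericMatrix verts, IntegerMatrix tets,
                         NumericVector u, NumericVector p,
                         NumericMatrix triads, NumericVector matpar,
                         NumericVector actpar, NumericVector act,
                         bool want_jac) {
  const int N = verts.nrow(), M = tets.nrow();
  MatPar mp = as_matpar(matpar);
  ActPar ap = as_actpar(actpar);
  NumericVector res(4 * N);  // u dofs then p dofs
  IntegerVector ti, tj;
  NumericVector tx;
  R_xlen_t nt = 0;
  if (want_jac) {
    ti = IntegerVector(static_cast<R_xlen_t>(M) * 256);
    tj = IntegerVector(static_cast<R_xlen_t>(M) * 256);
    tx = NumericVector(static_cast<R_xlen_t>(M) * 256);
  }
  double minJ = R_PosInf;
  int minJ_el = -1, bad_el = 0;

  for (int e = 0; e < M; ++e) {
    int nd[4];
    for (int a = 0; a < 4; ++a) nd[a] = tets(e, a) - 1;
    double X[4][3];
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) X[a][i] = verts(nd[a], i);
    // edge matrix columns X_a - X_0 (a = 1..3)
    double Dm[3][3];
    for (int i = 0; i < 3; ++i)
      for (int a = 0; a < 3; ++a) Dm[i][a] = X[a + 1][i] - X[0][i];
    double detDm = det3(Dm);
    double vol = detDm / 6.0;
    if (vol <= 0.0) { bad_el = e + 1; break; }
    // shape gradients G[a][J]: rows of [ -1 -1 -1; I ] * Dm^{-1}
    double DmiT[3][3];
    invT3(Dm, detDm, DmiT);  // DmiT = (Dm^-1)^T, so Dm^-1 = DmiT^T
    double G[4][3];
    for (int J = 0; J < 3; ++J) {
      G[1][J] = DmiT[J][0];
      G[2][J] = DmiT[J][1];
      G[3][J] = DmiT[J][2];
      G[0][J] = -(G[1][J] + G[2][J] + G[3][J]);
    }
    // deformation gradient F = I + sum_a u_a (x) G_a
    double F[3][3] = { {1, 0, 0}, {0, 1, 0}, {0, 0, 1} };
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) {
        double ui = u[3 * nd[a] + i];
        for (int J = 0; J < 3; ++J) F[i][J] += ui * G[a][J];
      }
    double J = det3(F);
    if (J < minJ) { minJ = J; minJ_el = e + 1; }
    if (J <= 0.0) { bad_el = e + 1; break; }
    double FiT[3][3];
    invT3(F, J, FiT);
    double E[3][3];
    for (int a = 0; a < 3; ++a)
      for (int c = 0; c < 3; ++c) {
        double s = 0.0;
        for (int i = 0; i < 3; ++i) s += F[i][a] * F[i][c];
        E[a][c] = 0.5 * (s - (a == c ? 1.0 : 0.0));
      }
    double R[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) R[i][j] = triads(e, 3 * i + j);
    double S[3][3], D[3][3][3][3], Pact[3][3], Aact[3][3][3][3];
    if (!fung_eval(E, R, mp, S, D, nullptr, want_jac)) { bad_el = e + 1; break; }
    double f0[3] = { R[0][0], R[0][1], R[0][2] };
    double acte = act[e];
    if (acte != 0.0) {
      if (!active_eval(F, f0, acte, ap, Pact, Aact, want_jac, nullptr, nullptr)) {
        bad_el = e + 1; break;
      }
    } else {
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) Pact[i][j] = 0.0;
      if (want_jac)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            for (int k = 0; k < 3; ++k)
              for (int l = 0; l < 3; ++l) Aact[i][j][k][l] = 0.0;
    }
    double pe = 0.25 * (p[nd[0]] + p[nd[1]] + p[nd[2]] + p[nd[3]]);
    // total first PK: P = F S + P_act - p J F^-T
    double Ptot[3][3];
    for (int i = 0; i < 3; ++i)
      for (int Jj = 0; Jj < 3; ++Jj) {
        double s = 0.0;
        for (int a = 0; a < 3; ++a) s += F[i][a] * S[a][Jj];
        Ptot[i][Jj] = s + Pact[i][Jj] - pe * J * FiT[i][Jj];
      }
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) {
        double s = 0.0;
        for (int Jj = 0; Jj < 3; ++Jj) s += Ptot[i][Jj] * G[a][Jj];
        res[3 * nd[a] + i] += vol * s;
      }
    double rp = -vol * (J - 1.0) * 0.25;
    for (int a = 0; a < 4; ++a) res[3 * N + nd[a]] += rp;

    if (want_jac) {
      // A_iJkL = d(Ptot_iJ)/dF_kL
      double A[3][3][3][3];
      for (int i = 0; i < 3; ++i)
        for (int Jj = 0; Jj < 3; ++Jj)
          for (int k = 0; k < 3; ++k)
            for (int L = 0; L < 3; ++L) {
              double v = Aact[i][Jj][k][L];
              if (i == k) v += S[Jj][L];
              double s = 0.0;
              for (int a = 0; a < 3; ++a)
                for (int c = 0; c < 3; ++c)
                  s += F[i][a] * D[a][Jj][c][L] * F[k][c];
              v += s;
              // follower-pressure (volumetric) part:
              // d(-p J F^-T_iJ)/dF_kL
              v += -pe * J * (FiT[i][Jj] * FiT[k][L] - FiT[i][L] * FiT[k][Jj]);
              A[i][Jj][k][L] = v;
            }
      double Ke[16][16];
      for (int r = 0; r < 16; ++r)
        for (int c = 0; c < 16; ++c) Ke[r][c] = 0.0;
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i)
          for (int b = 0; b < 4; ++b)
            for (int k = 0; k < 3; ++k) {
              double s = 0.0;
              for (int Jj = 0; Jj < 3; ++Jj)
                for (int L = 0; L < 3; ++L)
                  s += G[a][Jj] * A[i][Jj][k][L] * G[b][L];
              Ke[3 * a + i][3 * b + k] = vol * s;
            }
      // u-p coupling: d res_u / d p_b = -vol/4 (J F^-T) : G_a
      // p-u coupling: d res_p_a / d u_(b,k) = -vol/4 J F^-T_kL G_b L
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i) {
          double s = 0.0;
          for (int Jj = 0; Jj < 3; ++Jj) s += J * FiT[i][Jj] * G[a][Jj];
          for (int b = 0; b < 4; ++b) {
            Ke[3 * a + i][12 + b] = -0.25 * vol * s;
            Ke[12 + b][3 * a + i] = -0.25 * vol * s;
          }
        }
      int dof[16];
      for (int a = 0; a < 4; ++a) {
        for (int i = 0; i < 3; ++i) dof[3 * a + i] = 3 * nd[a] + i + 1;
        dof[12 + a] = 3 * N + nd[a] + 1;
      }
      for (int r = 0; r < 16; ++r)
        for (int c = 0; c < 16; ++c) {
          ti[nt] = dof[r];
          tj[nt] = dof[c];
          tx[nt] = Ke[r][c];
          ++nt;
        }
    }
  }

  List out = List::create(_["res"] = res, _["minJ"] = minJ,
                          _["minJ_el"] = minJ_el, _["bad_el"] = bad_el);
  if (want_jac && bad_el == 0) {
    out["i"] = ti;
    out["j"] = tj;
    out["x"] = tx;
  }
  return out;
}
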