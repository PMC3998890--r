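// Closure scan kernel: the residual of the tripeptide closure as a
// function of the middle-CA circle angle, evaluated for a batch of scan
// positions and branch-sign pairs. Mirrors the reference R implementation
// (closure_residual / solve_unit) exactly; the R side keeps the
// bracketing and polishing logic and cross-checks this kernel against the
// scalar R path in the tests.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
};
static inline V3 operator+(const V3 &a, const V3 &b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator-(const V3 &a, const V3 &b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator*(double s, const V3 &a) { return V3(s * a.x, s * a.y, s * a.z); }
static inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3 &a, const V3 &b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm3(const V3 &a) { return std::sqrt(dot(a, a)); }
static inline V3 unit(const V3 &a) { double n = norm3(a); return V3(a.x / n, a.y / n, a.z / n); }

// NeRF placement matching place_atom(): frame a-b-c, bond length l, bond
// angle th (deg), dihedral tau (deg)
static V3 nerf(const V3 &a, const V3 &b, const V3 &c, double l, double th,
               double tau) {
  double t = th * DEG, u = tau * DEG;
  V3 bc = unit(c - b);
  V3 n = unit(cross(b - a, bc));
  V3 m = cross(n, bc);
  return c + (-l * std::cos(t)) * bc + (l * std::sin(t) * std::cos(u)) * m +
         (-l * std::sin(t) * std::sin(u)) * n;
}

// Rodrigues rotation of p about the axis through o with unit direction u
static V3 rot(const V3 &p, const V3 &o, const V3 &u, double theta_deg) {
  double t = theta_deg * DEG, ct = std::cos(t), st = std::sin(t);
  V3 q = p - o;
  V3 cr = cross(u, q);
  double du = dot(q, u);
  return o + ct * q + st * cr + (du * (1 - ct)) * u;
}

struct UnitOut {
  V3 c, n_next, ca_next;
  bool ok;
};

// one peptide unit: cone branch + psi rotation, mirroring solve_unit()
static UnitOut solve_unit_c(const V3 &nm, const V3 &cam, const V3 &caT,
                            double b_cac, double a_ncac, double b_cn,
                            double a_cacn, double b_nca_next,
                            double a_cnca_next, double omega, double gamma,
                            double sgn) {
  UnitOut out; out.ok = false;
  V3 m = unit(nm - cam);
  V3 ref = (std::fabs(m.x) < 0.9) ? V3(1, 0, 0) : V3(0, 1, 0);
  V3 e1 = unit(cross(m, ref));
  V3 e2 = cross(m, e1);
  V3 v = unit(caT - cam);
  double th = a_ncac * DEG;
  double A = std::sin(th) * dot(e1, v);
  double B = std::sin(th) * dot(e2, v);
  double Cc = std::cos(gamma * DEG) - std::cos(th) * dot(m, v);
  double R = std::sqrt(A * A + B * B);
  if (R < std::fabs(Cc) || R <= 0) return out;
  double ratio = Cc / R;
  if (ratio > 1) ratio = 1; else if (ratio < -1) ratio = -1;
  double alpha = std::atan2(B, A) + sgn * std::acos(ratio);
  V3 cdir = std::cos(th) * m +
            std::sin(th) * (std::cos(alpha) * e1 + std::sin(alpha) * e2);
  V3 cp = cam + b_cac * cdir;
  V3 n0 = nerf(nm, cam, cp, b_cn, a_cacn, 0.0);
  V3 ca0 = nerf(cam, cp, n0, b_nca_next, a_cnca_next, omega);
  V3 u = unit(cp - cam);
  V3 w0 = ca0 - cp; w0 = w0 - dot(w0, u) * u;
  V3 w1 = caT - cp; w1 = w1 - dot(w1, u) * u;
  double delta = std::atan2(dot(cross(w0, w1), u), dot(w0, w1)) / DEG;
  V3 caA = rot(ca0, cp, u, delta);
  V3 caB = rot(ca0, cp, u, -delta);
  double dA = norm3(caA - caT), dB = norm3(caB - caT);
  if (dB < dA) { caA = caB; delta = -delta; dA = dB; }
  if (dA > 1e-6) return out;
  out.c = cp;
  out.n_next = rot(n0, cp, u, delta);
  out.ca_next = caA;
  out.ok = true;
  return out;
}

// [[Rcpp::export(name = ".closure_scan_cpp")]]
NumericVector closure_scan_cpp(NumericVector us, NumericVector s1,
                               NumericVector s2, NumericVector foot,
                               double rho, NumericVector e1v,
                               NumericVector e2v, double gamma1,
                               double gamma2, NumericVector c_prev,
                               NumericVector n1, NumericVector ca1,
                               NumericVector ca3, NumericVector c3,
                               NumericVector b_cac, NumericVector a_ncac,
                               NumericVector b_cn, NumericVector a_cacn,
                               NumericVector b_nca, NumericVector a_cnca,
                               NumericVector omega) {
  int n = us.size();
  NumericVector out(n);
  V3 F(foot[0], foot[1], foot[2]);
  V3 E1(e1v[0], e1v[1], e1v[2]), E2(e2v[0], e2v[1], e2v[2]);
  V3 N1(n1[0], n1[1], n1[2]), CA1(ca1[0], ca1[1], ca1[2]);
  V3 CA3(ca3[0], ca3[1], ca3[2]), C3(c3[0], c3[1], c3[2]);
  V3 cb = unit(C3 - CA3);
  for (int i = 0; i < n; i++) {
    double u = us[i];
    V3 caT2 = F + (rho * std::cos(u)) * E1 + (rho * std::sin(u)) * E2;
    double sg1 = s1[i % s1.size()];
    double sg2 = s2[i % s2.size()];
    UnitOut u1 = solve_unit_c(N1, CA1, caT2, b_cac[0], a_ncac[0], b_cn[0],
                              a_cacn[0], b_nca[1], a_cnca[1], omega[0],
                              gamma1, sg1);
    if (!u1.ok) { out[i] = NA_REAL; continue; }
    UnitOut u2 = solve_unit_c(u1.n_next, caT2, CA3, b_cac[1], a_ncac[1],
                              b_cn[1], a_cacn[1], b_nca[2], a_cnca[2],
                              omega[1], gamma2, sg2);
    if (!u2.ok) { out[i] = NA_REAL; continue; }
    V3 a = unit(u2.n_next - CA3);
    double cang = dot(a, cb);
    if (cang > 1) cang = 1; else if (cang < -1) cang = -1;
    out[i] = std::acos(cang) / DEG - a_ncac[2];
  }
  return out;
}
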