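// Trial generation for one growth step, compiled: distance draws from the
// conditional KDE slices, circle/sphere intersections, omega-carried N
// placement, ellipsoid pruning and backbone clash pruning. Returns the
// feasible trials; dihedral filtering and Boltzmann selection stay in R.
// Uses R's RNG (via the Rcpp RNGScope), so runs remain reproducible under
// set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

struct V3 { double x, y, z; };
static inline V3 mk(double x, double y, double z) { V3 v; v.x = x; v.y = y; v.z = z; return v; }
static inline V3 operator+(const V3 &a, const V3 &b) { return mk(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator-(const V3 &a, const V3 &b) { return mk(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator*(double s, const V3 &a) { return mk(s * a.x, s * a.y, s * a.z); }
static inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3 &a, const V3 &b) {
  return mk(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm3(const V3 &a) { return std::sqrt(dot(a, a)); }
static inline V3 unit(const V3 &a) { double n = norm3(a); return mk(a.x / n, a.y / n, a.z / n); }
static inline V3 getrow(const NumericVector &v) { return mk(v[0], v[1], v[2]); }

static V3 nerf(const V3 &a, const V3 &b, const V3 &c, double l, double th_deg,
               double tau_deg) {
  double t = th_deg * DEG, u = tau_deg * DEG;
  V3 bc = unit(c - b);
  V3 n = unit(cross(b - a, bc));
  V3 m = cross(n, bc);
  return c + (-l * std::cos(t)) * bc + (l * std::sin(t) * std::cos(u)) * m +
         (-l * std::sin(t) * std::sin(u)) * n;
}

static V3 rot_axis(const V3 &p, const V3 &o, const V3 &u, double theta_deg) {
  double t = theta_deg * DEG, ct = std::cos(t), st = std::sin(t);
  V3 q = p - o;
  V3 cr = cross(u, q);
  double du = dot(q, u);
  return o + ct * q + st * cr + (du * (1 - ct)) * u;
}

// measured dihedral in degrees, IUPAC convention, [-180, 180)
static double dihedral(const V3 &a, const V3 &b, const V3 &c, const V3 &d) {
  V3 b1 = b - a, b2 = c - b, b3 = d - c;
  V3 n1 = cross(b1, b2), n2 = cross(b2, b3);
  V3 m1 = cross(n1, unit(b2));
  double ang = std::atan2(dot(m1, n2), dot(n1, n2)) / DEG;
  if (ang >= 180.0) ang -= 360.0;
  return ang;
}

// sample from a piecewise-linear density on nodes xs with values f;
// returns -1 when the slice has no mass
static double sample_pl(const std::vector<double> &xs,
                        const std::vector<double> &f) {
  int n = xs.size();
  std::vector<double> w(n - 1);
  double tot = 0;
  for (int j = 0; j < n - 1; j++) {
    w[j] = (f[j] + f[j + 1]) / 2.0 * (xs[j + 1] - xs[j]);
    tot += w[j];
  }
  if (!(tot > 0)) return -1.0;
  double u = R::runif(0, 1) * tot;
  double acc = 0;
  int cell = n - 2;
  for (int j = 0; j < n - 1; j++) {
    if (u <= acc + w[j]) { cell = j; break; }
    acc += w[j];
  }
  double u_rem = u - acc;
  double dx = xs[cell + 1] - xs[cell];
  double f0 = f[cell], s = f[cell + 1] - f[cell];
  double a = u_rem / dx;
  double t;
  if (std::fabs(s) < 1e-12 * std::max(f0, 1e-300))
    t = a / std::max(f0, 1e-300);
  else
    t = (-f0 + std::sqrt(std::max(f0 * f0 + 2 * s * a, 0.0))) / s;
  if (t < 0) t = 0; if (t > 1) t = 1;
  return xs[cell] + t * dx;
}

// conditional slice of a KDE grid at d_prev (bilinear between columns);
// falls back to the trapezoid marginal when d_prev is outside the domain
static void kde_slice(const NumericMatrix &grid, const NumericVector &gx,
                      const NumericVector &gy, double d_prev,
                      std::vector<double> &f) {
  int nx = gx.size(), ny = gy.size();
  f.assign(ny, 0.0);
  if (d_prev >= gx[0] && d_prev <= gx[nx - 1]) {
    int xi = nx - 2;
    for (int i = 0; i < nx - 1; i++)
      if (d_prev >= gx[i] && d_prev <= gx[i + 1]) { xi = i; break; }
    double tx = (d_prev - gx[xi]) / (gx[xi + 1] - gx[xi]);
    double tot = 0;
    for (int j = 0; j < ny; j++) {
      f[j] = (1 - tx) * grid(xi, j) + tx * grid(xi + 1, j);
      tot += f[j];
    }
    if (tot > 0) return;
  }
  // marginal fallback
  for (int j = 0; j < ny; j++) {
    double s = 0;
    for (int i = 0; i < nx - 1; i++)
      s += (grid(i, j) + grid(i + 1, j)) / 2.0 * (gx[i + 1] - gx[i]);
    f[j] = s;
  }
}

struct Circle { V3 center, normal; double radius; };

// 0, 1 or 2 intersection points of a circle with the sphere |P-anchor|=d
static int circ_sphere(const Circle &C, const V3 &anchor, double d, V3 &p1,
                       V3 &p2) {
  V3 w = anchor - C.center;
  double wn = dot(w, C.normal);
  V3 wp = w - wn * C.normal;
  double rho = norm3(wp);
  double r = C.radius;
  double rhs = r * r + dot(w, w) - d * d;
  if (rho < 1e-9) return 0;
  double cosv = rhs / (2 * r * rho);
  if (cosv > 1 + 1e-9 || cosv < -1 - 1e-9) return 0;
  if (cosv > 1) cosv = 1; if (cosv < -1) cosv = -1;
  V3 e1 = (1.0 / rho) * wp;
  V3 e2 = cross(C.normal, e1);
  double delta = std::acos(cosv);
  p1 = C.center + (r * std::cos(delta)) * e1 + (r * std::sin(delta)) * e2;
  if (std::fabs(std::fabs(cosv) - 1) < 1e-9) return 1;
  p2 = C.center + (r * std::cos(delta)) * e1 - (r * std::sin(delta)) * e2;
  return 2;
}

static inline bool in_ell(const V3 &p, const V3 &f1, const V3 &f2,
                          double thr) {
  return norm3(p - f1) + norm3(p - f2) < thr;
}

static inline bool excl_pep(int lo, int hi) {
  return (lo == 3 && hi == 1) || (lo == 3 && hi == 2) ||
         (lo == 2 && hi == 1) || (lo == 4 && hi == 1);
}

// clash of one atom against a context array
static bool atom_clash(const V3 &p, double rad, int res, int bb,
                       const NumericMatrix &Cxyz, const NumericVector &Crad,
                       const IntegerVector &Cres, const IntegerVector &Cbb,
                       double ratio) {
  int n = Cxyz.nrow();
  for (int j = 0; j < n; j++) {
    double lim = ratio * (rad + Crad[j]);
    double dx = Cxyz(j, 0) - p.x, dy = Cxyz(j, 1) - p.y, dz = Cxyz(j, 2) - p.z;
    if (dx * dx + dy * dy + dz * dz >= lim * lim) continue;
    int rj = Cres[j];
    if (rj == res) continue;
    if (rj == res + 1 && excl_pep(bb, Cbb[j])) continue;
    if (rj == res - 1 && excl_pep(Cbb[j], bb)) continue;
    return true;
  }
  return false;
}

// [[Rcpp::export(name = ".grow_trials_cpp")]]
List grow_trials_cpp(NumericVector n_i, NumericVector ca_i,
                     NumericVector c_prev, NumericVector anchor, int m,
                     NumericVector slice_c_y, NumericVector slice_c_f,
                     NumericMatrix grid_ca, NumericVector gx_ca,
                     NumericVector gy_ca, double b_cac, double a_ncac,
                     double b_co, double a_caco, double b_cn, double a_cacn,
                     double b_nca2, double a_cnca2, double omega_sd,
                     NumericVector ell_f1, NumericVector ell_f2,
                     double ell_thr, double reach_hi,
                     NumericMatrix Exyz, NumericVector Erad,
                     IntegerVector Eres, IntegerVector Ebb,
                     NumericMatrix Gxyz, NumericVector Grad,
                     IntegerVector Gres, IntegerVector Gbb,
                     double clash_ratio, int res_i, int res_n) {
  V3 N = getrow(n_i), CA = getrow(ca_i), CP = getrow(c_prev),
     A = getrow(anchor);
  V3 F1 = getrow(ell_f1), F2 = getrow(ell_f2);
  // placement circle of C about the N->CA axis
  Circle cc;
  cc.normal = unit(CA - N);
  cc.center = CA - (b_cac * std::cos(a_ncac * DEG)) * cc.normal;
  cc.radius = b_cac * std::sin(a_ncac * DEG);
  std::vector<double> ys(slice_c_y.begin(), slice_c_y.end());
  std::vector<double> fc(slice_c_f.begin(), slice_c_f.end());
  std::vector<double> gyv(gy_ca.begin(), gy_ca.end());
  std::vector<double> fca;
  std::vector<double> outx; std::vector<double> phiv, psiv;
  int nt = 0;
  const double rad_bb[4] = {1.55, 1.70, 1.70, 1.52};
  for (int t = 0; t < m; t++) {
    // C placement: batched redraws against the circle band
    V3 Ci; bool okc = false;
    for (int rd = 0; rd < 8; rd++) {
      double d = sample_pl(ys, fc);
      if (d <= 0) break;
      V3 p1, p2;
      int np = circ_sphere(cc, A, d, p1, p2);
      if (np == 0) continue;
      Ci = (np == 2 && R::unif_rand() < 0.5) ? p2 : p1;
      okc = true; break;
    }
    if (!okc) continue;
    double omega = R::rnorm(180.0, omega_sd);
    V3 N0 = nerf(N, CA, Ci, b_cn, a_cacn, 0.0);
    V3 CA0 = nerf(CA, Ci, N0, b_nca2, a_cnca2, omega);
    V3 u = unit(Ci - CA);
    V3 ctr = CA + dot(CA0 - CA, u) * u;
    Circle cca; cca.center = ctr; cca.normal = u;
    cca.radius = norm3(CA0 - ctr);
    kde_slice(grid_ca, gx_ca, gy_ca, norm3(Ci - A), fca);
    V3 CAn; bool okca = false;
    for (int rd = 0; rd < 8; rd++) {
      double d = sample_pl(gyv, fca);
      if (d <= 0) break;
      if (reach_hi > 0 && d > reach_hi) continue;
      V3 p1, p2;
      int np = circ_sphere(cca, A, d, p1, p2);
      if (np == 0) continue;
      CAn = (np == 2 && R::unif_rand() < 0.5) ? p2 : p1;
      okca = true; break;
    }
    if (!okca) continue;
    // recover psi by the signed rotation taking CA0 to CAn about u
    V3 w0 = CA0 - ctr;
    V3 w1 = CAn - ctr;
    double delta = std::atan2(dot(cross(w0, w1), u), dot(w0, w1)) / DEG;
    V3 Nn = rot_axis(N0, Ci, u, delta);
    V3 chk = rot_axis(CA0, Ci, u, delta);
    if (norm3(chk - CAn) > 1e-9) {
      Nn = rot_axis(N0, Ci, u, -delta);
    }
    double psi = dihedral(N, CA, Ci, Nn);
    V3 Oi = nerf(N, CA, Ci, b_co, a_caco,
                 (psi + 180.0 >= 180.0) ? psi - 180.0 : psi + 180.0);
    // ellipsoid pruning
    if (!in_ell(Ci, F1, F2, ell_thr) || !in_ell(Oi, F1, F2, ell_thr) ||
        !in_ell(Nn, F1, F2, ell_thr) || !in_ell(CAn, F1, F2, ell_thr))
      continue;
    // backbone clash pruning against environment and grown atoms
    const V3 pts[4] = {Ci, Oi, Nn, CAn};
    const int bbs[4] = {3, 4, 1, 2};
    const int rks[4] = {res_i, res_i, res_n, res_n};
    bool clash = false;
    for (int a2 = 0; a2 < 4 && !clash; a2++) {
      double rd = rad_bb[bbs[a2] - 1];
      if (Exyz.nrow() > 0 &&
          atom_clash(pts[a2], rd, rks[a2], bbs[a2], Exyz, Erad, Eres, Ebb,
                     clash_ratio))
        clash = true;
      if (!clash && Gxyz.nrow() > 0 &&
          atom_clash(pts[a2], rd, rks[a2], bbs[a2], Gxyz, Grad, Gres, Gbb,
                     clash_ratio))
        clash = true;
    }
    if (clash) continue;
    double phi = dihedral(CP, N, CA, Ci);
    for (int a2 = 0; a2 < 4; a2++) {
      outx.push_back(pts[a2].x);
      outx.push_back(pts[a2].y);
      outx.push_back(pts[a2].z);
    }
    phiv.push_back(phi);
    psiv.push_back(psi);
    nt++;
  }
  NumericMatrix xyz(4 * nt, 3);
  for (int i = 0; i < 4 * nt; i++) {
    xyz(i, 0) = outx[3 * i];
    xyz(i, 1) = outx[3 * i + 1];
    xyz(i, 2) = outx[3 * i + 2];
  }
  return List::create(_["n"] = nt, _["xyz"] = xyz,
                      _["phi"] = NumericVector(phiv.begin(), phiv.end()),
                      _["psi"] = NumericVector(psiv.begin(), psiv.end()));
}
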