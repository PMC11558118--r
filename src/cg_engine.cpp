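// Coarse-grained energy function and Langevin integrator.
//
// Terms: harmonic bonds/angles/dihedrals about native values, 12-10 native
// contacts (intra-protein and base stacking), the residue-base 12-10
// interface potential with per-residue reference distances r_i0,
// Debye-Hueckel electrostatics between protein charges and phosphates
// (shifted at the cutoff), soft excluded volume, harmonic anchors and a
// half-harmonic spherical wall. Units: Angstrom, kcal/mol, unit masses.
//
// The integrator is BAOAB with an internal PCG32 RNG so trajectories are
// bit-reproducible for a fixed seed, independent of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq = 54u) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double uniform() {  // (0, 1)
    return (next() + 1.0) * (1.0 / 4294967297.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  double normal() {  // Box-Muller, cached pair
    if (have_spare) {
      have_spare = false;
      return spare;
    }
    double u1 = uniform(), u2 = uniform();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// ------------------------------------------------------------ topology ----
struct Topo {
  int n;
  // bonds
  std::vector<int> b_i, b_j;
  std::vector<double> b_r0, b_k;
  // angles
  std::vector<int> a_i, a_j, a_k;
  std::vector<double> a_t0, a_kth;
  // dihedrals
  std::vector<int> d_i, d_j, d_k, d_l;
  std::vector<double> d_p0, d_kphi;
  // 12-10 contacts (intra-protein native + stacking)
  std::vector<int> c_i, c_j;
  std::vector<double> c_r0, c_eps;
  // interface residues x all bases
  std::vector<int> f_i;
  std::vector<double> f_r0;
  std::vector<int> base_idx;
  double eps_interface;
  // electrostatics (precomputed charged inter-molecular pairs)
  std::vector<int> e_i, e_j;
  std::vector<double> e_qq;
  double lambda, elec_rc, inv_eps_r;
  // excluded volume candidates
  std::vector<int> x_i, x_j;
  double exv_sigma12, exv_rc2, exv_eps, exv_shift;
  // anchors
  std::vector<int> an_i;
  std::vector<double> an_x, an_y, an_z, an_k, an_r0;
  // wall
  double wall_cx, wall_cy, wall_cz, wall_r, wall_k;
};

static std::vector<int> ivec(const List& l, const char* nm) {
  IntegerVector v = l[nm];
  return std::vector<int>(v.begin(), v.end());
}
static std::vector<double> dvec(const List& l, const char* nm) {
  NumericVector v = l[nm];
  return std::vector<double>(v.begin(), v.end());
}

static Topo parse_topo(const List& tl) {
  Topo t;
  t.n = as<int>(tl["n"]);
  t.b_i = ivec(tl, "b_i"); t.b_j = ivec(tl, "b_j");
  t.b_r0 = dvec(tl, "b_r0"); t.b_k = dvec(tl, "b_k");
  t.a_i = ivec(tl, "a_i"); t.a_j = ivec(tl, "a_j"); t.a_k = ivec(tl, "a_k");
  t.a_t0 = dvec(tl, "a_t0"); t.a_kth = dvec(tl, "a_kth");
  t.d_i = ivec(tl, "d_i"); t.d_j = ivec(tl, "d_j");
  t.d_k = ivec(tl, "d_k"); t.d_l = ivec(tl, "d_l");
  t.d_p0 = dvec(tl, "d_p0"); t.d_kphi = dvec(tl, "d_kphi");
  t.c_i = ivec(tl, "c_i"); t.c_j = ivec(tl, "c_j");
  t.c_r0 = dvec(tl, "c_r0"); t.c_eps = dvec(tl, "c_eps");
  t.f_i = ivec(tl, "f_i"); t.f_r0 = dvec(tl, "f_r0");
  t.base_idx = ivec(tl, "base_idx");
  t.eps_interface = as<double>(tl["eps_interface"]);
  t.e_i = ivec(tl, "e_i"); t.e_j = ivec(tl, "e_j"); t.e_qq = dvec(tl, "e_qq");
  t.lambda = as<double>(tl["lambda"]);
  t.elec_rc = as<double>(tl["elec_rc"]);
  t.inv_eps_r = 1.0 / as<double>(tl["eps_r"]);
  t.x_i = ivec(tl, "x_i"); t.x_j = ivec(tl, "x_j");
  double sig = as<double>(tl["exv_sigma"]);
  t.exv_eps = as<double>(tl["exv_eps"]);
  t.exv_sigma12 = std::pow(sig, 12);
  double rc = 2.0 * sig;
  t.exv_rc2 = rc * rc;
  t.exv_shift = t.exv_eps * t.exv_sigma12 / std::pow(rc, 12);
  t.an_i = ivec(tl, "an_i");
  t.an_x = dvec(tl, "an_x"); t.an_y = dvec(tl, "an_y");
  t.an_z = dvec(tl, "an_z"); t.an_k = dvec(tl, "an_k");
  t.an_r0 = dvec(tl, "an_r0");
  NumericVector wc = tl["wall_center"];
  t.wall_cx = wc[0]; t.wall_cy = wc[1]; t.wall_cz = wc[2];
  t.wall_r = as<double>(tl["wall_radius"]);
  t.wall_k = as<double>(tl["wall_k"]);
  return t;
}

static const double COULOMB = 332.0637;  // kcal/mol * A for unit charges

struct EnergyTerms {
  double bonds = 0, angles = 0, dihedrals = 0, contacts = 0, interface = 0,
         elec = 0, exv = 0, anchors = 0, wall = 0;
  double total() const {
    return bonds + angles + dihedrals + contacts + interface + elec + exv +
           anchors + wall;
  }
};

static inline void addf(std::vector<double>& g, int i, double fx, double fy,
                        double fz) {
  g[3 * i] += fx;
  g[3 * i + 1] += fy;
  g[3 * i + 2] += fz;
}

// 12-10 pair energy/gradient magnitude: U = eps(5 q^6 - 6 q^5), q = (r0/r)^2
static inline double pair1210(double r2, double r0, double eps, double& dUdr_over_r) {
  double q = r0 * r0 / r2;
  double q5 = q * q * q * q * q;
  double q6 = q5 * q;
  // dU/dr = eps(60 q^5 - 60 q^6)/r ; dU/dr / r = 60 eps (q^5 - q^6) / r^2
  dUdr_over_r = 60.0 * eps * (q5 - q6) / r2;
  return eps * (5.0 * q6 - 6.0 * q5);
}

// neighbor list for excluded volume
struct NeighborList {
  std::vector<int> p_i, p_j;
  std::vector<double> ref;  // coords at build time
  double skin = 2.0;
  bool built = false;

  void build(const std::vector<double>& x, const Topo& t) {
    p_i.clear();
    p_j.clear();
    double rc2 = t.exv_rc2;
    double rl = std::sqrt(rc2) + skin;
    double rl2 = rl * rl;
    size_t m = t.x_i.size();
    for (size_t p = 0; p < m; ++p) {
      int i = t.x_i[p], j = t.x_j[p];
      double dx = x[3 * i] - x[3 * j];
      double dy = x[3 * i + 1] - x[3 * j + 1];
      double dz = x[3 * i + 2] - x[3 * j + 2];
      if (dx * dx + dy * dy + dz * dz < rl2) {
        p_i.push_back(i);
        p_j.push_back(j);
      }
    }
    ref = x;
    built = true;
  }
  bool stale(const std::vector<double>& x) const {
    if (!built) return true;
    double lim = (skin * 0.5) * (skin * 0.5);
    for (size_t i = 0; i < x.size(); i += 3) {
      double dx = x[i] - ref[i], dy = x[i + 1] - ref[i + 1],
             dz = x[i + 2] - ref[i + 2];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }
};

static EnergyTerms energy_forces(const std::vector<double>& x, const Topo& t,
                                 std::vector<double>& g, NeighborList* nl) {
  EnergyTerms E;
  std::fill(g.begin(), g.end(), 0.0);

  // bonds: U = k (r - r0)^2
  for (size_t p = 0; p < t.b_i.size(); ++p) {
    int i = t.b_i[p], j = t.b_j[p];
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dev = r - t.b_r0[p];
    E.bonds += t.b_k[p] * dev * dev;
    double c = 2.0 * t.b_k[p] * dev / std::max(r, 1e-12);
    addf(g, i, c * dx, c * dy, c * dz);
    addf(g, j, -c * dx, -c * dy, -c * dz);
  }

  // angles: U = kth (theta - theta0)^2
  for (size_t p = 0; p < t.a_i.size(); ++p) {
    int i = t.a_i[p], j = t.a_j[p], k = t.a_k[p];
    double ux = x[3 * i] - x[3 * j], uy = x[3 * i + 1] - x[3 * j + 1],
           uz = x[3 * i + 2] - x[3 * j + 2];
    double vx = x[3 * k] - x[3 * j], vy = x[3 * k + 1] - x[3 * j + 1],
           vz = x[3 * k + 2] - x[3 * j + 2];
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    double ct = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double st = std::sqrt(std::max(1.0 - ct * ct, 1e-12));
    double dev = th - t.a_t0[p];
    E.angles += t.a_kth[p] * dev * dev;
    double dU = 2.0 * t.a_kth[p] * dev;
    // dtheta/dxi = (ct*uhat - vhat) / (|u| st)
    double gix = (ct * ux / nu - vx / nv) / (nu * st);
    double giy = (ct * uy / nu - vy / nv) / (nu * st);
    double giz = (ct * uz / nu - vz / nv) / (nu * st);
    double gkx = (ct * vx / nv - ux / nu) / (nv * st);
    double gky = (ct * vy / nv - uy / nu) / (nv * st);
    double gkz = (ct * vz / nv - uz / nu) / (nv * st);
    addf(g, i, dU * gix, dU * giy, dU * giz);
    addf(g, k, dU * gkx, dU * gky, dU * gkz);
    addf(g, j, -dU * (gix + gkx), -dU * (giy + gky), -dU * (giz + gkz));
  }

  // dihedrals: U = kphi * wrap(phi - phi0)^2
  for (size_t p = 0; p < t.d_i.size(); ++p) {
    int i = t.d_i[p], j = t.d_j[p], k = t.d_k[p], l = t.d_l[p];
    double b1x = x[3 * j] - x[3 * i], b1y = x[3 * j + 1] - x[3 * i + 1],
           b1z = x[3 * j + 2] - x[3 * i + 2];
    double b2x = x[3 * k] - x[3 * j], b2y = x[3 * k + 1] - x[3 * j + 1],
           b2z = x[3 * k + 2] - x[3 * j + 2];
    double b3x = x[3 * l] - x[3 * k], b3y = x[3 * l + 1] - x[3 * k + 1],
           b3z = x[3 * l + 2] - x[3 * k + 2];
    double mx = b1y * b2z - b1z * b2y, my = b1z * b2x - b1x * b2z,
           mz = b1x * b2y - b1y * b2x;
    double nx = b2y * b3z - b2z * b3y, ny = b2z * b3x - b2x * b3z,
           nz = b2x * b3y - b2y * b3x;
    double b2n = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    double m2 = mx * mx + my * my + mz * mz;
    double n2 = nx * nx + ny * ny + nz * nz;
    if (m2 < 1e-12 || n2 < 1e-12 || b2n < 1e-12) continue;
    double cx = my * nz - mz * ny, cy = mz * nx - mx * nz,
           cz = mx * ny - my * nx;
    double sphi = (cx * b2x + cy * b2y + cz * b2z) / b2n;
    double cphi = mx * nx + my * ny + mz * nz;
    double phi = std::atan2(sphi, cphi);
    double dev = phi - t.d_p0[p];
    while (dev > M_PI) dev -= 2.0 * M_PI;
    while (dev < -M_PI) dev += 2.0 * M_PI;
    E.dihedrals += t.d_kphi[p] * dev * dev;
    double dU = 2.0 * t.d_kphi[p] * dev;
    // dphi/dri = -(|b2|/|m|^2) m ; dphi/drl = (|b2|/|n|^2) n
    double gix = -b2n / m2 * mx, giy = -b2n / m2 * my, giz = -b2n / m2 * mz;
    double glx = b2n / n2 * nx, gly = b2n / n2 * ny, glz = b2n / n2 * nz;
    double s12 = (b1x * b2x + b1y * b2y + b1z * b2z) / (b2n * b2n);
    double s32 = (b3x * b2x + b3y * b2y + b3z * b2z) / (b2n * b2n);
    double gjx = -(1.0 + s12) * gix + s32 * glx;
    double gjy = -(1.0 + s12) * giy + s32 * gly;
    double gjz = -(1.0 + s12) * giz + s32 * glz;
    double gkx2 = -(1.0 + s32) * glx + s12 * gix;
    double gky2 = -(1.0 + s32) * gly + s12 * giy;
    double gkz2 = -(1.0 + s32) * glz + s12 * giz;
    addf(g, i, dU * gix, dU * giy, dU * giz);
    addf(g, j, dU * gjx, dU * gjy, dU * gjz);
    addf(g, k, dU * gkx2, dU * gky2, dU * gkz2);
    addf(g, l, dU * glx, dU * gly, dU * glz);
  }

  // native contacts / stacking (12-10)
  for (size_t p = 0; p < t.c_i.size(); ++p) {
    int i = t.c_i[p], j = t.c_j[p];
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    double c;
    E.contacts += pair1210(r2, t.c_r0[p], t.c_eps[p], c);
    addf(g, i, c * dx, c * dy, c * dz);
    addf(g, j, -c * dx, -c * dy, -c * dz);
  }

  // interface 12-10: tabulated residues x all bases
  for (size_t p = 0; p < t.f_i.size(); ++p) {
    int i = t.f_i[p];
    double r0 = t.f_r0[p];
    for (size_t bq = 0; bq < t.base_idx.size(); ++bq) {
      int j = t.base_idx[bq];
      double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
             dz = x[3 * i + 2] - x[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < 1e-12) stop("singular residue-base pair (r = 0)");
      double c;
      E.interface += pair1210(r2, r0, t.eps_interface, c);
      addf(g, i, c * dx, c * dy, c * dz);
      addf(g, j, -c * dx, -c * dy, -c * dz);
    }
  }

  // Debye-Hueckel electrostatics, shifted at the cutoff
  {
    double rc = t.elec_rc;
    double shift = std::exp(-rc / t.lambda) / rc;
    for (size_t p = 0; p < t.e_i.size(); ++p) {
      int i = t.e_i[p], j = t.e_j[p];
      double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
             dz = x[3 * i + 2] - x[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc * rc) continue;
      double r = std::sqrt(r2);
      if (r < 1e-12) stop("singular charged pair (r = 0)");
      double pref = COULOMB * t.e_qq[p] * t.inv_eps_r;
      double ex = std::exp(-r / t.lambda);
      E.elec += pref * (ex / r - shift);
      // dU/dr = -pref * ex * (1/r^2 + 1/(lambda r))
      double dUdr = -pref * ex * (1.0 / r2 + 1.0 / (t.lambda * r));
      double c = dUdr / r;
      addf(g, i, c * dx, c * dy, c * dz);
      addf(g, j, -c * dx, -c * dy, -c * dz);
    }
  }

  // excluded volume: U = eps (sigma/r)^12 - shift, r < 2 sigma
  {
    const std::vector<int>* pi = &t.x_i;
    const std::vector<int>* pj = &t.x_j;
    if (nl != nullptr) {
      if (nl->stale(x)) nl->build(x, t);
      pi = &nl->p_i;
      pj = &nl->p_j;
    }
    for (size_t p = 0; p < pi->size(); ++p) {
      int i = (*pi)[p], j = (*pj)[p];
      double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
             dz = x[3 * i + 2] - x[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= t.exv_rc2) continue;
      if (r2 < 0.25) {
        // report near-overlaps instead of silently diverging
        stop("excluded-volume divergence: beads %d and %d overlap (r = %f A)",
             i + 1, j + 1, std::sqrt(r2));
      }
      double inv2 = 1.0 / r2;
      double s12r12 = t.exv_sigma12 * inv2 * inv2 * inv2 * inv2 * inv2 * inv2;
      E.exv += t.exv_eps * s12r12 - t.exv_shift;
      double c = -12.0 * t.exv_eps * s12r12 * inv2;
      addf(g, i, c * dx, c * dy, c * dz);
      addf(g, j, -c * dx, -c * dy, -c * dz);
    }
  }

  // anchors: U = 0.5 k (|r - p| - r0)^2; r0 = 0 is a plain positional
  // restraint, r0 > 0 a radial spring to a fixed point
  for (size_t p = 0; p < t.an_i.size(); ++p) {
    int i = t.an_i[p];
    double dx = x[3 * i] - t.an_x[p], dy = x[3 * i + 1] - t.an_y[p],
           dz = x[3 * i + 2] - t.an_z[p];
    double r0 = t.an_r0[p];
    if (r0 == 0.0) {
      E.anchors += 0.5 * t.an_k[p] * (dx * dx + dy * dy + dz * dz);
      addf(g, i, t.an_k[p] * dx, t.an_k[p] * dy, t.an_k[p] * dz);
    } else {
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dev = d - r0;
      E.anchors += 0.5 * t.an_k[p] * dev * dev;
      if (d > 1e-12) {
        double c = t.an_k[p] * dev / d;
        addf(g, i, c * dx, c * dy, c * dz);
      }
    }
  }

  // half-harmonic spherical wall
  if (t.wall_k > 0) {
    for (int i = 0; i < t.n; ++i) {
      double dx = x[3 * i] - t.wall_cx, dy = x[3 * i + 1] - t.wall_cy,
             dz = x[3 * i + 2] - t.wall_cz;
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > t.wall_r) {
        double dev = d - t.wall_r;
        E.wall += 0.5 * t.wall_k * dev * dev;
        double c = t.wall_k * dev / d;
        addf(g, i, c * dx, c * dy, c * dz);
      }
    }
  }

  return E;
}

static NumericVector terms_vector(const EnergyTerms& E) {
  NumericVector v = NumericVector::create(
      _["bonds"] = E.bonds, _["angles"] = E.angles,
      _["dihedrals"] = E.dihedrals, _["contacts"] = E.contacts,
      _["interface"] = E.interface, _["elec"] = E.elec, _["exv"] = E.exv,
      _["anchors"] = E.anchors, _["wall"] = E.wall);
  return v;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix coords, List topo) {
  Topo t = parse_topo(topo);
  if (coords.nrow() != t.n) stop("coords do not match topology");
  std::vector<double> x(3 * t.n);
  for (int i = 0; i < t.n; ++i) {
    x[3 * i] = coords(i, 0);
    x[3 * i + 1] = coords(i, 1);
    x[3 * i + 2] = coords(i, 2);
  }
  std::vector<double> g(3 * t.n);
  EnergyTerms E = energy_forces(x, t, g, nullptr);
  NumericMatrix grad(t.n, 3);
  for (int i = 0; i < t.n; ++i) {
    grad(i, 0) = g[3 * i];
    grad(i, 1) = g[3 * i + 1];
    grad(i, 2) = g[3 * i + 2];
  }
  return List::create(_["terms"] = terms_vector(E), _["total"] = E.total(),
                      _["gradient"] = grad);
}

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix coords, List topo, int n_steps, int stride,
                      double dt, double friction, double kbt, double mass,
                      uint32_t seed, double energy_abort) {
  Topo t = parse_topo(topo);
  if (coords.nrow() != t.n) stop("coords do not match topology");
  int n = t.n;
  std::vector<double> x(3 * n), v(3 * n), g(3 * n);
  for (int i = 0; i < n; ++i) {
    x[3 * i] = coords(i, 0);
    x[3 * i + 1] = coords(i, 1);
    x[3 * i + 2] = coords(i, 2);
  }
  Pcg32 rng((uint64_t)seed);
  double vsig = std::sqrt(kbt / mass);
  for (int i = 0; i < 3 * n; ++i) v[i] = vsig * rng.normal();

  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1)) * vsig;
  if (friction == 0.0) {
    c1 = 1.0;
    c2 = 0.0;
  }

  NeighborList nl;
  EnergyTerms E = energy_forces(x, t, g, &nl);

  int n_frames = n_steps / stride;
  NumericVector frames((R_xlen_t)n_frames * n * 3);
  NumericMatrix eterms(n_frames, 10);
  NumericVector kinetic(n_frames);
  bool diverged = false;
  int frames_done = 0;
  double half = 0.5 * dt, halfm = 0.5 * dt / mass;

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < 3 * n; ++i) v[i] -= halfm * g[i];
    for (int i = 0; i < 3 * n; ++i) x[i] += half * v[i];
    if (c2 > 0.0) {
      for (int i = 0; i < 3 * n; ++i) v[i] = c1 * v[i] + c2 * rng.normal();
    }
    for (int i = 0; i < 3 * n; ++i) x[i] += half * v[i];
    E = energy_forces(x, t, g, &nl);
    for (int i = 0; i < 3 * n; ++i) v[i] -= halfm * g[i];

    if (step % stride == 0) {
      double tot = E.total();
      if (!std::isfinite(tot) || std::fabs(tot) > energy_abort) {
        diverged = true;
        break;
      }
      double ke = 0;
      for (int i = 0; i < 3 * n; ++i) ke += 0.5 * mass * v[i] * v[i];
      int f = frames_done;
      for (int i = 0; i < n; ++i) {
        frames[(R_xlen_t)f * n * 3 + i] = x[3 * i];
        frames[(R_xlen_t)f * n * 3 + n + i] = x[3 * i + 1];
        frames[(R_xlen_t)f * n * 3 + 2 * n + i] = x[3 * i + 2];
      }
      eterms(f, 0) = E.bonds;
      eterms(f, 1) = E.angles;
      eterms(f, 2) = E.dihedrals;
      eterms(f, 3) = E.contacts;
      eterms(f, 4) = E.interface;
      eterms(f, 5) = E.elec;
      eterms(f, 6) = E.exv;
      eterms(f, 7) = E.anchors;
      eterms(f, 8) = E.wall;
      eterms(f, 9) = tot;
      kinetic[f] = ke;
      frames_done++;
    }
  }

  NumericMatrix final_coords(n, 3), final_vel(n, 3);
  for (int i = 0; i < n; ++i) {
    final_coords(i, 0) = x[3 * i];
    final_coords(i, 1) = x[3 * i + 1];
    final_coords(i, 2) = x[3 * i + 2];
    final_vel(i, 0) = v[3 * i];
    final_vel(i, 1) = v[3 * i + 1];
    final_vel(i, 2) = v[3 * i + 2];
  }
  frames.attr("dim") = IntegerVector::create(n, 3, n_frames);
  colnames(eterms) = CharacterVector::create(
      "bonds", "angles", "dihedrals", "contacts", "interface", "elec", "exv",
      "anchors", "wall", "total");
  return List::create(
      _["frames"] = frames, _["energy"] = eterms, _["kinetic"] = kinetic,
      _["frames_done"] = frames_done, _["diverged"] = diverged,
      _["final_coords"] = final_coords, _["final_velocities"] = final_vel);
}
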