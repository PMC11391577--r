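// Core CG-MD kernels: pair/bonded forces, Ewald electrostatics, virtual
// walls, velocity-Verlet with Nose-Hoover chain thermostat and MTK-style
// barostat, Verlet neighbor list, rejection-packing helpers, minimizer.
//
// Internal units: length A, time fs, mass amu, energy kcal/mol.
// Forces in kcal/mol/A; accelerations need the amu*A^2/fs^2 <-> kcal/mol
// conversion (KCAL_PER_MVV below). Pressure virial accumulated in
// kcal/mol; conversion to bar happens in R.

#include <Rcpp.h>
#include <cmath>
#include <complex>
#include <vector>

using namespace Rcpp;

static const double KCAL_PER_MVV = 2390.057361;   // 1 amu*A^2/fs^2 in kcal/mol
static const double KB_KCAL = 0.0019872041;       // kcal/mol/K
static const double COULOMB_K = 332.0637;         // kcal*A/(mol*e^2)

// ---------------------------------------------------------------------------
// parameter bundle unpacked from the R-side force-field table
// ---------------------------------------------------------------------------
struct FFData {
  int ntype;
  std::vector<double> eps, sig;   // ntype*ntype, row-major
  std::vector<int> form;          // 1 = LJ 9-6, 2 = LJ 12-4, 0 = none
  double cutoff;
  bool lj_shift;                  // energy-shift LJ to zero at cutoff
  // electrostatics: 0 none, 1 cutoff_shifted, 2 ewald
  int es_method;
  double eps_r;
  double ewald_s;                 // dimensionless accuracy factor (alpha = s/rc)
  std::vector<double> charge;     // per type
  double bond_prefactor;          // 1.0 => U = k (x-x0)^2 (no 1/2)
};

static FFData unpack_ff(const List& ff) {
  FFData d;
  NumericMatrix eps = ff["eps"], sig = ff["sig"];
  IntegerMatrix form = ff["form"];
  d.ntype = eps.nrow();
  d.eps.assign(eps.begin(), eps.end());
  d.sig.assign(sig.begin(), sig.end());
  d.form.assign(form.begin(), form.end());
  d.cutoff = as<double>(ff["cutoff"]);
  d.lj_shift = as<bool>(ff["lj_shift"]);
  d.es_method = as<int>(ff["es_method"]);
  d.eps_r = as<double>(ff["eps_r"]);
  d.ewald_s = as<double>(ff["ewald_s"]);
  NumericVector q = ff["charge"];
  d.charge.assign(q.begin(), q.end());
  d.bond_prefactor = as<double>(ff["bond_prefactor"]);
  return d;
}

static inline double min_image(double dx, double L) {
  return dx - L * std::round(dx / L);
}

// pair LJ energy/force (radial force = -dU/dr); unshifted value
static inline void lj_eval(double r, double eps, double sig, int form,
                           double& u, double& fr) {
  if (form == 1) {             // 9-6
    double s3 = sig * sig * sig / (r * r * r);
    double s6 = s3 * s3, s9 = s6 * s3;
    u = 6.75 * eps * (s9 - s6);
    fr = 6.75 * eps * (9.0 * s9 - 6.0 * s6) / r;
  } else if (form == 2) {      // 12-4
    double s2 = sig * sig / (r * r);
    double s4 = s2 * s2, s12 = s4 * s4 * s4;
    const double c = 2.598076211353316; // 3*sqrt(3)/2
    u = c * eps * (s12 - s4);
    fr = c * eps * (12.0 * s12 - 4.0 * s4) / r;
  } else {
    u = 0.0; fr = 0.0;
  }
}

// [[Rcpp::export]]
List cpp_lj_pair(double r, double eps, double sig, int form, double cutoff,
                 bool shift) {
  if (r <= 0) stop("pair distance must be positive (overlapping beads)");
  double u = 0, fr = 0;
  if (r <= cutoff) {
    lj_eval(r, eps, sig, form, u, fr);
    if (shift) {
      double us, fs;
      lj_eval(cutoff, eps, sig, form, us, fs);
      u -= us;
    }
  }
  return List::create(_["energy"] = u, _["force"] = fr);
}

// ---------------------------------------------------------------------------
// walls: one-sided repulsive planes acting on selected types only
// wall matrix columns: axis(0..2), position, side(+1/-1), k, law(1 quad, 2 lin)
// ---------------------------------------------------------------------------
struct Walls {
  int n;
  std::vector<int> axis, side, law;
  std::vector<double> pos, k;
  std::vector<int> affected; // n * ntype, 0/1
};

static Walls unpack_walls(const List& wl, int ntype) {
  Walls w;
  if (wl.size() == 0) { w.n = 0; return w; }
  NumericMatrix m = wl["params"];
  IntegerMatrix aff = wl["affected"];
  w.n = m.nrow();
  for (int i = 0; i < w.n; i++) {
    w.axis.push_back((int)m(i, 0));
    w.pos.push_back(m(i, 1));
    w.side.push_back((int)m(i, 2));
    w.k.push_back(m(i, 3));
    w.law.push_back((int)m(i, 4));
  }
  // aff is ntype rows x n_walls cols; store row-major per wall
  w.affected.assign((size_t)w.n * ntype, 0);
  for (int j = 0; j < w.n; j++)
    for (int t = 0; t < ntype; t++)
      w.affected[(size_t)j * ntype + t] = aff(t, j);
  return w;
}

// ---------------------------------------------------------------------------
// full force evaluation
// ---------------------------------------------------------------------------
struct ForceResult {
  std::vector<double> f;        // 3N
  double e_lj, e_coul, e_bond, e_angle, e_wall;
  double vir[6];                // xx yy zz xy xz yz (kcal/mol)
  std::vector<double> wall_f;   // per wall, instantaneous total |force|
};

struct Topology {
  std::vector<int> bond_i, bond_j;
  std::vector<double> bond_k, bond_r0;
  std::vector<int> ang_i, ang_j, ang_k_;
  std::vector<double> ang_kth, ang_th0;
  std::vector<int> ang_corr;
  // exclusion list per bead (sorted), and 1-3 corr pairs
  std::vector< std::vector<int> > excl;
};

static Topology unpack_topo(const List& topo, int N) {
  Topology t;
  t.excl.resize(N);
  if (topo.size() == 0) return t;
  IntegerMatrix b = topo["bonds"];       // i j (0-based already)
  NumericVector bk = topo["bond_k"], br0 = topo["bond_r0"];
  for (int e = 0; e < b.nrow(); e++) {
    t.bond_i.push_back(b(e, 0)); t.bond_j.push_back(b(e, 1));
    t.bond_k.push_back(bk[e]); t.bond_r0.push_back(br0[e]);
    t.excl[b(e, 0)].push_back(b(e, 1));
    t.excl[b(e, 1)].push_back(b(e, 0));
  }
  IntegerMatrix a = topo["angles"];
  NumericVector ak = topo["angle_k"], ath = topo["angle_theta0"];
  IntegerVector ac = topo["angle_corr"];
  for (int e = 0; e < a.nrow(); e++) {
    t.ang_i.push_back(a(e, 0)); t.ang_j.push_back(a(e, 1));
    t.ang_k_.push_back(a(e, 2));
    t.ang_kth.push_back(ak[e]); t.ang_th0.push_back(ath[e]);
    t.ang_corr.push_back(ac[e]);
    // 1-3 exclusion (LJ re-added below when corr flag set)
    t.excl[a(e, 0)].push_back(a(e, 2));
    t.excl[a(e, 2)].push_back(a(e, 0));
  }
  for (int i = 0; i < N; i++) {
    std::sort(t.excl[i].begin(), t.excl[i].end());
    t.excl[i].erase(std::unique(t.excl[i].begin(), t.excl[i].end()),
                    t.excl[i].end());
  }
  return t;
}

static inline bool is_excluded(const Topology& t, int i, int j) {
  const std::vector<int>& e = t.excl[i];
  return std::binary_search(e.begin(), e.end(), j);
}

// Ewald reciprocal + self + excluded-pair corrections. Adds to f and virial.
static double ewald_kspace(const std::vector<double>& x,
                           const std::vector<int>& type,
                           const FFData& ff, const double* L,
                           std::vector<double>& f, double* vir,
                           const Topology& topo) {
  int N = (int)type.size();
  std::vector<int> ch; // indices of charged beads
  for (int i = 0; i < N; i++) if (ff.charge[type[i]] != 0.0) ch.push_back(i);
  int Nq = (int)ch.size();
  if (Nq == 0) return 0.0;

  double alpha = ff.ewald_s / ff.cutoff;
  double V = L[0] * L[1] * L[2];
  double pref = COULOMB_K / ff.eps_r;
  int kmax[3];
  for (int d = 0; d < 3; d++) {
    kmax[d] = (int)std::ceil(alpha * ff.ewald_s * L[d] / M_PI);
    if (kmax[d] < 1) kmax[d] = 1;
  }
  typedef std::complex<double> cplx;
  // tabulate exp(i 2pi k x / L) per dimension
  std::vector< std::vector<cplx> > ex(3);
  for (int d = 0; d < 3; d++) ex[d].assign((size_t)Nq * (kmax[d] + 1), cplx(1, 0));
  for (int d = 0; d < 3; d++) {
    double tpiL = 2.0 * M_PI / L[d];
    for (int a = 0; a < Nq; a++) {
      cplx e1 = std::polar(1.0, tpiL * x[3 * ch[a] + d]);
      for (int k = 1; k <= kmax[d]; k++)
        ex[d][(size_t)a * (kmax[d] + 1) + k] =
          ex[d][(size_t)a * (kmax[d] + 1) + k - 1] * e1;
    }
  }
  double energy = 0.0;
  double inv4a2 = 1.0 / (4.0 * alpha * alpha);
  std::vector<cplx> eikr(Nq);
  // half-space: kx > 0 full range ky,kz; kx = 0, ky > 0; kx=ky=0, kz>0
  for (int kx = 0; kx <= kmax[0]; kx++) {
    int ky0 = (kx == 0) ? 0 : -kmax[1];
    for (int ky = ky0; ky <= kmax[1]; ky++) {
      int kz0 = (kx == 0 && ky == 0) ? 1 : -kmax[2];
      for (int kz = kz0; kz <= kmax[2]; kz++) {
        double rx = (double)kx / kmax[0], ry = (double)ky / kmax[1],
               rz = (double)kz / kmax[2];
        if (rx * rx + ry * ry + rz * rz > 1.0) continue;
        double gx = 2.0 * M_PI * kx / L[0];
        double gy = 2.0 * M_PI * ky / L[1];
        double gz = 2.0 * M_PI * kz / L[2];
        double k2 = gx * gx + gy * gy + gz * gz;
        double A = std::exp(-k2 * inv4a2) / k2;
        cplx S(0, 0);
        for (int a = 0; a < Nq; a++) {
          cplx eky = (ky >= 0) ? ex[1][(size_t)a * (kmax[1] + 1) + ky]
                               : std::conj(ex[1][(size_t)a * (kmax[1] + 1) - ky]);
          cplx ekz = (kz >= 0) ? ex[2][(size_t)a * (kmax[2] + 1) + kz]
                               : std::conj(ex[2][(size_t)a * (kmax[2] + 1) - kz]);
          eikr[a] = ex[0][(size_t)a * (kmax[0] + 1) + kx] * eky * ekz *
                    ff.charge[type[ch[a]]];
          S += eikr[a];
        }
        double S2 = std::norm(S);
        double w = 2.0; // half-space factor
        double Ek = pref * (2.0 * M_PI / V) * A * S2 * w;
        energy += Ek;
        // forces
        double fpref = pref * (4.0 * M_PI / V) * A * w;
        for (int a = 0; a < Nq; a++) {
          double im = std::imag(eikr[a] * std::conj(S));
          int i = ch[a];
          f[3 * i + 0] += fpref * gx * im;
          f[3 * i + 1] += fpref * gy * im;
          f[3 * i + 2] += fpref * gz * im;
        }
        // virial (diagonal + off-diagonal)
        double c2 = 2.0 * (1.0 / k2 + inv4a2);
        vir[0] += Ek * (1.0 - c2 * gx * gx);
        vir[1] += Ek * (1.0 - c2 * gy * gy);
        vir[2] += Ek * (1.0 - c2 * gz * gz);
        vir[3] += Ek * (-c2 * gx * gy);
        vir[4] += Ek * (-c2 * gx * gz);
        vir[5] += Ek * (-c2 * gy * gz);
      }
    }
  }
  // self energy
  double sumq2 = 0.0;
  for (int a = 0; a < Nq; a++) {
    double q = ff.charge[type[ch[a]]];
    sumq2 += q * q;
  }
  energy -= pref * alpha / std::sqrt(M_PI) * sumq2;
  // excluded-pair correction: remove the erf (reciprocal-space) part
  for (int a = 0; a < Nq; a++) {
    int i = ch[a];
    for (size_t m = 0; m < topo.excl[i].size(); m++) {
      int j = topo.excl[i][m];
      if (j <= i) continue;
      double qq = ff.charge[type[i]] * ff.charge[type[j]];
      if (qq == 0.0) continue;
      double dx = min_image(x[3 * i] - x[3 * j], L[0]);
      double dy = min_image(x[3 * i + 1] - x[3 * j + 1], L[1]);
      double dz = min_image(x[3 * i + 2] - x[3 * j + 2], L[2]);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double erf_r = std::erf(alpha * r);
      double u = pref * qq * erf_r / r;
      energy -= u;
      double fr = pref * qq * (erf_r / r -
                  2.0 * alpha / std::sqrt(M_PI) * std::exp(-alpha * alpha * r * r)) / r;
      // subtract: force -= d/dr of the erf term
      double fx = -fr * dx / r, fy = -fr * dy / r, fz = -fr * dz / r;
      f[3 * i] += fx; f[3 * i + 1] += fy; f[3 * i + 2] += fz;
      f[3 * j] -= fx; f[3 * j + 1] -= fy; f[3 * j + 2] -= fz;
      vir[0] += dx * fx; vir[1] += dy * fy; vir[2] += dz * fz;
      vir[3] += dx * fy; vir[4] += dx * fz; vir[5] += dy * fz;
    }
  }
  return energy;
}

// core force routine working on flat arrays
static void eval_forces(const std::vector<double>& x,
                        const std::vector<int>& type, const double* L,
                        const FFData& ff, const Topology& topo,
                        const Walls& walls,
                        const std::vector<int>& nl_i,
                        const std::vector<int>& nl_j, bool use_nl,
                        ForceResult& out) {
  int N = (int)type.size();
  out.f.assign(3 * N, 0.0);
  out.e_lj = out.e_coul = out.e_bond = out.e_angle = out.e_wall = 0.0;
  for (int k = 0; k < 6; k++) out.vir[k] = 0.0;
  out.wall_f.assign(walls.n, 0.0);

  double rc = ff.cutoff, rc2 = rc * rc;
  double pref = COULOMB_K / ff.eps_r;
  double alpha = ff.ewald_s / rc;
  bool ewald = (ff.es_method == 2);
  bool coul_cut = (ff.es_method == 1);

  // nonbonded pair interaction for one (i, j)
  auto do_pair = [&](int i, int j) {
    double dx = min_image(x[3 * i] - x[3 * j], L[0]);
    double dy = min_image(x[3 * i + 1] - x[3 * j + 1], L[1]);
    double dz = min_image(x[3 * i + 2] - x[3 * j + 2], L[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > rc2) return;
    bool excl = is_excluded(topo, i, j);
    double r = std::sqrt(r2);
    if (r < 0.1)
      stop("bead overlap: pair (%d, %d) at r = %f A", i + 1, j + 1, r);
    int ti = type[i], tj = type[j];
    double u = 0, fr = 0;
    if (!excl) {
      int form = ff.form[ti * ff.ntype + tj];
      if (form > 0) {
        double e = ff.eps[ti * ff.ntype + tj], s = ff.sig[ti * ff.ntype + tj];
        lj_eval(r, e, s, form, u, fr);
        if (ff.lj_shift) {
          double us, fs;
          lj_eval(rc, e, s, form, us, fs);
          u -= us;
        }
        out.e_lj += u;
      }
      double qq = ff.charge[ti] * ff.charge[tj];
      if (qq != 0.0) {
        if (ewald) {
          double erfc_r = std::erfc(alpha * r);
          double uc = pref * qq * erfc_r / r;
          out.e_coul += uc;
          fr += pref * qq * (erfc_r / r +
                2.0 * alpha / std::sqrt(M_PI) * std::exp(-alpha * alpha * r2)) / r;
        } else if (coul_cut) {
          double uc = pref * qq * (1.0 / r - 1.0 / rc);
          out.e_coul += uc;
          fr += pref * qq / r2;
        }
      }
    }
    if (fr != 0.0 || u != 0.0) {
      double fx = fr * dx / r, fy = fr * dy / r, fz = fr * dz / r;
      out.f[3 * i] += fx; out.f[3 * i + 1] += fy; out.f[3 * i + 2] += fz;
      out.f[3 * j] -= fx; out.f[3 * j + 1] -= fy; out.f[3 * j + 2] -= fz;
      out.vir[0] += dx * fx; out.vir[1] += dy * fy; out.vir[2] += dz * fz;
      out.vir[3] += dx * fy; out.vir[4] += dx * fz; out.vir[5] += dy * fz;
    }
  };
  if (use_nl) {
    for (size_t p = 0; p < nl_i.size(); p++) do_pair(nl_i[p], nl_j[p]);
  } else {
    for (int i = 0; i < N - 1; i++)
      for (int j = i + 1; j < N; j++) do_pair(i, j);
  }

  // reciprocal-space electrostatics
  if (ewald)
    out.e_coul += ewald_kspace(x, type, ff, L, out.f, out.vir, topo);

  // bonds: U = pf * k * (r - r0)^2
  for (size_t b = 0; b < topo.bond_i.size(); b++) {
    int i = topo.bond_i[b], j = topo.bond_j[b];
    double dx = min_image(x[3 * i] - x[3 * j], L[0]);
    double dy = min_image(x[3 * i + 1] - x[3 * j + 1], L[1]);
    double dz = min_image(x[3 * i + 2] - x[3 * j + 2], L[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - topo.bond_r0[b];
    double kb = ff.bond_prefactor * topo.bond_k[b];
    out.e_bond += kb * dr * dr;
    double fr = -2.0 * kb * dr; // radial force (-dU/dr)
    double fx = fr * dx / r, fy = fr * dy / r, fz = fr * dz / r;
    out.f[3 * i] += fx; out.f[3 * i + 1] += fy; out.f[3 * i + 2] += fz;
    out.f[3 * j] -= fx; out.f[3 * j + 1] -= fy; out.f[3 * j + 2] -= fz;
    out.vir[0] += dx * fx; out.vir[1] += dy * fy; out.vir[2] += dz * fz;
    out.vir[3] += dx * fy; out.vir[4] += dx * fz; out.vir[5] += dy * fz;
  }

  // angles: U = pf * k * (theta - theta0)^2, plus optional 1-3 LJ correction
  for (size_t a = 0; a < topo.ang_i.size(); a++) {
    int i = topo.ang_i[a], j = topo.ang_j[a], k = topo.ang_k_[a];
    double r1x = min_image(x[3 * i] - x[3 * j], L[0]);
    double r1y = min_image(x[3 * i + 1] - x[3 * j + 1], L[1]);
    double r1z = min_image(x[3 * i + 2] - x[3 * j + 2], L[2]);
    double r2x = min_image(x[3 * k] - x[3 * j], L[0]);
    double r2y = min_image(x[3 * k + 1] - x[3 * j + 1], L[1]);
    double r2z = min_image(x[3 * k + 2] - x[3 * j + 2], L[2]);
    double n1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
    double n2 = std::sqrt(r2x * r2x + r2y * r2y + r2z * r2z);
    if (n1 < 1e-10 || n2 < 1e-10)
      stop("degenerate angle geometry (zero-length arm) in angle %d", (int)a + 1);
    double cth = (r1x * r2x + r1y * r2y + r1z * r2z) / (n1 * n2);
    if (cth > 1.0) cth = 1.0;
    if (cth < -1.0) cth = -1.0;
    double th = std::acos(cth);
    double sth = std::sqrt(1.0 - cth * cth);
    if (sth < 1e-8) sth = 1e-8; // regularize collinear geometry
    double ka = ff.bond_prefactor * topo.ang_kth[a];
    double dth = th - topo.ang_th0[a];
    out.e_angle += ka * dth * dth;
    double dUdth = 2.0 * ka * dth;
    double c = dUdth / sth; // dU/dcos(theta) = -dU/dtheta / sin(theta); sign folded below
    // grad of cos(theta)
    double gi_x = (r2x / (n1 * n2)) - cth * r1x / (n1 * n1);
    double gi_y = (r2y / (n1 * n2)) - cth * r1y / (n1 * n1);
    double gi_z = (r2z / (n1 * n2)) - cth * r1z / (n1 * n1);
    double gk_x = (r1x / (n1 * n2)) - cth * r2x / (n2 * n2);
    double gk_y = (r1y / (n1 * n2)) - cth * r2y / (n2 * n2);
    double gk_z = (r1z / (n1 * n2)) - cth * r2z / (n2 * n2);
    double fi_x = c * gi_x, fi_y = c * gi_y, fi_z = c * gi_z;
    double fk_x = c * gk_x, fk_y = c * gk_y, fk_z = c * gk_z;
    out.f[3 * i] += fi_x; out.f[3 * i + 1] += fi_y; out.f[3 * i + 2] += fi_z;
    out.f[3 * k] += fk_x; out.f[3 * k + 1] += fk_y; out.f[3 * k + 2] += fk_z;
    out.f[3 * j] -= (fi_x + fk_x);
    out.f[3 * j + 1] -= (fi_y + fk_y);
    out.f[3 * j + 2] -= (fi_z + fk_z);
    out.vir[0] += r1x * fi_x + r2x * fk_x;
    out.vir[1] += r1y * fi_y + r2y * fk_y;
    out.vir[2] += r1z * fi_z + r2z * fk_z;
    out.vir[3] += r1x * fi_y + r2x * fk_y;
    out.vir[4] += r1x * fi_z + r2x * fk_z;
    out.vir[5] += r1y * fi_z + r2y * fk_z;
    // 1-3 LJ correction against angle collapse
    if (topo.ang_corr[a]) {
      double dx = min_image(x[3 * i] - x[3 * k], L[0]);
      double dy = min_image(x[3 * i + 1] - x[3 * k + 1], L[1]);
      double dz = min_image(x[3 * i + 2] - x[3 * k + 2], L[2]);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r <= rc) {
        int ti = type[i], tk = type[k];
        int form = ff.form[ti * ff.ntype + tk];
        if (form > 0) {
          double u, fr;
          lj_eval(r, ff.eps[ti * ff.ntype + tk], ff.sig[ti * ff.ntype + tk],
                  form, u, fr);
          if (ff.lj_shift) {
            double us, fs;
            lj_eval(rc, ff.eps[ti * ff.ntype + tk], ff.sig[ti * ff.ntype + tk],
                    form, us, fs);
            u -= us;
          }
          out.e_angle += u;
          double fx = fr * dx / r, fy = fr * dy / r, fz = fr * dz / r;
          out.f[3 * i] += fx; out.f[3 * i + 1] += fy; out.f[3 * i + 2] += fz;
          out.f[3 * k] -= fx; out.f[3 * k + 1] -= fy; out.f[3 * k + 2] -= fz;
          out.vir[0] += dx * fx; out.vir[1] += dy * fy; out.vir[2] += dz * fz;
          out.vir[3] += dx * fy; out.vir[4] += dx * fz; out.vir[5] += dy * fz;
        }
      }
    }
  }

  // virtual walls (one-sided; excluded from internal virial)
  for (int w = 0; w < walls.n; w++) {
    int ax = walls.axis[w];
    for (int i = 0; i < N; i++) {
      if (!walls.affected[(size_t)w * ff.ntype + type[i]]) continue;
      double d = (x[3 * i + ax] - walls.pos[w]) * walls.side[w];
      if (d <= 0.0) continue;
      double fmag, u;
      if (walls.law[w] == 1) { fmag = walls.k[w] * d * d; u = walls.k[w] * d * d * d / 3.0; }
      else { fmag = walls.k[w] * d; u = 0.5 * walls.k[w] * d * d; }
      out.e_wall += u;
      out.f[3 * i + ax] -= fmag * walls.side[w]; // push back toward allowed side
      out.wall_f[w] += fmag;
    }
  }
}

// neighbor-list construction (all pairs within cutoff + skin)
static void build_nlist(const std::vector<double>& x, const double* L,
                        double rlist, std::vector<int>& nl_i,
                        std::vector<int>& nl_j) {
  int N = (int)x.size() / 3;
  nl_i.clear(); nl_j.clear();
  double rl2 = rlist * rlist;
  for (int i = 0; i < N - 1; i++)
    for (int j = i + 1; j < N; j++) {
      double dx = min_image(x[3 * i] - x[3 * j], L[0]);
      double dy = min_image(x[3 * i + 1] - x[3 * j + 1], L[1]);
      double dz = min_image(x[3 * i + 2] - x[3 * j + 2], L[2]);
      if (dx * dx + dy * dy + dz * dz <= rl2) {
        nl_i.push_back(i); nl_j.push_back(j);
      }
    }
}

static List force_result_to_list(const ForceResult& fr, int N) {
  NumericMatrix f(N, 3);
  for (int i = 0; i < N; i++)
    for (int d = 0; d < 3; d++) f(i, d) = fr.f[3 * i + d];
  NumericVector vir = NumericVector::create(
    fr.vir[0], fr.vir[1], fr.vir[2], fr.vir[3], fr.vir[4], fr.vir[5]);
  double pe = fr.e_lj + fr.e_coul + fr.e_bond + fr.e_angle + fr.e_wall;
  return List::create(
    _["forces"] = f,
    _["energy"] = List::create(_["lj"] = fr.e_lj, _["coul"] = fr.e_coul,
                               _["bond"] = fr.e_bond, _["angle"] = fr.e_angle,
                               _["wall"] = fr.e_wall, _["potential"] = pe),
    _["virial"] = vir,
    _["wall_forces"] = NumericVector(fr.wall_f.begin(), fr.wall_f.end()));
}

// [[Rcpp::export]]
List cpp_compute_forces(NumericMatrix pos, NumericVector box,
                        IntegerVector type0, List ffdata, List topo,
                        List walls, bool use_nlist, double skin) {
  int N = pos.nrow();
  FFData ff = unpack_ff(ffdata);
  Topology tp = unpack_topo(topo, N);
  Walls wl = unpack_walls(walls, ff.ntype);
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; i++)
    for (int d = 0; d < 3; d++) x[3 * i + d] = pos(i, d);
  std::vector<int> type(type0.begin(), type0.end()); // 0-based from R wrapper
  double L[3] = { box[0], box[1], box[2] };
  std::vector<int> nl_i, nl_j;
  if (use_nlist) build_nlist(x, L, ff.cutoff + skin, nl_i, nl_j);
  ForceResult out;
  eval_forces(x, type, L, ff, tp, wl, nl_i, nl_j, use_nlist, out);
  return force_result_to_list(out, N);
}

// ---------------------------------------------------------------------------
// Nose-Hoover chain thermostat (length 3) and MTK barostat
// ---------------------------------------------------------------------------
struct NHC {
  double xi[3], vxi[3], Q[3];
  void init(double Nf, double T, double tau) {
    for (int k = 0; k < 3; k++) { xi[k] = 0; vxi[k] = 0; }
    Q[0] = Nf * KB_KCAL * T * tau * tau / KCAL_PER_MVV; // internal units
    Q[1] = Q[2] = KB_KCAL * T * tau * tau / KCAL_PER_MVV;
  }
  // returns velocity scale factor for half-step dt2; ke2 = 2*KE (internal units)
  double update(double ke2, double Nf, double T, double dt2) {
    double kT = KB_KCAL * T / KCAL_PER_MVV;
    double G2, G3;
    double dt4 = dt2 / 2.0, dt8 = dt4 / 2.0;
    G3 = (Q[1] * vxi[1] * vxi[1] - kT) / Q[2];
    vxi[2] += G3 * dt4;
    G2 = (Q[0] * vxi[0] * vxi[0] - kT) / Q[1];
    vxi[1] *= std::exp(-vxi[2] * dt8);
    vxi[1] += G2 * dt4;
    vxi[1] *= std::exp(-vxi[2] * dt8);
    double G1 = (ke2 - Nf * kT) / Q[0];
    vxi[0] *= std::exp(-vxi[1] * dt8);
    vxi[0] += G1 * dt4;
    vxi[0] *= std::exp(-vxi[1] * dt8);
    double s = std::exp(-vxi[0] * dt2);
    ke2 *= s * s;
    xi[0] += vxi[0] * dt2; xi[1] += vxi[1] * dt2; xi[2] += vxi[2] * dt2;
    vxi[0] *= std::exp(-vxi[1] * dt8);
    G1 = (ke2 - Nf * kT) / Q[0];
    vxi[0] += G1 * dt4;
    vxi[0] *= std::exp(-vxi[1] * dt8);
    G2 = (Q[0] * vxi[0] * vxi[0] - kT) / Q[1];
    vxi[1] *= std::exp(-vxi[2] * dt8);
    vxi[1] += G2 * dt4;
    vxi[1] *= std::exp(-vxi[2] * dt8);
    G3 = (Q[1] * vxi[1] * vxi[1] - kT) / Q[2];
    vxi[2] += G3 * dt4;
    return s;
  }
};

// pressure-cell groups: axes sharing one barostat degree of freedom
struct BaroGroup {
  std::vector<int> axes;
  double veps, W;
  NHC chain; // dedicated thermostat for the cell variable
};

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, NumericVector box,
             IntegerVector type0, NumericVector mass_by_type, List ffdata,
             List topo, List walls, List ens, int n_steps, int sample_every,
             bool store_frames, bool use_nlist, double skin) {
  int N = pos.nrow();
  FFData ff = unpack_ff(ffdata);
  Topology tp = unpack_topo(topo, N);
  Walls wl = unpack_walls(walls, ff.ntype);
  std::vector<double> x(3 * N), v(3 * N), m(N);
  for (int i = 0; i < N; i++) {
    m[i] = mass_by_type[type0[i]];
    for (int d = 0; d < 3; d++) { x[3*i+d] = pos(i, d); v[3*i+d] = vel(i, d); }
  }
  std::vector<int> type(type0.begin(), type0.end());
  double L[3] = { box[0], box[1], box[2] };

  std::string kind = as<std::string>(ens["kind"]);
  double T0 = as<double>(ens["temperature"]);
  double P0 = as<double>(ens["pressure"]);           // bar
  double dt = as<double>(ens["dt"]);
  double tau_t = as<double>(ens["tau_t"]);
  double tau_p = as<double>(ens["tau_p"]);
  std::string npt_mode = as<std::string>(ens["npt_mode"]); // iso / z / xy_z

  bool thermo = (kind != "NVE");
  bool baro = (kind == "NPT");
  double Nf = 3.0 * N - 3.0;
  double kT = KB_KCAL * T0 / KCAL_PER_MVV;
  double P0_int = P0 / 69476.95457 / KCAL_PER_MVV; // bar -> internal E/A^3

  NHC part_chain; part_chain.init(Nf, T0, tau_t);
  std::vector<BaroGroup> groups;
  if (baro) {
    if (npt_mode == "iso") {
      BaroGroup g; g.axes = {0, 1, 2}; groups.push_back(g);
    } else if (npt_mode == "z") {
      BaroGroup g; g.axes = {2}; groups.push_back(g);
    } else if (npt_mode == "xy_z") {
      BaroGroup g1; g1.axes = {0, 1}; groups.push_back(g1);
      BaroGroup g2; g2.axes = {2}; groups.push_back(g2);
    } else stop("unknown npt_mode");
    for (size_t g = 0; g < groups.size(); g++) {
      int d = (int)groups[g].axes.size();
      groups[g].veps = 0.0;
      groups[g].W = (Nf + d) * kT * tau_p * tau_p;
      groups[g].chain.init(1.0, T0, tau_p);
    }
  }

  std::vector<int> nl_i, nl_j;
  std::vector<double> x_at_build(3 * N);
  double L_at_build[3] = { L[0], L[1], L[2] };
  double skin2 = (skin / 2.0) * (skin / 2.0);
  bool need_build = true;

  ForceResult fr;
  // per-sample channels
  std::vector<double> ch_time, ch_pe, ch_ke, ch_T, ch_vol;
  std::vector<double> ch_P(0), ch_box, ch_wall;
  List frames;
  std::vector<NumericMatrix> frame_pos, frame_vel;
  std::vector<NumericVector> frame_box;
  std::vector<double> frame_time;

  double t = 0.0;
  double dt2 = dt / 2.0;

  // lambdas -------------------------------------------------------------
  auto wrap = [&]() {
    for (int i = 0; i < N; i++)
      for (int d = 0; d < 3; d++) {
        double& xi = x[3 * i + d];
        xi -= L[d] * std::floor(xi / L[d]);
      }
  };
  auto maybe_rebuild = [&]() {
    if (!use_nlist) return;
    if (!need_build) {
      for (int d = 0; d < 3; d++)
        if (std::fabs(L[d] / L_at_build[d] - 1.0) > 0.003) need_build = true;
    }
    if (!need_build) {
      double maxd2 = 0.0;
      for (int i = 0; i < 3 * N; i++) {
        double dd = x[i] - x_at_build[i];
        // displacement test ignores periodic wrap; conservative enough with wrap step below
        double d2 = dd * dd;
        if (d2 > maxd2) maxd2 = d2;
      }
      if (maxd2 > skin2 / 3.0) need_build = true; // per-component bound
    }
    if (need_build) {
      wrap();
      build_nlist(x, L, ff.cutoff + skin, nl_i, nl_j);
      x_at_build = x;
      for (int d = 0; d < 3; d++) L_at_build[d] = L[d];
      need_build = false;
    }
  };
  auto kinetic2 = [&]() { // 2*KE in internal units
    double s = 0;
    for (int i = 0; i < N; i++)
      for (int d = 0; d < 3; d++) s += m[i] * v[3*i+d] * v[3*i+d];
    return s;
  };
  auto ptensor_diag = [&](double* P) { // internal units E/A^3
    double V = L[0] * L[1] * L[2];
    for (int d = 0; d < 3; d++) {
      double kin = 0;
      for (int i = 0; i < N; i++) kin += m[i] * v[3*i+d] * v[3*i+d];
      P[d] = (kin + fr.vir[d] / KCAL_PER_MVV) / V;
    }
  };

  maybe_rebuild();
  eval_forces(x, type, L, ff, tp, wl, nl_i, nl_j, use_nlist, fr);

  auto sample = [&]() {
    double ke2 = kinetic2();
    double pe = (fr.e_lj + fr.e_coul + fr.e_bond + fr.e_angle + fr.e_wall);
    double Tk = ke2 * KCAL_PER_MVV / (Nf * KB_KCAL);
    double V = L[0] * L[1] * L[2];
    ch_time.push_back(t);
    ch_pe.push_back(pe);
    ch_ke.push_back(0.5 * ke2 * KCAL_PER_MVV);
    ch_T.push_back(Tk);
    ch_vol.push_back(V);
    double Pd[3]; ptensor_diag(Pd);
    for (int d = 0; d < 3; d++)
      ch_P.push_back(Pd[d] * KCAL_PER_MVV * 69476.95457);
    // off-diagonals (virial only + kinetic cross terms)
    double kxy = 0, kxz = 0, kyz = 0;
    for (int i = 0; i < N; i++) {
      kxy += m[i] * v[3*i] * v[3*i+1];
      kxz += m[i] * v[3*i] * v[3*i+2];
      kyz += m[i] * v[3*i+1] * v[3*i+2];
    }
    ch_P.push_back((kxy + fr.vir[3] / KCAL_PER_MVV) / V * KCAL_PER_MVV * 69476.95457);
    ch_P.push_back((kxz + fr.vir[4] / KCAL_PER_MVV) / V * KCAL_PER_MVV * 69476.95457);
    ch_P.push_back((kyz + fr.vir[5] / KCAL_PER_MVV) / V * KCAL_PER_MVV * 69476.95457);
    for (int d = 0; d < 3; d++) ch_box.push_back(L[d]);
    for (int w = 0; w < wl.n; w++) ch_wall.push_back(fr.wall_f[w]);
    if (store_frames) {
      NumericMatrix fp(N, 3), fv(N, 3);
      for (int i = 0; i < N; i++)
        for (int d = 0; d < 3; d++) { fp(i,d) = x[3*i+d]; fv(i,d) = v[3*i+d]; }
      frame_pos.push_back(fp); frame_vel.push_back(fv);
      frame_box.push_back(NumericVector::create(L[0], L[1], L[2]));
      frame_time.push_back(t);
    }
  };

  wrap();
  sample(); // initial state

  for (int step = 0; step < n_steps; step++) {
    // --- thermostats (half) ---
    if (thermo) {
      double s = part_chain.update(kinetic2(), Nf, T0, dt2);
      for (int i = 0; i < 3 * N; i++) v[i] *= s;
    }
    if (baro) {
      for (size_t g = 0; g < groups.size(); g++) {
        BaroGroup& bg = groups[g];
        double ke2b = bg.W * bg.veps * bg.veps;
        double sb = bg.chain.update(ke2b, 1.0, T0, dt2);
        bg.veps *= sb;
        double Pd[3]; ptensor_diag(Pd);
        double V = L[0] * L[1] * L[2];
        double Pbar = 0;
        for (size_t a = 0; a < bg.axes.size(); a++) Pbar += Pd[bg.axes[a]];
        Pbar /= bg.axes.size();
        int d = (int)bg.axes.size();
        double Feps = d * V * (Pbar - P0_int) + (d / Nf) * kinetic2();
        bg.veps += dt2 * Feps / bg.W;
      }
    }
    // --- half kick ---
    double alpha_ax[3] = {0, 0, 0};
    if (baro)
      for (size_t g = 0; g < groups.size(); g++)
        for (size_t a = 0; a < groups[g].axes.size(); a++)
          alpha_ax[groups[g].axes[a]] =
            groups[g].veps * (1.0 + (double)groups[g].axes.size() / Nf);
    for (int i = 0; i < N; i++)
      for (int d = 0; d < 3; d++) {
        double ex = baro ? std::exp(-dt2 * alpha_ax[d]) : 1.0;
        v[3*i+d] = v[3*i+d] * ex +
          dt2 * (fr.f[3*i+d] / KCAL_PER_MVV / m[i]) * (baro ? std::exp(-dt2 * alpha_ax[d] / 2.0) : 1.0);
      }
    // --- drift ---
    for (int d = 0; d < 3; d++) {
      double veps_d = 0;
      if (baro)
        for (size_t g = 0; g < groups.size(); g++)
          for (size_t a = 0; a < groups[g].axes.size(); a++)
            if (groups[g].axes[a] == d) veps_d = groups[g].veps;
      double e1 = baro ? std::exp(dt * veps_d) : 1.0;
      double e2 = baro ? std::exp(dt2 * veps_d) : 1.0;
      for (int i = 0; i < N; i++)
        x[3*i+d] = x[3*i+d] * e1 + dt * v[3*i+d] * e2;
      if (baro) L[d] *= e1;
    }

    // --- forces ---
    maybe_rebuild();
    eval_forces(x, type, L, ff, tp, wl, nl_i, nl_j, use_nlist, fr);
    // --- second half kick ---
    for (int i = 0; i < N; i++)
      for (int d = 0; d < 3; d++) {
        double ex = baro ? std::exp(-dt2 * alpha_ax[d]) : 1.0;
        v[3*i+d] = (v[3*i+d] +
          dt2 * (fr.f[3*i+d] / KCAL_PER_MVV / m[i]) * (baro ? std::exp(-dt2 * alpha_ax[d] / 2.0) : 1.0)) * ex;
      }
    if (baro) {
      for (size_t g = 0; g < groups.size(); g++) {
        BaroGroup& bg = groups[g];
        double Pd[3]; ptensor_diag(Pd);
        double V = L[0] * L[1] * L[2];
        double Pbar = 0;
        for (size_t a = 0; a < bg.axes.size(); a++) Pbar += Pd[bg.axes[a]];
        Pbar /= bg.axes.size();
        int d = (int)bg.axes.size();
        double Feps = d * V * (Pbar - P0_int) + (d / Nf) * kinetic2();
        bg.veps += dt2 * Feps / bg.W;
        double ke2b = bg.W * bg.veps * bg.veps;
        double sb = bg.chain.update(ke2b, 1.0, T0, dt2);
        bg.veps *= sb;
      }
    }
    if (thermo) {
      double s = part_chain.update(kinetic2(), Nf, T0, dt2);
      for (int i = 0; i < 3 * N; i++) v[i] *= s;
    }
    t += dt;
    for (int i = 0; i < 3 * N; i++)
      if (!std::isfinite(x[i]) || !std::isfinite(v[i]))
        stop("integration blow-up at step %d (non-finite coordinate/velocity)",
             step + 1);
    if ((step + 1) % sample_every == 0) { wrap(); sample(); }
  }

  int ns = (int)ch_time.size();
  NumericMatrix Pm(ns, 6), Bm(ns, 3);
  for (int s = 0; s < ns; s++) {
    for (int k = 0; k < 6; k++) Pm(s, k) = ch_P[(size_t)s * 6 + k];
    for (int k = 0; k < 3; k++) Bm(s, k) = ch_box[(size_t)s * 3 + k];
  }
  NumericMatrix Wm(ns, wl.n > 0 ? wl.n : 0);
  for (int s = 0; s < ns; s++)
    for (int w = 0; w < wl.n; w++) Wm(s, w) = ch_wall[(size_t)s * wl.n + w];
  List fl;
  if (store_frames) {
    fl = List(frame_pos.size());
    for (size_t i = 0; i < frame_pos.size(); i++)
      fl[i] = List::create(_["pos"] = frame_pos[i], _["vel"] = frame_vel[i],
                           _["box"] = frame_box[i], _["time"] = frame_time[i]);
  }
  NumericMatrix fpos(N, 3), fvel(N, 3);
  for (int i = 0; i < N; i++)
    for (int d = 0; d < 3; d++) { fpos(i,d) = x[3*i+d]; fvel(i,d) = v[3*i+d]; }
  return List::create(
    _["time"] = NumericVector(ch_time.begin(), ch_time.end()),
    _["pe"] = NumericVector(ch_pe.begin(), ch_pe.end()),
    _["ke"] = NumericVector(ch_ke.begin(), ch_ke.end()),
    _["temperature"] = NumericVector(ch_T.begin(), ch_T.end()),
    _["volume"] = NumericVector(ch_vol.begin(), ch_vol.end()),
    _["pressure"] = Pm, _["box"] = Bm, _["wall_forces"] = Wm,
    _["frames"] = fl,
    _["final"] = List::create(_["pos"] = fpos, _["vel"] = fvel,
                              _["box"] = NumericVector::create(L[0], L[1], L[2])));
}

// ---------------------------------------------------------------------------
// steepest-descent minimizer with displacement cap (removes packing overlaps)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_minimize(NumericMatrix pos, NumericVector box, IntegerVector type0,
                  List ffdata, List topo, List walls, int n_steps,
                  double max_disp) {
  int N = pos.nrow();
  FFData ff = unpack_ff(ffdata);
  Topology tp = unpack_topo(topo, N);
  Walls wl = unpack_walls(walls, ff.ntype);
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; i++)
    for (int d = 0; d < 3; d++) x[3 * i + d] = pos(i, d);
  std::vector<int> type(type0.begin(), type0.end());
  double L[3] = { box[0], box[1], box[2] };
  std::vector<int> nl_i, nl_j;
  ForceResult fr;
  double e_prev = R_PosInf;
  // soft-core ramp not needed at CG densities; displacement cap suffices
  for (int it = 0; it < n_steps; it++) {
    build_nlist(x, L, ff.cutoff + 1.0, nl_i, nl_j);
    eval_forces(x, type, L, ff, tp, wl, nl_i, nl_j, true, fr);
    double fmax = 0;
    for (int i = 0; i < 3 * N; i++) fmax = std::max(fmax, std::fabs(fr.f[i]));
    double e = fr.e_lj + fr.e_coul + fr.e_bond + fr.e_angle + fr.e_wall;
    if (fmax < 1e-4) break;
    double scale = max_disp / std::max(fmax, 1e-12);
    for (int i = 0; i < 3 * N; i++) {
      double dx = fr.f[i] * scale;
      if (dx > max_disp) dx = max_disp;
      if (dx < -max_disp) dx = -max_disp;
      x[i] += dx;
    }
    for (int i = 0; i < N; i++)
      for (int d = 0; d < 3; d++) {
        double& xi = x[3 * i + d];
        xi -= L[d] * std::floor(xi / L[d]);
      }
    if (std::isfinite(e) && e_prev < e) max_disp *= 0.5;
    e_prev = e;
  }
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; i++)
    for (int d = 0; d < 3; d++) out(i, d) = x[3 * i + d];
  build_nlist(x, L, ff.cutoff + 1.0, nl_i, nl_j);
  eval_forces(x, type, L, ff, tp, wl, nl_i, nl_j, true, fr);
  double pe = fr.e_lj + fr.e_coul + fr.e_bond + fr.e_angle + fr.e_wall;
  return List::create(_["pos"] = out, _["energy"] = pe);
}

// ---------------------------------------------------------------------------
// packing helpers
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
double cpp_min_pair_dist(NumericMatrix pos, NumericVector box) {
  int N = pos.nrow();
  double best = R_PosInf;
  for (int i = 0; i < N - 1; i++)
    for (int j = i + 1; j < N; j++) {
      double dx = min_image(pos(i,0) - pos(j,0), box[0]);
      double dy = min_image(pos(i,1) - pos(j,1), box[1]);
      double dz = min_image(pos(i,2) - pos(j,2), box[2]);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r < best) best = r;
    }
  return best;
}

// [[Rcpp::export]]
bool cpp_candidate_ok(NumericMatrix pos, int n_placed, NumericVector cand,
                      NumericVector box, double min_dist) {
  double md2 = min_dist * min_dist;
  for (int i = 0; i < n_placed; i++) {
    double dx = min_image(pos(i,0) - cand[0], box[0]);
    double dy = min_image(pos(i,1) - cand[1], box[1]);
    double dz = min_image(pos(i,2) - cand[2], box[2]);
    if (dx*dx + dy*dy + dz*dz < md2) return false;
  }
  return true;
}
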