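#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// ---------------------------------------------------------------------------
// geometry
// ---------------------------------------------------------------------------

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

static inline void unit3(double* a) {
  double n = norm3(a);
  a[0] /= n; a[1] /= n; a[2] /= n;
}

// Build backbone Cartesian coordinates from internal coordinates by the
// natural-extension (NeRF) construction.  Dihedrals follow the IUPAC
// right-handed convention with trans = 180 deg.
static void build_chain(const double* dih_deg, int n, double l, double theta_deg,
                        double* xyz /* n x 3, row-major */) {
  double theta = theta_deg * DEG;
  xyz[0] = 0.0; xyz[1] = 0.0; xyz[2] = 0.0;
  if (n == 1) return;
  xyz[3] = l; xyz[4] = 0.0; xyz[5] = 0.0;
  if (n == 2) return;
  xyz[6] = l - l * std::cos(theta);
  xyz[7] = l * std::sin(theta);
  xyz[8] = 0.0;
  for (int i = 3; i < n; ++i) {
    const double* A = xyz + 3 * (i - 3);
    const double* B = xyz + 3 * (i - 2);
    const double* C = xyz + 3 * (i - 1);
    double phi = dih_deg[i - 3] * DEG;
    double bc[3] = {C[0] - B[0], C[1] - B[1], C[2] - B[2]};
    unit3(bc);
    double ab[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
    double nvec[3];
    cross3(ab, bc, nvec);
    unit3(nvec);
    double mvec[3];
    cross3(nvec, bc, mvec);
    double d0 = -l * std::cos(theta);
    double d1 = l * std::sin(theta) * std::cos(phi);
    double d2 = -l * std::sin(theta) * std::sin(phi);
    double* D = xyz + 3 * i;
    D[0] = C[0] + d0 * bc[0] + d1 * mvec[0] + d2 * nvec[0];
    D[1] = C[1] + d0 * bc[1] + d1 * mvec[1] + d2 * nvec[1];
    D[2] = C[2] + d0 * bc[2] + d1 * mvec[2] + d2 * nvec[2];
  }
}

// [[Rcpp::export]]
NumericMatrix build_chain_cpp(NumericVector dihedrals, int n_carbons,
                              double bond_length, double bond_angle) {
  if (n_carbons < 1) stop("n_carbons must be >= 1");
  std::vector<double> xyz(3 * n_carbons);
  build_chain(dihedrals.begin(), n_carbons, bond_length, bond_angle, xyz.data());
  NumericMatrix out(n_carbons, 3);
  for (int i = 0; i < n_carbons; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = xyz[3 * i + j];
  return out;
}

static double dihedral_of(const double* A, const double* B, const double* C,
                          const double* D) {
  double b1[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
  double b2[3] = {C[0] - B[0], C[1] - B[1], C[2] - B[2]};
  double b3[3] = {D[0] - C[0], D[1] - C[1], D[2] - C[2]};
  double n1[3], n2[3], m1[3];
  cross3(b1, b2, n1);
  cross3(b2, b3, n2);
  double b2u[3] = {b2[0], b2[1], b2[2]};
  unit3(b2u);
  cross3(n1, b2u, m1);
  double x = dot3(n1, n2);
  double y = dot3(m1, n2);
  double phi = std::atan2(y, x) / DEG;
  if (phi <= -180.0) phi += 360.0;
  return phi;  // (-180, 180]
}

// [[Rcpp::export]]
NumericVector measure_dihedrals_cpp(NumericMatrix coords) {
  int n = coords.nrow();
  if (n < 4) return NumericVector(0);
  NumericVector out(n - 3);
  std::vector<double> xyz(3 * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) xyz[3 * i + j] = coords(i, j);
  for (int i = 0; i < n - 3; ++i)
    out[i] = dihedral_of(&xyz[3 * i], &xyz[3 * (i + 1)], &xyz[3 * (i + 2)],
                         &xyz[3 * (i + 3)]);
  return out;
}

// ---------------------------------------------------------------------------
// energy terms
// ---------------------------------------------------------------------------

// cosine-polynomial torsion, sum_k c_k cos^k(phi - 180)
static double torsion_one(double phi_deg, const double* c) {
  double x = std::cos((phi_deg - 180.0) * DEG);
  double e = 0.0, xp = 1.0;
  for (int k = 0; k < 6; ++k) { e += c[k] * xp; xp *= x; }
  return e;
}

// [[Rcpp::export]]
NumericVector torsion_energy_cpp(NumericVector phi_deg, NumericVector coefs) {
  if (coefs.size() != 6) stop("coefs must have length 6");
  NumericVector out(phi_deg.size());
  for (R_xlen_t i = 0; i < phi_deg.size(); ++i)
    out[i] = torsion_one(phi_deg[i], coefs.begin());
  return out;
}

static double lj_energy(const double* xyz, int n, double eps, double sigma,
                        int excl_depth, bool* bad) {
  double e = 0.0;
  *bad = false;
  for (int i = 0; i < n; ++i) {
    for (int j = i + excl_depth + 1; j < n; ++j) {
      double dx = xyz[3 * i] - xyz[3 * j];
      double dy = xyz[3 * i + 1] - xyz[3 * j + 1];
      double dz = xyz[3 * i + 2] - xyz[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 == 0.0) { *bad = true; return R_PosInf; }
      double s2 = sigma * sigma / r2;
      double s6 = s2 * s2 * s2;
      e += 4.0 * eps * (s6 * s6 - s6);
    }
  }
  return e;
}

// [[Rcpp::export]]
double lj_energy_cpp(NumericMatrix coords, double eps, double sigma,
                     int excl_depth) {
  int n = coords.nrow();
  std::vector<double> xyz(3 * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) xyz[3 * i + j] = coords(i, j);
  bool bad;
  double e = lj_energy(xyz.data(), n, eps, sigma, excl_depth, &bad);
  if (bad) stop("coincident interaction sites in Lennard-Jones sum");
  return e;
}

// soft prolate-ellipsoid wall: k * max(0, s - 1)^2 with
// s = sqrt((x^2+y^2)/a^2 + z^2/c^2), axis along z, centred at origin
static double wall_energy(const double* xyz, int n, double a, double c,
                          double k) {
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    double x = xyz[3 * i], y = xyz[3 * i + 1], z = xyz[3 * i + 2];
    double s = std::sqrt((x * x + y * y) / (a * a) + z * z / (c * c));
    if (s > 1.0) e += k * (s - 1.0) * (s - 1.0);
  }
  return e;
}

// [[Rcpp::export]]
double confinement_energy_cpp(NumericMatrix coords, double a, double c,
                              double k) {
  int n = coords.nrow();
  std::vector<double> xyz(3 * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) xyz[3 * i + j] = coords(i, j);
  return wall_energy(xyz.data(), n, a, c, k);
}

// Centre coordinates on their centroid and rotate the principal gyration
// axis onto z (the cavity axis).  Power iteration on the gyration tensor;
// deterministic start vector.
static void align_principal(double* xyz, int n) {
  double cm[3] = {0, 0, 0};
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) cm[j] += xyz[3 * i + j];
  for (int j = 0; j < 3; ++j) cm[j] /= n;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) xyz[3 * i + j] -= cm[j];
  // gyration tensor
  double S[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) S[a][b] += xyz[3 * i + a] * xyz[3 * i + b];
  double v[3] = {1.0, 0.7071067811865476, 0.5773502691896258};
  unit3(v);
  for (int it = 0; it < 60; ++it) {
    double w[3];
    for (int a = 0; a < 3; ++a)
      w[a] = S[a][0] * v[0] + S[a][1] * v[1] + S[a][2] * v[2];
    double nw = norm3(w);
    if (nw < 1e-14) return;  // degenerate (single point); leave as is
    v[0] = w[0] / nw; v[1] = w[1] / nw; v[2] = w[2] / nw;
  }
  // rotate v onto z by Rodrigues' formula
  double zax[3] = {0, 0, 1};
  double axis[3];
  cross3(v, zax, axis);
  double s = norm3(axis);
  double cth = v[2];
  if (s < 1e-12) {
    if (cth > 0) return;  // already aligned
    // anti-aligned: rotate pi about x
    for (int i = 0; i < n; ++i) {
      xyz[3 * i + 1] = -xyz[3 * i + 1];
      xyz[3 * i + 2] = -xyz[3 * i + 2];
    }
    return;
  }
  axis[0] /= s; axis[1] /= s; axis[2] /= s;
  double K[3][3] = {{0, -axis[2], axis[1]},
                    {axis[2], 0, -axis[0]},
                    {-axis[1], axis[0], 0}};
  double Rm[3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) {
      double kk = 0.0;
      for (int q = 0; q < 3; ++q) kk += K[a][q] * K[q][b];
      Rm[a][b] = (a == b ? 1.0 : 0.0) + s * K[a][b] + (1.0 - cth) * kk / (s * s);
    }
  for (int i = 0; i < n; ++i) {
    double p[3] = {xyz[3 * i], xyz[3 * i + 1], xyz[3 * i + 2]};
    for (int a = 0; a < 3; ++a)
      xyz[3 * i + a] = Rm[a][0] * p[0] + Rm[a][1] * p[1] + Rm[a][2] * p[2];
  }
}

// [[Rcpp::export]]
NumericMatrix align_principal_cpp(NumericMatrix coords) {
  int n = coords.nrow();
  std::vector<double> xyz(3 * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) xyz[3 * i + j] = coords(i, j);
  align_principal(xyz.data(), n);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = xyz[3 * i + j];
  return out;
}

struct ChainModel {
  int n;
  double l, theta;
  double tors[6];
  double eps, sigma;
  int excl;
  bool use_lj;
  bool use_wall;
  double wa, wc, wk;
  bool use_bias;
  double bk, br0;
};

// total potential of a torsion-space state; also returns r_ee
static double chain_energy(const ChainModel& M, const double* dih,
                           double* xyz_scratch, double* ree_out) {
  build_chain(dih, M.n, M.l, M.theta, xyz_scratch);
  double e = 0.0;
  for (int i = 0; i < M.n - 3; ++i) e += torsion_one(dih[i], M.tors);
  if (M.use_lj) {
    bool bad;
    e += lj_energy(xyz_scratch, M.n, M.eps, M.sigma, M.excl, &bad);
    if (bad) return R_PosInf;
  }
  double dx = xyz_scratch[3 * (M.n - 1)] - xyz_scratch[0];
  double dy = xyz_scratch[3 * (M.n - 1) + 1] - xyz_scratch[1];
  double dz = xyz_scratch[3 * (M.n - 1) + 2] - xyz_scratch[2];
  double ree = std::sqrt(dx * dx + dy * dy + dz * dz);
  *ree_out = ree;
  if (M.use_wall) {
    align_principal(xyz_scratch, M.n);
    e += wall_energy(xyz_scratch, M.n, M.wa, M.wc, M.wk);
  }
  if (M.use_bias) {
    double d = ree - M.br0;
    e += 0.5 * M.bk * d * d;
  }
  return e;
}

// [[Rcpp::export]]
List chain_energy_cpp(NumericVector dihedrals, int n_carbons,
                      double bond_length, double bond_angle,
                      NumericVector tors_coefs, double eps, double sigma,
                      int excl_depth, bool use_lj, bool use_wall, double wall_a,
                      double wall_c, double wall_k, bool use_bias,
                      double bias_k, double bias_r0) {
  ChainModel M;
  M.n = n_carbons; M.l = bond_length; M.theta = bond_angle;
  for (int k = 0; k < 6; ++k) M.tors[k] = tors_coefs[k];
  M.eps = eps; M.sigma = sigma; M.excl = excl_depth;
  M.use_lj = use_lj; M.use_wall = use_wall;
  M.wa = wall_a; M.wc = wall_c; M.wk = wall_k;
  M.use_bias = use_bias; M.bk = bias_k; M.br0 = bias_r0;
  std::vector<double> xyz(3 * n_carbons);
  double ree;
  double e = chain_energy(M, dihedrals.begin(), xyz.data(), &ree);
  return List::create(_["energy"] = e, _["r_ee"] = ree);
}

// ---------------------------------------------------------------------------
// Metropolis Monte Carlo in torsion space
// ---------------------------------------------------------------------------

// Moves: with probability p_pivot redraw one dihedral uniformly on
// (-180, 180] (a torsion-space pivot: the whole tail rotates), otherwise
// perturb one dihedral by U(-max_step, max_step).  Uses R's RNG so set.seed
// in R controls reproducibility.
// [[Rcpp::export]]
List mc_chain_cpp(NumericVector dih0, int n_carbons, double bond_length,
                  double bond_angle, NumericVector tors_coefs, double eps,
                  double sigma, int excl_depth, bool use_lj, bool use_wall,
                  double wall_a, double wall_c, double wall_k, bool use_bias,
                  double bias_k, double bias_r0, double temperature,
                  int n_steps, double max_step, double p_pivot, int stride,
                  bool save_frames) {
  RNGScope scope;
  ChainModel M;
  M.n = n_carbons; M.l = bond_length; M.theta = bond_angle;
  for (int k = 0; k < 6; ++k) M.tors[k] = tors_coefs[k];
  M.eps = eps; M.sigma = sigma; M.excl = excl_depth;
  M.use_lj = use_lj; M.use_wall = use_wall;
  M.wa = wall_a; M.wc = wall_c; M.wk = wall_k;
  M.use_bias = use_bias; M.bk = bias_k; M.br0 = bias_r0;

  const double kB = 8.31446261815324e-3;  // kJ/(mol K)
  double beta = 1.0 / (kB * temperature);
  int m = n_carbons - 3;
  std::vector<double> dih(dih0.begin(), dih0.end());
  std::vector<double> xyz(3 * n_carbons);
  double ree;
  double e = chain_energy(M, dih.data(), xyz.data(), &ree);

  int n_samples = (stride > 0) ? n_steps / stride : 0;
  NumericVector ree_out(n_samples);
  NumericVector e_out(n_samples);
  NumericMatrix frames;
  if (save_frames) frames = NumericMatrix(n_samples, m);
  long accepted = 0;
  int isamp = 0;
  for (int step = 1; step <= n_steps; ++step) {
    int k = (int)(unif_rand() * m);
    if (k >= m) k = m - 1;
    double old = dih[k];
    if (unif_rand() < p_pivot) {
      double u = unif_rand();
      dih[k] = -180.0 + 360.0 * u;
      if (dih[k] <= -180.0) dih[k] = 180.0;
    } else {
      double d = (2.0 * unif_rand() - 1.0) * max_step;
      double nv = dih[k] + d;
      while (nv > 180.0) nv -= 360.0;
      while (nv <= -180.0) nv += 360.0;
      dih[k] = nv;
    }
    double ree_new;
    double e_new = chain_energy(M, dih.data(), xyz.data(), &ree_new);
    double dE = e_new - e;
    bool accept = (dE <= 0.0) || (unif_rand() < std::exp(-beta * dE));
    if (accept) {
      e = e_new;
      ree = ree_new;
      ++accepted;
    } else {
      dih[k] = old;
    }
    if (stride > 0 && step % stride == 0) {
      ree_out[isamp] = ree;
      e_out[isamp] = e;
      if (save_frames)
        for (int q = 0; q < m; ++q) frames(isamp, q) = dih[q];
      ++isamp;
    }
  }
  List out = List::create(
      _["r_ee"] = ree_out, _["energy"] = e_out,
      _["acceptance"] = (double)accepted / (double)n_steps,
      _["final_dihedrals"] = NumericVector(dih.begin(), dih.end()),
      _["final_energy"] = e);
  if (save_frames) out["frames"] = frames;
  return out;
}

// ---------------------------------------------------------------------------
// rotational-isomeric-state (RIS) chain
// ---------------------------------------------------------------------------

static inline double state_angle(int s) {
  return s == 0 ? 180.0 : (s == 1 ? 60.0 : -60.0);
}

// E = eps_g * (# gauche) + eps_pent * (# adjacent g+g- / g-g+ pairs)
static double ris_energy(const int* st, int m, double eps_g, double eps_pent) {
  double e = 0.0;
  for (int i = 0; i < m; ++i)
    if (st[i] != 0) e += eps_g;
  for (int i = 0; i + 1 < m; ++i)
    if ((st[i] == 1 && st[i + 1] == 2) || (st[i] == 2 && st[i + 1] == 1))
      e += eps_pent;
  return e;
}

// [[Rcpp::export]]
List ris_enumerate_cpp(int m, double bond_length, double bond_angle,
                       double eps_g, double eps_pent) {
  if (m < 1 || m > 12) stop("m must be in 1..12 for full enumeration");
  long nstates = 1;
  for (int i = 0; i < m; ++i) nstates *= 3;
  int n = m + 3;
  NumericVector energy(nstates), ree(nstates);
  IntegerVector ngauche(nstates);
  std::vector<int> st(m, 0);
  std::vector<double> dih(m), xyz(3 * n);
  for (long s = 0; s < nstates; ++s) {
    long v = s;
    int ng = 0;
    for (int i = 0; i < m; ++i) {
      st[i] = v % 3;
      v /= 3;
      dih[i] = state_angle(st[i]);
      if (st[i] != 0) ++ng;
    }
    energy[s] = ris_energy(st.data(), m, eps_g, eps_pent);
    build_chain(dih.data(), n, bond_length, bond_angle, xyz.data());
    double dx = xyz[3 * (n - 1)] - xyz[0];
    double dy = xyz[3 * (n - 1) + 1] - xyz[1];
    double dz = xyz[3 * (n - 1) + 2] - xyz[2];
    ree[s] = std::sqrt(dx * dx + dy * dy + dz * dz);
    ngauche[s] = ng;
  }
  return List::create(_["energy"] = energy, _["r_ee"] = ree,
                      _["n_gauche"] = ngauche);
}

static double ris_ree(const int* st, int m, double l, double theta,
                      double* dih, double* xyz) {
  int n = m + 3;
  for (int i = 0; i < m; ++i) dih[i] = state_angle(st[i]);
  build_chain(dih, n, l, theta, xyz);
  double dx = xyz[3 * (n - 1)] - xyz[0];
  double dy = xyz[3 * (n - 1) + 1] - xyz[1];
  double dz = xyz[3 * (n - 1) + 2] - xyz[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Discrete-state Metropolis sampler on the RIS chain, with an optional
// harmonic umbrella bias on r_ee.  Proposal: pick a dihedral, propose one
// of the two other states uniformly.
// [[Rcpp::export]]
List ris_mc_cpp(IntegerVector state0, double bond_length, double bond_angle,
                double eps_g, double eps_pent, double temperature, int n_steps,
                int stride, bool save_frames, bool use_bias = false,
                double bias_k = 0.0, double bias_r0 = 0.0) {
  RNGScope scope;
  const double kB = 8.31446261815324e-3;
  double beta = 1.0 / (kB * temperature);
  int m = state0.size();
  int n = m + 3;
  std::vector<int> st(state0.begin(), state0.end());
  std::vector<double> dih(m), xyz(3 * n);
  int n_samples = (stride > 0) ? n_steps / stride : 0;
  NumericVector ree_out(n_samples);
  IntegerVector ng_out(n_samples);
  IntegerMatrix frames;
  if (save_frames) frames = IntegerMatrix(n_samples, m);
  long accepted = 0;
  int isamp = 0;
  double ree = ris_ree(st.data(), m, bond_length, bond_angle, dih.data(),
                       xyz.data());
  double e = ris_energy(st.data(), m, eps_g, eps_pent);
  if (use_bias) e += 0.5 * bias_k * (ree - bias_r0) * (ree - bias_r0);
  for (int step = 1; step <= n_steps; ++step) {
    int k = (int)(unif_rand() * m);
    if (k >= m) k = m - 1;
    int old = st[k];
    int shift = 1 + (int)(unif_rand() * 2);
    if (shift > 2) shift = 2;
    st[k] = (old + shift) % 3;
    double e_new = ris_energy(st.data(), m, eps_g, eps_pent);
    double ree_new = ree;
    if (use_bias) {
      ree_new = ris_ree(st.data(), m, bond_length, bond_angle, dih.data(),
                        xyz.data());
      e_new += 0.5 * bias_k * (ree_new - bias_r0) * (ree_new - bias_r0);
    }
    double dE = e_new - e;
    bool accept = (dE <= 0.0) || (unif_rand() < std::exp(-beta * dE));
    if (accept) {
      e = e_new;
      ree = ree_new;
      ++accepted;
    } else {
      st[k] = old;
    }
    if (stride > 0 && step % stride == 0) {
      int ng = 0;
      for (int i = 0; i < m; ++i)
        if (st[i] != 0) ++ng;
      if (!use_bias)
        ree = ris_ree(st.data(), m, bond_length, bond_angle, dih.data(),
                      xyz.data());
      ree_out[isamp] = ree;
      ng_out[isamp] = ng;
      if (save_frames)
        for (int q = 0; q < m; ++q) frames(isamp, q) = st[q];
      ++isamp;
    }
  }
  List out = List::create(
      _["r_ee"] = ree_out, _["n_gauche"] = ng_out,
      _["acceptance"] = (double)accepted / (double)n_steps,
      _["final_state"] = IntegerVector(st.begin(), st.end()));
  if (save_frames) out["frames"] = frames;
  return out;
}

// Monte Carlo union-of-spheres volume.  Points are drawn in the bounding
// box; returns hit count so R can form the estimate and its standard error.
// [[Rcpp::export]]
long mc_volume_hits_cpp(NumericMatrix centers, NumericVector radii,
                        NumericVector lo, NumericVector hi, int n_points) {
  RNGScope scope;
  int na = centers.nrow();
  std::vector<double> cx(na), cy(na), cz(na), r2(na);
  for (int i = 0; i < na; ++i) {
    cx[i] = centers(i, 0); cy[i] = centers(i, 1); cz[i] = centers(i, 2);
    r2[i] = radii[i] * radii[i];
  }
  double lx = lo[0], ly = lo[1], lz = lo[2];
  double wx = hi[0] - lo[0], wy = hi[1] - lo[1], wz = hi[2] - lo[2];
  long hits = 0;
  for (int p = 0; p < n_points; ++p) {
    double x = lx + wx * unif_rand();
    double y = ly + wy * unif_rand();
    double z = lz + wz * unif_rand();
    for (int i = 0; i < na; ++i) {
      double dx = x - cx[i], dy = y - cy[i], dz = z - cz[i];
      if (dx * dx + dy * dy + dz * dz <= r2[i]) { ++hits; break; }
    }
  }
  return hits;
}
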