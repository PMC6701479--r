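#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <functional>
using namespace Rcpp;

static inline int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Union-find connectivity of the implicit spring graph (all pairs within
// cutoff). Returns the number of connected components.
// [[Rcpp::export]]
int cpp_n_components(NumericMatrix xyz, double cutoff) {
  const int n = xyz.nrow();
  const double c2 = cutoff * cutoff;
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = xyz(i, 0); y[i] = xyz(i, 1); z[i] = xyz(i, 2);
  }
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i], zi = z[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
      if (dx * dx + dy * dy + dz * dz <= c2) {
        const int a = uf_find(parent, i), b = uf_find(parent, j);
        if (a != b) parent[a] = b;
      }
    }
  }
  int comp = 0;
  for (int i = 0; i < n; ++i)
    if (uf_find(parent, i) == i) ++comp;
  return comp;
}

// Pair-distance histogram Debye evaluation. Binning pair distances (bin
// width `bin`, default 0.5 A upstream) turns the O(N^2 * nq) Debye double
// sum into O(N^2 + nbins * nq); the relative error is O((q*bin)^2/24),
// negligible below q = 1/A for sub-Angstrom bins.
// fixed-size fast path: h must have nb slots; the top slot absorbs any
// overflow (callers size nb beyond the model's maximum dimension).
// Returns the largest occupied bin index.
static int pair_hist_fixed(const std::vector<double>& x,
                           const std::vector<double>& y,
                           const std::vector<double>& z,
                           double inv_bin, double* h, int nb) {
  const int n = (int)x.size();
  int bmax = 0;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i], zi = z[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      int b = (int)(d * inv_bin);
      if (b >= nb) b = nb - 1;
      if (b > bmax) bmax = b;
      h[b] += 1.0;
    }
  }
  return bmax;
}

static int pair_hist(const std::vector<double>& x,
                     const std::vector<double>& y,
                     const std::vector<double>& z,
                     double bin, std::vector<double>& h) {
  const int n = (int)x.size();
  // bound the histogram by the bounding-box diagonal
  double lo[3] = {x[0], y[0], z[0]}, hi[3] = {x[0], y[0], z[0]};
  for (int i = 1; i < n; ++i) {
    if (x[i] < lo[0]) lo[0] = x[i];
    if (x[i] > hi[0]) hi[0] = x[i];
    if (y[i] < lo[1]) lo[1] = y[i];
    if (y[i] > hi[1]) hi[1] = y[i];
    if (z[i] < lo[2]) lo[2] = z[i];
    if (z[i] > hi[2]) hi[2] = z[i];
  }
  const double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                                (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                                (hi[2] - lo[2]) * (hi[2] - lo[2]));
  const int nb = (int)(diag / bin) + 2;
  h.assign(nb, 0.0);
  return pair_hist_fixed(x, y, z, 1.0 / bin, h.data(), nb);
}

static bool is_uniform(const NumericVector& q) {
  const int nq = q.size();
  if (nq < 3) return false;
  const double d = q[1] - q[0];
  for (int k = 2; k < nq; ++k)
    if (std::fabs(q[k] - q[k - 1] - d) > 1e-9 * d) return false;
  return true;
}

static void hist_profile(const double* h, int bmax, int n, double bin,
                         const NumericVector& q, double w,
                         std::vector<double>& I) {
  const int nq = q.size();
  std::fill(I.begin(), I.end(), 0.0);
  std::vector<double> invq(nq);
  for (int k = 0; k < nq; ++k) invq[k] = 1.0 / q[k];
  if (is_uniform(q)) {
    // sine recurrence over the uniform q grid: sin(r(q0 + k dq)) built
    // from one sin/cos pair per histogram bin; multiplication-only inner
    // loop
    const double q0 = q[0], dq = q[1] - q[0];
    for (int b = 0; b <= bmax; ++b) {
      if (h[b] == 0.0) continue;
      const double r = (b + 0.5) * bin;
      const double a = h[b] / r;
      double s = std::sin(q0 * r), c = std::cos(q0 * r);
      const double sd = std::sin(dq * r), cd = std::cos(dq * r);
      for (int k = 0; k < nq; ++k) {
        I[k] += a * s * invq[k];
        const double s2 = s * cd + c * sd;
        c = c * cd - s * sd;
        s = s2;
      }
    }
  } else {
    for (int b = 0; b <= bmax; ++b) {
      if (h[b] == 0.0) continue;
      const double r = (b + 0.5) * bin;
      for (int k = 0; k < nq; ++k) {
        const double x = q[k] * r;
        I[k] += h[b] * (x < 1e-8 ? 1.0 : std::sin(x) / x);
      }
    }
  }
  for (int k = 0; k < nq; ++k) {
    const double ff = std::exp(-q[k] * q[k] * w * w); // form factor squared
    I[k] = ff * ((double)n + 2.0 * I[k]);
  }
}

// [[Rcpp::export]]
NumericVector cpp_debye(NumericMatrix xyz, NumericVector q, double w,
                        double bin) {
  const int n = xyz.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = xyz(i, 0); y[i] = xyz(i, 1); z[i] = xyz(i, 2);
  }
  std::vector<double> h;
  const int bmax = pair_hist(x, y, z, bin, h);
  std::vector<double> I(q.size());
  hist_profile(h.data(), bmax, n, bin, q, w, I);
  return wrap(I);
}

// [[Rcpp::export]]
NumericVector cpp_pair_hist(NumericMatrix xyz, double bin, double rmax) {
  const int n = xyz.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = xyz(i, 0); y[i] = xyz(i, 1); z[i] = xyz(i, 2);
  }
  std::vector<double> h((size_t)(rmax / bin) + 2, 0.0);
  pair_hist_fixed(x, y, z, 1.0 / bin, h.data(), (int)h.size());
  return wrap(h);
}

// [[Rcpp::export]]
double cpp_max_dist(NumericMatrix xyz) {
  const int n = xyz.nrow();
  double m2 = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = xyz(i, 0) - xyz(j, 0);
      const double dy = xyz(i, 1) - xyz(j, 1);
      const double dz = xyz(i, 2) - xyz(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > m2) m2 = d2;
    }
  return std::sqrt(m2);
}

// All bead pairs within `cutoff`, with current distances as rest lengths.
// [[Rcpp::export]]
List cpp_springs(NumericMatrix xyz, double cutoff) {
  const int n = xyz.nrow();
  const double c2 = cutoff * cutoff;
  std::vector<int> vi, vj;
  std::vector<double> vd;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = xyz(i, 0) - xyz(j, 0);
      const double dy = xyz(i, 1) - xyz(j, 1);
      const double dz = xyz(i, 2) - xyz(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= c2) {
        vi.push_back(i + 1); vj.push_back(j + 1);
        vd.push_back(std::sqrt(d2));
      }
    }
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj),
                      _["d0"] = wrap(vd));
}

// RTB (rotations-translations of blocks) projected Hessian and mass matrix
// of a uniform-spring elastic network. Block generators are ordered
// (tx, ty, tz, rx, ry, rz) about the block centre of mass; masses are
// per-bead. Returns dense 6B x 6B H and M.
// [[Rcpp::export]]
List cpp_rtb_hessian(NumericMatrix xyz, IntegerVector si, IntegerVector sj,
                     NumericVector mass, IntegerVector block, int nblock,
                     double k) {
  const int nb6 = 6 * nblock;
  NumericMatrix H(nb6, nb6), M(nb6, nb6);
  NumericMatrix com(nblock, 3);
  std::vector<double> bm(nblock, 0.0);
  const int n = xyz.nrow();
  for (int i = 0; i < n; ++i) {
    const int b = block[i] - 1;
    bm[b] += mass[i];
    for (int d = 0; d < 3; ++d) com(b, d) += mass[i] * xyz(i, d);
  }
  for (int b = 0; b < nblock; ++b)
    for (int d = 0; d < 3; ++d) com(b, d) /= bm[b];

  // mass matrix: translations decouple from rotations about the COM
  for (int i = 0; i < n; ++i) {
    const int b = block[i] - 1;
    const double rx = xyz(i, 0) - com(b, 0);
    const double ry = xyz(i, 1) - com(b, 1);
    const double rz = xyz(i, 2) - com(b, 2);
    const double m = mass[i];
    const int o = 6 * b;
    for (int d = 0; d < 3; ++d) M(o + d, o + d) += m;
    // inertia: m * (|r|^2 I - r r^T)
    const double r2 = rx * rx + ry * ry + rz * rz;
    M(o + 3, o + 3) += m * (r2 - rx * rx);
    M(o + 4, o + 4) += m * (r2 - ry * ry);
    M(o + 5, o + 5) += m * (r2 - rz * rz);
    M(o + 3, o + 4) += -m * rx * ry; M(o + 4, o + 3) += -m * rx * ry;
    M(o + 3, o + 5) += -m * rx * rz; M(o + 5, o + 3) += -m * rx * rz;
    M(o + 4, o + 5) += -m * ry * rz; M(o + 5, o + 4) += -m * ry * rz;
  }

  // Hessian: for a spring (i,j) with unit vector u, bead-space blocks are
  // +/- k u u^T; project through G_i = [I | -skew(r_i - c_b)].
  const int ns = si.size();
  for (int s = 0; s < ns; ++s) {
    const int i = si[s] - 1, j = sj[s] - 1;
    const int a = block[i] - 1, b = block[j] - 1;
    if (a == b) continue; // intra-block springs contribute exactly zero
    double u[3] = {xyz(i, 0) - xyz(j, 0), xyz(i, 1) - xyz(j, 1),
                   xyz(i, 2) - xyz(j, 2)};
    const double d = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    if (d < 1e-12) continue;
    for (int d3 = 0; d3 < 3; ++d3) u[d3] /= d;
    // generator rows: displacement of bead under unit DOF of its block
    // G (3 x 6): [I3 | -skew(rr)] where rr = r - c
    double Ga[3][6], Gb[3][6];
    {
      const double rx = xyz(i, 0) - com(a, 0), ry = xyz(i, 1) - com(a, 1),
                   rz = xyz(i, 2) - com(a, 2);
      double g[3][6] = {{1, 0, 0, 0, rz, -ry},
                        {0, 1, 0, -rz, 0, rx},
                        {0, 0, 1, ry, -rx, 0}};
      for (int r = 0; r < 3; ++r) for (int c = 0; c < 6; ++c) Ga[r][c] = g[r][c];
    }
    {
      const double rx = xyz(j, 0) - com(b, 0), ry = xyz(j, 1) - com(b, 1),
                   rz = xyz(j, 2) - com(b, 2);
      double g[3][6] = {{1, 0, 0, 0, rz, -ry},
                        {0, 1, 0, -rz, 0, rx},
                        {0, 0, 1, ry, -rx, 0}};
      for (int r = 0; r < 3; ++r) for (int c = 0; c < 6; ++c) Gb[r][c] = g[r][c];
    }
    // wa = u^T Ga (1 x 6), wb = u^T Gb
    double wa[6], wb[6];
    for (int c = 0; c < 6; ++c) {
      wa[c] = u[0] * Ga[0][c] + u[1] * Ga[1][c] + u[2] * Ga[2][c];
      wb[c] = u[0] * Gb[0][c] + u[1] * Gb[1][c] + u[2] * Gb[2][c];
    }
    const int oa = 6 * a, ob = 6 * b;
    for (int r = 0; r < 6; ++r)
      for (int c = 0; c < 6; ++c) {
        H(oa + r, oa + c) += k * wa[r] * wa[c];
        H(ob + r, ob + c) += k * wb[r] * wb[c];
        H(oa + r, ob + c) -= k * wa[r] * wb[c];
        H(ob + r, oa + c) -= k * wb[r] * wa[c];
      }
  }
  return List::create(_["H"] = H, _["M"] = M, _["com"] = com,
                      _["block_mass"] = wrap(bm));
}

// Finite screw motion of one block given its instantaneous mode velocity
// (t, omega) at reference point c and amplitude a: rotation by a*|omega|
// about the mode axis through the screw centre plus pitch translation.
static void screw_transform(const double* tv, const double* om, double a,
                            const double* c, double R[3][3], double T[3]) {
  const double w2 = om[0] * om[0] + om[1] * om[1] + om[2] * om[2];
  const double wn = std::sqrt(w2);
  if (wn < 1e-12) { // pure translation
    R[0][0] = R[1][1] = R[2][2] = 1.0;
    R[0][1] = R[0][2] = R[1][0] = R[1][2] = R[2][0] = R[2][1] = 0.0;
    T[0] = a * tv[0]; T[1] = a * tv[1]; T[2] = a * tv[2];
    return;
  }
  const double n[3] = {om[0] / wn, om[1] / wn, om[2] / wn};
  const double tdotn = tv[0] * n[0] + tv[1] * n[1] + tv[2] * n[2];
  const double tp[3] = {tv[0] - tdotn * n[0], tv[1] - tdotn * n[1],
                        tv[2] - tdotn * n[2]};
  // screw centre p = c + (omega x t_perp) / |omega|^2
  const double p[3] = {
      c[0] + (om[1] * tp[2] - om[2] * tp[1]) / w2,
      c[1] + (om[2] * tp[0] - om[0] * tp[2]) / w2,
      c[2] + (om[0] * tp[1] - om[1] * tp[0]) / w2};
  const double th = a * wn;
  const double ct = std::cos(th), st = std::sin(th), vt = 1.0 - ct;
  R[0][0] = ct + n[0] * n[0] * vt;
  R[0][1] = n[0] * n[1] * vt - n[2] * st;
  R[0][2] = n[0] * n[2] * vt + n[1] * st;
  R[1][0] = n[1] * n[0] * vt + n[2] * st;
  R[1][1] = ct + n[1] * n[1] * vt;
  R[1][2] = n[1] * n[2] * vt - n[0] * st;
  R[2][0] = n[2] * n[0] * vt - n[1] * st;
  R[2][1] = n[2] * n[1] * vt + n[0] * st;
  R[2][2] = ct + n[2] * n[2] * vt;
  // x' = R (x - p) + p + a * (t.n) n
  for (int d = 0; d < 3; ++d) {
    T[d] = p[d] + a * tdotn * n[d] -
           (R[d][0] * p[0] + R[d][1] * p[1] + R[d][2] * p[2]);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_apply_screw(NumericMatrix xyz, IntegerVector block,
                              NumericMatrix bcom, NumericMatrix screw6,
                              double amplitude) {
  // screw6: nblock x 6 (t, omega) per block for one mode
  const int n = xyz.nrow(), nb = bcom.nrow();
  NumericMatrix out(n, 3);
  std::vector<double> Rm(nb * 9), Tm(nb * 3);
  for (int b = 0; b < nb; ++b) {
    double tv[3] = {screw6(b, 0), screw6(b, 1), screw6(b, 2)};
    double om[3] = {screw6(b, 3), screw6(b, 4), screw6(b, 5)};
    double c[3] = {bcom(b, 0), bcom(b, 1), bcom(b, 2)};
    double R[3][3], T[3];
    screw_transform(tv, om, amplitude, c, R, T);
    for (int r = 0; r < 3; ++r) {
      for (int cc = 0; cc < 3; ++cc) Rm[b * 9 + 3 * r + cc] = R[r][cc];
      Tm[b * 3 + r] = T[r];
    }
  }
  for (int i = 0; i < n; ++i) {
    const int b = block[i] - 1;
    const double* R = &Rm[b * 9];
    const double* T = &Tm[b * 3];
    for (int d = 0; d < 3; ++d)
      out(i, d) = R[3 * d] * xyz(i, 0) + R[3 * d + 1] * xyz(i, 1) +
                  R[3 * d + 2] * xyz(i, 2) + T[d];
  }
  return out;
}

// chi^2 with closed-form scale c and offset b minimising
// sum(((c*Icalc + b - Iexp)/sigma)^2), reduced by N - 2.
static double chi2_scale_offset(const std::vector<double>& Ic,
                                const NumericVector& Ie,
                                const NumericVector& sg) {
  const int n = Ic.size();
  double s11 = 0, s1x = 0, s1y = 0, sxx = 0, sxy = 0;
  for (int k = 0; k < n; ++k) {
    const double w = 1.0 / (sg[k] * sg[k]);
    s11 += w; s1x += w * Ic[k]; s1y += w * Ie[k];
    sxx += w * Ic[k] * Ic[k]; sxy += w * Ic[k] * Ie[k];
  }
  const double det = sxx * s11 - s1x * s1x;
  double c = 1.0, b = 0.0;
  if (std::fabs(det) > 1e-300) {
    c = (sxy * s11 - s1x * s1y) / det;
    b = (sxx * s1y - s1x * sxy) / det;
  }
  double chi2 = 0.0;
  for (int k = 0; k < n; ++k) {
    const double r = (c * Ic[k] + b - Ie[k]) / sg[k];
    chi2 += r * r;
  }
  return chi2 / (double)(n - 2);
}

// Evaluate the chi^2 of every trial deformation (mode x signed amplitude)
// against an experimental profile, on a stride-subsampled bead set.
// screws: 6 x nblock x nmodes (column-major as passed from R array).
// [[Rcpp::export]]
NumericMatrix cpp_sweep_trials(NumericMatrix xyz, IntegerVector block,
                               NumericMatrix bcom, NumericVector screws,
                               int nmodes, NumericMatrix amps,
                               NumericVector q, double w, double bin,
                               NumericVector Iexp, NumericVector sigma,
                               int stride) {
  const int n = xyz.nrow(), nb = bcom.nrow(), namp = amps.ncol();
  const int nq = q.size();
  std::vector<int> sub;
  for (int i = 0; i < n; i += stride) sub.push_back(i);
  const int ns = sub.size();
  std::vector<double> x(ns), y(ns), z(ns);
  NumericMatrix chi2(nmodes, namp);
  std::vector<double> Ic(nq);
  // fixed histogram sized from the current bounding box with headroom for
  // trial motion; rare overflow clamps into the top bin
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) lo[d] = hi[d] = xyz(0, d);
  for (int i = 1; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      if (xyz(i, d) < lo[d]) lo[d] = xyz(i, d);
      if (xyz(i, d) > hi[d]) hi[d] = xyz(i, d);
    }
  double diag = 0.0;
  for (int d = 0; d < 3; ++d) diag += (hi[d] - lo[d]) * (hi[d] - lo[d]);
  diag = std::sqrt(diag);
  const int nhb = (int)(1.5 * diag / bin) + 2;
  const double inv_bin = 1.0 / bin;
  std::vector<double> h(nhb);
  for (int m = 0; m < nmodes; ++m) {
    const double* sc = &screws[(size_t)m * 6 * nb];
    for (int a = 0; a < namp; ++a) {
      const double amp = amps(m, a);
      // per-block transforms
      std::vector<double> Rm(nb * 9), Tm(nb * 3);
      for (int b = 0; b < nb; ++b) {
        const double tv[3] = {sc[6 * b], sc[6 * b + 1], sc[6 * b + 2]};
        const double om[3] = {sc[6 * b + 3], sc[6 * b + 4], sc[6 * b + 5]};
        const double c[3] = {bcom(b, 0), bcom(b, 1), bcom(b, 2)};
        double R[3][3], T[3];
        screw_transform(tv, om, amp, c, R, T);
        for (int r = 0; r < 3; ++r) {
          for (int cc = 0; cc < 3; ++cc) Rm[b * 9 + 3 * r + cc] = R[r][cc];
          Tm[b * 3 + r] = T[r];
        }
      }
      for (int s = 0; s < ns; ++s) {
        const int i = sub[s];
        const int b = block[i] - 1;
        const double* R = &Rm[b * 9];
        const double* T = &Tm[b * 3];
        const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
        x[s] = R[0] * xi + R[1] * yi + R[2] * zi + T[0];
        y[s] = R[3] * xi + R[4] * yi + R[5] * zi + T[1];
        z[s] = R[6] * xi + R[7] * yi + R[8] * zi + T[2];
      }
      std::fill(h.begin(), h.end(), 0.0);
      const int bmax = pair_hist_fixed(x, y, z, inv_bin, h.data(), nhb);
      hist_profile(h.data(), bmax, ns, bin, q, w, Ic);
      chi2(m, a) = chi2_scale_offset(Ic, Iexp, sigma);
    }
  }
  return chi2;
}

// Steepest-descent restraint minimisation restoring bond lengths and
// pseudo-angles toward reference values. Beads with block id 0 move freely;
// beads sharing a positive block id move only as a rigid body.
// [[Rcpp::export]]
List cpp_regularize(NumericMatrix xyz_in, IntegerVector bi, IntegerVector bj,
                    NumericVector bd0, IntegerVector ai, IntegerVector aj,
                    IntegerVector ak, NumericVector ac0, IntegerVector block,
                    int nblock, double kb, double ka, double gamma,
                    double tol, int max_steps) {
  NumericMatrix xyz = clone(xyz_in);
  const int n = xyz.nrow();
  const int nbond = bi.size(), nang = ai.size();
  std::vector<double> fx(n), fy(n), fz(n);
  double maxdev = 0.0;
  double plateau_ref = 1e300;
  int step = 0;
  for (step = 0; step < max_steps; ++step) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    maxdev = 0.0;
    for (int s = 0; s < nbond; ++s) {
      const int i = bi[s] - 1, j = bj[s] - 1;
      double u[3] = {xyz(i, 0) - xyz(j, 0), xyz(i, 1) - xyz(j, 1),
                     xyz(i, 2) - xyz(j, 2)};
      const double d = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
      const double dev = d - bd0[s];
      if (std::fabs(dev) > maxdev) maxdev = std::fabs(dev);
      if (d < 1e-12) continue;
      const double f = -2.0 * kb * dev / d; // force on i along u
      fx[i] += f * u[0]; fy[i] += f * u[1]; fz[i] += f * u[2];
      fx[j] -= f * u[0]; fy[j] -= f * u[1]; fz[j] -= f * u[2];
    }
    if (maxdev < tol && step > 0) break;
    if (step % 40 == 0) {
      // descent has plateaued: further steps will not restore the bonds
      if (maxdev > 0.98 * plateau_ref) break;
      plateau_ref = maxdev;
    }
    for (int s = 0; s < nang; ++s) {
      const int i = ai[s] - 1, j = aj[s] - 1, k = ak[s] - 1;
      double u[3] = {xyz(i, 0) - xyz(j, 0), xyz(i, 1) - xyz(j, 1),
                     xyz(i, 2) - xyz(j, 2)};
      double v[3] = {xyz(k, 0) - xyz(j, 0), xyz(k, 1) - xyz(j, 1),
                     xyz(k, 2) - xyz(j, 2)};
      const double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
      const double nv = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
      if (nu < 1e-12 || nv < 1e-12) continue;
      const double c =
          (u[0] * v[0] + u[1] * v[1] + u[2] * v[2]) / (nu * nv);
      const double dE = 2.0 * ka * (c - ac0[s]);
      for (int d = 0; d < 3; ++d) {
        const double gi = (v[d] / (nu * nv) - c * u[d] / (nu * nu));
        const double gk = (u[d] / (nu * nv) - c * v[d] / (nv * nv));
        const double Fi = -dE * gi, Fk = -dE * gk;
        if (d == 0) { fx[i] += Fi; fx[k] += Fk; fx[j] -= Fi + Fk; }
        else if (d == 1) { fy[i] += Fi; fy[k] += Fk; fy[j] -= Fi + Fk; }
        else { fz[i] += Fi; fz[k] += Fk; fz[j] -= Fi + Fk; }
      }
    }
    // block aggregation: rigid bodies translate with net force and rotate
    // with net torque about their COM
    if (nblock > 0) {
      std::vector<double> bfx(nblock, 0.0), bfy(nblock, 0.0),
          bfz(nblock, 0.0), btx(nblock, 0.0), bty(nblock, 0.0),
          btz(nblock, 0.0), bcx(nblock, 0.0), bcy(nblock, 0.0),
          bcz(nblock, 0.0), bi2(nblock, 0.0);
      std::vector<int> bn(nblock, 0);
      for (int i = 0; i < n; ++i) {
        const int b = block[i];
        if (b <= 0) continue;
        bcx[b - 1] += xyz(i, 0); bcy[b - 1] += xyz(i, 1);
        bcz[b - 1] += xyz(i, 2); bn[b - 1]++;
      }
      for (int b = 0; b < nblock; ++b)
        if (bn[b] > 0) { bcx[b] /= bn[b]; bcy[b] /= bn[b]; bcz[b] /= bn[b]; }
      for (int i = 0; i < n; ++i) {
        const int b = block[i];
        if (b <= 0) continue;
        const double rx = xyz(i, 0) - bcx[b - 1];
        const double ry = xyz(i, 1) - bcy[b - 1];
        const double rz = xyz(i, 2) - bcz[b - 1];
        bfx[b - 1] += fx[i]; bfy[b - 1] += fy[i]; bfz[b - 1] += fz[i];
        btx[b - 1] += ry * fz[i] - rz * fy[i];
        bty[b - 1] += rz * fx[i] - rx * fz[i];
        btz[b - 1] += rx * fy[i] - ry * fx[i];
        bi2[b - 1] += rx * rx + ry * ry + rz * rz;
      }
      // displace free beads; move rigid blocks as bodies
      for (int i = 0; i < n; ++i) {
        const int b = block[i];
        if (b > 0) continue;
        double dx = gamma * fx[i], dy = gamma * fy[i], dz = gamma * fz[i];
        const double dn = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (dn > 0.5) { dx *= 0.5 / dn; dy *= 0.5 / dn; dz *= 0.5 / dn; }
        xyz(i, 0) += dx; xyz(i, 1) += dy; xyz(i, 2) += dz;
      }
      for (int b = 0; b < nblock; ++b) {
        if (bn[b] == 0) continue;
        double dx = gamma * bfx[b] / bn[b], dy = gamma * bfy[b] / bn[b],
               dz = gamma * bfz[b] / bn[b];
        const double dn = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (dn > 0.5) { dx *= 0.5 / dn; dy *= 0.5 / dn; dz *= 0.5 / dn; }
        double wx = 0, wy = 0, wz = 0;
        if (bi2[b] > 1e-12) {
          wx = gamma * btx[b] / bi2[b];
          wy = gamma * bty[b] / bi2[b];
          wz = gamma * btz[b] / bi2[b];
          const double wn = std::sqrt(wx * wx + wy * wy + wz * wz);
          const double wmax = 0.05; // rad per step cap
          if (wn > wmax) { wx *= wmax / wn; wy *= wmax / wn; wz *= wmax / wn; }
        }
        const double wn = std::sqrt(wx * wx + wy * wy + wz * wz);
        double R[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
        if (wn > 1e-12) {
          const double nx = wx / wn, ny = wy / wn, nz = wz / wn;
          const double ct = std::cos(wn), st = std::sin(wn), vt = 1 - ct;
          R[0][0] = ct + nx * nx * vt; R[0][1] = nx * ny * vt - nz * st;
          R[0][2] = nx * nz * vt + ny * st;
          R[1][0] = ny * nx * vt + nz * st; R[1][1] = ct + ny * ny * vt;
          R[1][2] = ny * nz * vt - nx * st;
          R[2][0] = nz * nx * vt - ny * st; R[2][1] = nz * ny * vt + nx * st;
          R[2][2] = ct + nz * nz * vt;
        }
        for (int i = 0; i < n; ++i) {
          if (block[i] != b + 1) continue;
          const double rx = xyz(i, 0) - bcx[b];
          const double ry = xyz(i, 1) - bcy[b];
          const double rz = xyz(i, 2) - bcz[b];
          xyz(i, 0) = bcx[b] + R[0][0] * rx + R[0][1] * ry + R[0][2] * rz + dx;
          xyz(i, 1) = bcy[b] + R[1][0] * rx + R[1][1] * ry + R[1][2] * rz + dy;
          xyz(i, 2) = bcz[b] + R[2][0] * rx + R[2][1] * ry + R[2][2] * rz + dz;
        }
      }
    } else {
      for (int i = 0; i < n; ++i) {
        double dx = gamma * fx[i], dy = gamma * fy[i], dz = gamma * fz[i];
        const double dn = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (dn > 0.5) { dx *= 0.5 / dn; dy *= 0.5 / dn; dz *= 0.5 / dn; }
        xyz(i, 0) += dx; xyz(i, 1) += dy; xyz(i, 2) += dz;
      }
    }
  }
  return List::create(_["xyz"] = xyz, _["max_bond_dev"] = maxdev,
                      _["steps"] = step);
}
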