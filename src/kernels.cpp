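#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// sin(x)/x with a series branch near 0 for numerical stability
static inline double sinc(double x) {
  if (x < 1e-4) return 1.0 - x * x / 6.0;
  return std::sin(x) / x;
}

static inline double sq(double x) { return x * x; }

// minimum-image displacement component for a cubic box of edge L (L <= 0: none)
static inline double mimg(double d, double L) {
  if (L > 0.0) d -= L * std::round(d / L);
  return d;
}

static inline double pair_dist2(const double* xyz, int nb, int u, int v,
                                double L) {
  double dx = mimg(xyz[u] - xyz[v], L);
  double dy = mimg(xyz[u + nb] - xyz[v + nb], L);
  double dz = mimg(xyz[u + 2 * nb] - xyz[v + 2 * nb], L);
  return dx * dx + dy * dy + dz * dz;
}

// Minimum distance between the beads of two residues; early exit below `stop2`.
static double res_min_dist2(const double* xyz, int nb, int s1, int c1, int s2,
                            int c2, double L, double stop2) {
  double best = R_PosInf;
  for (int u = s1; u < s1 + c1; ++u) {
    for (int v = s2; v < s2 + c2; ++v) {
      double d2 = pair_dist2(xyz, nb, u, v, L);
      if (d2 < best) {
        best = d2;
        if (best < stop2) return best;
      }
    }
  }
  return best;
}

// Mean inter-residue distance R(s) vs sequence separation s over an ensemble.
// coords: [nb x 3 x nf]; beadStart/beadCount/backbone: per selected residue
// (0-based global bead indices); seq: 1-based sequence positions (for s).
// rms: accumulate squared distances and return sqrt of the mean.
// [[Rcpp::export]]
List cpp_scaling_curve(NumericVector coords, int nb, int nf,
                       IntegerVector beadStart, IntegerVector beadCount,
                       IntegerVector backbone, IntegerVector seq,
                       bool useBackbone, bool rms) {
  int nres = beadStart.size();
  int smax = 0;
  for (int i = 0; i < nres; ++i)
    for (int j = i + 1; j < nres; ++j)
      smax = std::max(smax, std::abs(seq[j] - seq[i]));
  std::vector<double> acc(smax + 1, 0.0);
  std::vector<double> cnt(smax + 1, 0.0);
  const double* base = REAL(coords);
  for (int f = 0; f < nf; ++f) {
    const double* xyz = base + (size_t)f * nb * 3;
    for (int i = 0; i < nres; ++i) {
      for (int j = i + 1; j < nres; ++j) {
        int s = std::abs(seq[j] - seq[i]);
        double d2;
        if (useBackbone) {
          d2 = pair_dist2(xyz, nb, backbone[i], backbone[j], -1.0);
        } else {
          d2 = res_min_dist2(xyz, nb, beadStart[i], beadCount[i], beadStart[j],
                             beadCount[j], -1.0, -1.0);
        }
        acc[s] += rms ? d2 : std::sqrt(d2);
        cnt[s] += 1.0;
      }
    }
  }
  std::vector<double> sv, rv;
  for (int s = 1; s <= smax; ++s) {
    if (cnt[s] > 0) {
      sv.push_back(s);
      rv.push_back(rms ? std::sqrt(acc[s] / cnt[s]) : acc[s] / cnt[s]);
    }
  }
  return List::create(_["s"] = wrap(sv), _["R"] = wrap(rv));
}

// Residue-residue contact matrix for a single frame (all molecules).
// xyz: nb x 3; beadStart/beadCount: per global residue; mol: molecule index
// per global residue (0-based); seq: 1-based position within its molecule.
// inter: contacts across molecules (minimum image, box edge L); otherwise
// within-molecule contacts with |seq_i - seq_j| > nIgnore excluded.
// [[Rcpp::export]]
LogicalMatrix cpp_residue_contacts(NumericMatrix xyz, IntegerVector beadStart,
                                   IntegerVector beadCount, IntegerVector mol,
                                   IntegerVector seq, double cutoff,
                                   int nIgnore, bool inter, double L) {
  int nres = beadStart.size();
  int nb = xyz.nrow();
  double c2 = cutoff * cutoff;
  LogicalMatrix out(nres, nres);
  const double* p = REAL(xyz);
  for (int i = 0; i < nres; ++i) {
    for (int j = i + 1; j < nres; ++j) {
      bool same = (mol[i] == mol[j]);
      if (inter) {
        if (same) continue;
      } else {
        if (!same || std::abs(seq[i] - seq[j]) <= nIgnore) continue;
      }
      double d2 = res_min_dist2(p, nb, beadStart[i], beadCount[i], beadStart[j],
                                beadCount[j], inter ? L : -1.0, c2);
      if (d2 < c2) {
        out(i, j) = true;
        out(j, i) = true;
      }
    }
  }
  return out;
}

// Blocked contact counts over a whole ensemble, reduced to per-molecule
// residue indices. Returns [nResMol x nResMol x nBlocks].
// Intra scope: counts (frame, molecule) events, so divide by nFrames*nMol.
// Inter scope: counts frames in which residues i and j of *any* two distinct
// molecules are in contact (union event), so divide by nFrames.
// [[Rcpp::export]]
NumericVector cpp_contact_map_ensemble(NumericVector coords, int nb, int nf,
                                       IntegerVector beadStart,
                                       IntegerVector beadCount,
                                       IntegerVector mol, IntegerVector seq,
                                       int nResMol, int nMol, double cutoff,
                                       int nIgnore, bool inter,
                                       NumericVector box,
                                       IntegerVector blockId, int nBlocks) {
  int nres = beadStart.size();
  double c2 = cutoff * cutoff;
  NumericVector out((size_t)nResMol * nResMol * nBlocks);
  std::vector<int> hit; // union accumulator for inter scope
  if (inter) hit.assign((size_t)nResMol * nResMol, 0);
  const double* base = REAL(coords);
  for (int f = 0; f < nf; ++f) {
    const double* xyz = base + (size_t)f * nb * 3;
    double L = box[f];
    int blk = blockId[f];
    double* slab = REAL(out) + (size_t)blk * nResMol * nResMol;
    if (inter) std::fill(hit.begin(), hit.end(), 0);
    for (int i = 0; i < nres; ++i) {
      for (int j = i + 1; j < nres; ++j) {
        bool same = (mol[i] == mol[j]);
        if (inter) {
          if (same) continue;
        } else {
          if (!same || std::abs(seq[i] - seq[j]) <= nIgnore) continue;
        }
        double d2 = res_min_dist2(xyz, nb, beadStart[i], beadCount[i],
                                  beadStart[j], beadCount[j],
                                  inter ? L : -1.0, c2);
        if (d2 < c2) {
          int a = seq[i] - 1, b = seq[j] - 1;
          if (inter) {
            int lo = std::min(a, b), hi = std::max(a, b);
            hit[(size_t)hi * nResMol + lo] = 1;
          } else {
            slab[(size_t)b * nResMol + a] += 1.0;
            if (a != b) slab[(size_t)a * nResMol + b] += 1.0;
          }
        }
      }
    }
    if (inter) {
      for (int a = 0; a < nResMol; ++a)
        for (int b2 = a; b2 < nResMol; ++b2)
          if (hit[(size_t)b2 * nResMol + a]) {
            slab[(size_t)b2 * nResMol + a] += 1.0;
            if (a != b2) slab[(size_t)a * nResMol + b2] += 1.0;
          }
    }
  }
  out.attr("dim") = IntegerVector::create(nResMol, nResMol, nBlocks);
  return out;
}

// Molecule-molecule contact matrix for one frame: any bead pair across two
// molecules within cutoff (minimum image).
// [[Rcpp::export]]
LogicalMatrix cpp_mol_contacts(NumericMatrix xyz, IntegerVector beadMol,
                               int nMol, double cutoff, double L) {
  int nb = xyz.nrow();
  double c2 = cutoff * cutoff;
  LogicalMatrix out(nMol, nMol);
  const double* p = REAL(xyz);
  for (int u = 0; u < nb; ++u) {
    for (int v = u + 1; v < nb; ++v) {
      int mu = beadMol[u], mv = beadMol[v];
      if (mu == mv || out(mu, mv)) continue;
      if (pair_dist2(p, nb, u, v, L) < c2) {
        out(mu, mv) = true;
        out(mv, mu) = true;
      }
    }
  }
  return out;
}

// Smallest minimum-image distance between two bead sets (packing check).
// [[Rcpp::export]]
double cpp_min_cross_dist(NumericMatrix a, NumericMatrix b, double L) {
  double best = R_PosInf;
  for (int u = 0; u < a.nrow(); ++u)
    for (int v = 0; v < b.nrow(); ++v) {
      double dx = mimg(a(u, 0) - b(v, 0), L);
      double dy = mimg(a(u, 1) - b(v, 1), L);
      double dz = mimg(a(u, 2) - b(v, 2), L);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}

// [[Rcpp::export]]
double cpp_max_diameter(NumericMatrix xyz) {
  int nb = xyz.nrow();
  const double* p = REAL(xyz);
  double best = 0.0;
  for (int u = 0; u < nb; ++u)
    for (int v = u + 1; v < nb; ++v) {
      double d2 = pair_dist2(p, nb, u, v, -1.0);
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}

// Debye scattering intensity of one frame:
// I(q) = sum_u sum_v f_u f_v sinc(q r_uv); q -> 0 limit is (sum f)^2.
// [[Rcpp::export]]
NumericVector cpp_debye(NumericMatrix xyz, NumericVector f, NumericVector q) {
  int nb = xyz.nrow(), nq = q.size();
  NumericVector I(nq);
  const double* p = REAL(xyz);
  double self = 0.0;
  for (int u = 0; u < nb; ++u) self += f[u] * f[u];
  for (int k = 0; k < nq; ++k) I[k] = self;
  for (int u = 0; u < nb; ++u) {
    for (int v = u + 1; v < nb; ++v) {
      double r = std::sqrt(pair_dist2(p, nb, u, v, -1.0));
      double w = 2.0 * f[u] * f[v];
      for (int k = 0; k < nq; ++k) I[k] += w * sinc(q[k] * r);
    }
  }
  return I;
}

// Ensemble-averaged Debye intensity: mean over frames of cpp_debye.
// [[Rcpp::export]]
NumericVector cpp_debye_ensemble(NumericVector coords, int nb, int nf,
                                 IntegerVector beadSel, NumericVector f,
                                 NumericVector q) {
  int ns = beadSel.size(), nq = q.size();
  NumericVector I(nq);
  double self = 0.0;
  for (int u = 0; u < ns; ++u) self += f[u] * f[u];
  const double* base = REAL(coords);
  for (int fr = 0; fr < nf; ++fr) {
    const double* xyz = base + (size_t)fr * nb * 3;
    for (int u = 0; u < ns; ++u) {
      int bu = beadSel[u];
      for (int v = u + 1; v < ns; ++v) {
        int bv = beadSel[v];
        double r = std::sqrt(pair_dist2(xyz, nb, bu, bv, -1.0));
        double w = 2.0 * f[u] * f[v];
        for (int k = 0; k < nq; ++k) I[k] += w * sinc(q[k] * r);
      }
    }
  }
  for (int k = 0; k < nq; ++k) I[k] = I[k] / nf + self;
  return I;
}

// ---------------------------------------------------------------------------
// Metropolis Monte Carlo of a bead-spring chain.
//
// Energy (kT units):
//   bonds:      kbond * (r - b)^2
//   non-bonded (|i-j| >= 2): hard core for r < rex; square well of depth
//   -eps on rex <= r < rex + well when eps < 0 (eps >= 0: core only).
// Moves: single-bead random displacement (all beads) and crankshaft rotation
// about the axis through the two sequence neighbours (interior beads).
// ---------------------------------------------------------------------------

struct McChain {
  int n;
  double b, rex, eps, well, kbond;
  std::vector<double> x, y, z;
  double rex2, rw2;

  double pairE(int i, int j) const {
    double d2 = sq(x[i] - x[j]) + sq(y[i] - y[j]) + sq(z[i] - z[j]);
    if (d2 < rex2) return 1e9;
    if (eps < 0.0 && d2 < rw2) return eps;
    return 0.0;
  }
  double bondE(int i, int j) const {
    double r = std::sqrt(sq(x[i] - x[j]) + sq(y[i] - y[j]) + sq(z[i] - z[j]));
    return kbond * sq(r - b);
  }
  // energy of all terms involving bead i
  double beadE(int i) const {
    double e = 0.0;
    if (i > 0) e += bondE(i, i - 1);
    if (i < n - 1) e += bondE(i, i + 1);
    for (int j = 0; j < n; ++j)
      if (std::abs(j - i) >= 2) e += pairE(i, j);
    return e;
  }
};

// [[Rcpp::export]]
NumericVector cpp_mc_chain(int n, double b, double rex, double eps, double well,
                           double kbond, int nFrames, int sweepsPerFrame,
                           int burninSweeps, double maxDisp, int seed) {
  McChain ch;
  ch.n = n;
  ch.b = b;
  ch.rex = rex;
  ch.eps = eps;
  ch.well = well;
  ch.kbond = kbond;
  ch.rex2 = rex * rex;
  ch.rw2 = sq(rex + well);
  ch.x.assign(n, 0.0);
  ch.y.assign(n, 0.0);
  ch.z.assign(n, 0.0);
  for (int i = 0; i < n; ++i) ch.x[i] = i * b; // straight rod start

  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);

  NumericVector out((size_t)n * 3 * nFrames);
  double* po = REAL(out);

  // energy between the tail (beads > p) and the head (beads <= p)
  auto crossE = [&](int p) {
    double e = 0.0;
    for (int u = p + 1; u < n; ++u)
      for (int v = 0; v <= p; ++v)
        if (u - v >= 2) e += ch.pairE(u, v);
    return e;
  };

  long totalSweeps = (long)burninSweeps + (long)nFrames * sweepsPerFrame;
  long saved = 0;
  std::vector<double> bx(n), by(n), bz(n); // backup for pivot moves
  for (long sw = 0; sw < totalSweeps; ++sw) {
    // two pivot moves per sweep: rotate the tail beyond a random bead
    for (int pm = 0; pm < 2; ++pm) {
      int p = (int)(U(rng) * (n - 1));
      if (p >= n - 1) p = n - 2;
      double e0 = crossE(p);
      for (int u = p + 1; u < n; ++u) { bx[u] = ch.x[u]; by[u] = ch.y[u]; bz[u] = ch.z[u]; }
      // random axis + angle rotation about bead p
      double zax = 2.0 * U(rng) - 1.0, phi = 2.0 * M_PI * U(rng);
      double rxy = std::sqrt(std::max(0.0, 1.0 - zax * zax));
      double ax = rxy * std::cos(phi), ay = rxy * std::sin(phi), az = zax;
      double th = (2.0 * U(rng) - 1.0) * M_PI;
      double c = std::cos(th), s = std::sin(th);
      for (int u = p + 1; u < n; ++u) {
        double vx = ch.x[u] - ch.x[p], vy = ch.y[u] - ch.y[p],
               vz = ch.z[u] - ch.z[p];
        double dot = ax * vx + ay * vy + az * vz;
        ch.x[u] = ch.x[p] + vx * c + (ay * vz - az * vy) * s + ax * dot * (1 - c);
        ch.y[u] = ch.y[p] + vy * c + (az * vx - ax * vz) * s + ay * dot * (1 - c);
        ch.z[u] = ch.z[p] + vz * c + (ax * vy - ay * vx) * s + az * dot * (1 - c);
      }
      double dE = crossE(p) - e0;
      if (dE > 0.0 && U(rng) > std::exp(-dE)) {
        for (int u = p + 1; u < n; ++u) { ch.x[u] = bx[u]; ch.y[u] = by[u]; ch.z[u] = bz[u]; }
      }
    }
    for (int m = 0; m < n; ++m) {
      int i = (int)(U(rng) * n);
      if (i >= n) i = n - 1;
      double ox = ch.x[i], oy = ch.y[i], oz = ch.z[i];
      double e0 = ch.beadE(i);
      if (i > 0 && i < n - 1 && U(rng) < 0.5) {
        // crankshaft: rotate bead i about the (i-1, i+1) axis
        double ax = ch.x[i + 1] - ch.x[i - 1];
        double ay = ch.y[i + 1] - ch.y[i - 1];
        double az = ch.z[i + 1] - ch.z[i - 1];
        double an = std::sqrt(ax * ax + ay * ay + az * az);
        if (an > 1e-12) {
          ax /= an; ay /= an; az /= an;
          double th = (2.0 * U(rng) - 1.0) * M_PI;
          double c = std::cos(th), s = std::sin(th);
          double vx = ox - ch.x[i - 1], vy = oy - ch.y[i - 1],
                 vz = oz - ch.z[i - 1];
          double dot = ax * vx + ay * vy + az * vz;
          double rx = vx * c + (ay * vz - az * vy) * s + ax * dot * (1 - c);
          double ry = vy * c + (az * vx - ax * vz) * s + ay * dot * (1 - c);
          double rz = vz * c + (ax * vy - ay * vx) * s + az * dot * (1 - c);
          ch.x[i] = ch.x[i - 1] + rx;
          ch.y[i] = ch.y[i - 1] + ry;
          ch.z[i] = ch.z[i - 1] + rz;
        }
      } else {
        ch.x[i] = ox + (2.0 * U(rng) - 1.0) * maxDisp;
        ch.y[i] = oy + (2.0 * U(rng) - 1.0) * maxDisp;
        ch.z[i] = oz + (2.0 * U(rng) - 1.0) * maxDisp;
      }
      double e1 = ch.beadE(i);
      double dE = e1 - e0;
      if (dE > 0.0 && U(rng) > std::exp(-dE)) {
        ch.x[i] = ox;
        ch.y[i] = oy;
        ch.z[i] = oz;
      }
    }
    if (sw >= burninSweeps &&
        (sw - burninSweeps + 1) % sweepsPerFrame == 0) {
      double* fr = po + (size_t)saved * n * 3;
      for (int i = 0; i < n; ++i) {
        fr[i] = ch.x[i];
        fr[i + n] = ch.y[i];
        fr[i + 2 * n] = ch.z[i];
      }
      ++saved;
      if (saved == nFrames) break;
    }
  }
  out.attr("dim") = IntegerVector::create(n, 3, nFrames);
  return out;
}
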