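// Canonical Metropolis Monte Carlo of the primitive model in a cubic
// periodic box with plain Ewald electrostatics (tin-foil boundary).
//
// Units: lengths in angstrom, charges in elementary charges, energies
// in k_B*T (the Bjerrum length carries all physical constants).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>

using namespace Rcpp;

namespace {

// lightweight complex type: keeps the structure-factor arithmetic in
// plain doubles so the compiler inlines it (std::complex multiplies
// go through the __muldc3 runtime call with default flags)
struct cplx {
  double re, im;
};
inline cplx operator*(cplx a, cplx b) {
  return {a.re * b.re - a.im * b.im, a.re * b.im + a.im * b.re};
}
inline cplx operator+(cplx a, cplx b) { return {a.re + b.re, a.im + b.im}; }
inline cplx operator-(cplx a, cplx b) { return {a.re - b.re, a.im - b.im}; }
inline cplx conj(cplx a) { return {a.re, -a.im}; }
inline double norm2(cplx a) { return a.re * a.re + a.im * a.im; }

struct KVec {
  int nx, ny, nz;
  double pref;  // 4*pi/V * exp(-k^2/(4 a^2)) / k^2, half-space factor applied
};

struct Ewald {
  double L, lB, alpha, rcut;
  int kmax;
  std::vector<KVec> kvecs;
  std::vector<cplx> S;  // structure factors

  void build_kvecs(double V) {
    kvecs.clear();
    double twoPiL = 2.0 * M_PI / L;
    int k2max = kmax * kmax;
    for (int nx = 0; nx <= kmax; ++nx)
      for (int ny = (nx == 0 ? 0 : -kmax); ny <= kmax; ++ny)
        for (int nz = ((nx == 0 && ny == 0) ? 1 : -kmax); nz <= kmax; ++nz) {
          int n2 = nx * nx + ny * ny + nz * nz;
          if (n2 == 0 || n2 > k2max) continue;
          double k2 = twoPiL * twoPiL * n2;
          KVec kv;
          kv.nx = nx; kv.ny = ny; kv.nz = nz;
          // half-space: factor 2 for all vectors generated above
          kv.pref = 2.0 * (2.0 * M_PI / V) * std::exp(-k2 / (4.0 * alpha * alpha)) / k2;
          kvecs.push_back(kv);
        }
  }
};

inline double min_image(double d, double L) {
  d -= L * std::round(d / L);
  return d;
}

// per-particle axis phase table e^{i 2 pi n x / L}, n = 0..kmax
inline void phase_table(double x, double L, int kmax,
                        std::vector<cplx>& tab) {
  cplx w = {std::cos(2.0 * M_PI * x / L), std::sin(2.0 * M_PI * x / L)};
  tab[0] = {1.0, 0.0};
  for (int n = 1; n <= kmax; ++n) tab[n] = tab[n - 1] * w;
}

inline cplx axis_phase(const std::vector<cplx>& tab, int n) {
  return n >= 0 ? tab[n] : conj(tab[-n]);
}

void structure_factors(Ewald& ew, const NumericMatrix& pos,
                       const NumericVector& q) {
  int N = pos.nrow();
  ew.S.assign(ew.kvecs.size(), cplx{0.0, 0.0});
  std::vector<cplx> tx(ew.kmax + 1), ty(ew.kmax + 1), tz(ew.kmax + 1);
  for (int i = 0; i < N; ++i) {
    if (q[i] == 0.0) continue;
    phase_table(pos(i, 0), ew.L, ew.kmax, tx);
    phase_table(pos(i, 1), ew.L, ew.kmax, ty);
    phase_table(pos(i, 2), ew.L, ew.kmax, tz);
    for (size_t k = 0; k < ew.kvecs.size(); ++k) {
      const KVec& kv = ew.kvecs[k];
      cplx ph = axis_phase(tx, kv.nx) * axis_phase(ty, kv.ny) *
                axis_phase(tz, kv.nz);
      ew.S[k] = ew.S[k] + cplx{q[i] * ph.re, q[i] * ph.im};
    }
  }
}

double recip_energy(const Ewald& ew) {
  double e = 0.0;
  for (size_t k = 0; k < ew.kvecs.size(); ++k)
    e += ew.kvecs[k].pref * norm2(ew.S[k]);
  return ew.lB * e;
}

double real_self_energy(const Ewald& ew, const NumericMatrix& pos,
                        const NumericVector& q) {
  int N = pos.nrow();
  double e = 0.0, q2sum = 0.0;
  for (int i = 0; i < N; ++i) {
    q2sum += q[i] * q[i];
    for (int j = i + 1; j < N; ++j) {
      if (q[i] == 0.0 || q[j] == 0.0) continue;
      double dx = min_image(pos(i, 0) - pos(j, 0), ew.L);
      double dy = min_image(pos(i, 1) - pos(j, 1), ew.L);
      double dz = min_image(pos(i, 2) - pos(j, 2), ew.L);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < ew.rcut)
        e += ew.lB * q[i] * q[j] * std::erfc(ew.alpha * r) / r;
    }
  }
  e -= ew.lB * ew.alpha / std::sqrt(M_PI) * q2sum;
  return e;
}

}  // namespace

// Total Ewald Coulomb energy (k_B*T units) of a configuration.
// [[Rcpp::export(name = ".cpp_ewald_energy")]]
double cpp_ewald_energy(NumericMatrix pos, NumericVector q, double L,
                        double lB, double alpha, int kmax, double rcut) {
  Ewald ew;
  ew.L = L; ew.lB = lB; ew.alpha = alpha; ew.rcut = rcut; ew.kmax = kmax;
  ew.build_kvecs(L * L * L);
  structure_factors(ew, pos, q);
  return real_self_energy(ew, pos, q) + recip_energy(ew);
}

// Metropolis MC driver.  species: 0-based per-particle species index;
// dmat: species-pair distance of closest approach.
// [[Rcpp::export(name = ".cpp_run_mc")]]
List cpp_run_mc(NumericMatrix pos0, NumericVector q, IntegerVector species,
                NumericMatrix dmat, double L, double lB,
                double alpha, int kmax, double rcut,
                double max_disp, double n_equil_d, double n_prod_d,
                int seed, double rdf_bin, double rdf_rmax, int n_blocks,
                int n_snapshots, int check_every) {
  long long n_equil = (long long)n_equil_d;
  long long n_prod = (long long)n_prod_d;
  int N = pos0.nrow();
  int ns = dmat.nrow();
  bool charged = false;
  for (int i = 0; i < N; ++i) if (q[i] != 0.0) charged = true;

  NumericMatrix pos = clone(pos0);
  Ewald ew;
  ew.L = L; ew.lB = lB; ew.alpha = alpha; ew.rcut = rcut; ew.kmax = kmax;
  if (charged) {
    ew.build_kvecs(L * L * L);
    structure_factors(ew, pos, q);
  }
  double U = charged ? real_self_energy(ew, pos, q) + recip_energy(ew) : 0.0;

  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  int npair = ns * (ns + 1) / 2;
  int nbins = (int)std::floor(rdf_rmax / rdf_bin + 0.5);
  // RDF raw pair counts per block: [block][pair][bin]
  std::vector<std::vector<std::vector<double>>> rdf_cnt(
      n_blocks, std::vector<std::vector<double>>(npair,
                std::vector<double>(nbins, 0.0)));
  std::vector<double> blk_energy(n_blocks, 0.0);
  std::vector<long long> blk_nE(n_blocks, 0);
  std::vector<long long> rdf_samples(n_blocks, 0);

  auto pair_id = [ns](int a, int b) {
    if (a > b) std::swap(a, b);
    return a * ns - a * (a - 1) / 2 + (b - a);
  };

  long long accepted = 0, attempted = 0;
  double max_drift = 0.0;
  std::vector<cplx> tx_o(kmax + 1), ty_o(kmax + 1), tz_o(kmax + 1),
      tx_n(kmax + 1), ty_n(kmax + 1), tz_n(kmax + 1);
  std::vector<cplx> dS(charged ? ew.kvecs.size() : 0);

  List snapshots(n_snapshots);
  long long snap_every = n_snapshots > 0 ? std::max((long long)1, n_prod / n_snapshots)
                                         : n_prod + 1;
  int snap_taken = 0;
  long long rdf_every = std::max((long long)1, (long long)(N / 4));
  long long total = n_equil + n_prod;

  for (long long step = 0; step < total; ++step) {
    bool production = step >= n_equil;
    int blk = production
        ? (int)std::min((long long)(n_blocks - 1),
                        (step - n_equil) * n_blocks / std::max((long long)1, n_prod))
        : 0;
    // --- single-particle displacement ---
    int i = (int)(unif(rng) * N);
    if (i == N) i = N - 1;
    double xo = pos(i, 0), yo = pos(i, 1), zo = pos(i, 2);
    double xn = xo + (unif(rng) - 0.5) * 2.0 * max_disp;
    double yn = yo + (unif(rng) - 0.5) * 2.0 * max_disp;
    double zn = zo + (unif(rng) - 0.5) * 2.0 * max_disp;
    xn -= L * std::floor(xn / L);
    yn -= L * std::floor(yn / L);
    zn -= L * std::floor(zn / L);
    if (production) ++attempted;

    // hard-core check + real-space energy difference
    bool overlap = false;
    double dreal = 0.0;
    for (int j = 0; j < N && !overlap; ++j) {
      if (j == i) continue;
      double dxn = min_image(xn - pos(j, 0), L);
      double dyn = min_image(yn - pos(j, 1), L);
      double dzn = min_image(zn - pos(j, 2), L);
      double rn = std::sqrt(dxn * dxn + dyn * dyn + dzn * dzn);
      if (rn < dmat(species[i], species[j])) { overlap = true; break; }
      if (charged && q[i] != 0.0 && q[j] != 0.0) {
        double dxo = min_image(xo - pos(j, 0), L);
        double dyo = min_image(yo - pos(j, 1), L);
        double dzo = min_image(zo - pos(j, 2), L);
        double ro = std::sqrt(dxo * dxo + dyo * dyo + dzo * dzo);
        if (rn < rcut) dreal += lB * q[i] * q[j] * std::erfc(alpha * rn) / rn;
        if (ro < rcut) dreal -= lB * q[i] * q[j] * std::erfc(alpha * ro) / ro;
      }
    }

    bool accept = false;
    double dU = 0.0;
    if (!overlap) {
      double drecip = 0.0;
      if (charged && q[i] != 0.0) {
        phase_table(xo, L, kmax, tx_o); phase_table(yo, L, kmax, ty_o);
        phase_table(zo, L, kmax, tz_o);
        phase_table(xn, L, kmax, tx_n); phase_table(yn, L, kmax, ty_n);
        phase_table(zn, L, kmax, tz_n);
        for (size_t k = 0; k < ew.kvecs.size(); ++k) {
          const KVec& kv = ew.kvecs[k];
          cplx eo = axis_phase(tx_o, kv.nx) * axis_phase(ty_o, kv.ny) *
                    axis_phase(tz_o, kv.nz);
          cplx en = axis_phase(tx_n, kv.nx) * axis_phase(ty_n, kv.ny) *
                    axis_phase(tz_n, kv.nz);
          cplx d = en - eo;
          dS[k] = {q[i] * d.re, q[i] * d.im};
          drecip += kv.pref * (norm2(ew.S[k] + dS[k]) - norm2(ew.S[k]));
        }
        drecip *= lB;
      }
      dU = dreal + drecip;
      accept = (dU <= 0.0) || (unif(rng) < std::exp(-dU));
      if (accept) {
        pos(i, 0) = xn; pos(i, 1) = yn; pos(i, 2) = zn;
        U += dU;
        if (charged && q[i] != 0.0)
          for (size_t k = 0; k < ew.kvecs.size(); ++k)
            ew.S[k] = ew.S[k] + dS[k];
      }
    }
    if (production && accept) ++accepted;

    // bookkeeping check: running energy vs full recomputation
    if (charged && check_every > 0 && (step + 1) % check_every == 0) {
      structure_factors(ew, pos, q);
      double Ufull = real_self_energy(ew, pos, q) + recip_energy(ew);
      double drift = std::fabs(U - Ufull) /
                     std::max(1.0, std::fabs(Ufull));
      if (drift > max_drift) max_drift = drift;
    }

    if (production) {
      blk_energy[blk] += U;
      blk_nE[blk] += 1;
      long long pstep = step - n_equil;
      if (pstep % rdf_every == 0) {
        ++rdf_samples[blk];
        for (int a = 0; a < N; ++a)
          for (int b = a + 1; b < N; ++b) {
            double dx = min_image(pos(a, 0) - pos(b, 0), L);
            double dy = min_image(pos(a, 1) - pos(b, 1), L);
            double dz = min_image(pos(a, 2) - pos(b, 2), L);
            double r = std::sqrt(dx * dx + dy * dy + dz * dz);
            if (r < rdf_rmax) {
              int bin = (int)(r / rdf_bin);
              if (bin < nbins)
                rdf_cnt[blk][pair_id(species[a], species[b])][bin] += 1.0;
            }
          }
      }
      if (snap_taken < n_snapshots && pstep % snap_every == 0) {
        snapshots[snap_taken++] = clone(pos);
      }
    }
  }

  // flatten RDF counts: [pair, bin, block] as a numeric vector
  NumericVector rdf_flat((R_xlen_t)npair * nbins * n_blocks);
  for (int b = 0; b < n_blocks; ++b)
    for (int p = 0; p < npair; ++p)
      for (int k = 0; k < nbins; ++k)
        rdf_flat[(R_xlen_t)b * npair * nbins + (R_xlen_t)p * nbins + k] =
            rdf_cnt[b][p][k];

  NumericVector be(n_blocks);
  for (int b = 0; b < n_blocks; ++b)
    be[b] = blk_nE[b] > 0 ? blk_energy[b] / blk_nE[b] : NA_REAL;
  NumericVector rs(n_blocks);
  for (int b = 0; b < n_blocks; ++b) rs[b] = (double)rdf_samples[b];

  return List::create(
      _["positions"] = pos,
      _["energy"] = U,
      _["block_energy"] = be,
      _["acceptance_rate"] = attempted > 0 ? (double)accepted / attempted : NA_REAL,
      _["rdf_counts"] = rdf_flat,
      _["rdf_samples"] = rs,
      _["n_bins"] = nbins,
      _["n_pair_channels"] = npair,
      _["max_energy_drift"] = max_drift,
      _["snapshots"] = snapshots,
      _["n_snapshots_taken"] = snap_taken);
}
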