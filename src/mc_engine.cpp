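// Simplified voxel Monte Carlo dose engine for positron emitters.
//
// Physics model:
//  * decays sampled per voxel (multinomial over the activity distribution),
//    emission point uniform within the voxel;
//  * positron kinetic energy deposited locally in the source voxel (the
//    positron range of Ga-68 is below the voxel size used here);
//  * two back-to-back 0.511 MeV annihilation photons plus any nuclear
//    gamma lines transported by Woodcock (delta) tracking with
//    density-scaled water cross-sections;
//  * Compton scattering sampled from the Klein-Nishina distribution
//    (free-electron approximation), photoelectric absorption from a
//    tabulated water cross-section (NIST XCOM values, log-log
//    interpolated), no coherent scattering;
//  * photons below a 10 keV cutoff deposit locally.
//
// Energy is tallied in MeV per voxel, per batch; conversion to Gy happens
// on the R side.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double ELECTRONS_PER_GRAM_WATER = 3.343e23;
static const double RE2_2PI = 2.0 * M_PI * 2.8179403262e-13 * 2.8179403262e-13; // cm^2

// Klein-Nishina total cross-section per electron (cm^2), k = E / 511 keV.
static double kn_total(double k) {
  double t1 = (1.0 + k) / (k * k) *
    (2.0 * (1.0 + k) / (1.0 + 2.0 * k) - std::log(1.0 + 2.0 * k) / k);
  double t2 = std::log(1.0 + 2.0 * k) / (2.0 * k);
  double t3 = -(1.0 + 3.0 * k) / ((1.0 + 2.0 * k) * (1.0 + 2.0 * k));
  return RE2_2PI * (t1 + t2 + t3);
}

// Compton mass attenuation for water, cm^2/g.
static double mu_compton(double E) {
  return kn_total(E / 0.51099895) * ELECTRONS_PER_GRAM_WATER;
}

// Photoelectric mass attenuation for water, cm^2/g (NIST XCOM, log-log).
static const double PE_E[] = {0.010, 0.015, 0.020, 0.030, 0.040, 0.050,
                              0.060, 0.080, 0.100, 0.150, 0.200, 0.300,
                              0.500, 1.000, 1.500};
static const double PE_MU[] = {4.944, 1.374, 0.5503, 0.1557, 0.0617,
                               0.0297, 0.0160, 0.00599, 0.00279, 7.68e-4,
                               2.99e-4, 8.30e-5, 2.05e-5, 4.08e-6, 1.8e-6};
static const int PE_N = 15;

static double mu_photo(double E) {
  if (E <= PE_E[0]) E = PE_E[0];
  int i = 0;
  while (i < PE_N - 2 && PE_E[i + 1] < E) ++i;
  double lx0 = std::log(PE_E[i]), lx1 = std::log(PE_E[i + 1]);
  double ly0 = std::log(PE_MU[i]), ly1 = std::log(PE_MU[i + 1]);
  double f = (std::log(E) - lx0) / (lx1 - lx0);
  return std::exp(ly0 + f * (ly1 - ly0));
}

struct Grid {
  int nx, ny, nz;
  double vx, vy, vz;        // voxel size, cm
  const double *rho;        // g/cm3
  int idx(int i, int j, int k) const { return i + nx * (j + ny * k); }
  bool inside(double x, double y, double z) const {
    return x >= 0 && y >= 0 && z >= 0 &&
      x < nx * vx && y < ny * vy && z < nz * vz;
  }
  int voxel_at(double x, double y, double z) const {
    int i = (int)(x / vx), j = (int)(y / vy), k = (int)(z / vz);
    if (i >= nx) i = nx - 1; if (j >= ny) j = ny - 1; if (k >= nz) k = nz - 1;
    if (i < 0) i = 0; if (j < 0) j = 0; if (k < 0) k = 0;
    return idx(i, j, k);
  }
};

struct Tally {
  std::vector<double> edep;   // MeV per voxel
  double escaped = 0.0;
  double emitted = 0.0;
};

// Deposit energy, re-routing deposits in zero-density voxels to the last
// visited voxel with non-zero density along the track.
static void deposit(Tally &t, const Grid &g, int vox, int last_solid,
                    double E) {
  if (g.rho[vox] > 0.0) {
    t.edep[vox] += E;
  } else if (last_solid >= 0) {
    t.edep[last_solid] += E;
  } else {
    t.escaped += E;
  }
}

// Sample Compton scatter: returns energy fraction eps = E'/E and cos(theta).
static void sample_kn(std::mt19937_64 &rng,
                      std::uniform_real_distribution<double> &U,
                      double k, double &eps, double &cost) {
  double eps0 = 1.0 / (1.0 + 2.0 * k);
  double a1 = -std::log(eps0);
  double a2 = 0.5 * (1.0 - eps0 * eps0);
  double sint2, g;
  do {
    if (U(rng) * (a1 + a2) < a1)
      eps = std::exp(-a1 * U(rng));
    else
      eps = std::sqrt(eps0 * eps0 + (1.0 - eps0 * eps0) * U(rng));
    double t = (1.0 - eps) / (k * eps);
    sint2 = t * (2.0 - t);
    g = 1.0 - eps * sint2 / (1.0 + eps * eps);
  } while (U(rng) > g);
  cost = 1.0 - (1.0 - eps) / (k * eps);
}

// Rotate direction (u,v,w) by polar angle with cosine `cost` and uniform
// azimuth `phi`.
static void rotate_dir(double &u, double &v, double &w, double cost,
                       double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cp = std::cos(phi), sp = std::sin(phi);
  double norm = std::sqrt(u * u + v * v);
  double nu, nv, nw;
  if (norm > 1e-12) {
    nu = u * cost + sint * (u * w * cp - v * sp) / norm;
    nv = v * cost + sint * (v * w * cp + u * sp) / norm;
    nw = w * cost - sint * norm * cp;
  } else {
    nu = sint * cp; nv = sint * sp; nw = (w > 0 ? cost : -cost);
  }
  double n = std::sqrt(nu * nu + nv * nv + nw * nw);
  u = nu / n; v = nv / n; w = nw / n;
}

static void transport_photon(std::mt19937_64 &rng,
                             std::uniform_real_distribution<double> &U,
                             const Grid &g, Tally &t,
                             double x, double y, double z,
                             double u, double v, double w,
                             double E, double rho_max, double cutoff) {
  int last_solid = -1;
  {
    int v0 = g.voxel_at(x, y, z);
    if (g.rho[v0] > 0.0) last_solid = v0;
  }
  while (true) {
    double mu_c = mu_compton(E), mu_p = mu_photo(E);
    double mu_max = (mu_c + mu_p) * rho_max; // 1/cm
    if (mu_max <= 0.0) { t.escaped += E; return; }
    // Woodcock flight to the next (real or virtual) interaction
    bool interacted = false;
    while (true) {
      double s = -std::log(1.0 - U(rng)) / mu_max;
      x += s * u; y += s * v; z += s * w;
      if (!g.inside(x, y, z)) { t.escaped += E; return; }
      int vox = g.voxel_at(x, y, z);
      double rho = g.rho[vox];
      if (rho > 0.0) last_solid = vox;
      double mu_real = (mu_c + mu_p) * rho;
      if (U(rng) * mu_max < mu_real) { interacted = true; break; }
    }
    if (!interacted) return;
    int vox = g.voxel_at(x, y, z);
    if (U(rng) * (mu_c + mu_p) < mu_p) {
      deposit(t, g, vox, last_solid, E);       // photoelectric
      return;
    }
    double eps, cost;
    sample_kn(rng, U, E / 0.51099895, eps, cost);
    deposit(t, g, vox, last_solid, E * (1.0 - eps));
    E *= eps;
    if (E <= cutoff) {                          // local deposition cutoff
      deposit(t, g, vox, last_solid, E);
      return;
    }
    rotate_dir(u, v, w, cost, 2.0 * M_PI * U(rng));
  }
}

// [[Rcpp::export(name = ".mc_run")]]
List mc_run(NumericVector activity, IntegerVector dims,
            NumericVector voxel_size_mm, NumericVector density,
            double positron_yield, double positron_mean_energy,
            double annihilation_energy,
            NumericVector gamma_energies, NumericVector gamma_yields,
            double n_histories, int n_batches, double cutoff_mev,
            int seed) {
  const int nvox = activity.size();
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.vx = voxel_size_mm[0] / 10.0;  // mm -> cm
  g.vy = voxel_size_mm[1] / 10.0;
  g.vz = voxel_size_mm[2] / 10.0;
  g.rho = REAL(density);

  double rho_max = 0.0, atot = 0.0;
  for (int i = 0; i < nvox; ++i) {
    if (g.rho[i] > rho_max) rho_max = g.rho[i];
    atot += activity[i];
  }
  if (atot <= 0.0) stop("total activity is zero");

  std::mt19937_64 rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  std::uniform_real_distribution<double> U(0.0, 1.0);

  NumericMatrix edep_batches(nvox, n_batches);
  NumericVector escaped(n_batches), emitted(n_batches);

  // per-batch history counts (even split, remainder to the first batches)
  long long ntot = (long long)n_histories;
  std::vector<long long> nb(n_batches, ntot / n_batches);
  for (int b = 0; b < ntot % n_batches; ++b) nb[b] += 1;

  const int ng = gamma_energies.size();

  for (int b = 0; b < n_batches; ++b) {
    Tally t; t.edep.assign(nvox, 0.0);
    // per-voxel multinomial decay counts (sequential conditional binomial)
    long long remaining = nb[b];
    double prem = atot;
    for (int vi = 0; vi < nvox && remaining > 0; ++vi) {
      double a = activity[vi];
      if (a <= 0.0) continue;
      long long nv;
      if (a >= prem) {
        nv = remaining;
      } else {
        std::binomial_distribution<long long> B(remaining, a / prem);
        nv = B(rng);
      }
      prem -= a;
      if (nv == 0) continue;
      remaining -= nv;
      int k = vi / (g.nx * g.ny);
      int j = (vi / g.nx) % g.ny;
      int i = vi % g.nx;
      for (long long h = 0; h < nv; ++h) {
        double x = (i + U(rng)) * g.vx;
        double y = (j + U(rng)) * g.vy;
        double z = (k + U(rng)) * g.vz;
        if (U(rng) < positron_yield) {
          // local positron deposit + annihilation pair
          t.emitted += positron_mean_energy + 2.0 * annihilation_energy;
          deposit(t, g, vi, g.rho[vi] > 0 ? vi : -1, positron_mean_energy);
          double cost = 2.0 * U(rng) - 1.0;
          double phi = 2.0 * M_PI * U(rng);
          double sint = std::sqrt(1.0 - cost * cost);
          double u = sint * std::cos(phi), v = sint * std::sin(phi),
            w = cost;
          transport_photon(rng, U, g, t, x, y, z, u, v, w,
                           annihilation_energy, rho_max, cutoff_mev);
          transport_photon(rng, U, g, t, x, y, z, -u, -v, -w,
                           annihilation_energy, rho_max, cutoff_mev);
        }
        for (int gi = 0; gi < ng; ++gi) {
          if (U(rng) < gamma_yields[gi]) {
            t.emitted += gamma_energies[gi];
            double cost = 2.0 * U(rng) - 1.0;
            double phi = 2.0 * M_PI * U(rng);
            double sint = std::sqrt(1.0 - cost * cost);
            transport_photon(rng, U, g, t, x, y, z,
                             sint * std::cos(phi), sint * std::sin(phi),
                             cost, gamma_energies[gi], rho_max, cutoff_mev);
          }
        }
      }
    }
    for (int i = 0; i < nvox; ++i) edep_batches(i, b) = t.edep[i];
    escaped[b] = t.escaped;
    emitted[b] = t.emitted;
  }

  return List::create(_["edep_mev"] = edep_batches,
                      _["escaped_mev"] = escaped,
                      _["emitted_mev"] = emitted,
                      _["n_histories"] = (double)ntot);
}

// [[Rcpp::export(name = ".water_mass_attenuation")]]
DataFrame water_mass_attenuation(NumericVector energies_mev) {
  int n = energies_mev.size();
  NumericVector comp(n), photo(n);
  for (int i = 0; i < n; ++i) {
    comp[i] = mu_compton(energies_mev[i]);
    photo[i] = mu_photo(energies_mev[i]);
  }
  return DataFrame::create(_["energy_mev"] = energies_mev,
                           _["compton"] = comp, _["photoelectric"] = photo);
}
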