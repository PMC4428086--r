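// Numerical kernels: Shrake-Rupley SASA, cell-list pairwise Lennard-Jones /
// Coulomb energies and gradients. All distances in Angstrom, energies in
// kcal/mol, charges in elementary charges.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_set>
#include <cstdint>

using namespace Rcpp;

static const double COULOMB_K = 332.0636; // kcal*A/(mol*e^2)

// ---- neighbour cell list -------------------------------------------------

struct CellList {
  double cell;
  int nx, ny, nz;
  double ox, oy, oz;
  std::vector<std::vector<int>> cells;

  CellList(const NumericMatrix& xyz, double cell_size) : cell(cell_size) {
    int n = xyz.nrow();
    double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
    double xmax = R_NegInf, ymax = R_NegInf, zmax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      xmin = std::min(xmin, xyz(i,0)); xmax = std::max(xmax, xyz(i,0));
      ymin = std::min(ymin, xyz(i,1)); ymax = std::max(ymax, xyz(i,1));
      zmin = std::min(zmin, xyz(i,2)); zmax = std::max(zmax, xyz(i,2));
    }
    ox = xmin; oy = ymin; oz = zmin;
    nx = std::max(1, (int)std::floor((xmax - xmin) / cell) + 1);
    ny = std::max(1, (int)std::floor((ymax - ymin) / cell) + 1);
    nz = std::max(1, (int)std::floor((zmax - zmin) / cell) + 1);
    cells.resize((size_t)nx * ny * nz);
    for (int i = 0; i < n; ++i) cells[index_of(xyz(i,0), xyz(i,1), xyz(i,2))].push_back(i);
  }
  inline size_t index_of(double x, double y, double z) const {
    int cx = std::min(nx - 1, std::max(0, (int)std::floor((x - ox) / cell)));
    int cy = std::min(ny - 1, std::max(0, (int)std::floor((y - oy) / cell)));
    int cz = std::min(nz - 1, std::max(0, (int)std::floor((z - oz) / cell)));
    return ((size_t)cx * ny + cy) * nz + cz;
  }
  template <typename F>
  void for_neighbours(double x, double y, double z, F&& f) const {
    int cx = (int)std::floor((x - ox) / cell);
    int cy = (int)std::floor((y - oy) / cell);
    int cz = (int)std::floor((z - oz) / cell);
    for (int ix = std::max(0, cx-1); ix <= std::min(nx-1, cx+1); ++ix)
      for (int iy = std::max(0, cy-1); iy <= std::min(ny-1, cy+1); ++iy)
        for (int iz = std::max(0, cz-1); iz <= std::min(nz-1, cz+1); ++iz)
          for (int j : cells[((size_t)ix * ny + iy) * nz + iz]) f(j);
  }
};

// ---- Shrake-Rupley SASA --------------------------------------------------

// Golden-spiral unit sphere points.
static std::vector<double> sphere_points(int npts) {
  std::vector<double> pts(3 * npts);
  double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < npts; ++i) {
    double y = 1.0 - 2.0 * (i + 0.5) / npts;
    double r = std::sqrt(std::max(0.0, 1.0 - y * y));
    double th = golden * i;
    pts[3*i]   = std::cos(th) * r;
    pts[3*i+1] = y;
    pts[3*i+2] = std::sin(th) * r;
  }
  return pts;
}

// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radius,
                       double probe = 1.4, int npts = 240) {
  int n = xyz.nrow();
  if (n == 0) stop("SASA of a structure with zero atoms");
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radius[i]);
  CellList cl(xyz, 2.0 * (rmax + probe));
  std::vector<double> pts = sphere_points(npts);
  NumericVector area(n);
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    double ri = radius[i] + probe;
    double xi = xyz(i,0), yi = xyz(i,1), zi = xyz(i,2);
    nbr.clear();
    cl.for_neighbours(xi, yi, zi, [&](int j) {
      if (j == i) return;
      double dx = xyz(j,0)-xi, dy = xyz(j,1)-yi, dz = xyz(j,2)-zi;
      double rj = radius[j] + probe;
      double d2 = dx*dx + dy*dy + dz*dz;
      double s = ri + rj;
      if (d2 < s * s) nbr.push_back(j);
    });
    int acc = 0;
    for (int p = 0; p < npts; ++p) {
      double px = xi + ri * pts[3*p], py = yi + ri * pts[3*p+1],
             pz = zi + ri * pts[3*p+2];
      bool buried = false;
      for (int j : nbr) {
        double rj = radius[j] + probe;
        double dx = xyz(j,0)-px, dy = xyz(j,1)-py, dz = xyz(j,2)-pz;
        if (dx*dx + dy*dy + dz*dz < rj * rj) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * acc / npts;
  }
  return area;
}

// ---- pairwise nonbonded energies ----------------------------------------

static inline uint64_t pair_key(int i, int j) {
  if (i > j) std::swap(i, j);
  return ((uint64_t)i << 32) | (uint64_t)j;
}

// Lennard-Jones + Coulomb over non-excluded pairs within cutoff.
// excl: 2-column integer matrix (0-based) of excluded pairs (1-2, 1-3);
// pairs14: 2-column integer matrix of 1-4 pairs, scaled by scale14_*.
// softcore: below r_sc = sc_frac * sigma_ij the LJ potential continues
// linearly (finite for overlapping atoms; used during relaxation).
// [[Rcpp::export(name = ".pair_energy_cpp")]]
List pair_energy_cpp(NumericMatrix xyz, NumericVector charge,
                     NumericVector sigma, NumericVector eps,
                     IntegerMatrix excl, IntegerMatrix pairs14,
                     double cutoff = 10.0, double scale14_lj = 1.0,
                     double scale14_coul = 1.0, bool gradient = false,
                     bool softcore = false, double sc_frac = 0.7) {
  int n = xyz.nrow();
  std::unordered_set<uint64_t> excl_set, p14_set;
  for (int k = 0; k < excl.nrow(); ++k)
    excl_set.insert(pair_key(excl(k,0), excl(k,1)));
  for (int k = 0; k < pairs14.nrow(); ++k)
    p14_set.insert(pair_key(pairs14(k,0), pairs14(k,1)));

  CellList cl(xyz, cutoff);
  double evdw = 0.0, ecoul = 0.0;
  NumericMatrix grad(gradient ? n : 1, 3);
  double cut2 = cutoff * cutoff;

  for (int i = 0; i < n; ++i) {
    double xi = xyz(i,0), yi = xyz(i,1), zi = xyz(i,2);
    cl.for_neighbours(xi, yi, zi, [&](int j) {
      if (j <= i) return;
      double dx = xyz(j,0)-xi, dy = xyz(j,1)-yi, dz = xyz(j,2)-zi;
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= cut2) return;
      uint64_t key = pair_key(i, j);
      if (excl_set.count(key)) return;
      double slj = 1.0, scl = 1.0;
      if (p14_set.count(key)) { slj = scale14_lj; scl = scale14_coul; }
      double r = std::sqrt(r2);
      double sij = 0.5 * (sigma[i] + sigma[j]);
      double eij = std::sqrt(eps[i] * eps[j]);
      double qq = COULOMB_K * charge[i] * charge[j];
      double de_dr = 0.0;  // dE/dr
      double rsc = sc_frac * sij;
      if (softcore && r < rsc && eij > 0.0) {
        // linear continuation of LJ below rsc
        double s6 = std::pow(sij / rsc, 6.0);
        double v0 = 4.0 * eij * (s6 * s6 - s6);
        double d0 = 4.0 * eij * (-12.0 * s6 * s6 + 6.0 * s6) / rsc;
        evdw += slj * (v0 + d0 * (r - rsc));
        de_dr += slj * d0;
      } else if (eij > 0.0) {
        double s6 = std::pow(sij / r, 6.0);
        evdw += slj * 4.0 * eij * (s6 * s6 - s6);
        de_dr += slj * 4.0 * eij * (-12.0 * s6 * s6 + 6.0 * s6) / r;
      }
      double rr = softcore ? std::max(r, 0.5) : r;  // guard Coulomb blowup
      ecoul += scl * qq / rr;
      if (rr == r) de_dr += -scl * qq / (r * r);
      if (gradient) {
        double g = de_dr / r;
        grad(i,0) -= g * dx; grad(i,1) -= g * dy; grad(i,2) -= g * dz;
        grad(j,0) += g * dx; grad(j,1) += g * dy; grad(j,2) += g * dz;
      }
    });
  }
  List out = List::create(_["vdw"] = evdw, _["coulomb"] = ecoul);
  if (gradient) out["gradient"] = grad;
  return out;
}
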