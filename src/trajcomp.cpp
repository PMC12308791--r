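#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Cell key for a 3D grid hash. Offsets keep indices non-negative.
static inline int64_t cell_key(int ix, int iy, int iz) {
  return (static_cast<int64_t>(ix + 1048576) << 42) |
         (static_cast<int64_t>(iy + 1048576) << 21) |
          static_cast<int64_t>(iz + 1048576);
}

// Count pairs (i in set_a, j in set_b) with d_ij <= cutoff in one frame.
// Cell-list accelerated; contractually equal to the all-pairs answer.
// xyz: n_atoms x 3; set_a/set_b: 0-based atom indices.
// [[Rcpp::export]]
int cpp_count_contacts(NumericMatrix xyz, IntegerVector set_a,
                       IntegerVector set_b, double cutoff) {
  const double c2 = cutoff * cutoff;
  const double inv = 1.0 / cutoff;
  std::unordered_map<int64_t, std::vector<int> > grid;
  grid.reserve(set_b.size() * 2);
  for (int k = 0; k < set_b.size(); ++k) {
    int j = set_b[k];
    int ix = (int)std::floor(xyz(j, 0) * inv);
    int iy = (int)std::floor(xyz(j, 1) * inv);
    int iz = (int)std::floor(xyz(j, 2) * inv);
    grid[cell_key(ix, iy, iz)].push_back(j);
  }
  int count = 0;
  for (int k = 0; k < set_a.size(); ++k) {
    int i = set_a[k];
    double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    int ix = (int)std::floor(xi * inv);
    int iy = (int)std::floor(yi * inv);
    int iz = (int)std::floor(zi * inv);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            double ddx = xi - xyz(j, 0), ddy = yi - xyz(j, 1),
                   ddz = zi - xyz(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz <= c2) ++count;
          }
        }
  }
  return count;
}

// Shrake-Rupley solvent-accessible surface area, one frame.
// Deterministic golden-spiral point set on each atom's solvent sphere.
// Returns per-atom SASA in A^2.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix xyz, NumericVector radii,
                       double probe, int n_points) {
  const int n = xyz.nrow();
  NumericVector out(n);
  if (n == 0) return out;

  // unit sphere points (golden spiral)
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * k;
    px[k] = r * std::cos(th);
    py[k] = r * std::sin(th);
    pz[k] = z;
  }

  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  const double cell = 2.0 * (rmax + probe);
  const double inv = 1.0 / cell;
  std::unordered_map<int64_t, std::vector<int> > grid;
  grid.reserve(n * 2);
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor(xyz(i, 0) * inv);
    int iy = (int)std::floor(xyz(i, 1) * inv);
    int iz = (int)std::floor(xyz(i, 2) * inv);
    grid[cell_key(ix, iy, iz)].push_back(i);
  }

  std::vector<int> nbr;
  std::vector<double> nx, ny, nz, nr2;
  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    nbr.clear(); nx.clear(); ny.clear(); nz.clear(); nr2.clear();
    int ix = (int)std::floor(xi * inv);
    int iy = (int)std::floor(yi * inv);
    int iz = (int)std::floor(zi * inv);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j == i) continue;
            double rj = radii[j] + probe;
            double ddx = xi - xyz(j, 0), ddy = yi - xyz(j, 1),
                   ddz = zi - xyz(j, 2);
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 < (ri + rj) * (ri + rj)) {
              nbr.push_back(j);
              nx.push_back(xyz(j, 0));
              ny.push_back(xyz(j, 1));
              nz.push_back(xyz(j, 2));
              nr2.push_back(rj * rj);
            }
          }
        }
    int acc = 0;
    const size_t nn = nbr.size();
    for (int k = 0; k < n_points; ++k) {
      double sx = xi + ri * px[k], sy = yi + ri * py[k], sz = zi + ri * pz[k];
      bool buried = false;
      for (size_t m = 0; m < nn; ++m) {
        double ddx = sx - nx[m], ddy = sy - ny[m], ddz = sz - nz[m];
        if (ddx * ddx + ddy * ddy + ddz * ddz < nr2[m]) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    out[i] = 4.0 * M_PI * ri * ri * (double)acc / (double)n_points;
  }
  return out;
}

// Distance-fluctuation matrix: DF_ij = <d_ij^2> - <d_ij>^2 over frames.
// X, Y, Z: frames x n_sel coordinate matrices of the selected atoms.
// Returns list(mean = <d>, var = DF).
// [[Rcpp::export]]
List cpp_distance_fluctuation(NumericMatrix X, NumericMatrix Y,
                              NumericMatrix Z) {
  const int F = X.nrow(), N = X.ncol();
  std::vector<double> s1v((size_t)N * N, 0.0), s2v((size_t)N * N, 0.0);
  std::vector<double> xf(N), yf(N), zf(N);
  for (int f = 0; f < F; ++f) {
    for (int i = 0; i < N; ++i) {
      xf[i] = X(f, i); yf[i] = Y(f, i); zf[i] = Z(f, i);
    }
    for (int i = 0; i < N; ++i) {
      const double xi = xf[i], yi = yf[i], zi = zf[i];
      double *r1 = &s1v[(size_t)i * N], *r2 = &s2v[(size_t)i * N];
      for (int j = i + 1; j < N; ++j) {
        double dx = xi - xf[j], dy = yi - yf[j], dz = zi - zf[j];
        double d2 = dx * dx + dy * dy + dz * dz;
        r1[j] += std::sqrt(d2);
        r2[j] += d2;
      }
    }
  }
  NumericMatrix s1(N, N), s2(N, N);
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      s1(i, j) = s1v[(size_t)i * N + j];
      s2(i, j) = s2v[(size_t)i * N + j];
    }
  NumericMatrix m(N, N), v(N, N);
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double mu = s1(i, j) / F;
      double va = s2(i, j) / F - mu * mu;
      if (va < 0) va = 0;  // numerical guard
      m(i, j) = m(j, i) = mu;
      v(i, j) = v(j, i) = va;
    }
  return List::create(_["mean"] = m, _["var"] = v);
}

// Per atom-pair distance statistics across frames, for vdW contact lists.
// Returns for each (i in idx_a) x (j in idx_b): min distance over frames,
// mean distance over frames with d <= cutoff, and that frame count.
// [[Rcpp::export]]
DataFrame cpp_pair_distance_stats(NumericMatrix X, NumericMatrix Y,
                                  NumericMatrix Z, IntegerVector idx_a,
                                  IntegerVector idx_b, double cutoff) {
  const int F = X.nrow();
  const int na = idx_a.size(), nb = idx_b.size();
  IntegerVector ai(na * nb), bj(na * nb), nin(na * nb);
  NumericVector dmin(na * nb), dmean(na * nb);
  int p = 0;
  for (int a = 0; a < na; ++a) {
    int i = idx_a[a];
    for (int b = 0; b < nb; ++b, ++p) {
      int j = idx_b[b];
      double mn = R_PosInf, sum = 0.0;
      int cnt = 0;
      for (int f = 0; f < F; ++f) {
        double dx = X(f, i) - X(f, j), dy = Y(f, i) - Y(f, j),
               dz = Z(f, i) - Z(f, j);
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d < mn) mn = d;
        if (d <= cutoff) { sum += d; ++cnt; }
      }
      ai[p] = i; bj[p] = j; dmin[p] = mn; nin[p] = cnt;
      dmean[p] = cnt > 0 ? sum / cnt : NA_REAL;
    }
  }
  return DataFrame::create(_["i"] = ai, _["j"] = bj, _["min_distance"] = dmin,
                           _["mean_distance"] = dmean, _["n_within"] = nin);
}
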