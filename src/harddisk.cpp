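// Hard-disk Monte Carlo core: periodic square box, minimum-image metric.
// All randomness comes from R's RNG so set.seed() on the R side makes every
// routine deterministic.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

static inline double pdist2(double x1, double y1, double x2, double y2, double L) {
  double dx = min_image(x1 - x2, L);
  double dy = min_image(y1 - y2, L);
  return dx * dx + dy * dy;
}

// Simple cell list over a periodic square box. Cells are at least `min_cell`
// wide so that any neighbour within `min_cell` lies in the 3x3 block.
struct CellList {
  int nc;                 // cells per side (0 => degenerate, use brute force)
  double L;
  std::vector<std::vector<int> > cells;
  std::vector<int> cell_of;

  CellList(double L_, double min_cell, int n) : L(L_) {
    nc = (int)std::floor(L_ / min_cell);
    // finer than ~sqrt(n) cells per side wastes memory without speedup
    int nc_cap = (int)std::sqrt((double)n) + 2;
    if (nc_cap < 3) nc_cap = 3;
    if (nc > nc_cap) nc = nc_cap;
    if (nc < 3) nc = 0;
    if (nc > 0) cells.assign((size_t)nc * nc, std::vector<int>());
    cell_of.assign(n, -1);
  }
  bool active() const { return nc > 0; }
  int cell_index(double x, double y) const {
    int cx = (int)std::floor(x / L * nc);
    int cy = (int)std::floor(y / L * nc);
    if (cx >= nc) cx = nc - 1;
    if (cy >= nc) cy = nc - 1;
    if (cx < 0) cx = 0;
    if (cy < 0) cy = 0;
    return cx * nc + cy;
  }
  void insert(int i, double x, double y) {
    if (!active()) return;
    int c = cell_index(x, y);
    cells[c].push_back(i);
    cell_of[i] = c;
  }
  void move(int i, double x, double y) {
    if (!active()) return;
    int c = cell_index(x, y);
    int old = cell_of[i];
    if (c == old) return;
    std::vector<int> &v = cells[old];
    for (size_t k = 0; k < v.size(); ++k) {
      if (v[k] == i) { v[k] = v.back(); v.pop_back(); break; }
    }
    cells[c].push_back(i);
    cell_of[i] = c;
  }
};

// true if disk at (x,y) overlaps any other disk (pair distance < 2*Re),
// ignoring index `skip`.
static bool has_overlap(const std::vector<double> &px, const std::vector<double> &py,
                        const CellList &cl, double L, double x, double y,
                        double two_Re, int skip) {
  double r2 = two_Re * two_Re;
  int n = (int)px.size();
  if (!cl.active()) {
    for (int j = 0; j < n; ++j) {
      if (j == skip) continue;
      if (pdist2(x, y, px[j], py[j], L) < r2) return true;
    }
    return false;
  }
  int nc = cl.nc;
  int cx = (int)std::floor(x / L * nc);
  int cy = (int)std::floor(y / L * nc);
  if (cx >= nc) cx = nc - 1;
  if (cy >= nc) cy = nc - 1;
  for (int a = -1; a <= 1; ++a) {
    for (int b = -1; b <= 1; ++b) {
      int ax = (cx + a + nc) % nc;
      int by = (cy + b + nc) % nc;
      const std::vector<int> &v = cl.cells[(size_t)ax * nc + by];
      for (size_t k = 0; k < v.size(); ++k) {
        int j = v[k];
        if (j == skip) continue;
        if (pdist2(x, y, px[j], py[j], L) < r2) return true;
      }
    }
  }
  return false;
}

static inline double wrap(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;   // floating-point edge guard
  if (x < 0) x = 0;
  return x;
}

// Random sequential addition of n disks of non-penetration radius Re.
// Returns the centers placed; may hold fewer than n rows if max_fail
// consecutive insertion failures were hit (caller decides the fallback).
// [[Rcpp::export]]
NumericMatrix cpp_rsa_pack(int n, double L, double Re, double max_fail) {
  std::vector<double> px, py;
  px.reserve(n); py.reserve(n);
  CellList cl(L, 2.0 * Re, n);
  double fails = 0;
  int placed = 0;
  while (placed < n) {
    double x = unif_rand() * L;
    double y = unif_rand() * L;
    if (!has_overlap(px, py, cl, L, x, y, 2.0 * Re, -1)) {
      px.push_back(x); py.push_back(y);
      cl.insert(placed, x, y);
      ++placed;
      fails = 0;
    } else {
      fails += 1;
      if (fails >= max_fail) break;
    }
    if (placed % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix out(placed, 2);
  for (int i = 0; i < placed; ++i) { out(i, 0) = px[i]; out(i, 1) = py[i]; }
  return out;
}

// Metropolis sweeps with single-disk uniform displacements in [-delta,delta]^2.
// When tune=true, delta is adjusted every tune_interval sweeps toward a
// 30-50% acceptance window. Returns updated centers, final delta, acceptance.
// [[Rcpp::export]]
List cpp_mc_sweeps(NumericMatrix centers, double L, double Re, int nsweeps,
                   double delta, bool tune, int tune_interval = 50) {
  int n = centers.nrow();
  std::vector<double> px(n), py(n);
  for (int i = 0; i < n; ++i) { px[i] = wrap(centers(i, 0), L); py[i] = wrap(centers(i, 1), L); }
  CellList cl(L, 2.0 * Re, n);
  for (int i = 0; i < n; ++i) cl.insert(i, px[i], py[i]);

  double acc_total = 0, att_total = 0;
  double acc_win = 0, att_win = 0;
  for (int s = 0; s < nsweeps; ++s) {
    for (int m = 0; m < n; ++m) {
      int i = (int)std::floor(unif_rand() * n);
      if (i >= n) i = n - 1;
      double nx = wrap(px[i] + (2.0 * unif_rand() - 1.0) * delta, L);
      double ny = wrap(py[i] + (2.0 * unif_rand() - 1.0) * delta, L);
      att_total += 1; att_win += 1;
      if (!has_overlap(px, py, cl, L, nx, ny, 2.0 * Re, i)) {
        px[i] = nx; py[i] = ny;
        cl.move(i, nx, ny);
        acc_total += 1; acc_win += 1;
      }
    }
    if (tune && ((s + 1) % tune_interval == 0) && att_win > 0) {
      double a = acc_win / att_win;
      if (a > 0.5) delta *= 1.25;
      else if (a < 0.3) delta /= 1.25;
      if (delta > L / 4.0) delta = L / 4.0;
      if (delta < 1e-4 * Re) delta = 1e-4 * Re;
      acc_win = 0; att_win = 0;
    }
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = px[i]; out(i, 1) = py[i]; }
  return List::create(_["centers"] = out, _["delta"] = delta,
                      _["acceptance"] = att_total > 0 ? acc_total / att_total : NA_REAL);
}

// Brute-force O(n^2) minimum periodic pair distance (overlap oracle).
// [[Rcpp::export]]
double cpp_min_pair_dist(NumericMatrix centers, double L) {
  int n = centers.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d2 = pdist2(centers(i, 0), centers(i, 1), centers(j, 0), centers(j, 1), L);
      if (d2 < best) best = d2;
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return std::sqrt(best);
}

// Histogram of periodic pair distances below rmax, each unordered pair once.
// [[Rcpp::export]]
NumericVector cpp_pair_histogram(NumericMatrix centers, double L, double rmax, int nbins) {
  int n = centers.nrow();
  NumericVector counts(nbins);
  double r2max = rmax * rmax;
  double w = rmax / nbins;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d2 = pdist2(centers(i, 0), centers(i, 1), centers(j, 0), centers(j, 1), L);
      if (d2 < r2max) {
        int b = (int)std::floor(std::sqrt(d2) / w);
        if (b >= 0 && b < nbins) counts[b] += 1;
      }
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}

// Lattice proximity statistics. A point of a regular (L/m)-spaced lattice is
// "matrix" when its distance to the nearest disk center exceeds R; for each
// threshold d the count of matrix points with (distance - R) <= d is returned.
// [[Rcpp::export]]
List cpp_proximity_counts(NumericMatrix centers, double L, double R,
                          double spacing, NumericVector dists) {
  int n = centers.nrow();
  double dmax = 0.0;
  for (int k = 0; k < dists.size(); ++k) if (dists[k] > dmax) dmax = dists[k];
  double cutoff = R + dmax;
  int m = (int)std::round(L / spacing);
  if (m < 1) m = 1;
  double h = L / m;

  std::vector<double> px(n), py(n);
  for (int i = 0; i < n; ++i) { px[i] = wrap(centers(i, 0), L); py[i] = wrap(centers(i, 1), L); }
  CellList cl(L, cutoff, n);
  for (int i = 0; i < n; ++i) cl.insert(i, px[i], py[i]);

  double n_matrix = 0;
  NumericVector within(dists.size());
  double cut2 = cutoff * cutoff;
  for (int ix = 0; ix < m; ++ix) {
    double x = (ix + 0.5) * h;
    for (int iy = 0; iy < m; ++iy) {
      double y = (iy + 0.5) * h;
      double best2 = R_PosInf;
      if (cl.active()) {
        int nc = cl.nc;
        int cx = (int)std::floor(x / L * nc); if (cx >= nc) cx = nc - 1;
        int cy = (int)std::floor(y / L * nc); if (cy >= nc) cy = nc - 1;
        for (int a = -1; a <= 1; ++a) {
          for (int b = -1; b <= 1; ++b) {
            int ax = (cx + a + nc) % nc;
            int by = (cy + b + nc) % nc;
            const std::vector<int> &v = cl.cells[(size_t)ax * nc + by];
            for (size_t k = 0; k < v.size(); ++k) {
              double d2 = pdist2(x, y, px[v[k]], py[v[k]], L);
              if (d2 < best2) best2 = d2;
            }
          }
        }
        // anything farther than cutoff is irrelevant to every threshold
        if (best2 > cut2) best2 = R_PosInf;
      } else {
        for (int j = 0; j < n; ++j) {
          double d2 = pdist2(x, y, px[j], py[j], L);
          if (d2 < best2) best2 = d2;
        }
      }
      double d = std::sqrt(best2);
      if (!(d <= R)) {                       // matrix point (also d = Inf)
        n_matrix += 1;
        for (int k = 0; k < dists.size(); ++k)
          if (d - R <= dists[k]) within[k] += 1;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["n_matrix"] = n_matrix, _["within"] = within,
                      _["n_total"] = (double)m * m, _["spacing_used"] = h);
}

// Periodic distance from each query point to the nearest disk center.
// [[Rcpp::export]]
NumericVector cpp_nearest_center_dist(NumericMatrix centers, double L,
                                      NumericMatrix pts) {
  int n = centers.nrow(), np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      double d2 = pdist2(pts(p, 0), pts(p, 1), centers(j, 0), centers(j, 1), L);
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
    if (p % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Static structure factor by direct summation over integer wave vectors
// q = (2*pi/L) * (nx, ny): S = |sum_j exp(i q.r_j)|^2 / N per row of nvec.
// [[Rcpp::export]]
NumericVector cpp_direct_sf(NumericMatrix centers, double L, IntegerMatrix nvec) {
  int n = centers.nrow(), nq = nvec.nrow();
  NumericVector S(nq);
  double two_pi_L = 2.0 * M_PI / L;
  for (int k = 0; k < nq; ++k) {
    double qx = two_pi_L * nvec(k, 0);
    double qy = two_pi_L * nvec(k, 1);
    double re = 0, im = 0;
    for (int j = 0; j < n; ++j) {
      double ph = qx * centers(j, 0) + qy * centers(j, 1);
      re += std::cos(ph);
      im += std::sin(ph);
    }
    S[k] = (re * re + im * im) / n;
    if (k % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return S;
}
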