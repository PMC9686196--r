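#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Deterministic quasi-uniform point set on the unit sphere (golden-spiral /
// Fibonacci lattice).  Deterministic quadrature keeps SASA results exactly
// reproducible across runs and platforms.
// [[Rcpp::export(rng = false)]]
NumericMatrix golden_spiral_points(int n) {
  if (n < 1) stop("need at least one quadrature point");
  NumericMatrix out(n, 3);
  const double ga = M_PI * (1.0 + std::sqrt(5.0));
  for (int i = 0; i < n; ++i) {
    double z = 1.0 - 2.0 * (i + 0.5) / n;          // cos(polar angle)
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double t = ga * (i + 0.5);
    out(i, 0) = r * std::cos(t);
    out(i, 1) = r * std::sin(t);
    out(i, 2) = z;
  }
  return out;
}

// Shrake-Rupley accessible areas.  `pos` holds the reported atoms first
// (n_report of them); all rows act as occluders.  Radii are per-atom van der
// Waals radii; every sphere is expanded by the probe radius.
// [[Rcpp::export(rng = false)]]
NumericVector sasa_areas_cpp(NumericMatrix pos, NumericVector radii,
                             double probe, int n_points, int n_report) {
  const int n = pos.nrow();
  if (n == 0) stop("empty coordinate set");
  if (radii.size() != n) stop("radii must match coordinate rows");
  if (n_report < 1 || n_report > n) stop("invalid n_report");
  NumericMatrix sph = golden_spiral_points(n_points);
  NumericVector area(n_report);

  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);

  std::vector<int> neigh;
  neigh.reserve(64);
  for (int i = 0; i < n_report; ++i) {
    const double Ri = radii[i] + probe;
    const double xi = pos(i, 0), yi = pos(i, 1), zi = pos(i, 2);
    const double reach = Ri + rmax + probe;
    neigh.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = pos(j, 0) - xi, dy = pos(j, 1) - yi, dz = pos(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      double rj = radii[j] + probe;
      if (d2 < (Ri + rj) * (Ri + rj) && d2 > 1e-18) neigh.push_back(j);
      if (d2 <= 1e-18 && reach > 0) {
        // coincident occluder: treat as fully burying only if it is at least
        // as large; callers warn and skip such atoms beforehand.
        if (rj >= Ri) neigh.push_back(j);
      }
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      const double px = xi + Ri * sph(k, 0);
      const double py = yi + Ri * sph(k, 1);
      const double pz = zi + Ri * sph(k, 2);
      bool free_pt = true;
      for (size_t m = 0; m < neigh.size(); ++m) {
        const int j = neigh[m];
        const double rj = radii[j] + probe;
        const double dx = px - pos(j, 0), dy = py - pos(j, 1),
                     dz = pz - pos(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)n_points;
  }
  return area;
}

// Coordination numbers within a cutoff (open boundary).
// [[Rcpp::export(rng = false)]]
IntegerVector coordination_cpp(NumericMatrix pos, double cutoff) {
  const int n = pos.nrow();
  IntegerVector cn(n);
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      if (dx * dx + dy * dy + dz * dz <= c2) { ++cn[i]; ++cn[j]; }
    }
  }
  return cn;
}

static inline double wrap_delta(double d, double box) {
  if (box > 0) {
    d -= box * std::round(d / box);
  }
  return d;
}

// Lower-triangle pairwise distances with optional cubic minimum image.
// metric: 0 = euclidean, 1 = manhattan (componentwise minimum image).
// Returned in the packing used by stats::dist (column-major lower triangle).
// [[Rcpp::export(rng = false)]]
NumericVector pairdist_cpp(NumericMatrix x, double box, int metric) {
  const int n = x.nrow();
  if (n < 2) return NumericVector(0);
  NumericVector out((double)n * (n - 1) / 2);
  R_xlen_t k = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = wrap_delta(x(i, 0) - x(j, 0), box);
      double dy = wrap_delta(x(i, 1) - x(j, 1), box);
      double dz = wrap_delta(x(i, 2) - x(j, 2), box);
      if (metric == 1)
        out[k++] = std::fabs(dx) + std::fabs(dy) + std::fabs(dz);
      else
        out[k++] = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  }
  return out;
}

// For each row of `a`, the minimum-image euclidean distance to the nearest
// row of `b` and that row's (1-based) index.
// [[Rcpp::export(rng = false)]]
List nearest_neighbour_cpp(NumericMatrix a, NumericMatrix b, double box) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector d(na);
  IntegerVector idx(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    int bj = NA_INTEGER;
    for (int j = 0; j < nb; ++j) {
      double dx = wrap_delta(a(i, 0) - b(j, 0), box);
      double dy = wrap_delta(a(i, 1) - b(j, 1), box);
      double dz = wrap_delta(a(i, 2) - b(j, 2), box);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j + 1; }
    }
    d[i] = std::sqrt(best);
    idx[i] = bj;
  }
  return List::create(_["distance"] = d, _["index"] = idx);
}

// Distances from rows of `x` to a single reference point under minimum image.
// [[Rcpp::export(rng = false)]]
NumericVector dist_to_point_cpp(NumericMatrix x, NumericVector p, double box) {
  const int n = x.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double dx = wrap_delta(x(i, 0) - p[0], box);
    double dy = wrap_delta(x(i, 1) - p[1], box);
    double dz = wrap_delta(x(i, 2) - p[2], box);
    out[i] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  return out;
}
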