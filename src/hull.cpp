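// Incremental (beneath-beyond) convex hull in general dimension d.
// Facets are (d-1)-simplices kept with outward normals; the hull volume is
// the sum of signed simplex volumes against an interior point. Degenerate
// inputs (n < d+1 or affinely dependent point sets) have volume 0 by
// contract, not by exception.
#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::vector<double> Vec;

// determinant of a k x k matrix (row-major), in-place Gaussian elimination
static double det_inplace(std::vector<Vec>& m) {
  int k = m.size();
  double det = 1.0;
  for (int col = 0; col < k; ++col) {
    int piv = col;
    for (int r = col + 1; r < k; ++r)
      if (std::fabs(m[r][col]) > std::fabs(m[piv][col])) piv = r;
    if (m[piv][col] == 0.0) return 0.0;
    if (piv != col) { std::swap(m[piv], m[col]); det = -det; }
    det *= m[col][col];
    for (int r = col + 1; r < k; ++r) {
      double f = m[r][col] / m[col][col];
      for (int c = col; c < k; ++c) m[r][c] -= f * m[col][c];
    }
  }
  return det;
}

struct Facet {
  std::vector<int> v;   // d vertex indices
  Vec normal;           // outward unit-ish normal
  double offset;        // normal . x = offset on the facet plane
  bool alive;
};

// normal of the hyperplane through d points (generalised cross product of
// the d-1 difference vectors), not normalised
static Vec facet_normal(const NumericMatrix& P, const std::vector<int>& idx) {
  int d = P.ncol();
  // rows: v_i - v_0, i = 1..d-1  (a (d-1) x d matrix)
  std::vector<Vec> diff(d - 1, Vec(d));
  for (int i = 1; i < d; ++i)
    for (int j = 0; j < d; ++j)
      diff[i - 1][j] = P(idx[i], j) - P(idx[0], j);
  Vec n(d);
  for (int j = 0; j < d; ++j) {
    // cofactor: delete column j
    std::vector<Vec> sub(d - 1, Vec(d - 1));
    for (int r = 0; r < d - 1; ++r) {
      int cc = 0;
      for (int c = 0; c < d; ++c)
        if (c != j) sub[r][cc++] = diff[r][c];
    }
    double dd = det_inplace(sub);
    n[j] = ((j % 2) == 0) ? dd : -dd;
  }
  return n;
}

static double dot_row(const NumericMatrix& P, int row, const Vec& n) {
  double s = 0.0;
  for (size_t j = 0; j < n.size(); ++j) s += P(row, j) * n[j];
  return s;
}

// build a facet oriented away from the interior point
static Facet make_facet(const NumericMatrix& P, std::vector<int> idx,
                        const Vec& interior) {
  Facet f;
  f.alive = true;
  f.v = idx;
  f.normal = facet_normal(P, idx);
  double nrm = 0.0;
  for (double x : f.normal) nrm += x * x;
  nrm = std::sqrt(nrm);
  if (nrm > 0) for (double& x : f.normal) x /= nrm;
  f.offset = dot_row(P, idx[0], f.normal);
  double s = 0.0;
  for (size_t j = 0; j < f.normal.size(); ++j) s += interior[j] * f.normal[j];
  if (s > f.offset) {
    for (double& x : f.normal) x = -x;
    f.offset = -f.offset;
  }
  return f;
}

// greedy affinely-independent initial simplex; returns empty if degenerate
static std::vector<int> initial_simplex(const NumericMatrix& P, double eps) {
  int n = P.nrow(), d = P.ncol();
  std::vector<int> simp;
  simp.push_back(0);
  // orthonormal basis of the affine span so far
  std::vector<Vec> basis;
  while ((int)simp.size() < d + 1) {
    int best = -1;
    double bestd = eps;
    for (int i = 0; i < n; ++i) {
      Vec r(d);
      for (int j = 0; j < d; ++j) r[j] = P(i, j) - P(simp[0], j);
      for (const Vec& b : basis) {
        double pr = 0.0;
        for (int j = 0; j < d; ++j) pr += r[j] * b[j];
        for (int j = 0; j < d; ++j) r[j] -= pr * b[j];
      }
      double nr = 0.0;
      for (int j = 0; j < d; ++j) nr += r[j] * r[j];
      nr = std::sqrt(nr);
      if (nr > bestd) { bestd = nr; best = i; }
    }
    if (best < 0) return std::vector<int>();  // affinely degenerate
    // extend basis with the residual direction of `best`
    Vec r(d);
    for (int j = 0; j < d; ++j) r[j] = P(best, j) - P(simp[0], j);
    for (const Vec& b : basis) {
      double pr = 0.0;
      for (int j = 0; j < d; ++j) pr += r[j] * b[j];
      for (int j = 0; j < d; ++j) r[j] -= pr * b[j];
    }
    double nr = 0.0;
    for (int j = 0; j < d; ++j) nr += r[j] * r[j];
    nr = std::sqrt(nr);
    for (int j = 0; j < d; ++j) r[j] /= nr;
    basis.push_back(r);
    simp.push_back(best);
  }
  return simp;
}

// core construction; fills `facets` and `interior`; returns false if degenerate
static bool build_hull(const NumericMatrix& P, std::vector<Facet>& facets,
                       Vec& interior, double& eps_out) {
  int n = P.nrow(), d = P.ncol();
  if (n < d + 1) return false;
  double scale = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) scale = std::max(scale, std::fabs(P(i, j)));
  double eps = 1e-10 * (1.0 + scale);
  eps_out = eps;

  std::vector<int> simp = initial_simplex(P, eps);
  if (simp.empty()) return false;

  interior.assign(d, 0.0);
  for (int v : simp)
    for (int j = 0; j < d; ++j) interior[j] += P(v, j) / (d + 1);

  facets.clear();
  for (int skip = 0; skip <= d; ++skip) {
    std::vector<int> idx;
    for (int k = 0; k <= d; ++k)
      if (k != skip) idx.push_back(simp[k]);
    facets.push_back(make_facet(P, idx, interior));
  }

  std::vector<bool> used(n, false);
  for (int v : simp) used[v] = true;

  for (int p = 0; p < n; ++p) {
    if (used[p]) continue;
    std::vector<int> visible;
    for (size_t f = 0; f < facets.size(); ++f) {
      if (!facets[f].alive) continue;
      if (dot_row(P, p, facets[f].normal) - facets[f].offset > eps)
        visible.push_back((int)f);
    }
    if (visible.empty()) continue;
    // horizon ridges = ridges of visible facets seen exactly once
    std::map<std::vector<int>, int> ridge_count;
    for (int f : visible) {
      for (int skip = 0; skip < d; ++skip) {
        std::vector<int> ridge;
        for (int k = 0; k < d; ++k)
          if (k != skip) ridge.push_back(facets[f].v[k]);
        std::sort(ridge.begin(), ridge.end());
        ridge_count[ridge]++;
      }
    }
    for (int f : visible) facets[f].alive = false;
    for (std::map<std::vector<int>, int>::iterator it = ridge_count.begin();
         it != ridge_count.end(); ++it) {
      if (it->second != 1) continue;
      std::vector<int> idx = it->first;
      idx.push_back(p);
      facets.push_back(make_facet(P, idx, interior));
    }
    // periodic compaction keeps the scan linear in live facets
    if (facets.size() > 4096) {
      std::vector<Facet> live;
      for (const Facet& f : facets) if (f.alive) live.push_back(f);
      facets.swap(live);
    }
  }
  return true;
}

static double ld_factorial(int d) {
  double f = 1.0;
  for (int i = 2; i <= d; ++i) f *= i;
  return f;
}

// [[Rcpp::export]]
double hull_volume_cpp(NumericMatrix P) {
  int d = P.ncol();
  std::vector<Facet> facets;
  Vec interior;
  double eps;
  if (!build_hull(P, facets, interior, eps)) return 0.0;
  double vol = 0.0, dfact = ld_factorial(d);
  for (const Facet& f : facets) {
    if (!f.alive) continue;
    std::vector<Vec> m(d, Vec(d));
    for (int i = 0; i < d; ++i)
      for (int j = 0; j < d; ++j)
        m[i][j] = P(f.v[i], j) - interior[j];
    vol += std::fabs(det_inplace(m)) / dfact;
  }
  return vol;
}

// [[Rcpp::export]]
List hull_facets_cpp(NumericMatrix P) {
  int d = P.ncol();
  std::vector<Facet> facets;
  Vec interior;
  double eps;
  if (!build_hull(P, facets, interior, eps))
    return List::create(_["normals"] = NumericMatrix(0, d),
                        _["offsets"] = NumericVector(0),
                        _["degenerate"] = true);
  int nf = 0;
  for (const Facet& f : facets) if (f.alive) ++nf;
  NumericMatrix normals(nf, d);
  NumericVector offsets(nf);
  int r = 0;
  for (const Facet& f : facets) {
    if (!f.alive) continue;
    for (int j = 0; j < d; ++j) normals(r, j) = f.normal[j];
    offsets[r] = f.offset;
    ++r;
  }
  return List::create(_["normals"] = normals, _["offsets"] = offsets,
                      _["degenerate"] = false);
}
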