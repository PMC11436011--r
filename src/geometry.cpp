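// Spatial primitives shared by segmentation, completion and reconstruction:
// hash-grid k-nearest-neighbour search, covariance normals/curvature,
// surface region growing and fixed-radius Gaussian smoothing.
#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// 3 signed cell indices packed into one 64-bit key; cells span far less than
// 2^21 per axis at seed/scene scale so the masked packing is collision-free.
inline long long packKey(long long ix, long long iy, long long iz) {
  return (ix & 0x1FFFFFLL) | ((iy & 0x1FFFFFLL) << 21) | ((iz & 0x1FFFFFLL) << 42);
}

struct HashGrid {
  double h;
  double ox, oy, oz;
  std::unordered_map<long long, std::vector<int> > cells;

  void build(const arma::mat& P, double cell) {
    h = cell;
    ox = P.col(0).min();
    oy = P.col(1).min();
    oz = P.col(2).min();
    cells.reserve(P.n_rows / 2 + 8);
    for (arma::uword i = 0; i < P.n_rows; ++i) {
      long long ix = (long long)std::floor((P(i, 0) - ox) / h);
      long long iy = (long long)std::floor((P(i, 1) - oy) / h);
      long long iz = (long long)std::floor((P(i, 2) - oz) / h);
      cells[packKey(ix, iy, iz)].push_back((int)i);
    }
  }
};

// Median nearest-neighbour spacing from a strided subsample (brute force).
double spacingEstimate(const arma::mat& P) {
  arma::uword n = P.n_rows;
  if (n < 2) return 1.0;
  arma::uword m = std::min<arma::uword>(n, 400);
  arma::uword stride = std::max<arma::uword>(1, n / m);
  std::vector<double> ds;
  ds.reserve(m + 1);
  for (arma::uword i = 0; i < n; i += stride) {
    double best = R_PosInf;
    for (arma::uword j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = P(i, 0) - P(j, 0);
      double dy = P(i, 1) - P(j, 1);
      double dz = P(i, 2) - P(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    if (best > 0 && best < R_PosInf) ds.push_back(std::sqrt(best));
  }
  if (ds.empty()) return 1.0;
  std::nth_element(ds.begin(), ds.begin() + ds.size() / 2, ds.end());
  double med = ds[ds.size() / 2];
  return (med > 0 && R_finite(med)) ? med : 1.0;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_spacing")]]
double cpp_spacing(const arma::mat& P) {
  return spacingEstimate(P);
}

// k nearest reference points for every query point. Returns 1-based index
// matrix and distance matrix; k must not exceed nrow(ref).
// [[Rcpp::export(name = "cpp_knn")]]
List cpp_knn(const arma::mat& ref, const arma::mat& query, int k,
             double cell = -1.0) {
  const arma::uword n = ref.n_rows, nq = query.n_rows;
  if (k < 1 || (arma::uword)k > n)
    stop("k must be between 1 and nrow(ref)");
  double h = cell;
  if (h <= 0) h = 2.0 * spacingEstimate(ref);
  if (!R_finite(h) || h <= 0) h = 1.0;

  HashGrid g;
  g.build(ref, h);

  // conservative shell bound from the reference bounding box
  double span = std::max(std::max(ref.col(0).max() - g.ox,
                                  ref.col(1).max() - g.oy),
                         ref.col(2).max() - g.oz);
  long long maxShell = (long long)std::ceil(span / h) + 2;

  IntegerMatrix idxOut(nq, k);
  NumericMatrix distOut(nq, k);

  typedef std::pair<double, int> DI; // (squared distance, index)
  for (arma::uword q = 0; q < nq; ++q) {
    double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    long long cx = (long long)std::floor((qx - g.ox) / h);
    long long cy = (long long)std::floor((qy - g.oy) / h);
    long long cz = (long long)std::floor((qz - g.oz) / h);

    std::priority_queue<DI> heap; // max-heap on squared distance
    for (long long m = 0;; ++m) {
      // shell of cells at Chebyshev distance m
      for (long long dx = -m; dx <= m; ++dx) {
        for (long long dy = -m; dy <= m; ++dy) {
          for (long long dz = -m; dz <= m; ++dz) {
            if (std::max(std::llabs(dx), std::max(std::llabs(dy), std::llabs(dz))) != m)
              continue;
            std::unordered_map<long long, std::vector<int> >::const_iterator it =
              g.cells.find(packKey(cx + dx, cy + dy, cz + dz));
            if (it == g.cells.end()) continue;
            const std::vector<int>& pts = it->second;
            for (size_t t = 0; t < pts.size(); ++t) {
              int j = pts[t];
              double ddx = ref(j, 0) - qx;
              double ddy = ref(j, 1) - qy;
              double ddz = ref(j, 2) - qz;
              double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if ((int)heap.size() < k) heap.push(DI(d2, j));
              else if (d2 < heap.top().first) { heap.pop(); heap.push(DI(d2, j)); }
            }
          }
        }
      }
      // cells beyond shell m hold points at distance >= m*h
      if ((int)heap.size() == k && std::sqrt(heap.top().first) <= (double)m * h)
        break;
      if (m > maxShell) break;
    }

    int got = (int)heap.size();
    for (int s = got - 1; s >= 0; --s) {
      idxOut(q, s) = heap.top().second + 1;
      distOut(q, s) = std::sqrt(heap.top().first);
      heap.pop();
    }
    for (int s = got; s < k; ++s) { idxOut(q, s) = NA_INTEGER; distOut(q, s) = NA_REAL; }
  }
  return List::create(_["idx"] = idxOut, _["dist"] = distOut);
}

// Per-point unit normal (smallest covariance eigenvector of the k-NN
// neighbourhood) and surface-variation curvature lambda_min / sum(lambda).
// [[Rcpp::export(name = "cpp_normals")]]
List cpp_normals(const arma::mat& P, const IntegerMatrix& nbr) {
  const arma::uword n = P.n_rows;
  const int k = nbr.ncol();
  arma::mat N(n, 3, arma::fill::zeros);
  arma::vec curv(n, arma::fill::zeros);
  arma::mat Q(k, 3);
  for (arma::uword i = 0; i < n; ++i) {
    int got = 0;
    for (int j = 0; j < k; ++j) {
      int id = nbr(i, j);
      if (id == NA_INTEGER) continue;
      Q.row(got++) = P.row(id - 1);
    }
    if (got < 3) { N(i, 2) = 1.0; continue; }
    arma::mat Qi = Q.rows(0, got - 1);
    arma::rowvec mu = arma::mean(Qi, 0);
    Qi.each_row() -= mu;
    arma::mat C = Qi.t() * Qi / (double)(got - 1);
    arma::vec ev;
    arma::mat evec;
    if (!arma::eig_sym(ev, evec, C)) { N(i, 2) = 1.0; continue; }
    N.row(i) = evec.col(0).t(); // ascending order: col 0 = smallest
    double s = arma::sum(ev);
    curv(i) = (s > 0) ? ev(0) / s : 0.0;
  }
  return List::create(_["normals"] = N, _["curvature"] = curv);
}

// Smoothness/curvature region growing over a k-NN graph. Seeds are visited in
// ascending-curvature order; a neighbour joins the cluster when its normal
// deviates from the current point's normal by at most the smoothness angle,
// and becomes a growth front itself when its curvature is below the
// curvature threshold.
// [[Rcpp::export(name = "cpp_region_grow")]]
IntegerVector cpp_region_grow(const IntegerMatrix& nbr, const arma::mat& normals,
                              const arma::vec& curvature, double cosThresh,
                              double curvThresh) {
  const int n = normals.n_rows;
  const int k = nbr.ncol();
  arma::uvec order = arma::sort_index(curvature);
  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int current = 0;
  for (int s = 0; s < n; ++s) {
    int seed = (int)order(s);
    if (labels[seed] != 0) continue;
    ++current;
    labels[seed] = current;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      int c = stack.back();
      stack.pop_back();
      for (int j = 0; j < k; ++j) {
        int id = nbr(c, j);
        if (id == NA_INTEGER) continue;
        int nb = id - 1;
        if (labels[nb] != 0) continue;
        double dot = std::fabs(normals(c, 0) * normals(nb, 0) +
                               normals(c, 1) * normals(nb, 1) +
                               normals(c, 2) * normals(nb, 2));
        if (dot >= cosThresh) {
          labels[nb] = current;
          if (curvature(nb) < curvThresh) stack.push_back(nb);
        }
      }
    }
  }
  return labels;
}

// Gaussian-weighted mean within a fixed radius; point count unchanged.
// [[Rcpp::export(name = "cpp_gaussian_smooth")]]
arma::mat cpp_gaussian_smooth(const arma::mat& P, double radius, double sigma) {
  const arma::uword n = P.n_rows;
  HashGrid g;
  g.build(P, radius);
  arma::mat out(n, 3);
  const double r2 = radius * radius;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (arma::uword i = 0; i < n; ++i) {
    double qx = P(i, 0), qy = P(i, 1), qz = P(i, 2);
    long long cx = (long long)std::floor((qx - g.ox) / radius);
    long long cy = (long long)std::floor((qy - g.oy) / radius);
    long long cz = (long long)std::floor((qz - g.oz) / radius);
    double sw = 0, sx = 0, sy = 0, sz = 0;
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          std::unordered_map<long long, std::vector<int> >::const_iterator it =
            g.cells.find(packKey(cx + dx, cy + dy, cz + dz));
          if (it == g.cells.end()) continue;
          const std::vector<int>& pts = it->second;
          for (size_t t = 0; t < pts.size(); ++t) {
            int j = pts[t];
            double ddx = P(j, 0) - qx, ddy = P(j, 1) - qy, ddz = P(j, 2) - qz;
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 > r2) continue;
            double w = std::exp(-d2 * inv2s2);
            sw += w;
            sx += w * P(j, 0);
            sy += w * P(j, 1);
            sz += w * P(j, 2);
          }
        }
    if (sw > 0) { out(i, 0) = sx / sw; out(i, 1) = sy / sw; out(i, 2) = sz / sw; }
    else        { out(i, 0) = qx;      out(i, 1) = qy;      out(i, 2) = qz; }
  }
  return out;
}
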