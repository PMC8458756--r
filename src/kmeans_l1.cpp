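#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// L1 (Manhattan) distances from every row of X to every centroid row.
// [[Rcpp::export(name = ".l1_distances")]]
NumericMatrix l1_distances(const NumericMatrix& X, const NumericMatrix& C) {
  const int n = X.nrow(), d = X.ncol(), k = C.nrow();
  if (C.ncol() != d) stop("dimension mismatch between points and centroids");
  NumericMatrix D(n, k);
  const double* xp = X.begin();
  const double* cp = C.begin();
  double* dp = D.begin();
  for (int j = 0; j < k; ++j) {
    double* dcol = dp + (size_t)j * n;
    for (int c = 0; c < d; ++c) {
      const double cv = cp[(size_t)c * k + j];
      const double* xcol = xp + (size_t)c * n;
      for (int i = 0; i < n; ++i) {
        dcol[i] += std::fabs(xcol[i] - cv);
      }
    }
  }
  return D;
}

static void assign_nearest(const NumericMatrix& D, IntegerVector& lab,
                           NumericVector& dist) {
  const int n = D.nrow(), k = D.ncol();
  for (int i = 0; i < n; ++i) {
    int best = 0;
    double bd = D(i, 0);
    for (int j = 1; j < k; ++j) {
      if (D(i, j) < bd) { bd = D(i, j); best = j; }  // ties -> lowest id
    }
    lab[i] = best;
    dist[i] = bd;
  }
}

static double column_median(std::vector<double>& v) {
  const size_t n = v.size();
  const size_t mid = n / 2;
  std::nth_element(v.begin(), v.begin() + mid, v.end());
  double hi = v[mid];
  if (n % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + mid - 1, v.begin() + mid);
  return 0.5 * (v[mid - 1] + hi);  // even count: midpoint of the two middles
}

// One restart of Lloyd-style k-means under L1 distance: assignment to the
// nearest centroid, component-wise median update (the exact L1 minimizer),
// empty clusters reseeded with the point farthest from its centroid.
// init: 0-based row indices of the initial centroids.
// [[Rcpp::export(name = ".kmeans_l1_restart")]]
List kmeans_l1_restart(const NumericMatrix& X, const IntegerVector& init,
                       int max_iter) {
  const int n = X.nrow(), d = X.ncol(), k = init.size();
  NumericMatrix C(k, d);
  for (int j = 0; j < k; ++j) {
    for (int c = 0; c < d; ++c) C(j, c) = X(init[j], c);
  }
  IntegerVector lab(n), prev(n, -1);
  NumericVector dist(n);
  std::vector<double> objective_trace;
  int iter = 0;
  std::vector<double> members;
  members.reserve(n);
  for (iter = 0; iter < max_iter; ++iter) {
    NumericMatrix D = l1_distances(X, C);
    assign_nearest(D, lab, dist);

    // reseed empty clusters with the farthest-from-centroid point
    bool reseeded = true;
    while (reseeded) {
      reseeded = false;
      std::vector<int> count(k, 0);
      for (int i = 0; i < n; ++i) count[lab[i]]++;
      for (int j = 0; j < k; ++j) {
        if (count[j] == 0) {
          int far = 0;
          double fd = -1.0;
          for (int i = 0; i < n; ++i) {
            if (dist[i] > fd) { fd = dist[i]; far = i; }
          }
          lab[far] = j;
          dist[far] = 0.0;
          reseeded = true;
        }
      }
    }

    double obj = 0.0;
    for (int i = 0; i < n; ++i) obj += dist[i];
    objective_trace.push_back(obj);

    bool changed = false;
    for (int i = 0; i < n; ++i) {
      if (lab[i] != prev[i]) { changed = true; break; }
    }
    if (!changed) break;
    prev = clone(lab);

    // column-major sweep: one contiguous pass over each column, gathering
    // members per cluster, then the component-wise median
    std::vector<std::vector<double>> bufs(k);
    for (int j = 0; j < k; ++j) bufs[j].reserve(n / k + 16);
    const double* xp = X.begin();
    const int* lp = lab.begin();
    for (int c = 0; c < d; ++c) {
      for (int j = 0; j < k; ++j) bufs[j].clear();
      const double* xcol = xp + (size_t)c * n;
      for (int i = 0; i < n; ++i) bufs[lp[i]].push_back(xcol[i]);
      for (int j = 0; j < k; ++j) {
        if (!bufs[j].empty()) C(j, c) = column_median(bufs[j]);
      }
    }
  }

  // final objective against the final centroids
  NumericMatrix D = l1_distances(X, C);
  assign_nearest(D, lab, dist);
  double obj = 0.0;
  for (int i = 0; i < n; ++i) obj += dist[i];

  return List::create(_["centroids"] = C,
                      _["labels"] = lab + 1,
                      _["objective"] = obj,
                      _["objective_trace"] = NumericVector(objective_trace.begin(),
                                                           objective_trace.end()),
                      _["iterations"] = iter + 1);
}
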