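#include <Rcpp.h>
using namespace Rcpp;

// Pairwise allele-fraction distances restricted to k nearest neighbours.
//
// af:  sites x cells matrix of allele fractions (arbitrary where uncovered)
// cov: sites x cells 0/1 coverage mask
// The distance between two cells is the mean |af_a - af_b| over sites covered
// in BOTH cells; it is undefined (no edge candidate) when the shared-site
// count is below min_shared.
//
// Returns k x n matrices of 1-based neighbour indices (0 = no neighbour) and
// distances (NA where absent). Ties in distance are broken by lower cell
// index, making the graph deterministic.
// [[Rcpp::export(name = ".knn_af_distance")]]
List knn_af_distance(NumericMatrix af, NumericMatrix cov, int k, int min_shared) {
  const int S = af.nrow(), N = af.ncol();
  if (cov.nrow() != S || cov.ncol() != N)
    stop("af and cov dimensions differ");
  if (k < 1) stop("k must be >= 1");

  IntegerMatrix nn_idx(k, N);
  NumericMatrix nn_dist(k, N);
  std::fill(nn_idx.begin(), nn_idx.end(), 0);
  std::fill(nn_dist.begin(), nn_dist.end(), NA_REAL);

  // per-cell bounded insertion sort of (dist, idx)
  std::vector<std::vector<std::pair<double,int> > > best(N);
  for (int i = 0; i < N; ++i) best[i].reserve(k + 1);

  const double* A = REAL(af);
  const double* C = REAL(cov);

  for (int a = 0; a < N; ++a) {
    const double* afa = A + (size_t)a * S;
    const double* cva = C + (size_t)a * S;
    for (int b = a + 1; b < N; ++b) {
      const double* afb = A + (size_t)b * S;
      const double* cvb = C + (size_t)b * S;
      double sum = 0.0; int shared = 0;
      for (int s = 0; s < S; ++s) {
        if (cva[s] > 0 && cvb[s] > 0) {
          ++shared;
          double d = afa[s] - afb[s];
          sum += d < 0 ? -d : d;
        }
      }
      if (shared < min_shared) continue;
      double dist = sum / shared;
      for (int cell = 0; cell < 2; ++cell) {
        int self = cell ? b : a, other = cell ? a : b;
        std::vector<std::pair<double,int> >& v = best[self];
        std::pair<double,int> item(dist, other);
        if ((int)v.size() < k) {
          v.push_back(item);
          std::push_heap(v.begin(), v.end());
        } else if (item < v.front()) {
          std::pop_heap(v.begin(), v.end());
          v.back() = item;
          std::push_heap(v.begin(), v.end());
        }
      }
    }
    if (a % 256 == 0) Rcpp::checkUserInterrupt();
  }

  for (int i = 0; i < N; ++i) {
    std::sort(best[i].begin(), best[i].end());
    for (size_t j = 0; j < best[i].size(); ++j) {
      nn_idx(j, i) = best[i][j].second + 1;  // 1-based for R
      nn_dist(j, i) = best[i][j].first;
    }
  }
  return List::create(_["idx"] = nn_idx, _["dist"] = nn_dist);
}
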