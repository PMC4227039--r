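#include <Rcpp.h>
#include <queue>
#include <unordered_set>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// One element of the strictly-decreasing index lattice over the sorted
// candidate order. Positions are 1-based into the sorted order; k == 0 for
// two-sphere elements. priority is the sum of the per-sphere coverages, an
// upper bound on the union coverage that is exact for admissible
// (non-overlapping, non-tangent) configurations.
struct Elem {
  double pri;
  int i, j, k;
};

struct ElemLess {
  // max-heap on priority; ties pop the lexicographically smallest tuple
  bool operator()(const Elem &a, const Elem &b) const {
    if (a.pri != b.pri) return a.pri < b.pri;
    if (a.i != b.i) return a.i > b.i;
    if (a.j != b.j) return a.j > b.j;
    return a.k > b.k;
  }
};

static inline long long encode(int i, int j, int k, long long m) {
  return ((long long)i * m + j) * m + k;
}

static double union_cover(const std::vector<int> &centers,
                          const std::vector<std::vector<int> > &nb,
                          const NumericVector &counts,
                          std::vector<char> &seen) {
  std::fill(seen.begin(), seen.end(), 0);
  double tot = 0.0;
  for (size_t c = 0; c < centers.size(); ++c) {
    const std::vector<int> &v = nb[centers[c]];
    for (size_t t = 0; t < v.size(); ++t) {
      if (!seen[v[t]]) { seen[v[t]] = 1; tot += counts[v[t]]; }
    }
  }
  return tot;
}

// Best-first search for the s non-overlapping spheres (centers at residue
// alpha-carbons, common radius r) maximizing covered mutation occurrences.
//
// counts:  per-residue mutation occurrences (length N, residue order)
// nb:      per-residue neighborhood at radius r (1-based residue indices,
//          includes the residue itself)
// dmat:    N x N alpha-carbon distance matrix (Angstrom)
// s:       number of spheres (1, 2 or 3)
// enumerate_only: traverse the lattice in priority order without the
//          non-overlap acceptance test (used to inspect traversal order);
//          max_pops bounds the number of popped elements.
//
// Returns feasible flag, centers (ascending residue indices), covered union
// count, the popped priorities in pop order, and the popped tuples.
// [[Rcpp::export(name = ".sphere_search_cpp")]]
List sphere_search_cpp(NumericVector counts, List nb, NumericMatrix dmat,
                       double r, int s, bool enumerate_only = false,
                       int max_pops = -1) {
  const int N = counts.size();
  if (s < 1) stop("s must be >= 1");
  if ((int)nb.size() != N) stop("neighborhood list length != counts length");

  // neighborhoods to 0-based vectors
  std::vector<std::vector<int> > nbv(N);
  for (int i = 0; i < N; ++i) {
    IntegerVector v = nb[i];
    nbv[i].resize(v.size());
    for (int t = 0; t < v.size(); ++t) nbv[i][t] = v[t] - 1;
  }

  // per-candidate coverage and sorted order (coverage desc, index asc)
  std::vector<double> cov(N);
  for (int i = 0; i < N; ++i) {
    double tot = 0.0;
    for (size_t t = 0; t < nbv[i].size(); ++t) tot += counts[nbv[i][t]];
    cov[i] = tot;
  }
  std::vector<int> ord(N);
  for (int i = 0; i < N; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (cov[a] != cov[b]) return cov[a] > cov[b];
    return a < b;
  });

  NumericVector covOut(N);
  IntegerVector ordOut(N);
  for (int i = 0; i < N; ++i) { covOut[i] = cov[i]; ordOut[i] = ord[i] + 1; }

  std::vector<char> seen(N, 0);
  std::vector<double> pops;
  std::vector<int> popTuples;
  const double tol = 1e-9;

  if (s == 1 && !enumerate_only) {
    int best = ord[0];
    std::vector<int> centers(1, best);
    double covered = union_cover(centers, nbv, counts, seen);
    pops.push_back(cov[best]);
    popTuples.push_back(1); popTuples.push_back(0); popTuples.push_back(0);
    return List::create(_["feasible"] = true,
                        _["centers"] = IntegerVector::create(best + 1),
                        _["covered"] = covered,
                        _["npops"] = 1,
                        _["pops"] = wrap(pops),
                        _["tuples"] = wrap(popTuples),
                        _["cov"] = covOut, _["order"] = ordOut);
  }

  if (N < s) {
    return List::create(_["feasible"] = false,
                        _["centers"] = IntegerVector(0),
                        _["covered"] = NA_REAL,
                        _["npops"] = 0,
                        _["pops"] = NumericVector(0),
                        _["tuples"] = IntegerVector(0),
                        _["cov"] = covOut, _["order"] = ordOut);
  }

  std::priority_queue<Elem, std::vector<Elem>, ElemLess> heap;
  std::unordered_set<long long> visited;
  const long long m = N + 2;

  auto pushElem = [&](int i, int j, int k) {
    long long code = encode(i, j, k, m);
    if (visited.count(code)) return;
    visited.insert(code);
    double p = cov[ord[i - 1]] + cov[ord[j - 1]];
    if (k > 0) p += cov[ord[k - 1]];
    heap.push(Elem{p, i, j, k});
  };

  if (s == 1) {
    // enumerate_only for a single sphere: pop candidates in sorted order
    int lim = (max_pops > 0) ? std::min(max_pops, N) : N;
    for (int t = 0; t < lim; ++t) {
      pops.push_back(cov[ord[t]]);
      popTuples.push_back(t + 1); popTuples.push_back(0); popTuples.push_back(0);
    }
    return List::create(_["feasible"] = false, _["centers"] = IntegerVector(0),
                        _["covered"] = NA_REAL, _["npops"] = (int)pops.size(),
                        _["pops"] = wrap(pops), _["tuples"] = wrap(popTuples),
                        _["cov"] = covOut, _["order"] = ordOut);
  } else if (s == 2) {
    pushElem(2, 1, 0);
  } else if (s == 3) {
    pushElem(3, 2, 1);
  } else {
    stop("s > 3 is not supported by the search kernel");
  }

  double lastPri = R_PosInf;
  int npops = 0;
  while (!heap.empty()) {
    if (max_pops > 0 && npops >= max_pops) break;
    Elem e = heap.top(); heap.pop();
    ++npops;
    if (e.pri > lastPri + tol)
      stop("internal error: popped priorities not non-increasing");
    lastPri = e.pri;
    pops.push_back(e.pri);
    popTuples.push_back(e.i); popTuples.push_back(e.j); popTuples.push_back(e.k);

    if (!enumerate_only) {
      std::vector<int> centers;
      centers.push_back(ord[e.i - 1]);
      centers.push_back(ord[e.j - 1]);
      if (s == 3) centers.push_back(ord[e.k - 1]);
      bool ok = true;
      for (size_t a = 0; a < centers.size() && ok; ++a)
        for (size_t b = a + 1; b < centers.size() && ok; ++b)
          if (dmat(centers[a], centers[b]) < 2.0 * r - tol) ok = false;
      if (ok) {
        double covered = union_cover(centers, nbv, counts, seen);
        std::sort(centers.begin(), centers.end());
        IntegerVector cOut(centers.size());
        for (size_t a = 0; a < centers.size(); ++a) cOut[a] = centers[a] + 1;
        return List::create(_["feasible"] = true, _["centers"] = cOut,
                            _["covered"] = covered, _["npops"] = npops,
                            _["pops"] = wrap(pops),
                            _["tuples"] = wrap(popTuples),
                            _["cov"] = covOut, _["order"] = ordOut);
      }
    }

    // lattice successors: each coordinate advanced by one where the
    // strictly-decreasing constraint allows
    if (e.i + 1 <= N) pushElem(e.i + 1, e.j, e.k);
    if (e.j + 1 < e.i) pushElem(e.i, e.j + 1, e.k);
    if (e.k > 0 && e.k + 1 < e.j) pushElem(e.i, e.j, e.k + 1);
  }

  return List::create(_["feasible"] = false, _["centers"] = IntegerVector(0),
                      _["covered"] = NA_REAL, _["npops"] = npops,
                      _["pops"] = wrap(pops), _["tuples"] = wrap(popTuples),
                      _["cov"] = covOut, _["order"] = ordOut);
}
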