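#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// All kernels operate on a 3-D integer array of discretized grey levels
// (1..ng inside the ROI, 0 outside). Direction sets are passed from R as an
// n x 3 integer matrix of lattice offsets so tests can restrict to a single
// direction. Dimensions are taken from the "dim" attribute.

static inline int lin(int i, int j, int k, int n1, int n2) {
  return i + n1 * (j + n2 * k);
}

// Pooled symmetric co-occurrence counts over the given directions.
// [[Rcpp::export]]
NumericMatrix cpp_glcm_counts(IntegerVector levels, int ng, IntegerMatrix dirs) {
  IntegerVector dm = levels.attr("dim");
  int n1 = dm[0], n2 = dm[1], n3 = dm[2];
  NumericMatrix out(ng, ng);
  for (int d = 0; d < dirs.nrow(); ++d) {
    int dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          int a = levels[lin(i, j, k, n1, n2)];
          if (a == 0) continue;
          int ii = i + dx, jj = j + dy, kk = k + dz;
          if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
            continue;
          int b = levels[lin(ii, jj, kk, n1, n2)];
          if (b == 0) continue;
          // symmetric accumulation: count the pair in both orientations
          out(a - 1, b - 1) += 1.0;
          out(b - 1, a - 1) += 1.0;
        }
  }
  return out;
}

// Run-length counts pooled over directions. A run is a maximal collinear
// streak of equal level; background voxels break runs.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm_counts(IntegerVector levels, int ng, IntegerMatrix dirs) {
  IntegerVector dm = levels.attr("dim");
  int n1 = dm[0], n2 = dm[1], n3 = dm[2];
  int maxdim = std::max(n1, std::max(n2, n3));
  // runs cannot exceed the longest diagonal: bound by total voxel count
  NumericMatrix out(ng, maxdim);
  for (int d = 0; d < dirs.nrow(); ++d) {
    int dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          int a = levels[lin(i, j, k, n1, n2)];
          if (a == 0) continue;
          // run starts here iff predecessor along -d is absent or different
          int pi = i - dx, pj = j - dy, pk = k - dz;
          if (pi >= 0 && pi < n1 && pj >= 0 && pj < n2 && pk >= 0 && pk < n3 &&
              levels[lin(pi, pj, pk, n1, n2)] == a)
            continue;
          int len = 1;
          int ci = i + dx, cj = j + dy, ck = k + dz;
          while (ci >= 0 && ci < n1 && cj >= 0 && cj < n2 && ck >= 0 &&
                 ck < n3 && levels[lin(ci, cj, ck, n1, n2)] == a) {
            ++len;
            ci += dx; cj += dy; ck += dz;
          }
          if (len > out.ncol()) stop("run length exceeds matrix bound");
          out(a - 1, len - 1) += 1.0;
        }
  }
  return out;
}

// Per-level neighbourhood absolute-difference sums s(i) and level counts
// N(i) against the 26-neighbourhood restricted to in-ROI voxels.
// [[Rcpp::export]]
List cpp_ngldm_sums(IntegerVector levels, int ng) {
  IntegerVector dm = levels.attr("dim");
  int n1 = dm[0], n2 = dm[1], n3 = dm[2];
  NumericVector s(ng);
  NumericVector cnt(ng);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int a = levels[lin(i, j, k, n1, n2)];
        if (a == 0) continue;
        double sum = 0.0;
        int nn = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int ii = i + dx, jj = j + dy, kk = k + dz;
              if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 ||
                  kk >= n3)
                continue;
              int b = levels[lin(ii, jj, kk, n1, n2)];
              if (b == 0) continue;
              sum += b;
              ++nn;
            }
        cnt[a - 1] += 1.0;
        if (nn > 0) s[a - 1] += std::abs((double)a - sum / nn);
      }
  return List::create(_["s"] = s, _["count"] = cnt);
}

// Zone (26-connected equal-level component) sizes: returns a two-column
// matrix (level, size), one row per zone.
// [[Rcpp::export]]
IntegerMatrix cpp_glzlm_zones(IntegerVector levels, int ng) {
  IntegerVector dm = levels.attr("dim");
  int n1 = dm[0], n2 = dm[1], n3 = dm[2];
  int n = n1 * n2 * n3;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, stack;
  for (int start = 0; start < n; ++start) {
    int a = levels[start];
    if (a == 0 || seen[start]) continue;
    int size = 0;
    stack.clear();
    stack.push_back(start);
    seen[start] = 1;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      ++size;
      int ci = cur % n1, cj = (cur / n1) % n2, ck = cur / (n1 * n2);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int ii = ci + dx, jj = cj + dy, kk = ck + dz;
            if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 ||
                kk >= n3)
              continue;
            int idx = lin(ii, jj, kk, n1, n2);
            if (!seen[idx] && levels[idx] == a) {
              seen[idx] = 1;
              stack.push_back(idx);
            }
          }
    }
    zl.push_back(a);
    zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t r = 0; r < zl.size(); ++r) {
    out(r, 0) = zl[r];
    out(r, 1) = zs[r];
  }
  return out;
}
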