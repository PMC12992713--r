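// Gray-level texture matrix kernels. Levels arrays hold 0 outside the ROI
// and 1..Ng inside; all neighborhoods are distance-1 (Chebyshev), i.e.
// 26-connectivity in 3D.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// The 13 unique 3D direction vectors (half of the 26 neighbors).
static const int DIRS13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// [[Rcpp::export(name = ".cpp_directions13")]]
IntegerMatrix cpp_directions13() {
  IntegerMatrix d(13, 3);
  for (int r = 0; r < 13; ++r)
    for (int c = 0; c < 3; ++c) d(r, c) = DIRS13[r][c];
  return d;
}

// Connected-component labeling of a binary mask (flood fill).
// connectivity: 6 or 26.
// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dims,
                          int connectivity = 26) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int v = lin(i, j, k, nx, ny);
        if (!mask[v] || labels[v]) continue;
        labels[v] = ++next;
        stack.clear();
        stack.push_back(v);
        while (!stack.empty()) {
          const int c = stack.back();
          stack.pop_back();
          const int ci = c % nx, cj = (c / nx) % ny, ck = c / (nx * ny);
          for (int dk = -1; dk <= 1; ++dk)
            for (int dj = -1; dj <= 1; ++dj)
              for (int di = -1; di <= 1; ++di) {
                if (!di && !dj && !dk) continue;
                if (connectivity == 6 &&
                    std::abs(di) + std::abs(dj) + std::abs(dk) != 1) continue;
                const int ii = ci + di, jj = cj + dj, kk = ck + dk;
                if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                  continue;
                const int w = lin(ii, jj, kk, nx, ny);
                if (mask[w] && !labels[w]) {
                  labels[w] = next;
                  stack.push_back(w);
                }
              }
        }
      }
  labels.attr("n_components") = next;
  return labels;
}

// Symmetric co-occurrence counts at distance 1 for the 13 unique
// directions. Returns an Ng x Ng x 13 array.
// [[Rcpp::export(name = ".cpp_glcm")]]
NumericVector cpp_glcm(IntegerVector levels, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(ng * ng * 13);
  for (int d = 0; d < 13; ++d) {
    const int di = DIRS13[d][0], dj = DIRS13[d][1], dk = DIRS13[d][2];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const int a = levels[lin(i, j, k, nx, ny)];
          if (!a) continue;
          const int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          const int b = levels[lin(ii, jj, kk, nx, ny)];
          if (!b) continue;
          out[(a - 1) + ng * (b - 1) + ng * ng * d] += 1;
          out[(b - 1) + ng * (a - 1) + ng * ng * d] += 1;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// Run-length counts per direction: Ng x maxRun x 13. A run is a maximal
// straight sequence of in-ROI voxels sharing one gray level; out-of-ROI
// voxels break runs.
// [[Rcpp::export(name = ".cpp_glrlm")]]
NumericVector cpp_glrlm(IntegerVector levels, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int ng = 0;
  for (int v = 0; v < nx * ny * nz; ++v) ng = std::max(ng, (int)levels[v]);
  const int maxr = std::max(std::max(nx, ny), nz);
  NumericVector out(ng * maxr * 13);
  for (int d = 0; d < 13; ++d) {
    const int di = DIRS13[d][0], dj = DIRS13[d][1], dk = DIRS13[d][2];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const int a = levels[lin(i, j, k, nx, ny)];
          if (!a) continue;
          // start of a run? predecessor must be outside grid/ROI or differ
          const int pi = i - di, pj = j - dj, pk = k - dk;
          if (pi >= 0 && pj >= 0 && pk >= 0 && pi < nx && pj < ny && pk < nz &&
              levels[lin(pi, pj, pk, nx, ny)] == a)
            continue;
          int len = 1, ii = i + di, jj = j + dj, kk = k + dk;
          while (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz &&
                 levels[lin(ii, jj, kk, nx, ny)] == a) {
            ++len;
            ii += di; jj += dj; kk += dk;
          }
          out[(a - 1) + ng * (len - 1) + ng * maxr * d] += 1;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxr, 13);
  return out;
}

// Dependence counts: P(i, j) = number of ROI voxels with level i whose
// dependence is j = 1 + #{26-neighbors in ROI with |level diff| <= alpha}.
// [[Rcpp::export(name = ".cpp_gldm")]]
NumericMatrix cpp_gldm(IntegerVector levels, IntegerVector dims, int ng,
                       int alpha = 0) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 27);  // dependence can be at most 1 + 26
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int a = levels[lin(i, j, k, nx, ny)];
        if (!a) continue;
        int dep = 1;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (!di && !dj && !dk) continue;
              const int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              const int b = levels[lin(ii, jj, kk, nx, ny)];
              if (b && std::abs(a - b) <= alpha) ++dep;
            }
        out(a - 1, dep - 1) += 1;
      }
  return out;
}

// NGTDM accumulators: per level i, n_i = count of ROI voxels at level i
// having at least one in-ROI neighbor, s_i = sum over those voxels of
// |i - mean level of their in-ROI 26-neighbors|.
// [[Rcpp::export(name = ".cpp_ngtdm")]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 2);  // columns: n_i, s_i
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int a = levels[lin(i, j, k, nx, ny)];
        if (!a) continue;
        double sum = 0;
        int cnt = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (!di && !dj && !dk) continue;
              const int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              const int b = levels[lin(ii, jj, kk, nx, ny)];
              if (b) { sum += b; ++cnt; }
            }
        if (cnt > 0) {
          out(a - 1, 0) += 1;
          out(a - 1, 1) += std::fabs(a - sum / cnt);
        }
      }
  return out;
}

// Zone-size counts: zones are 26-connected components of constant gray
// level. Returns Ng x maxZone counts.
// [[Rcpp::export(name = ".cpp_glszm")]]
NumericMatrix cpp_glszm(IntegerVector levels, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> stack;
  std::vector<std::pair<int, int> > zones;  // (level, size)
  int maxzone = 1;
  for (int v = 0; v < n; ++v) {
    const int a = levels[v];
    if (!a || seen[v]) continue;
    int size = 0;
    seen[v] = 1;
    stack.clear();
    stack.push_back(v);
    while (!stack.empty()) {
      const int c = stack.back();
      stack.pop_back();
      ++size;
      const int ci = c % nx, cj = (c / nx) % ny, ck = c / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            const int ii = ci + di, jj = cj + dj, kk = ck + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            const int w = lin(ii, jj, kk, nx, ny);
            if (!seen[w] && levels[w] == a) {
              seen[w] = 1;
              stack.push_back(w);
            }
          }
    }
    zones.push_back(std::make_pair(a, size));
    maxzone = std::max(maxzone, size);
  }
  NumericMatrix out(ng, maxzone);
  for (size_t z = 0; z < zones.size(); ++z)
    out(zones[z].first - 1, zones[z].second - 1) += 1;
  return out;
}
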