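#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimum-image displacement for an orthorhombic box.
static inline double mi(double d, double L) {
  return d - L * std::round(d / L);
}

static inline double dist2_mi(const double* a, const double* b,
                              const double* box) {
  double s = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = mi(a[k] - b[k], box[k]);
    s += d * d;
  }
  return s;
}

// All unordered pairs (i < j, 1-based) within `cutoff` under PBC.
// Brute-force path doubles as the oracle for the cell-list path.
// [[Rcpp::export]]
IntegerMatrix cpp_pairs_within(NumericMatrix coords, NumericVector box,
                               double cutoff, bool brute = false) {
  const int n = coords.nrow();
  const double c2 = cutoff * cutoff;
  double bx[3] = {box[0], box[1], box[2]};
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) P[3 * i + k] = coords(i, k);

  int nc[3];
  for (int k = 0; k < 3; ++k) nc[k] = (int)std::floor(bx[k] / cutoff);
  bool cells_ok = !brute && nc[0] >= 3 && nc[1] >= 3 && nc[2] >= 3 && n > 200;

  std::vector<int> out_i, out_j;
  if (!cells_ok) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (dist2_mi(&P[3 * i], &P[3 * j], bx) < c2) {
          out_i.push_back(i + 1); out_j.push_back(j + 1);
        }
  } else {
    const int ncx = nc[0], ncy = nc[1], ncz = nc[2];
    const int ncell = ncx * ncy * ncz;
    std::vector<int> headc(ncell, -1), nxt(n, -1), cellof(n);
    for (int i = 0; i < n; ++i) {
      double fx = P[3 * i] / bx[0];     fx -= std::floor(fx);
      double fy = P[3 * i + 1] / bx[1]; fy -= std::floor(fy);
      double fz = P[3 * i + 2] / bx[2]; fz -= std::floor(fz);
      int cx = (int)(fx * ncx); if (cx >= ncx) cx = ncx - 1;
      int cy = (int)(fy * ncy); if (cy >= ncy) cy = ncy - 1;
      int cz = (int)(fz * ncz); if (cz >= ncz) cz = ncz - 1;
      int c = (cz * ncy + cy) * ncx + cx;
      cellof[i] = c; nxt[i] = headc[c]; headc[c] = i;
    }
    for (int cz = 0; cz < ncz; ++cz)
      for (int cy = 0; cy < ncy; ++cy)
        for (int cx = 0; cx < ncx; ++cx) {
          int c = (cz * ncy + cy) * ncx + cx;
          // within-cell pairs
          for (int i = headc[c]; i != -1; i = nxt[i])
            for (int j = nxt[i]; j != -1; j = nxt[j])
              if (dist2_mi(&P[3 * i], &P[3 * j], bx) < c2) {
                int a = std::min(i, j) + 1, b = std::max(i, j) + 1;
                out_i.push_back(a); out_j.push_back(b);
              }
          // 13 half-shell neighbor cells
          static const int off[13][3] = {
            {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
            {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
          for (int o = 0; o < 13; ++o) {
            int nx = (cx + off[o][0] + ncx) % ncx;
            int ny = (cy + off[o][1] + ncy) % ncy;
            int nz2 = (cz + off[o][2] + ncz) % ncz;
            int c2i = (nz2 * ncy + ny) * ncx + nx;
            if (c2i == c) continue;
            for (int i = headc[c]; i != -1; i = nxt[i])
              for (int j = headc[c2i]; j != -1; j = nxt[j])
                if (dist2_mi(&P[3 * i], &P[3 * j], bx) < c2) {
                  int a = std::min(i, j) + 1, b = std::max(i, j) + 1;
                  out_i.push_back(a); out_j.push_back(b);
                }
          }
        }
  }
  const int m = out_i.size();
  IntegerMatrix res(m, 2);
  for (int p = 0; p < m; ++p) { res(p, 0) = out_i[p]; res(p, 1) = out_j[p]; }
  return res;
}

// Histogram of minimum-image A-B distances in [0, rmax), nbins equal bins.
// idA/idB identify beads so shared beads between selections are not paired
// with themselves.
// [[Rcpp::export]]
NumericVector cpp_cross_histogram(NumericMatrix A, NumericMatrix B,
                                  IntegerVector idA, IntegerVector idB,
                                  NumericVector box, double rmax, int nbins) {
  const int na = A.nrow(), nb = B.nrow();
  double bx[3] = {box[0], box[1], box[2]};
  NumericVector h(nbins);
  const double r2max = rmax * rmax;
  const double w = rmax / nbins;
  std::vector<double> PA(3 * na), PB(3 * nb);
  for (int i = 0; i < na; ++i)
    for (int k = 0; k < 3; ++k) PA[3 * i + k] = A(i, k);
  for (int j = 0; j < nb; ++j)
    for (int k = 0; k < 3; ++k) PB[3 * j + k] = B(j, k);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      if (idA[i] == idB[j]) continue;
      double d2 = dist2_mi(&PA[3 * i], &PB[3 * j], bx);
      if (d2 < r2max) {
        int b = (int)(std::sqrt(d2) / w);
        if (b >= nbins) b = nbins - 1;
        h[b] += 1.0;
      }
    }
  }
  return h;
}
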