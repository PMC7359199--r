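// Texture-matrix construction for 3D discretized grids.
// Grids arrive as integer arrays in R's column-major layout with grey level
// 0 marking out-of-mask voxels and levels 1..G inside. Feature formulas are
// evaluated in R; only the counting lives here.
#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// The 13 unique 3D directions (distance 1, opposite pairs collapsed).
static const int DIRS[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

static inline int at(const IntegerVector& lv, int nx, int ny, int nz,
                     int x, int y, int z) {
  if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
  return lv[x + nx * (y + ny * z)];
}

// Symmetric grey-level co-occurrence counts, G x G x 13.
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector levels, IntegerVector dim, int G) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(G * (R_xlen_t)G * 13);
  out.attr("dim") = IntegerVector::create(G, G, 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    double* M = &out[(R_xlen_t)d * G * G];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = at(levels, nx, ny, nz, x, y, z);
          if (a == 0) continue;
          int b = at(levels, nx, ny, nz, x + dx, y + dy, z + dz);
          if (b == 0) continue;
          M[(a - 1) + G * (b - 1)] += 1.0;
          M[(b - 1) + G * (a - 1)] += 1.0;
        }
  }
  return out;
}

// Run-length counts, G x Rmax x 13 (Rmax = longest grid extent).
// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector levels, IntegerVector dim, int G) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int rmax = std::max(nx, std::max(ny, nz));
  NumericVector out(G * (R_xlen_t)rmax * 13);
  out.attr("dim") = IntegerVector::create(G, rmax, 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    double* M = &out[(R_xlen_t)d * G * rmax];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = at(levels, nx, ny, nz, x, y, z);
          if (a == 0) continue;
          // start of a run: predecessor along -d differs
          if (at(levels, nx, ny, nz, x - dx, y - dy, z - dz) == a) continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (at(levels, nx, ny, nz, cx, cy, cz) == a) {
            ++len; cx += dx; cy += dy; cz += dz;
          }
          M[(a - 1) + G * (len - 1)] += 1.0;
        }
  }
  return out;
}

// Zones (26-connected equal-level components) with their sizes and their
// minimum city-block distance to the ROI border; returns the size-zone and
// distance-zone matrices. Border distance is 1 for in-mask voxels adjacent
// (6-connectivity) to a voxel outside the mask or outside the grid.
// [[Rcpp::export]]
List cpp_zones(IntegerVector levels, IntegerVector dim, int G) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t N = (R_xlen_t)nx * ny * nz;
  // distance map by BFS from the border
  std::vector<int> dist(N, -1);
  std::queue<int> q;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = x + nx * (y + ny * z);
        if (levels[i] == 0) continue;
        bool border =
          at(levels, nx, ny, nz, x - 1, y, z) == 0 ||
          at(levels, nx, ny, nz, x + 1, y, z) == 0 ||
          at(levels, nx, ny, nz, x, y - 1, z) == 0 ||
          at(levels, nx, ny, nz, x, y + 1, z) == 0 ||
          at(levels, nx, ny, nz, x, y, z - 1) == 0 ||
          at(levels, nx, ny, nz, x, y, z + 1) == 0;
        if (border) { dist[i] = 1; q.push(i); }
      }
  const int step6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty()) {
    int i = q.front(); q.pop();
    int z = i / (nx * ny), y = (i / nx) % ny, x = i % nx;
    for (int s = 0; s < 6; ++s) {
      int xx = x + step6[s][0], yy = y + step6[s][1], zz = z + step6[s][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      int j = xx + nx * (yy + ny * zz);
      if (levels[j] != 0 && dist[j] < 0) { dist[j] = dist[i] + 1; q.push(j); }
    }
  }
  // zones by flood fill over the 26-neighbourhood
  std::vector<char> seen(N, 0);
  std::vector<int> zlev, zsize, zdist;
  std::vector<int> stack;
  for (R_xlen_t start = 0; start < N; ++start) {
    if (levels[start] == 0 || seen[start]) continue;
    int lev = levels[start], size = 0, dmin = INT_MAX;
    stack.clear();
    stack.push_back((int)start);
    seen[start] = 1;
    while (!stack.empty()) {
      int i = stack.back(); stack.pop_back();
      ++size;
      if (dist[i] < dmin) dmin = dist[i];
      int z = i / (nx * ny), y = (i / nx) % ny, x = i % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int j = xx + nx * (yy + ny * zz);
            if (!seen[j] && levels[j] == lev) { seen[j] = 1; stack.push_back(j); }
          }
    }
    zlev.push_back(lev); zsize.push_back(size); zdist.push_back(dmin);
  }
  int smax = 1, dmax = 1;
  for (size_t k = 0; k < zsize.size(); ++k) {
    if (zsize[k] > smax) smax = zsize[k];
    if (zdist[k] > dmax) dmax = zdist[k];
  }
  NumericMatrix szm(G, smax), dzm(G, dmax);
  for (size_t k = 0; k < zsize.size(); ++k) {
    szm(zlev[k] - 1, zsize[k] - 1) += 1.0;
    dzm(zlev[k] - 1, zdist[k] - 1) += 1.0;
  }
  return List::create(_["glszm"] = szm, _["gldzm"] = dzm);
}

// Neighbourhood grey-tone difference ingredients: per level, the number of
// voxels with at least one in-mask 26-neighbour and the summed absolute
// difference between the voxel level and its in-mask neighbourhood mean.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dim, int G) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(G, 2); // n_i, s_i
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = at(levels, nx, ny, nz, x, y, z);
        if (a == 0) continue;
        double sum = 0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int b = at(levels, nx, ny, nz, x + dx, y + dy, z + dz);
              if (b > 0) { sum += b; ++cnt; }
            }
        if (cnt == 0) continue;
        out(a - 1, 0) += 1.0;
        out(a - 1, 1) += std::fabs(a - sum / cnt);
      }
  return out;
}

// Neighbouring grey-level dependence counts (coarseness alpha = 0):
// dependence k = number of in-mask 26-neighbours with the same level;
// matrix indexed (level, k + 1).
// [[Rcpp::export]]
NumericMatrix cpp_ngldm(IntegerVector levels, IntegerVector dim, int G) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(G, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = at(levels, nx, ny, nz, x, y, z);
        if (a == 0) continue;
        int k = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              if (at(levels, nx, ny, nz, x + dx, y + dy, z + dz) == a) ++k;
            }
        out(a - 1, k) += 1.0;
      }
  return out;
}
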